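---
title: "Ecological distance on dendritic river networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological distance on dendritic river networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
behind each stage, the assumptions they lean on, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open. Code chunks illustrate usage and
are not evaluated at build time; every empirical statement below is one
the test suite or `scripts/acceptance.R` computes.

## 1. The riverscape model

A landscape is a gridded DEM (matrix, row 1 = north, cell size in
metres; 100 m is the working resolution throughout). Three operations
turn it into an analyzable network:

* **Depression filling** raises interior sinks to a minimally drainable
  surface by iterative inundation: every cell relaxes to
  `max(ground, min(neighbour + eps))` until stable. `eps` (default
  `1e-6` m, scaled by `sqrt(2)` on diagonals) doubles as the flat
  resolver: after filling, every data cell has a *strictly* descending
  D8 path to the boundary, so steepest-descent routing is unambiguous.
  Elevations are only raised, never lowered, and filling an
  already-drainable surface is the identity.
* **D8 routing** sends each cell to the steepest of its eight
  neighbours (drop over distance, diagonal distance `sqrt(2)` cells).
  Ties are broken by the fixed precedence E, SE, S, SW, W, NW, N, NE —
  an arbitrary but documented rule whose only job is determinism.
  Accumulation counts the cell plus everything draining into it.
* **Channel extraction** keeps cells with accumulation at or above a
  threshold. There is no universally correct threshold (it sets
  drainage density), so it is a required parameter; 25 cells at 100 m
  resolution gives realistic densities on the synthetic terrain. The
  result is a forest: each cell has at most one downstream neighbour,
  and elevation strictly decreases along links — the class validity
  check enforces exactly this, which is what makes between-site paths
  unique.

Paths are cell sequences, not lengths. `pathBetween(a, b)` descends
from both endpoints to their lowest common downstream cell; endpoints
and the junction appear exactly once. This convention makes the chain
identity `d(a, c) = d(a, b) + d(b, c) - cost(b)` exact for any waypoint
`b` on the path, and the tests assert it to machine precision.

## 2. Habitat suitability

The presence/absence model is a random-forest classifier with 5,000
trees and 2 candidate predictors per split — deliberately heavy for
four predictors and a few hundred sites, so that out-of-bag (OOB)
probability estimates and partial-dependence curves are stable across
refits.

**Prevalence-matched cutoff.** The threshold `tau` is chosen so that
the predicted prevalence (sites with OOB presence probability at or
above `tau`) equals the observed prevalence. With `m = round(prev * n)`
any threshold between the `(m+1)`-th and `m`-th largest OOB
probabilities achieves this exactly; `tau` is the **midpoint** of that
interval. The choice of representative matters more than it looks:
when the forest separates classes well, the OOB distribution is bimodal
and the interval is wide; taking its upper end biases `tau` high enough
to clip response curves near their maxima (occasionally to an empty
suitability range). The midpoint is the least arbitrary value that
still matches prevalence exactly.

**Response curves and suitability ranges.** The partial-dependence
curve of a variable forces that variable to each grid value in every
training row and averages the predicted presence probability —
marginalizing over the empirical joint distribution of the other
predictors (training-set definition; a 100-point grid over the sampled
range). The suitability range is the convex hull of the super-level set
`{v : curve(v) >= tau}`; a non-contiguous super-level set triggers a
warning but still yields a single interval, because a single interval
per variable is what the downstream cost model consumes. An empty
super-level set is an error, not a silent degenerate interval.

**Known limitation — collinearity.** Partial dependence attributes
marginal effects poorly when predictors are strongly correlated: forced
substitution creates variable combinations the training data never
contained. On synthetic landscapes whose altitude-temperature
correlation reaches r about -0.8, the ALT lower bound can miss the
truth by a quarter of the sampled range even though the joint model
predicts well. This is a property of the response-curve construction,
not of the forest, and it is the main reason suitability-range recovery
is validated on a landscape with realistic (moderate) collinearity.

**Interval overlap.** Agreement between an observed and a predicted
range is `100 * |intersection| / |union|` (interval Jaccard). It is
symmetric, 100 exactly for equal intervals and 0 for disjoint ones, and
it reproduces the published worked values for three of the four habitat
variables at one-decimal precision; for the fourth (RWQ) it gives
96.15%, which rounds to 96.2 against a printed 96.1 — consistent with
the printed inputs themselves being rounded. The formula is asserted
as canonical in the acceptance tests.

## 3. Ecological cost and distance

Each variable is min-max scaled to [0, 1] using network-wide anchors,
and its suitability interval is transformed with the same map (clipped
to [0, 1]). The per-variable cost of a cell is the distance from its
scaled value to the closed scaled interval — zero on the boundary by
construction, matching the inclusive reading of "probability at or
above the threshold". The aggregate ecological cost is the Euclidean
norm of the per-variable costs: geometrically, the distance from the
cell's point in scaled variable space to the suitability
hyper-rectangle. Equal weights are the default (the model's predictors
are of comparable importance); a weight vector exists for sensitivity
analyses but is not part of the standard workflow.

Consequences that the tests exploit:

* costs are invariant under affine transformations of any raw variable
  (the scaling absorbs them);
* `0 <= ecologicalCost <= sqrt(#variables)`, with zero exactly when all
  variables are inside their intervals;
* every ecological distance is bounded by path length times
  `sqrt(#variables)`.

Ecological distance sums the aggregate cost over the unique river path,
each cell counted once (endpoint convention fixed so the chain identity
holds exactly). Cross-basin pairs have no hydrological path and are
reported as missing, never infinite: the analysis is simply silent
about them, and clustering refuses matrices with missing entries rather
than imputing.

## 4. Clustering, delineation, protected areas

Ward clustering runs on squared ecological distances (the `ward.D2`
convention). Ecological distances form a tree metric, not a Euclidean
one, so Ward's variance interpretation is approximate; the convention
is fixed and stated because results differ between `ward.D` and
`ward.D2` on the same matrix. The number of clusters is the user's
choice; `k = "auto"` takes the largest relative gap between successive
merge heights — a mechanical stand-in for visual dendrogram inspection,
always overridable, and degenerating (with a warning) to `k = 1` when
all merge heights are equal.

A cluster's river network is the union over member sites of (i) all
channel cells upstream of the site and (ii) the downstream chain until
the stream joins a larger river carrying no member population:
concretely, the walk stops at the first junction where another inflow
has strictly greater flow accumulation and no member site upstream.
"Strictly greater" decides the ambiguous equal-size confluence in
favour of continuing, which keeps sibling tributaries of one cluster
connected through their shared reach. Connector cells are whatever
remains of the inter-site paths. Protected-area membership is a
cell-centre point-in-polygon test (even-odd rule, holes honoured) —
the natural counterpart of per-cell network assignment; partial-area
coverage is deliberately not modelled.

Cost comparisons (within-cluster versus connector, inside versus
outside protected areas) use the two-sided Mann-Whitney rank-sum test:
exact for tie-free groups of at most 20, tie-corrected normal
approximation otherwise, matching the exact-enumeration oracle for all
small cases in the tests.

## 5. Population-genetic statistics

All estimators are computed from their defining formulas, with missing
genotypes excluded locus-wise:

* **Diversity**: Ho is the heterozygote fraction; He uses the
  small-sample correction `2n/(2n-1) * (1 - sum p^2)` (raw He is also
  reported); `FIS = 1 - Ho/He`, undefined for monomorphic cells.
* **Allelic richness** is rarefaction to `2g` gene copies,
  `sum_a [1 - choose(2n - N_a, 2g)/choose(2n, 2g)]`; it equals the
  observed allele count at `g = n`, is monotone in `g`, and matches
  exhaustive subset enumeration on small cases.
* **FST** is Weir and Cockerham's theta, variance components summed
  across alleles and loci before the ratio. Absolute values from other
  estimators (e.g. Nei-style FST in spreadsheet tools) can differ by a
  few hundredths; theta is stated prominently for that reason.
* **Null alleles** are estimated by EM with the null as an extra
  recessive allele; blanks are treated as null homozygotes, so genuine
  typing failure inflates the estimate — flagged, not hidden.
* **HWE** uses the conditional exact test (Levene's distribution):
  complete enumeration for two alleles, seeded Monte Carlo re-pairings
  otherwise, with a Bonferroni helper for test batteries.
* **Nei's Da** feeds a neighbour-joining tree (via `ape`), with
  bootstrap support from resampling loci.
* **Mantel tests** permute row/column labels jointly; the
  implementation is cross-checked against `vegan::mantel` in the test
  suite, and its null p-values are verified uniform.
* **AMOVA** uses allele-difference counts (0, 1 or 2 per locus) as
  squared inter-individual distances, the standard sums-of-squares
  decomposition with unbalanced-design coefficients, and permutation
  tests (individuals across populations for Phi-ST; whole populations
  across groups for Phi-CT). The distance metric is a documented
  choice — sum-of-squared-size differences would weight microsatellite
  steps differently and is out of scope.

## 6. The synthetic generator: what it emulates, and what it does not

The generator reproduces the *structure* of a real upland survey-and-
genotyping campaign with known ground truth. Defaults are the emulated
study conditions and are not tuning knobs:

* **Terrain**: diamond-square fractal surface plus a southward tilt,
  rescaled to 3-1420 m, on a 96 x 96 grid of 100 m cells (the tests use
  smaller grids where the property under test allows it; the grid size
  is a problem-size choice, stated here once). Channel threshold 25.
* **Variables**: ALT from the conditioned DEM; FFP as local times mean
  catchment slope (m/m); RWQ as the catchment mean of a smoothed
  categorical land-cover impact raster with scores {0, 1, 2, 3} covering
  roughly 40/30/20/10% of the landscape; MMT as a 6.5 degC/km lapse
  surface plus a 2 degC west-east continentality gradient and 1 degC
  interpolation noise. The gradient and noise keep temperature from
  being a deterministic function of altitude (realized ALT-MMT
  correlation about -0.7, typical of coarse climate surfaces resampled
  to DEM resolution) — without them the partial-dependence limitation
  of Section 2 dominates.
* **Surveys**: 274 sites at target prevalence 126/274 with 5% symmetric
  label noise (imperfect detectability). The ground truth is a
  per-variable box at the 10th-80th percentile of each variable.
  Stratified placement draws absences weighted toward the box boundary
  (`exp(-cost/0.3)`): field campaigns target plausible habitat, so most
  true absences are near-misses. This choice also reproduces the
  moderate class overlap seen in real data (realized cutoffs around
  0.35-0.5). Uniform placement is available for sensitivity checks.
* **Genotypes**: frequency-based Wright-Fisher drift, 23 populations,
  5 loci with 8 ancestral alleles (k-allele model, no mutation),
  Ne = 100, 200 generations, 10-66 diploids sampled per population, 1%
  missing data. Migration between populations i and j is
  `0.1 * exp(-lambda * D_ij) / (P - 1)` per generation, the remainder
  staying in place; total flux therefore *decreases* with `lambda`,
  which is what makes mean differentiation provably non-decreasing in
  the decay rate. `lambda = 0.5` matches the realized ecological-
  distance scale of the synthetic riverscapes (median about 2). These
  values reproduce the differentiation regime of real upland crayfish
  microsatellite data: overall theta around 0.17, pairwise values from
  about 0.05 to 0.3, and Mantel correlations near 0.5-0.7.

What the generator does **not** emulate: mutation (irrelevant over 200
generations at microsatellite rates), overland dispersal (the species
model is strictly within-channel), braided or anthropogenically
barriered channels, spatially autocorrelated detection error, and
selection. Passing tests therefore demonstrate that the estimators and
the pipeline recover planted structure under the stated model — not
that the model captures every feature of real riverscapes.

## 7. Numerical choices and degenerate inputs

* Depression-filling epsilon `1e-6` m: large enough to dominate float
  rounding at realistic elevations, small enough to be geographically
  invisible.
* Snap tie-breaks: smallest row, then smallest column. Costs at
  interval boundaries: exactly zero (closed intervals).
* Constant variables scale to zero everywhere (zero cost contribution)
  with a warning rather than an error: a constant layer carries no
  fragmentation information.
* EM convergence at `1e-8` frequency change, capped at 10,000
  iterations with a flag; the confounded all-homozygote single-allele
  case converges slowly toward zero and is flagged as such.
* Permutation p-values use the `(1 + hits)/(1 + permutations)`
  convention, so they are never exactly zero.
* Sub-seeds: every pipeline stage derives its own seed from the master
  seed (`seed * 101 + stage offset`), so stages can be re-run in
  isolation and the whole report is bit-reproducible (asserted by a
  determinism test on serialized reports).

## 8. Known limitations

* Suitability-range recovery inherits the partial-dependence
  collinearity problem (Section 2). At the standard study conditions
  (274 sites, 5% noise) the per-replicate probability that all eight
  recovered bounds fall within 10% of the sampled range is about 0.75 on
  the canonical landscape; the failures are exactly the surveys whose
  OOB distribution pushes the cutoff above ~0.5, near the
  response-curve maxima. Real survey data, whose classes overlap more
  than the synthetic box model's, sit further from this regime.
* Ward on a tree metric is a convention, not a theorem; the automatic k
  is a heuristic and should be inspected like any dendrogram cut.
* The null-allele model cannot separate nulls from genuine typing
  failure; with 1% missing data the inflation is negligible, with much
  more it is not.
* Cross-basin population pairs are outside the model entirely; analyses
  of multi-basin datasets must run per basin.
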