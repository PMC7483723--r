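## Microsatellite population-genetic statistics: diversity, F-statistics,
## null-allele EM, exact HWE tests, Nei's Da / neighbour-joining, Mantel
## tests and hierarchical AMOVA. Estimators are implemented from their
## defining formulas; missing genotypes are excluded locus-wise.

## alleles carried by one population at one locus (non-missing gene copies)
.lociCols <- function(l) c(2L * l - 1L, 2L * l)

.popLocusPairs <- function(table, pop, locus) {
  if (is.character(pop)) pop <- match(pop, table@pops)
  if (is.character(locus)) locus <- match(locus, table@loci)
  g <- table@genotypes[[pop]][, .lociCols(locus), drop = FALSE]
  g[stats::complete.cases(g), , drop = FALSE]
}

## per-locus list of population x allele frequency (or count) matrices,
## over the global allele set observed at the locus
#' Allele frequencies per locus and population
#'
#' Frequencies are computed over non-missing gene copies (locus-wise
#' deletion). Columns span the alleles observed anywhere in the table.
#'
#' @param table a [GenotypeTable-class].
#' @param counts return raw gene-copy counts instead of frequencies.
#' @return list per locus of population x allele matrices.
#' @export
alleleFreqs <- function(table, counts = FALSE) {
  L <- length(table@loci)
  out <- vector("list", L)
  names(out) <- table@loci
  for (l in seq_len(L)) {
    copies <- lapply(seq_along(table@pops), function(p) {
      g <- .popLocusPairs(table, p, l)
      as.vector(g)
    })
    alleles <- sort(unique(unlist(copies)))
    m <- matrix(0, length(table@pops), max(1L, length(alleles)),
                dimnames = list(table@pops,
                                if (length(alleles)) alleles else "1"))
    for (p in seq_along(copies)) {
      tb <- table(factor(copies[[p]], levels = alleles))
      if (length(alleles)) m[p, ] <- as.numeric(tb)
    }
    if (!counts) {
      tot <- rowSums(m)
      m <- m / ifelse(tot == 0, NA, tot)
    }
    out[[l]] <- m
  }
  out
}

#' Per-locus, per-population diversity statistics
#'
#' Observed heterozygosity Ho (fraction of heterozygous individuals),
#' expected heterozygosity He with the small-sample correction
#' \code{2n/(2n-1) * (1 - sum p^2)} (the raw value is reported alongside as
#' \code{HeRaw}), allele counts, and the inbreeding coefficient
#' \code{FIS = 1 - Ho/He} (NA for monomorphic locus-population cells).
#'
#' @param table a [GenotypeTable-class].
#' @return data.frame: pop, locus, n, nAlleles, Ho, HeRaw, He, FIS.
#' @export
diversityStats <- function(table) {
  rows <- list()
  for (p in seq_along(table@pops)) {
    for (l in seq_along(table@loci)) {
      g <- .popLocusPairs(table, p, l)
      n <- nrow(g)
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          pop = table@pops[p], locus = table@loci[l], n = 0L,
          nAlleles = NA_integer_, Ho = NA_real_, HeRaw = NA_real_,
          He = NA_real_, FIS = NA_real_)
        next
      }
      ho <- mean(g[, 1] != g[, 2])
      freq <- table(c(g[, 1], g[, 2])) / (2 * n)
      heRaw <- 1 - sum(freq^2)
      he <- (2 * n / (2 * n - 1)) * heRaw
      rows[[length(rows) + 1L]] <- data.frame(
        pop = table@pops[p], locus = table@loci[l], n = n,
        nAlleles = length(freq), Ho = ho, HeRaw = heRaw, He = he,
        FIS = if (he > 0) 1 - ho / he else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of \code{2g} gene copies, the
#' standard rarefaction that makes allele counts comparable across unequal
#' sample sizes:
#' \code{AR = sum_a [1 - choose(2n - N_a, 2g) / choose(2n, 2g)]}.
#'
#' @param table a [GenotypeTable-class].
#' @param g rarefaction size in diploid individuals; defaults to the
#'   smallest non-missing sample over all locus-population cells. An error
#'   is raised if \code{g} exceeds any cell's sample.
#' @return matrix of AR values, populations x loci.
#' @export
allelicRichness <- function(table, g = NULL) {
  cnts <- alleleFreqs(table, counts = TRUE)
  ns <- sapply(cnts, rowSums) / 2 # pops x loci individuals
  if (is.null(g)) g <- min(ns[ns > 0])
  if (g < 1) stop("rarefaction size must be >= 1")
  if (any(ns > 0 & ns < g))
    stop("rarefaction size ", g, " exceeds the smallest sample (",
         min(ns[ns > 0]), ")")
  out <- matrix(NA_real_, length(table@pops), length(table@loci),
                dimnames = list(table@pops, table@loci))
  for (l in seq_along(table@loci)) {
    cc <- cnts[[l]]
    for (p in seq_len(nrow(cc))) {
      tot <- sum(cc[p, ])
      if (tot == 0) next
      na <- cc[p, cc[p, ] > 0]
      out[p, l] <- sum(1 - exp(lchoose(tot - na, 2 * g) - lchoose(tot, 2 * g)))
    }
  }
  out
}

## Weir & Cockerham variance components for one locus over a set of
## populations; returns c(a, b, c) summed over alleles
.wcLocus <- function(table, pops, locus) {
  stats <- lapply(pops, function(p) {
    g <- .popLocusPairs(table, p, locus)
    g
  })
  n <- vapply(stats, nrow, 1L)
  keep <- n > 0
  stats <- stats[keep]; n <- n[keep]
  r <- length(n)
  if (r < 2 || sum(n) == r) return(c(a = 0, b = 0, c = 0))
  alleles <- sort(unique(unlist(stats)))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  abc <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- vapply(stats, function(g) mean(g == al), 1)
    h_i <- vapply(stats, function(g)
      mean((g[, 1] == al) != (g[, 2] == al)), 1)
    pbar <- sum(n * p_i) / (r * nbar)
    s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    abc <- abc + c(a, b, cc)
  }
  abc
}

## multilocus theta over a set of populations (ratio of summed components)
.wcTheta <- function(table, pops = seq_along(table@pops)) {
  comp <- rowSums(vapply(seq_along(table@loci),
                         function(l) .wcLocus(table, pops, l), numeric(3)))
  if (comp[1] + comp[2] + comp[3] == 0) return(NA_real_)
  unname(comp[1] / sum(comp))
}

#' Pairwise and overall FST (Weir-Cockerham theta)
#'
#' Weir & Cockerham's (1984) theta, combined across loci by summing the
#' among-population, among-individual and within-individual variance
#' components before taking the ratio. Populations with no data at any
#' locus are excluded with a warning.
#'
#' @param table a [GenotypeTable-class].
#' @return list: \code{pairwise} (symmetric matrix, zero diagonal),
#'   \code{overall} (multilocus theta over all populations).
#' @export
pairwiseFst <- function(table) {
  empty <- vapply(seq_along(table@pops), function(p)
    all(is.na(table@genotypes[[p]])), TRUE)
  if (any(empty)) {
    warning("excluding populations with no genotypes: ",
            paste(table@pops[empty], collapse = ", "))
    table <- new("GenotypeTable", loci = table@loci,
                 pops = table@pops[!empty],
                 genotypes = table@genotypes[!empty], trueFreqs = list())
  }
  P <- length(table@pops)
  if (P < 2) stop("need at least 2 populations")
  m <- matrix(0, P, P, dimnames = list(table@pops, table@pops))
  for (i in seq_len(P - 1))
    for (j in (i + 1):P)
      m[i, j] <- m[j, i] <- .wcTheta(table, c(i, j))
  list(pairwise = m, overall = .wcTheta(table))
}

#' Null-allele frequency by expectation-maximization
#'
#' Treats a null allele as an extra recessive allele under Hardy-Weinberg
#' proportions: heterozygotes for a visible and the null allele appear as
#' visible homozygotes, null homozygotes appear as blanks (missing
#' genotypes). The E-step splits each apparent homozygote class between
#' true homozygotes and visible/null heterozygotes in proportion
#' \code{p_i : 2 p_null}; the M-step re-estimates all frequencies from the
#' expected gene-copy counts. Genuinely failed genotypes are
#' indistinguishable from null homozygotes under this model, which inflates
#' the estimate when typing failure is common.
#'
#' @param table a [GenotypeTable-class].
#' @param locus,pop locus and population (name or index).
#' @param tol convergence tolerance on the frequency change.
#' @param maxIter iteration cap; non-convergence flags the estimate.
#' @return list: \code{estimate} (null-allele frequency in [0,1)),
#'   \code{freqs} (visible-allele frequencies), \code{iterations},
#'   \code{converged}, \code{flagged} (non-convergence or a confounded
#'   single-allele case).
#' @export
nullAlleleEM <- function(table, locus, pop, tol = 1e-8, maxIter = 10000L) {
  if (is.character(pop)) pop <- match(pop, table@pops)
  if (is.character(locus)) locus <- match(locus, table@loci)
  g <- table@genotypes[[pop]][, .lociCols(locus), drop = FALSE]
  blank <- !stats::complete.cases(g)
  nB <- sum(blank)
  g <- g[!blank, , drop = FALSE]
  N <- nrow(g) + nB
  if (nrow(g) == 0)
    return(list(estimate = NA_real_, freqs = numeric(0), iterations = 0L,
                converged = FALSE, flagged = TRUE))
  alleles <- sort(unique(as.vector(g)))
  k <- length(alleles)
  het <- g[, 1] != g[, 2]
  hetCopies <- table(factor(as.vector(g[het, , drop = FALSE]),
                            levels = alleles))
  nHom <- table(factor(g[!het, 1], levels = alleles))
  p <- as.numeric(table(factor(as.vector(g), levels = alleles)))
  p <- p / sum(p) * 0.95
  pn <- 0.05
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    w <- p / (p + 2 * pn) # P(true homozygote | apparent homozygote)
    w[p == 0] <- 0
    copies <- as.numeric(hetCopies) + as.numeric(nHom) * (1 + w)
    copiesN <- sum(as.numeric(nHom) * (1 - w)) + 2 * nB
    tot <- 2 * N
    pNew <- copies / tot
    pnNew <- copiesN / tot
    if (max(abs(c(pNew - p, pnNew - pn))) < tol) {
      p <- pNew; pn <- pnNew; converged <- TRUE; break
    }
    p <- pNew; pn <- pnNew
  }
  flagged <- !converged || (k == 1 && all(!het))
  list(estimate = pn, freqs = setNames(p, alleles), iterations = it,
       converged = converged, flagged = flagged)
}

## log conditional probability of a genotype table given its allele counts
## (Levene's distribution, multi-allelic form)
.hweLogProb <- function(pairs) {
  n <- nrow(pairs)
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  genoCounts <- table(key)
  alleleCounts <- table(as.vector(pairs))
  nHet <- sum(pairs[, 1] != pairs[, 2])
  lfactorial(n) - sum(lfactorial(genoCounts)) + nHet * log(2) +
    sum(lfactorial(alleleCounts)) - lfactorial(2 * n)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test: the probability of the observed genotype array
#' given the allele counts (Levene's distribution); the p-value sums the
#' probabilities of arrays no more likely than the observed one. Complete
#' enumeration is used for two alleles with moderate n; otherwise a Monte
#' Carlo estimate (random re-pairings of the observed gene copies).
#'
#' @param table a [GenotypeTable-class].
#' @param locus,pop locus and population (name or index).
#' @param mcIterations Monte Carlo re-pairings for the multi-allelic case.
#' @param seed integer seed for the Monte Carlo path.
#' @return list: \code{p}, \code{method} ("enumeration", "monte-carlo" or
#'   "monomorphic").
#' @export
hweTest <- function(table, locus, pop, mcIterations = 10000, seed = 1) {
  pairs <- .popLocusPairs(table, pop, locus)
  n <- nrow(pairs)
  alleles <- sort(unique(as.vector(pairs)))
  if (length(alleles) < 2 || n == 0)
    return(list(p = 1, method = "monomorphic"))
  if (length(alleles) == 2 && n <= 500) {
    n1 <- sum(pairs == alleles[1])
    n2 <- 2 * n - n1
    hs <- seq(n1 %% 2, min(n1, n2), by = 2)
    logP <- lfactorial(n) + lfactorial(n1) + lfactorial(n2) -
      lfactorial(2 * n) + hs * log(2) -
      lfactorial((n1 - hs) / 2) - lfactorial(hs) - lfactorial((n2 - hs) / 2)
    obsH <- sum(pairs[, 1] != pairs[, 2])
    pObs <- logP[match(obsH, hs)]
    p <- sum(exp(logP[logP <= pObs + 1e-9]))
    return(list(p = min(1, p), method = "enumeration"))
  }
  set.seed(seed)
  obs <- .hweLogProb(pairs)
  copies <- as.vector(pairs)
  hits <- 0L
  for (b in seq_len(mcIterations)) {
    perm <- matrix(sample(copies), ncol = 2)
    if (.hweLogProb(perm) <= obs + 1e-9) hits <- hits + 1L
  }
  list(p = (1 + hits) / (mcIterations + 1), method = "monte-carlo")
}

#' Bonferroni correction over a matrix of p-values
#'
#' Multiplies every p-value by the number of non-missing tests (capped at
#' 1), the correction conventionally applied to locus x population HWE
#' test batteries.
#'
#' @param p numeric vector or matrix of p-values.
#' @return corrected p-values, same shape.
#' @export
bonferroniCorrect <- function(p) {
  m <- sum(!is.na(p))
  out <- pmin(1, p * m)
  attributes(out) <- attributes(p)
  out
}

#' Nei's Da genetic distance
#'
#' \code{Da = 1 - (1/L) sum_l sum_a sqrt(x_a * y_a)}, averaged over the loci
#' with data in both populations.
#'
#' @param table a [GenotypeTable-class].
#' @return symmetric population x population matrix.
#' @export
neiDa <- function(table) {
  fr <- alleleFreqs(table)
  P <- length(table@pops)
  d <- matrix(0, P, P, dimnames = list(table@pops, table@pops))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      terms <- vapply(fr, function(m) {
        if (anyNA(m[i, ]) || anyNA(m[j, ])) return(NA_real_)
        sum(sqrt(m[i, ] * m[j, ]))
      }, 1)
      d[i, j] <- d[j, i] <- 1 - mean(terms, na.rm = TRUE)
    }
  }
  d
}

#' Neighbour-joining tree on Nei's Da distances
#'
#' Saitou-Nei neighbour joining on the Da matrix, with optional bootstrap
#' support from resampling loci with replacement (support = number of
#' bootstrap trees containing each internal bipartition).
#'
#' @param table a [GenotypeTable-class] with at least 3 populations.
#' @param bootstrap number of locus-resampling replicates (0 = none).
#' @param seed integer seed for the bootstrap.
#' @return an \code{ape::phylo} tree; bootstrap counts, if requested, are in
#'   \code{node.label}.
#' @export
neiDaNJ <- function(table, bootstrap = 0, seed = 1) {
  if (length(table@pops) < 3) stop("need at least 3 populations")
  tree <- nj(as.dist(neiDa(table)))
  if (bootstrap > 0) {
    set.seed(seed)
    L <- length(table@loci)
    boots <- lapply(seq_len(bootstrap), function(b) {
      pick <- sample.int(L, L, replace = TRUE)
      sub <- new("GenotypeTable", loci = sprintf("b%02d", seq_len(L)),
                 pops = table@pops,
                 genotypes = lapply(table@genotypes, function(g)
                   g[, as.vector(rbind(2L * pick - 1L, 2L * pick)),
                     drop = FALSE]),
                 trueFreqs = list())
      nj(as.dist(neiDa(sub)))
    })
    tree$node.label <- prop.clades(tree, boots, rooted = FALSE)
  }
  tree
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal entries, with significance
#' from jointly permuting the rows and columns of the second matrix.
#'
#' @param a,b symmetric matrices (or [EcoDistanceMatrix-class]) with zero
#'   diagonals and matching labels.
#' @param permutations number of label permutations.
#' @param seed integer seed.
#' @param alternative \code{"greater"} (positive association, the usual
#'   isolation-by-distance direction), \code{"less"} or \code{"two.sided"}.
#' @return list: \code{r}, \code{p}, \code{permutations}, \code{flagged}
#'   (TRUE when a matrix is constant and r is undefined).
#' @export
mantelTest <- function(a, b, permutations = 9999, seed = 1,
                       alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  A <- if (is(a, "EcoDistanceMatrix")) a@d else as.matrix(a)
  B <- if (is(b, "EcoDistanceMatrix")) b@d else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop("matrices must have matching dimensions")
  if (any(diag(A) != 0) || any(diag(B) != 0))
    stop("matrices must have zero diagonals")
  lt <- lower.tri(A)
  av <- A[lt]; bv <- B[lt]
  if (sd(av) == 0 || sd(bv) == 0)
    return(list(r = NA_real_, p = NA_real_, permutations = 0L,
                flagged = TRUE))
  r <- cor(av, bv)
  set.seed(seed)
  n <- nrow(A)
  rp <- vapply(seq_len(permutations), function(i) {
    idx <- sample.int(n)
    cor(av, B[idx, idx][lt])
  }, 1)
  p <- switch(alternative,
    greater = (1 + sum(rp >= r)) / (permutations + 1),
    less = (1 + sum(rp <= r)) / (permutations + 1),
    two.sided = (1 + sum(abs(rp) >= abs(r))) / (permutations + 1))
  list(r = r, p = p, permutations = permutations, flagged = FALSE)
}

## ---- AMOVA ----

## inter-individual squared distances: per locus, the number of allele
## differences between the two diploid genotypes (0, 1 or 2), summed over
## the loci typed in both individuals
.amovaDistances <- function(table) {
  pops <- rep(table@pops, vapply(table@genotypes, nrow, 1L))
  G <- do.call(rbind, table@genotypes)
  N <- nrow(G)
  L <- length(table@loci)
  d <- matrix(0, N, N)
  for (l in seq_len(L)) {
    g <- G[, .lociCols(l), drop = FALSE]
    ok <- stats::complete.cases(g)
    alleles <- sort(unique(as.vector(g[ok, , drop = FALSE])))
    if (length(alleles) < 1) next
    C <- matrix(0, N, length(alleles))
    for (ai in seq_along(alleles))
      C[, ai] <- (g[, 1] == alleles[ai]) + (g[, 2] == alleles[ai])
    C[!ok, ] <- 0
    ## |C_i - C_j| via the unit decomposition C = (C>=1) + (C>=2)
    B1 <- (C >= 1) * 1; B2 <- (C >= 2) * 1
    r1 <- rowSums(B1); r2 <- rowSums(B2)
    l1 <- outer(r1, r1, "+") - 2 * tcrossprod(B1) +
          outer(r2, r2, "+") - 2 * tcrossprod(B2)
    both <- ok & rep(TRUE, N)
    mask <- outer(both, both, "&")
    d <- d + ifelse(mask, l1 / 2, 0)
  }
  list(d = d, pops = pops)
}

.amovaSS <- function(d, strata) {
  tot <- sum(d[upper.tri(d)]) / nrow(d)
  within <- 0
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1)
      within <- within + sum(d[idx, idx][upper.tri(d[idx, idx])]) / length(idx)
  }
  c(total = tot, within = within)
}

.amovaPhiST <- function(d, pops) {
  N <- nrow(d)
  P <- length(unique(pops))
  ss <- .amovaSS(d, pops)
  ssA <- ss["total"] - ss["within"]
  dfA <- P - 1; dfW <- N - P
  msA <- ssA / dfA; msW <- ss["within"] / dfW
  np <- as.numeric(table(pops))
  n0 <- (N - sum(np^2) / N) / (P - 1)
  s2w <- msW
  s2a <- (msA - msW) / n0
  unname((s2a) / (s2a + s2w))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions genetic variation among groups, among populations within
#' groups, and within populations, from squared inter-individual distances
#' defined as allele-difference counts (0, 1 or 2 per locus, summed over
#' loci typed in both individuals). Without a grouping the design is
#' one-level (among / within populations). Significance of Phi-ST is
#' assessed by permuting individuals across populations; of Phi-CT (when
#' groups are present) by permuting whole populations across groups.
#'
#' Populations reduced to a single individual cannot contribute a
#' within-population term and are removed with a warning.
#'
#' @param table a [GenotypeTable-class].
#' @param grouping optional named vector mapping population id to group.
#' @param permutations permutations for the significance tests.
#' @param seed integer seed.
#' @return list: \code{components} (data.frame with df, SS, MS, variance
#'   component sigma2 and percent of total), \code{phi} (named
#'   Phi-statistics), \code{p} (permutation p-values), \code{flagged}
#'   (TRUE when total variance is zero and percentages are undefined).
#' @export
amova <- function(table, grouping = NULL, permutations = 999, seed = 1) {
  ns <- sampleSizes(table)
  if (any(ns < 2)) {
    warning("removing singleton populations: ",
            paste(names(ns)[ns < 2], collapse = ", "))
    keep <- which(ns >= 2)
    table <- new("GenotypeTable", loci = table@loci, pops = table@pops[keep],
                 genotypes = table@genotypes[keep], trueFreqs = list())
  }
  if (length(table@pops) < 2) stop("need >= 2 populations (or >= 2 groups)")
  ad <- .amovaDistances(table)
  d <- ad$d; pops <- ad$pops
  N <- nrow(d); P <- length(unique(pops))
  ssT <- .amovaSS(d, pops)
  if (is.null(grouping)) {
    ssW <- ssT["within"]; ssA <- ssT["total"] - ssW
    dfA <- P - 1; dfW <- N - P
    msA <- ssA / dfA; msW <- ssW / dfW
    np <- as.numeric(table(pops))
    n0 <- (N - sum(np^2) / N) / (P - 1)
    s2w <- unname(msW)
    s2a <- unname((msA - msW) / n0)
    tot <- s2a + s2w
    comp <- data.frame(
      source = c("among populations", "within populations", "total"),
      df = c(dfA, dfW, N - 1),
      SS = unname(c(ssA, ssW, ssT["total"])),
      MS = c(msA, msW, NA),
      sigma2 = c(s2a, s2w, tot),
      pct = if (tot > 0) 100 * c(s2a, s2w, tot) / tot else rep(NA_real_, 3))
    phi <- c(PhiST = if (tot > 0) s2a / tot else NA_real_)
  } else {
    grp <- grouping[pops]
    if (anyNA(grp)) stop("grouping must name every population")
    G <- length(unique(grp))
    ssWP <- ssT["within"]
    ssAPwg <- 0
    for (g in unique(grp)) {
      idx <- which(grp == g)
      sub <- .amovaSS(d[idx, idx, drop = FALSE], pops[idx])
      ssAPwg <- ssAPwg + (sub["total"] - sub["within"])
    }
    ssAG <- ssT["total"] - ssWP - ssAPwg
    dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
    msAG <- ssAG / dfAG; msAP <- ssAPwg / dfAP; msWP <- ssWP / dfWP
    Ng <- tapply(rep(1, N), grp, sum)
    npByPop <- table(pops)
    sumNp2ByGroup <- tapply(as.numeric(npByPop)^2,
                            grouping[names(npByPop)], sum)
    n1 <- (N - sum(sumNp2ByGroup / Ng[names(sumNp2ByGroup)])) / dfAP
    n2 <- (sum(sumNp2ByGroup / Ng[names(sumNp2ByGroup)]) -
             sum(as.numeric(npByPop)^2) / N) / dfAG
    n3 <- (N - sum(Ng^2) / N) / dfAG
    s2c <- unname(msWP)
    s2b <- unname((msAP - msWP) / n1)
    s2a <- unname((msAG - msWP - n2 * s2b) / n3)
    tot <- s2a + s2b + s2c
    comp <- data.frame(
      source = c("among groups", "among populations within groups",
                 "within populations", "total"),
      df = c(dfAG, dfAP, dfWP, N - 1),
      SS = unname(c(ssAG, ssAPwg, ssWP, ssT["total"])),
      MS = c(msAG, msAP, msWP, NA),
      sigma2 = c(s2a, s2b, s2c, tot),
      pct = if (tot > 0) 100 * c(s2a, s2b, s2c, tot) / tot
            else rep(NA_real_, 4))
    phi <- c(PhiST = if (tot > 0) (s2a + s2b) / tot else NA_real_,
             PhiSC = if ((s2b + s2c) > 0) s2b / (s2b + s2c) else NA_real_,
             PhiCT = if (tot > 0) s2a / tot else NA_real_)
  }
  flagged <- !is.finite(phi[["PhiST"]])
  p <- c(PhiST = NA_real_)
  if (!flagged && permutations > 0) {
    set.seed(seed)
    obs <- .amovaPhiST(d, pops)
    cnt <- 0L
    for (b in seq_len(permutations)) {
      if (.amovaPhiST(d, sample(pops)) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p["PhiST"] <- (1 + cnt) / (permutations + 1)
    if (!is.null(grouping)) {
      popIds <- unique(pops)
      obsCT <- phi[["PhiCT"]]
      cntCT <- 0L
      for (b in seq_len(permutations)) {
        permGrp <- setNames(sample(grouping[popIds]), popIds)
        sub <- tryCatch({
          grpB <- permGrp[pops]
          ssAPwgB <- 0
          for (g in unique(grpB)) {
            idx <- which(grpB == g)
            s <- .amovaSS(d[idx, idx, drop = FALSE], pops[idx])
            ssAPwgB <- ssAPwgB + (s["total"] - s["within"])
          }
          ssAGB <- ssT["total"] - ssT["within"] - ssAPwgB
          GB <- length(unique(grpB))
          NgB <- tapply(rep(1, N), grpB, sum)
          n3B <- (N - sum(NgB^2) / N) / (GB - 1)
          msAGB <- ssAGB / (GB - 1)
          msAPB <- ssAPwgB / (P - GB)
          msWPB <- ssT["within"] / (N - P)
          sumNp2B <- tapply(as.numeric(npByPop)^2, permGrp[names(npByPop)],
                            sum)
          n1B <- (N - sum(sumNp2B / NgB[names(sumNp2B)])) / (P - GB)
          n2B <- (sum(sumNp2B / NgB[names(sumNp2B)]) -
                    sum(as.numeric(npByPop)^2) / N) / (GB - 1)
          s2bB <- (msAPB - msWPB) / n1B
          s2aB <- (msAGB - msWPB - n2B * s2bB) / n3B
          unname(s2aB / (s2aB + s2bB + msWPB))
        }, error = function(e) NA_real_)
        if (!is.na(sub) && sub >= obsCT - 1e-12) cntCT <- cntCT + 1L
      }
      p["PhiCT"] <- (1 + cntCT) / (permutations + 1)
    }
  }
  list(components = comp, phi = phi, p = p, flagged = flagged)
}
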