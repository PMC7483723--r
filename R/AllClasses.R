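## Central S4 containers. Cells are addressed two ways throughout the
## package: "grid index" = linear index into the raster matrix (R
## column-major, row 1 = northern edge), and "position" = index into the
## sorted @cells vector of a RiverNetwork. All user-facing site arguments
## take positions; conversion helpers live in network.R.

#' RiverNetwork: a rasterized dendritic channel network
#'
#' Holds the channel cells extracted from a flow-routing grid, their tree
#' topology (each cell has at most one downstream neighbour; outlets have
#' none), per-cell environmental variables, and snapped site locations.
#'
#' @slot dims integer(2); rows and columns of the underlying raster.
#' @slot cellSize numeric(1); cell edge length in metres.
#' @slot cells sorted integer vector of grid indices of channel cells.
#' @slot downstream integer vector aligned with \code{cells}: position (into
#'   \code{cells}) of each cell's downstream neighbour, \code{NA} at outlets.
#' @slot accumulation numeric; upstream cell count (including the cell).
#' @slot elevation numeric; conditioned elevation, strictly decreasing along
#'   every downstream link (this is what guarantees the forest invariant).
#' @slot variables numeric matrix, one row per channel cell; columns are the
#'   environmental variables (FFP, RWQ, ALT, MMT in the standard workflow).
#' @slot siteIndex named integer; site id to channel-cell position.
#'
#' @seealso [extractNetwork()], [pathBetween()], [catchmentCells()]
#' @exportClass RiverNetwork
setClass("RiverNetwork",
  representation(
    dims = "integer",
    cellSize = "numeric",
    cells = "integer",
    downstream = "integer",
    accumulation = "numeric",
    elevation = "numeric",
    variables = "matrix",
    siteIndex = "integer"
  )
)

setValidity("RiverNetwork", function(object) {
  n <- length(object@cells)
  msg <- character()
  if (length(object@dims) != 2L || any(object@dims < 1L))
    msg <- c(msg, "dims must be two positive integers")
  if (is.unsorted(object@cells, strictly = TRUE))
    msg <- c(msg, "cells must be strictly increasing grid indices")
  if (length(object@downstream) != n || length(object@accumulation) != n ||
      length(object@elevation) != n)
    msg <- c(msg, "downstream/accumulation/elevation must align with cells")
  ok <- !is.na(object@downstream)
  if (any(ok & (object@downstream < 1L | object@downstream > n)))
    msg <- c(msg, "downstream positions out of range")
  ## strict elevation drop along links implies acyclicity (forest of trees)
  if (any(ok) && any(object@elevation[object@downstream[ok]] >=
                     object@elevation[ok]))
    msg <- c(msg, "elevation must strictly decrease along downstream links")
  if (nrow(object@variables) > 0 && nrow(object@variables) != n)
    msg <- c(msg, "variables must have one row per channel cell")
  if (nrow(object@variables) == n && n > 0 && !all(is.finite(object@variables)))
    msg <- c(msg, "variables must be finite on all channel cells")
  if (length(object@siteIndex) &&
      (any(object@siteIndex < 1L) || any(object@siteIndex > n)))
    msg <- c(msg, "siteIndex positions out of range")
  if (length(msg)) msg else TRUE
})

#' @describeIn RiverNetwork number of channel cells
#' @param x,object a \code{RiverNetwork}
#' @export
networkSize <- function(x) length(x@cells)

#' @describeIn RiverNetwork grid indices of channel cells
#' @export
channelCells <- function(x) x@cells

#' @describeIn RiverNetwork per-cell environmental variable matrix
#' @export
cellVariables <- function(x) x@variables

#' @describeIn RiverNetwork named positions of snapped sites
#' @export
siteIndex <- function(x) x@siteIndex

#' @describeIn RiverNetwork number of outlet cells (trees in the forest)
#' @export
nOutlets <- function(x) sum(is.na(x@downstream))

setMethod("show", "RiverNetwork", function(object) {
  cat("RiverNetwork:", length(object@cells), "channel cells on a",
      paste(object@dims, collapse = " x "), "grid (",
      object@cellSize, "m cells )\n")
  cat("  outlets:", nOutlets(object),
      " variables:", paste(colnames(object@variables), collapse = ", "), "\n")
  if (length(object@siteIndex))
    cat("  sites:", length(object@siteIndex), "\n")
})

#' SuitabilityFit: fitted presence/absence habitat model
#'
#' Wraps a random-forest classifier fitted to presence/absence records,
#' keeping the out-of-bag presence probabilities (used for the
#' prevalence-matched cutoff), the OOB error rates and the Gini variable
#' importance.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot predictors character; predictor column names.
#' @slot data the training data frame (predictors + response).
#' @slot response name of the 0/1 response column.
#' @slot oobProb numeric; out-of-bag presence-vote fraction per training row.
#' @slot oobError named numeric: overall, absence-class and presence-class
#'   OOB error rates.
#' @slot importance named numeric; mean decrease in Gini index per predictor.
#' @slot seed integer seed used for the fit.
#' @exportClass SuitabilityFit
setClass("SuitabilityFit",
  representation(
    forest = "ANY", predictors = "character", data = "data.frame",
    response = "character", oobProb = "numeric", oobError = "numeric",
    importance = "numeric", seed = "integer"
  )
)

setValidity("SuitabilityFit", function(object) {
  msg <- character()
  if (any(object@importance < -1e-9))
    msg <- c(msg, "Gini importance must be non-negative")
  if (any(object@oobProb < 0 | object@oobProb > 1))
    msg <- c(msg, "oobProb must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SuitabilityFit", function(object) {
  cat("SuitabilityFit:", object@forest$ntree, "trees, mtry",
      object@forest$mtry, "\n")
  cat("  OOB error:", sprintf("%.1f%% (absence %.1f%%, presence %.1f%%)",
      100 * object@oobError[["overall"]], 100 * object@oobError[["absence"]],
      100 * object@oobError[["presence"]]), "\n")
  cat("  importance:", paste(sprintf("%s=%.1f", names(object@importance),
      object@importance), collapse = ", "), "\n")
})

#' CostField: per-cell ecological costs over a river network
#'
#' Per channel cell: variables rescaled to [0,1] with network-wide anchors,
#' per-variable costs (distance to the scaled suitability interval) and the
#' aggregate ecological cost (Euclidean norm of the per-variable costs, i.e.
#' the distance from the cell's point in scaled variable space to the
#' suitability hyper-rectangle).
#'
#' @slot cells grid indices (copied from the network for alignment checks).
#' @slot scaled numeric matrix of scaled variable values in [0,1].
#' @slot costs numeric matrix of per-variable costs, same shape.
#' @slot total numeric; aggregate ecological cost per cell.
#' @slot anchors 2 x V matrix (min, max) used for scaling.
#' @slot scaledRanges 2 x V matrix; suitability intervals after scaling,
#'   clipped to [0,1].
#' @exportClass CostField
setClass("CostField",
  representation(
    cells = "integer", scaled = "matrix", costs = "matrix",
    total = "numeric", anchors = "matrix", scaledRanges = "matrix"
  )
)

setValidity("CostField", function(object) {
  msg <- character()
  if (any(object@costs < 0) || any(object@costs > 1 + 1e-12))
    msg <- c(msg, "per-variable costs must lie in [0,1]")
  v <- ncol(object@costs)
  if (any(object@total < 0) || any(object@total > sqrt(v) + 1e-12))
    msg <- c(msg, "aggregate cost must lie in [0, sqrt(#variables)]")
  zero <- rowSums(object@costs) == 0
  if (any(zero != (object@total == 0)))
    msg <- c(msg, "total must be zero exactly when all variable costs are")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CostField", function(object) {
  cat("CostField:", length(object@total), "cells,",
      ncol(object@costs), "variables\n")
  cat(sprintf("  ecological cost: range %.3f-%.3f, %.1f%% of cells at zero\n",
      min(object@total), max(object@total), 100 * mean(object@total == 0)))
})

#' EcoDistanceMatrix: pairwise ecological distances between populations
#'
#' Symmetric matrix of cumulative ecological costs along the unique river
#' path between every pair of snapped sites, with a companion matrix of path
#' lengths in cells. Pairs in different trees (no hydrological connection)
#' are \code{NA}.
#'
#' @slot ids character site ids.
#' @slot d symmetric numeric matrix of ecological distances; zero diagonal.
#' @slot pathLength integer matrix of path cell counts (1 on the diagonal).
#' @exportClass EcoDistanceMatrix
setClass("EcoDistanceMatrix",
  representation(ids = "character", d = "matrix", pathLength = "matrix")
)

setValidity("EcoDistanceMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (nrow(d) != ncol(d) || nrow(d) != length(object@ids))
    msg <- c(msg, "d must be square with one row per id")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d)))) msg <- c(msg, "d must be symmetric")
  if (any(d < 0, na.rm = TRUE)) msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EcoDistanceMatrix", function(object) {
  n <- length(object@ids)
  off <- object@d[upper.tri(object@d)]
  cat("EcoDistanceMatrix:", n, "sites,", sum(!is.na(off)), "connected pairs\n")
  if (any(!is.na(off)))
    cat(sprintf("  distances: %.3f-%.3f (median %.3f)\n",
        min(off, na.rm = TRUE), max(off, na.rm = TRUE),
        stats::median(off, na.rm = TRUE)))
})

#' @describeIn EcoDistanceMatrix the distance matrix itself
#' @param x an \code{EcoDistanceMatrix}
#' @export
distanceMatrix <- function(x) x@d

#' ClusterPartition: Ward clustering of populations on ecological distances
#'
#' @slot hclust the \code{hclust} object (Ward linkage on the ecological
#'   distance matrix, \code{ward.D2} convention).
#' @slot k integer; number of clusters (chosen or automatic).
#' @slot assignment named integer; site id to cluster id.
#' @slot heights numeric; merge heights (non-decreasing).
#' @slot autoK logical; whether k was chosen by the merge-height gap rule.
#' @exportClass ClusterPartition
setClass("ClusterPartition",
  representation(hclust = "ANY", k = "integer", assignment = "integer",
                 heights = "numeric", autoK = "logical")
)

setValidity("ClusterPartition", function(object) {
  msg <- character()
  if (length(object@heights) > 1 && is.unsorted(object@heights))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (object@k < 1L || object@k > length(object@assignment))
    msg <- c(msg, "k out of range")
  if (!setequal(unique(object@assignment), seq_len(object@k)))
    msg <- c(msg, "assignments must use cluster ids 1..k exhaustively")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition:", length(object@assignment), "sites in",
      object@k, if (object@autoK) "clusters (auto k)\n" else "clusters\n")
  print(table(cluster = object@assignment))
})

#' @describeIn ClusterPartition named cluster assignment vector
#' @param x a \code{ClusterPartition}
#' @export
clusterAssignment <- function(x) x@assignment

#' GenotypeTable: diploid microsatellite genotypes by population
#'
#' Genotypes are stored as one integer matrix per population with
#' \code{2 * nLoci} columns; columns \code{2l - 1} and \code{2l} hold the two
#' allele codes at locus \code{l}, \code{NA} for missing. Allele codes are
#' positive integers (GenePop-style, written as 2- or 3-digit codes).
#'
#' @slot loci character locus names.
#' @slot pops character population ids.
#' @slot genotypes list of integer matrices, one per population.
#' @slot trueFreqs optional list (per locus) of population x allele
#'   frequency matrices; retained by the simulator for oracle checks.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(loci = "character", pops = "character",
                 genotypes = "list", trueFreqs = "list")
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  L <- length(object@loci)
  if (length(object@genotypes) != length(object@pops))
    msg <- c(msg, "one genotype matrix per population required")
  for (g in object@genotypes) {
    if (!is.matrix(g) || ncol(g) != 2L * L)
      msg <- c(msg, "genotype matrices must have 2*nLoci columns")
    else if (nrow(g) < 1L)
      msg <- c(msg, "population sizes must be >= 1")
    else if (any(g[!is.na(g)] < 1))
      msg <- c(msg, "allele codes must be positive integers or NA")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "GenotypeTable", function(object) {
  ns <- vapply(object@genotypes, nrow, 1L)
  cat("GenotypeTable:", length(object@pops), "populations,",
      length(object@loci), "loci,", sum(ns), "individuals\n")
  cat("  sample sizes:", paste(range(ns), collapse = "-"),
      " missing:", sprintf("%.2f%%", 100 * missingRate(object)), "\n")
})

#' @describeIn GenotypeTable population ids
#' @param x,table a \code{GenotypeTable}
#' @export
popNames <- function(x) x@pops

#' @describeIn GenotypeTable locus names
#' @export
lociNames <- function(x) x@loci

#' @describeIn GenotypeTable individuals per population
#' @export
sampleSizes <- function(x) setNames(vapply(x@genotypes, nrow, 1L), x@pops)

#' @describeIn GenotypeTable genotype matrix of one population
#' @param pop population id or index
#' @export
genotypeMatrix <- function(x, pop) {
  if (is.character(pop)) pop <- match(pop, x@pops)
  x@genotypes[[pop]]
}

#' @describeIn GenotypeTable fraction of missing allele entries
#' @export
missingRate <- function(x) {
  tot <- sum(vapply(x@genotypes, length, 1L))
  miss <- sum(vapply(x@genotypes, function(g) sum(is.na(g)), 1L))
  miss / tot
}
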