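## Ecological costs and distances: the package's core computation. Scaled
## deviations from the suitability hyper-rectangle give a per-cell cost;
## summing costs along the unique river path between two populations gives
## their ecological distance.

#' Scale network variables to [0, 1]
#'
#' Linear min-max scaling with network-wide anchors, so every variable
#' carries comparable weight in the cost computation. Constant variables
#' scale to 0 everywhere (zero cost contribution) with a warning.
#'
#' @param variables numeric matrix of per-cell values (named columns).
#' @return list: \code{scaled} matrix, \code{anchors} 2 x V matrix (min, max).
#' @export
scaleVariables <- function(variables) {
  anchors <- rbind(min = apply(variables, 2, min),
                   max = apply(variables, 2, max))
  scaled <- variables
  for (j in seq_len(ncol(variables))) {
    rng <- anchors[2, j] - anchors[1, j]
    if (rng == 0) {
      warning("variable '", colnames(variables)[j],
              "' is constant across the network; scaled to 0")
      scaled[, j] <- 0
    } else {
      scaled[, j] <- (variables[, j] - anchors[1, j]) / rng
    }
  }
  list(scaled = scaled, anchors = anchors)
}

#' Transform a raw interval with scaling anchors
#'
#' Applies the same linear map used for the variable and clips to [0, 1].
#'
#' @param interval numeric(2) in native units.
#' @param anchor numeric(2): the variable's (min, max) anchors.
#' @return the scaled, clipped interval.
#' @export
scaleInterval <- function(interval, anchor) {
  rng <- anchor[2] - anchor[1]
  if (rng == 0) return(c(0, 0))
  pmin(1, pmax(0, (sort(interval[1:2]) - anchor[1]) / rng))
}

#' Per-variable cost of a scaled value
#'
#' Distance from a scaled value to the scaled suitability interval: 0 inside
#' the closed interval (boundaries included), otherwise the distance to the
#' nearer endpoint. Vectorised over \code{v}.
#'
#' @param v scaled values in [0, 1].
#' @param interval scaled interval, a subset of [0, 1].
#' @return non-negative costs, same length as \code{v}.
#' @export
variableCost <- function(v, interval) {
  l <- min(interval); h <- max(interval)
  pmax(l - v, v - h, 0)
}

#' Aggregate ecological cost of a cell
#'
#' Euclidean norm of the per-variable cost vector: the distance, in scaled
#' variable space, from the cell's point to the suitability
#' hyper-rectangle. Variables are weighted equally (the workflow's premise
#' is predictors of comparable model importance); a weight vector can be
#' supplied for sensitivity analyses.
#'
#' @param costs numeric vector of per-variable costs, or a matrix with one
#'   row per cell.
#' @param weights optional per-variable weights (default 1).
#' @return the ecological cost (scalar or per-row vector).
#' @export
cellCost <- function(costs, weights = NULL) {
  if (is.matrix(costs)) {
    w <- if (is.null(weights)) rep(1, ncol(costs)) else weights
    sqrt(as.vector(costs^2 %*% w))
  } else {
    w <- if (is.null(weights)) rep(1, length(costs)) else weights
    sqrt(sum(w * costs^2))
  }
}

#' Build the ecological cost field of a network
#'
#' Scales all variables with network-wide anchors, scales the suitability
#' intervals with the same maps, and computes per-variable and aggregate
#' costs for every channel cell.
#'
#' @param network a [RiverNetwork-class] with variables attached.
#' @param ranges suitability intervals in native units: 2 x V matrix or
#'   named list (see [suitabilityRange()]).
#' @param weights optional per-variable weights.
#' @return a [CostField-class].
#' @export
costField <- function(network, ranges, weights = NULL) {
  vars <- network@variables
  if (!ncol(vars)) stop("network has no variables attached")
  box <- .asBox(ranges, colnames(vars))
  sc <- scaleVariables(vars)
  scaledRanges <- sapply(colnames(vars), function(v)
    scaleInterval(box[, v], sc$anchors[, v]))
  costs <- sapply(colnames(vars), function(v)
    variableCost(sc$scaled[, v], scaledRanges[, v]))
  colnames(costs) <- colnames(vars)
  new("CostField", cells = network@cells, scaled = sc$scaled, costs = costs,
      total = cellCost(costs, weights), anchors = sc$anchors,
      scaledRanges = scaledRanges)
}

.checkAligned <- function(network, cf) {
  if (!identical(network@cells, cf@cells))
    stop("cost field was built for a different network")
}

#' Ecological distance between two sites
#'
#' Sum of the aggregate ecological cost over every cell of the unique river
#' path between the two sites; endpoints and the junction cell are counted
#' exactly once. Disconnected sites (different trees) give \code{NA}.
#'
#' @param network a [RiverNetwork-class].
#' @param cf the [CostField-class] built on it.
#' @param a,b channel-cell positions (e.g. from \code{siteIndex}).
#' @return cumulative cost, with attribute \code{pathLength} (cell count).
#' @export
ecologicalDistance <- function(network, cf, a, b) {
  .checkAligned(network, cf)
  path <- tryCatch(pathBetween(network, a, b), error = function(e) NULL)
  if (is.null(path))
    return(structure(NA_real_, pathLength = NA_integer_))
  structure(sum(cf@total[path]), pathLength = length(path))
}

#' Origin-destination ecological-distance matrix
#'
#' All pairwise ecological distances between snapped sites. Each site's
#' downstream chain and its cumulative cost are computed once, so a pair's
#' distance is two partial sums joined at the lowest common downstream
#' cell. Cross-basin pairs (no hydrological path) are \code{NA}, not
#' infinite: the analysis simply has nothing to say about them.
#'
#' @param network a [RiverNetwork-class].
#' @param cf the [CostField-class] built on it.
#' @param sites named integer positions; defaults to the network's
#'   \code{siteIndex}.
#' @return an [EcoDistanceMatrix-class].
#' @export
odMatrix <- function(network, cf, sites = siteIndex(network)) {
  .checkAligned(network, cf)
  if (length(sites) < 2) stop("need at least 2 sites")
  ids <- names(sites) %||% as.character(seq_along(sites))
  ns <- length(sites)
  chains <- lapply(sites, function(p) .chainToOutlet(network, p))
  csums <- lapply(chains, function(ch) cumsum(cf@total[ch]))
  d <- matrix(0, ns, ns, dimnames = list(ids, ids))
  plen <- matrix(1L, ns, ns, dimnames = list(ids, ids))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      hit <- match(chains[[i]], chains[[j]])
      a <- which(!is.na(hit))[1]
      if (is.na(a)) {
        d[i, j] <- d[j, i] <- NA_real_
        plen[i, j] <- plen[j, i] <- NA_integer_
      } else {
        k <- hit[a]
        dij <- csums[[i]][a] + (if (k > 1) csums[[j]][k - 1] else 0)
        d[i, j] <- d[j, i] <- dij
        plen[i, j] <- plen[j, i] <- a + k - 1L
      }
    }
  }
  new("EcoDistanceMatrix", ids = ids, d = d, pathLength = plen)
}

#' Per-variable contribution to the ecological cost of a cell set
#'
#' For each variable, the percentage of cells in the set where that
#' variable's cost is positive, plus the mean aggregate cost over the set.
#'
#' @param cf a [CostField-class].
#' @param cells channel-cell positions (non-empty).
#' @return list: \code{pctPositive} (named percentages), \code{meanCost}.
#' @export
variableContribution <- function(cf, cells) {
  if (!length(cells)) stop("empty cell set")
  sub <- cf@costs[cells, , drop = FALSE]
  list(pctPositive = 100 * colMeans(sub > 0),
       meanCost = mean(cf@total[cells]))
}

#' Fraction of the network that is suitable
#'
#' Two definitions are reported side by side: the model-based fraction of
#' channel cells whose predicted presence probability reaches tau, and the
#' cost-based fraction of cells with zero ecological cost (all variables
#' inside their suitability intervals). When the habitat model matches the
#' data-generating process the two agree closely.
#'
#' @param network a [RiverNetwork-class] with variables.
#' @param fit a [SuitabilityFit-class] (NULL to skip the model definition).
#' @param tau cutoff probability.
#' @param cf a [CostField-class] (NULL to skip the cost definition).
#' @return named numeric percentages: \code{model}, \code{cost} (NA when the
#'   corresponding input is absent).
#' @export
suitableFraction <- function(network, fit = NULL, tau = NULL, cf = NULL) {
  modelPct <- NA_real_
  if (!is.null(fit) && !is.null(tau)) {
    nd <- as.data.frame(network@variables)[, fit@predictors, drop = FALSE]
    pr <- predict(fit@forest, newdata = nd, type = "prob")[, "1"]
    modelPct <- 100 * mean(pr >= tau)
  }
  costPct <- if (is.null(cf)) NA_real_ else 100 * mean(cf@total == 0)
  c(model = modelPct, cost = costPct)
}

#' Write an ecological-distance matrix as square CSV
#' @param m an [EcoDistanceMatrix-class].
#' @param path output file.
#' @export
writeOdMatrix <- function(m, path) {
  write.csv(as.data.frame(m@d), path, row.names = TRUE)
  invisible(path)
}
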