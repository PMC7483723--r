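## Habitat-suitability modelling: random-forest presence/absence classifier,
## prevalence-matched classification cutoff, partial-dependence response
## curves and per-variable suitability intervals.

#' Fit the presence/absence habitat model
#'
#' Random-forest classifier on the occurrence table. The defaults (5,000
#' trees, 2 candidate predictors per split) are deliberately heavy: with
#' four predictors and a few hundred sites the fit is still fast, and the
#' large forest stabilises both the out-of-bag probability estimates (used
#' by [prevalenceCutoff()]) and the partial-dependence curves.
#'
#' @param occurrences data.frame holding the response and predictor columns.
#' @param predictors predictor column names (default FFP, RWQ, ALT, MMT).
#' @param response name of the 0/1 (or two-level factor) response column.
#' @param nTrees,mtry forest size and candidate predictors per split.
#' @param seed integer; the fit is deterministic for a fixed seed.
#' @return a [SuitabilityFit-class].
#' @export
fitSuitability <- function(occurrences,
                           predictors = c("FFP", "RWQ", "ALT", "MMT"),
                           response = "presence", nTrees = 5000, mtry = 2,
                           seed = 1) {
  miss <- setdiff(c(predictors, response), names(occurrences))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- occurrences[, c(predictors, response)]
  bad <- !stats::complete.cases(dat[, predictors, drop = FALSE])
  if (any(bad)) {
    warning("dropping ", sum(bad), " rows with missing predictor values")
    dat <- dat[!bad, , drop = FALSE]
  }
  y <- factor(as.integer(as.character(dat[[response]]) %in% c("1", "TRUE")),
              levels = c(0, 1))
  if (length(unique(y)) < 2)
    stop("single-class data: both presences and absences are required")
  set.seed(seed)
  rf <- randomForest(x = dat[, predictors, drop = FALSE], y = y,
                     ntree = nTrees, mtry = mtry)
  conf <- rf$confusion
  oobError <- c(overall = unname(rf$err.rate[nTrees, "OOB"]),
                absence = unname(conf["0", "class.error"]),
                presence = unname(conf["1", "class.error"]))
  new("SuitabilityFit",
      forest = rf, predictors = predictors, data = dat, response = response,
      oobProb = unname(rf$votes[, "1"]),
      oobError = oobError,
      importance = setNames(rf$importance[, "MeanDecreaseGini"],
                            rownames(rf$importance)),
      seed = as.integer(seed))
}

#' Prevalence-matched classification cutoff
#'
#' The discrimination threshold tau is chosen so that the predicted species
#' prevalence (fraction of sites with out-of-bag presence probability >=
#' tau) equals the observed prevalence as closely as the empirical
#' distribution allows. With m = round(prevalence * n), any threshold
#' between the (m+1)-th and m-th largest OOB probabilities classifies
#' exactly m sites as present; tau is taken at the midpoint of that
#' interval (the least arbitrary representative), which matters when the
#' OOB distribution is bimodal and the interval is wide.
#'
#' @param fit a [SuitabilityFit-class].
#' @return tau, with attributes \code{observedPrevalence} and
#'   \code{predictedPrevalence}.
#' @export
prevalenceCutoff <- function(fit) {
  p <- fit@oobProb
  prev <- mean(fit@data[[fit@response]] %in% c(1, "1", TRUE))
  if (diff(range(p)) == 0)
    warning("degenerate cutoff: all out-of-bag probabilities identical")
  m <- max(1L, round(prev * length(p)))
  srt <- sort(p, decreasing = TRUE)
  tau <- if (m < length(p)) (srt[m] + srt[m + 1]) / 2 else srt[m]
  structure(tau, observedPrevalence = prev,
            predictedPrevalence = mean(p >= tau))
}

#' Partial-dependence response curve
#'
#' Marginal effect of one variable on the predicted presence probability:
#' for each grid value v, the variable is forced to v in every training row
#' and predictions are averaged, integrating out the other predictors.
#'
#' @param fit a [SuitabilityFit-class].
#' @param variable one of the model's predictors.
#' @param gridSize number of evaluation points over the variable's sampled
#'   range.
#' @return data.frame with columns \code{value}, \code{prob}.
#' @export
responseCurve <- function(fit, variable, gridSize = 100) {
  if (!variable %in% fit@predictors)
    stop("'", variable, "' is not a model predictor")
  x <- fit@data[, fit@predictors, drop = FALSE]
  grid <- seq(min(x[[variable]]), max(x[[variable]]), length.out = gridSize)
  big <- x[rep(seq_len(nrow(x)), times = gridSize), , drop = FALSE]
  big[[variable]] <- rep(grid, each = nrow(x))
  pr <- predict(fit@forest, newdata = big, type = "prob")[, "1"]
  data.frame(value = grid,
             prob = colMeans(matrix(pr, nrow = nrow(x), ncol = gridSize)))
}

#' Suitability interval from a response curve
#'
#' The per-variable suitability range: values where the partial-dependence
#' presence probability reaches the discrimination threshold. The interval
#' is the convex hull of the super-level set; if that set is non-contiguous
#' on the grid a warning records the fact (a single interval is still
#' returned, matching how such ranges are reported).
#'
#' @param curve data.frame from [responseCurve()].
#' @param tau cutoff probability (see [prevalenceCutoff()]).
#' @return numeric(2): the interval in the variable's native units.
#' @export
suitabilityRange <- function(curve, tau) {
  sel <- which(curve$prob >= tau)
  if (!length(sel))
    stop("empty suitability range: response curve never reaches tau = ", tau)
  if (any(diff(sel) > 1))
    warning("super-level set is non-contiguous; returning its convex hull")
  c(curve$value[min(sel)], curve$value[max(sel)])
}

#' Percent overlap of two intervals
#'
#' Interval agreement as 100 times the ratio of intersection length to
#' union length (interval Jaccard index). Symmetric; 100 exactly for equal
#' intervals, 0 for disjoint ones.
#'
#' @param observed,predicted numeric(2) closed intervals (lo, hi), both
#'   non-degenerate.
#' @return overlap percentage in [0, 100].
#' @examples
#' rangeOverlapPct(c(0.012, 6.014), c(0, 6.1)) # 98.4
#' @export
rangeOverlapPct <- function(observed, predicted) {
  o <- sort(observed[1:2]); p <- sort(predicted[1:2])
  un <- max(o[2], p[2]) - min(o[1], p[1])
  if (un <= 0) stop("zero-length union: both intervals are degenerate")
  inter <- max(0, min(o[2], p[2]) - max(o[1], p[1]))
  100 * inter / un
}
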