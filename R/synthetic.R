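## Synthetic riverscape generator: fractal DEMs, environmental layers,
## protected areas and occurrence records with known ground truth. The
## defaults emulate the study system the package was built around: a ~100 m
## dendritic mountain network, four environmental variables (FFP, RWQ, ALT,
## MMT), 274 survey sites with prevalence 126/274, and roughly half of the
## landscape under protection.

#' Generate a synthetic DEM
#'
#' \code{method = "fractal"} builds a diamond-square fractal surface, adds a
#' global southward tilt (so the landscape drains coherently toward one
#' edge) and linearly rescales elevations to \code{elevRange}. After
#' depression filling such a surface is fully drainable and yields a
#' realistic dendritic channel network. \code{method = "ramp"} returns a
#' deterministic inclined plane (useful as a degenerate test surface).
#'
#' @param nrow,ncol grid shape; at least 8 x 8.
#' @param cellSize cell edge length in metres.
#' @param method \code{"fractal"} or \code{"ramp"}.
#' @param elevRange numeric(2); output elevation range in metres.
#' @param roughness amplitude decay per diamond-square octave in (0,1);
#'   smaller is smoother.
#' @param tilt strength of the global gradient, as a multiple of the fractal
#'   surface's standard deviation.
#' @param seed integer; the generator is bit-reproducible for a fixed seed.
#' @return numeric elevation matrix (row 1 = north).
#' @export
generateDEM <- function(nrow, ncol, cellSize = 100, method = c("fractal", "ramp"),
                        elevRange = c(3, 1420), roughness = 0.55, tilt = 1.5,
                        seed = 1) {
  method <- match.arg(method)
  if (nrow < 8 || ncol < 8)
    stop("degenerate grid shape: need at least 8 x 8 cells")
  if (method == "ramp") {
    z <- matrix(rep(seq(elevRange[2], elevRange[1], length.out = nrow), ncol),
                nrow, ncol)
    return(z)
  }
  set.seed(seed)
  z <- .diamondSquare(max(nrow, ncol), roughness)[seq_len(nrow), seq_len(ncol)]
  z <- z + tilt * sd(z) * (nrow - row(z)) / nrow   # drain toward the south edge
  elevRange[1] + (z - min(z)) / (max(z) - min(z)) * diff(elevRange)
}

## diamond-square on a (2^k + 1) square, cropped by the caller
.diamondSquare <- function(minSize, roughness) {
  k <- ceiling(log2(max(minSize - 1, 1)))
  n <- 2L^k + 1L
  z <- matrix(0, n, n)
  z[c(1, n), c(1, n)] <- rnorm(4)
  step <- n - 1L
  amp <- 1
  while (step > 1L) {
    half <- step %/% 2L
    ## diamond step: centres of squares
    for (r in seq(1L + half, n, by = step))
      for (c in seq(1L + half, n, by = step))
        z[r, c] <- mean(z[c(r - half, r + half), c(c - half, c + half)]) +
          rnorm(1) * amp
    ## square step: edge midpoints
    for (r in seq(1L, n, by = half)) {
      odd <- ((r - 1L) %/% half) %% 2L == 0L
      cs <- if (odd) seq(1L + half, n, by = step) else seq(1L, n, by = step)
      for (c in cs) {
        nb <- c(if (r - half >= 1L) z[r - half, c],
                if (r + half <= n) z[r + half, c],
                if (c - half >= 1L) z[r, c - half],
                if (c + half <= n) z[r, c + half])
        z[r, c] <- mean(nb) + rnorm(1) * amp
      }
    }
    step <- half
    amp <- amp * roughness
  }
  z
}

#' Generate a synthetic land-cover impact raster
#'
#' Categorical raster with integer impact scores \{0, 1, 2, 3\} representing
#' increasing anthropogenic influence (natural forest through intensive
#' use), with spatially coherent patches: smoothed Gaussian noise cut at
#' quantiles so that scores 0:3 cover roughly 40/30/20/10 percent of the
#' landscape.
#'
#' @param nrow,ncol grid shape.
#' @param weights expected area fraction per score, low to high impact.
#' @param smoothing box-blur passes applied to the noise field.
#' @param seed integer seed.
#' @return integer matrix of impact scores.
#' @export
generateLandCover <- function(nrow, ncol, weights = c(0.4, 0.3, 0.2, 0.1),
                              smoothing = 8, seed = 1) {
  set.seed(seed)
  g <- matrix(rnorm(nrow * ncol), nrow, ncol)
  for (i in seq_len(smoothing)) {  # 3x3 box blur with edge replication
    acc <- g; wt <- matrix(1, nrow, ncol)
    for (k in 1:8) {
      nb <- .shiftMat(g, .D8_DR[k], .D8_DC[k], fill = NA)
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      wt[ok] <- wt[ok] + 1
    }
    g <- acc / wt
  }
  br <- quantile(g, cumsum(weights)[-length(weights)])
  matrix(findInterval(g, br), nrow, ncol)
}

#' Populate a network with synthetic environmental layers
#'
#' Derives the four standard variables on every channel cell:
#' \describe{
#'   \item{ALT}{conditioned elevation of the cell (m).}
#'   \item{FFP}{flash-flood potential: local slope gradient times mean
#'     upstream-catchment slope (both dimensionless m/m gradients).}
#'   \item{RWQ}{remote water quality: area-weighted mean land-cover impact
#'     score over the cell's upstream catchment (cells have equal area, so
#'     this is the catchment mean; range 0-3).}
#'   \item{MMT}{multiannual mean temperature: a lapse-rate surface,
#'     \code{T0 - lapse * ALT}, plus a west-east continentality gradient and
#'     Gaussian noise (deg C). The gradient and noise mimic the regional
#'     structure and interpolation scatter of coarse climate surfaces
#'     resampled to the DEM resolution, and keep temperature from being a
#'     deterministic function of altitude.}
#' }
#'
#' @param flow a \code{D8Flow} object (provides catchment topology).
#' @param network the extracted [RiverNetwork-class].
#' @param landCover impact-score matrix from [generateLandCover()]; generated
#'   internally when NULL.
#' @param T0 sea-level temperature intercept (deg C).
#' @param lapse temperature lapse rate (deg C per metre of elevation).
#' @param tempNoiseSd standard deviation of the MMT noise (deg C).
#' @param tempGradient west-to-east temperature difference across the
#'   domain (deg C).
#' @param seed integer seed (land cover + temperature noise).
#' @return list: \code{network} (with variables attached), \code{layers}
#'   (full-grid matrices), \code{landCover}.
#' @export
generateEnvLayers <- function(flow, network, landCover = NULL, T0 = 12.2,
                              lapse = 0.0065, tempNoiseSd = 1,
                              tempGradient = 2, seed = 1) {
  stopifnot(inherits(flow, "D8Flow"))
  if (is.null(flow$dir)) stop("missing catchment topology: run d8Flow() first")
  set.seed(seed)
  dem <- flow$dem
  nr <- nrow(dem); nc <- ncol(dem)
  if (is.null(landCover))
    landCover <- generateLandCover(nr, nc, seed = seed)
  ## local slope: gradient (m/m) to the D8 downstream cell (0 at outlets)
  slope <- matrix(0, nr, nc)
  down <- flow$dir
  has <- which(!is.na(down))
  rr <- .cellRow(has, nr); cr <- .cellCol(has, nr)
  rd <- .cellRow(down[has], nr); cd <- .cellCol(down[has], nr)
  run <- sqrt((rr - rd)^2 + (cr - cd)^2) * flow$cellSize
  slope[has] <- (dem[has] - dem[down[has]]) / run
  ## catchment means by downstream accumulation of sums (high-to-low sweep)
  domain <- is.finite(dem)
  idx <- which(domain)
  ord <- idx[order(dem[idx], decreasing = TRUE)]
  sSlope <- slope; sImpact <- landCover * 1; cnt <- matrix(NA_real_, nr, nc)
  sImpact[!domain] <- NA; cnt[domain] <- 1
  for (i in ord) {
    d <- down[i]
    if (!is.na(d)) {
      sSlope[d] <- sSlope[d] + sSlope[i]
      sImpact[d] <- sImpact[d] + sImpact[i]
      cnt[d] <- cnt[d] + cnt[i]
    }
  }
  catchSlope <- sSlope / cnt
  rwq <- sImpact / cnt
  ffp <- slope * catchSlope
  mmt <- T0 - lapse * dem + tempGradient * (col(dem) - 1) / (nc - 1) +
    matrix(rnorm(nr * nc, sd = tempNoiseSd), nr, nc)
  cells <- network@cells
  vars <- cbind(FFP = ffp[cells], RWQ = rwq[cells],
                ALT = dem[cells], MMT = mmt[cells])
  list(network = setVariables(network, vars),
       layers = list(FFP = ffp, RWQ = rwq, ALT = dem, MMT = mmt,
                     slope = slope, catchSlope = catchSlope),
       landCover = landCover)
}

#' Generate synthetic protected-area polygons
#'
#' Random axis-aligned rectangular reserves are accumulated until the target
#' fraction of channel cells is covered. Returned in the same list-of-rings
#' structure used by [readGeoJSONPolygons()], so they can be written with
#' [writeGeoJSONPolygons()] and fed to [paOverlay()].
#'
#' @param network a [RiverNetwork-class].
#' @param coverage target fraction of channel cells inside a PA.
#' @param maxPolys cap on the number of rectangles.
#' @param seed integer seed.
#' @return list of polygons; each polygon is a list of rings (closed
#'   two-column coordinate matrices).
#' @export
generateProtectedAreas <- function(network, coverage = 0.5, maxPolys = 40,
                                   seed = 1) {
  set.seed(seed)
  ext <- network@dims[c(2, 1)] * network@cellSize  # x, y extent
  xy <- .cellXY(network@cells, network@dims, network@cellSize)
  covered <- rep(FALSE, nrow(xy))
  polys <- list()
  while (mean(covered) < coverage && length(polys) < maxPolys) {
    w <- runif(1, 0.1, 0.35) * ext[1]
    h <- runif(1, 0.1, 0.35) * ext[2]
    x0 <- runif(1, 0, ext[1] - w)
    y0 <- runif(1, 0, ext[2] - h)
    ring <- cbind(c(x0, x0 + w, x0 + w, x0, x0),
                  c(y0, y0, y0 + h, y0 + h, y0))
    polys[[length(polys) + 1L]] <- list(ring)
    covered <- covered | (xy[, 1] >= x0 & xy[, 1] <= x0 + w &
                          xy[, 2] >= y0 & xy[, 2] <= y0 + h)
  }
  polys
}

#' Sample presence/absence survey sites on a network
#'
#' Ground truth is a suitability box: a site is truly suitable when all four
#' variables fall inside \code{trueSuitability}. Detection noise flips
#' labels symmetrically with the given probability (emulating imperfect
#' field detectability). Placement is either \code{"stratified"} (sites
#' split between suitable and unsuitable cells so that expected prevalence
#' matches \code{prevalence}) or \code{"uniform"} (sites anywhere on the
#' channel; realized prevalence is whatever the landscape gives).
#'
#' Under stratified placement, absence sites are drawn with weights
#' \code{exp(-cost / absenceSpread)}, where cost is the cell's scaled
#' distance to the suitability box: field surveys concentrate on plausible
#' habitat, so most true absences are near-misses rather than extreme
#' cells. Set \code{absenceSpread = Inf} for unweighted absences.
#'
#' @param network a [RiverNetwork-class] with variables attached.
#' @param trueSuitability 2 x V matrix (rows lo, hi) or list of intervals,
#'   columns/names matching the network's variables.
#' @param nSites number of survey sites (<= number of channel cells).
#' @param prevalence target fraction of presences in (0, 1]; used by
#'   stratified placement.
#' @param detectionNoise label-flip probability in [0, 0.5).
#' @param placement \code{"stratified"} or \code{"uniform"}.
#' @param absenceSpread scale (in units of scaled ecological cost) of the
#'   boundary-weighting of absence sites under stratified placement.
#' @param paFlags optional logical per channel cell (from [paOverlay()]).
#' @param seed integer seed.
#' @return data.frame: site_id, cell (channel position), row, col, x, y,
#'   presence (0/1), in_pa, plus one column per variable.
#' @export
sampleOccurrences <- function(network, trueSuitability, nSites,
                              prevalence = 126 / 274, detectionNoise = 0,
                              placement = c("stratified", "uniform"),
                              absenceSpread = 0.3, paFlags = NULL, seed = 1) {
  placement <- match.arg(placement)
  box <- .asBox(trueSuitability, colnames(network@variables))
  if (detectionNoise < 0 || detectionNoise >= 0.5)
    stop("detectionNoise must lie in [0, 0.5)")
  n <- length(network@cells)
  if (nSites > n) stop("nSites exceeds the number of channel cells")
  if (prevalence * nSites < 1) stop("prevalence * nSites must be >= 1")
  set.seed(seed)
  vars <- network@variables
  sc <- scaleVariables(vars)
  boxCost <- cellCost(sapply(colnames(vars), function(v)
    variableCost(sc$scaled[, v], scaleInterval(box[, v], sc$anchors[, v]))))
  inBox <- boxCost == 0
  if (!any(inBox)) {
    warning("true suitability box is disjoint from the realized layer ",
            "ranges: all-absence output")
    placement <- "uniform"
  }
  if (placement == "stratified") {
    nIn <- round(prevalence * nSites)
    suit <- which(inBox); unsuit <- which(!inBox)
    if (length(suit) < nIn) {
      warning("only ", length(suit), " suitable cells for ", nIn,
              " presence sites")
      nIn <- length(suit)
    }
    nOut <- min(nSites - nIn, length(unsuit))
    w <- exp(-boxCost[unsuit] / absenceSpread)
    if (!any(w > 0)) w <- rep(1, length(unsuit))
    sel <- c(sample(suit, nIn), sample(unsuit, nOut, prob = w))
    if (length(sel) < nSites)
      sel <- c(sel, sample(setdiff(seq_len(n), sel), nSites - length(sel)))
  } else {
    sel <- sample.int(n, nSites)
  }
  label <- as.integer(inBox[sel])
  flip <- runif(nSites) < detectionNoise
  label[flip] <- 1L - label[flip]
  idx <- network@cells[sel]
  nr <- network@dims[1]
  xy <- .cellXY(idx, network@dims, network@cellSize)
  pa <- if (is.null(paFlags)) rep(FALSE, nSites) else paFlags[sel]
  out <- data.frame(site_id = sprintf("site%03d", seq_len(nSites)),
                    cell = sel, row = .cellRow(idx, nr),
                    col = .cellCol(idx, nr), x = xy[, 1], y = xy[, 2],
                    presence = label, in_pa = pa)
  cbind(out, as.data.frame(vars[sel, , drop = FALSE]))
}

## accept 2xV matrix, V x 2, or named list of c(lo, hi)
.asBox <- function(box, varNames) {
  if (is.list(box)) box <- sapply(box, function(b) sort(b[1:2]))
  box <- as.matrix(box)
  if (nrow(box) != 2 && ncol(box) == 2) box <- t(box)
  if (is.null(colnames(box))) colnames(box) <- varNames
  if (!all(varNames %in% colnames(box)))
    stop("suitability box must name intervals for: ",
         paste(varNames, collapse = ", "))
  if (any(box[1, ] > box[2, ])) stop("interval lower bounds exceed upper bounds")
  box[, varNames, drop = FALSE]
}

#' Write an occurrence table as CSV
#'
#' Standard column set: \code{site_id,row,col,x,y,presence,in_pa}.
#' @param occ data.frame from [sampleOccurrences()].
#' @param path output file.
#' @export
writeOccurrences <- function(occ, path) {
  write.csv(occ[, c("site_id", "row", "col", "x", "y", "presence", "in_pa")],
            path, row.names = FALSE)
  invisible(path)
}
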