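## Raster grid primitives: D8 neighbourhood, depression filling, flow
## routing and accumulation, plain-text (ESRI ASCII) raster I/O.
##
## Raster convention: numeric matrix, row 1 = northern edge, 0-based
## projected coordinates via x = (col - 0.5) * cellSize,
## y = (nrow - row + 0.5) * cellSize. NA cells are nodata (outside domain).

## D8 neighbour precedence (deterministic tie-break): E, SE, S, SW, W, NW, N, NE
.D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

## value of the neighbour in direction (dr, dc) for every cell; `fill`
## outside the grid
.shiftMat <- function(m, dr, dc, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

.checkRaster <- function(dem) {
  if (!is.matrix(dem) || !is.numeric(dem))
    stop("dem must be a numeric matrix")
  if (!any(is.finite(dem)))
    stop("raster contains no data cells (all nodata)")
  invisible(TRUE)
}

## cells on the grid edge or adjacent to nodata: these can drain off-domain
.borderMask <- function(domain) {
  nr <- nrow(domain); nc <- ncol(domain)
  border <- matrix(FALSE, nr, nc)
  border[c(1L, nr), ] <- TRUE
  border[, c(1L, nc)] <- TRUE
  for (k in 1:8)
    border <- border | !.shiftMat(domain, .D8_DR[k], .D8_DC[k], fill = FALSE)
  border & domain
}

#' Fill depressions in a DEM
#'
#' Raises interior sinks and flats to a minimally drainable surface: after
#' filling, every data cell has a strictly descending D8 path to the grid
#' boundary (or to a nodata edge). Elevations are only ever raised.
#' Flats are resolved by an epsilon gradient toward the outlet, so the
#' output supports unambiguous steepest-descent routing.
#'
#' Implementation is the iterative inundation scheme: start from an
#' infinitely flooded surface with the boundary pinned at ground level and
#' repeatedly lower every cell to
#' \code{max(ground, min(neighbour + eps))} until stable.
#'
#' @param dem numeric matrix; NA = nodata.
#' @param eps minimal elevation drop imposed between neighbouring cells on
#'   filled ground (metres); diagonal neighbours use \code{eps * sqrt(2)}.
#' @param maxIter safety cap on relaxation sweeps.
#' @return the conditioned DEM (same shape, NAs preserved).
#' @examples
#' dem <- outer(8:1, rep(1, 6)) + 0 # south-draining ramp
#' identical(fillDepressions(dem), dem)
#' @export
fillDepressions <- function(dem, eps = 1e-6, maxIter = 100000L) {
  .checkRaster(dem)
  domain <- is.finite(dem)
  border <- .borderMask(domain)
  W <- matrix(Inf, nrow(dem), ncol(dem))
  W[!domain] <- NA
  W[border] <- dem[border]
  ground <- dem
  for (it in seq_len(maxIter)) {
    cand <- matrix(Inf, nrow(dem), ncol(dem))
    for (k in 1:8) {
      nb <- .shiftMat(W, .D8_DR[k], .D8_DC[k], fill = Inf)
      nb[is.na(nb)] <- Inf # nodata neighbours do not receive drainage
      cand <- pmin(cand, nb + eps * .D8_DIST[k])
    }
    Wn <- pmax(ground, cand)
    Wn[border] <- dem[border]
    Wn[!domain] <- NA
    if (isTRUE(all(Wn[domain] == W[domain]))) return(Wn)
    W <- Wn
  }
  stop("depression filling did not converge in ", maxIter, " sweeps")
}

#' D8 flow directions and accumulation
#'
#' Routes every data cell to its steepest-descent D8 neighbour
#' (drop / distance, diagonal distance \code{sqrt(2) * cellSize}; ties are
#' broken by the fixed precedence E, SE, S, SW, W, NW, N, NE). Cells on the
#' boundary (grid edge or next to nodata) with no descending in-grid
#' neighbour drain off-domain and are outlets. Flow accumulation counts the
#' cell itself plus all cells draining into it.
#'
#' @param dem a conditioned DEM (see [fillDepressions()]); interior sinks or
#'   flats raise an error.
#' @param cellSize cell edge length in metres.
#' @return an object of class \code{D8Flow}: list with \code{dir} (matrix of
#'   grid indices of the downstream cell, NA at outlets), \code{acc}
#'   (accumulation matrix), \code{dem}, \code{cellSize}.
#' @export
d8Flow <- function(dem, cellSize = 100) {
  .checkRaster(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  domain <- is.finite(dem)
  border <- .borderMask(domain)
  best <- matrix(0, nr, nc)          # best descent rate so far (> 0 required)
  down <- matrix(NA_integer_, nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (k in 1:8) {
    nbElev <- .shiftMat(dem, .D8_DR[k], .D8_DC[k], fill = Inf)
    nbElev[is.na(nbElev)] <- Inf
    slope <- (dem - nbElev) / (.D8_DIST[k] * cellSize)
    upd <- domain & is.finite(slope) & slope > best # strict: precedence wins ties
    best[upd] <- slope[upd]
    down[upd] <- idx[upd] + .D8_DR[k] + .D8_DC[k] * nr
  }
  stuck <- domain & !border & is.na(down)
  if (any(stuck))
    stop("unresolved interior flats/sinks at ", sum(stuck),
         " cells; run fillDepressions() first")
  ## accumulation: visit cells from high to low, push counts downstream
  acc <- matrix(NA_real_, nr, nc)
  acc[domain] <- 1
  ord <- idx[domain][order(dem[domain], decreasing = TRUE)]
  for (i in ord) {
    d <- down[i]
    if (!is.na(d)) acc[d] <- acc[d] + acc[i]
  }
  structure(list(dir = down, acc = acc, dem = dem, cellSize = cellSize),
            class = "D8Flow")
}

#' @export
print.D8Flow <- function(x, ...) {
  cat("D8Flow:", sum(is.finite(x$dem)), "cells,",
      sum(is.finite(x$dem) & is.na(x$dir)), "outlets, max accumulation",
      max(x$acc, na.rm = TRUE), "\n")
  invisible(x)
}

## ---- ESRI ASCII grid I/O (plain-text raster exchange format) ----

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param mat numeric matrix (row 1 = north).
#' @param path output file.
#' @param cellSize cell size in map units.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata value written for NA cells.
#' @export
writeAsciiGrid <- function(mat, path, cellSize = 100, xll = 0, yll = 0,
                           nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cellSize), paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  for (r in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [writeAsciiGrid()] or any conforming tool.
#' @return list with \code{mat}, \code{cellSize}, \code{xll}, \code{yll}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid size mismatch in ", path)
  mat <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  list(mat = mat, cellSize = hdr$cellsize,
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## grid index <-> row/col/projected coordinates
.cellRow <- function(idx, nr) ((idx - 1L) %% nr) + 1L
.cellCol <- function(idx, nr) ((idx - 1L) %/% nr) + 1L
.cellXY <- function(idx, dims, cellSize) {
  r <- .cellRow(idx, dims[1]); c <- .cellCol(idx, dims[1])
  cbind(x = (c - 0.5) * cellSize, y = (dims[1] - r + 0.5) * cellSize)
}
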