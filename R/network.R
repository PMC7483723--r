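## River-network extraction and tree operations: channel thresholding,
## site snapping, unique between-site paths, catchments.

#' Extract the channel network from a flow grid
#'
#' Channel cells are the cells whose flow accumulation reaches the
#' initiation threshold; downstream links are restricted to channel cells
#' (the downstream cell of a channel cell always accumulates at least as
#' much, so the channel set is closed downstream). The result is a forest:
#' every cell has at most one downstream neighbour and elevations strictly
#' decrease along links.
#'
#' @param flow a \code{D8Flow} object from [d8Flow()].
#' @param threshold channel-initiation threshold in upstream cell count
#'   (>= 1). There is no universal value; it controls drainage density and
#'   must be chosen for the landscape at hand.
#' @return a [RiverNetwork-class] object (variables empty; see
#'   [generateEnvLayers()] or [setVariables()]).
#' @export
extractNetwork <- function(flow, threshold) {
  stopifnot(inherits(flow, "D8Flow"))
  if (threshold < 1) stop("threshold must be >= 1")
  acc <- flow$acc
  channel <- which(!is.na(acc) & acc >= threshold)
  if (!length(channel))
    stop("empty network: threshold ", threshold,
         " exceeds maximum accumulation ", max(acc, na.rm = TRUE))
  channel <- sort(channel)
  pos <- rep(NA_integer_, length(acc))
  pos[channel] <- seq_along(channel)
  downIdx <- flow$dir[channel]
  downstream <- ifelse(is.na(downIdx), NA_integer_, pos[pmax(downIdx, 1L)])
  new("RiverNetwork",
      dims = dim(acc), cellSize = flow$cellSize, cells = as.integer(channel),
      downstream = as.integer(downstream), accumulation = acc[channel],
      elevation = flow$dem[channel],
      variables = matrix(numeric(0), length(channel), 0),
      siteIndex = setNames(integer(0), character(0)))
}

#' Attach per-cell variable values to a network
#'
#' @param network a [RiverNetwork-class].
#' @param variables numeric matrix, one row per channel cell, named columns.
#' @return the updated network.
#' @export
setVariables <- function(network, variables) {
  variables <- as.matrix(variables)
  if (nrow(variables) != length(network@cells))
    stop("variables must have one row per channel cell")
  network@variables <- variables
  validObject(network)
  network
}

#' Snap sites to the nearest channel cell
#'
#' Sites are matched to the channel cell whose centre is nearest in
#' Euclidean distance; equidistant candidates are broken deterministically
#' (smallest row, then smallest column). Sites farther than \code{maxSnap}
#' from any channel cell are an error (their ids are listed).
#'
#' @param network a [RiverNetwork-class].
#' @param x,y projected site coordinates (metres, same frame as the raster).
#' @param ids site identifiers.
#' @param maxSnap maximum allowed snap distance in metres.
#' @return the network with \code{siteIndex} extended.
#' @export
snapSite <- function(network, x, y, ids = as.character(seq_along(x)),
                     maxSnap = 500) {
  xy <- .cellXY(network@cells, network@dims, network@cellSize)
  nr <- network@dims[1]
  rows <- .cellRow(network@cells, nr); cols <- .cellCol(network@cells, nr)
  snapped <- integer(length(x))
  dist <- numeric(length(x))
  for (i in seq_along(x)) {
    d2 <- (xy[, 1] - x[i])^2 + (xy[, 2] - y[i])^2
    cand <- which(d2 == min(d2))
    if (length(cand) > 1L) # tie-break: smallest row, then smallest column
      cand <- cand[order(rows[cand], cols[cand])][1]
    snapped[i] <- cand
    dist[i] <- sqrt(d2[cand])
  }
  bad <- dist > maxSnap
  if (any(bad))
    stop("unsnappable sites (no channel cell within ", maxSnap, " m): ",
         paste(ids[bad], collapse = ", "))
  network@siteIndex <- c(network@siteIndex, setNames(snapped, ids))
  network
}

## downstream chain from a position to its outlet, inclusive
.chainToOutlet <- function(network, pos) {
  n <- length(network@cells)
  chain <- integer(0)
  p <- pos
  while (!is.na(p)) {
    chain <- c(chain, p)
    if (length(chain) > n) stop("cycle detected in downstream links")
    p <- network@downstream[p]
  }
  chain
}

#' Unique path between two channel cells
#'
#' On a dendritic network any two hydrologically connected cells are joined
#' by exactly one path: up from \code{a} (downstream) to the lowest common
#' downstream cell, then upstream to \code{b}. Both endpoints and the
#' junction cell appear exactly once.
#'
#' @param network a [RiverNetwork-class].
#' @param a,b channel-cell positions (indices into \code{channelCells}).
#' @return integer vector of positions, ordered a -> b.
#' @export
pathBetween <- function(network, a, b) {
  if (a == b) return(a)
  ca <- .chainToOutlet(network, a)
  cb <- .chainToOutlet(network, b)
  hit <- match(ca, cb)
  j <- which(!is.na(hit))[1]
  if (is.na(j))
    stop("cells are in different trees: no hydrological connection")
  k <- hit[j]
  c(ca[seq_len(j)], rev(cb[seq_len(k - 1L)]))
}

## children lists: positions of channel cells draining directly into each cell
.networkChildren <- function(network) {
  kids <- vector("list", length(network@cells))
  ok <- which(!is.na(network@downstream))
  if (length(ok)) {
    sp <- split(ok, network@downstream[ok])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

## all channel cells upstream of (and including) a position
.upstreamChannel <- function(network, pos, children = .networkChildren(network)) {
  out <- integer(0)
  queue <- pos
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    out <- c(out, p)
    queue <- c(queue, children[[p]])
  }
  sort(out)
}

#' Catchment of a grid cell
#'
#' All cells of the full grid whose D8 flow path reaches the target cell,
#' plus the cell itself. Catchments are nested: the catchment of an upstream
#' cell is a subset of its downstream cell's catchment.
#'
#' @param flow a \code{D8Flow} object.
#' @param cell grid index of the target cell.
#' @return list with \code{target}, \code{members} (sorted grid indices) and
#'   \code{area} (m^2).
#' @export
catchmentCells <- function(flow, cell) {
  down <- flow$dir
  ok <- which(!is.na(down))
  kids <- split(ok, down[ok])
  members <- integer(0)
  queue <- cell
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    members <- c(members, p)
    k <- kids[[as.character(p)]]
    if (!is.null(k)) queue <- c(queue, k)
  }
  list(target = cell, members = sort(members),
       area = length(members) * flow$cellSize^2)
}

#' Write a network as plain-text tables
#'
#' Edge list (\code{cell_row,cell_col,down_row,down_col}; outlets have NA
#' downstream) and a per-cell variable table.
#'
#' @param network a [RiverNetwork-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeNetworkCSV <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nr <- network@dims[1]
  rows <- .cellRow(network@cells, nr); cols <- .cellCol(network@cells, nr)
  down <- network@downstream
  edges <- data.frame(
    cell_row = rows, cell_col = cols,
    down_row = ifelse(is.na(down), NA, rows[pmax(down, 1L)]),
    down_col = ifelse(is.na(down), NA, cols[pmax(down, 1L)]))
  write.csv(edges, file.path(dir, "network_edges.csv"), row.names = FALSE)
  vars <- data.frame(cell_row = rows, cell_col = cols,
                     accumulation = network@accumulation,
                     elevation = network@elevation)
  if (ncol(network@variables))
    vars <- cbind(vars, as.data.frame(network@variables))
  write.csv(vars, file.path(dir, "network_cells.csv"), row.names = FALSE)
  invisible(dir)
}
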