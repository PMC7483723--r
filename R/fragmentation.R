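## Fragmentation analysis: Ward clustering of populations on the
## ecological-distance matrix, delineation of cluster networks, protected-
## area overlay and the within/between-cluster cost comparisons.

#' Ward clustering on an ecological-distance matrix
#'
#' Hierarchical clustering with the Lance-Williams Ward update applied to
#' squared distances (the \code{ward.D2} convention). Ecological distances
#' are a tree metric, not Euclidean, so Ward's variance interpretation is
#' approximate; the convention is stated so results are reproducible.
#' \code{k = "auto"} picks the number of clusters at the largest relative
#' gap between successive merge heights (a mechanical stand-in for visual
#' dendrogram inspection); any k can be forced instead.
#'
#' @param m an [EcoDistanceMatrix-class] or complete symmetric matrix.
#' @param k number of clusters, or \code{"auto"}.
#' @return a [ClusterPartition-class].
#' @export
wardCluster <- function(m, k = "auto") {
  d <- if (is(m, "EcoDistanceMatrix")) m@d else as.matrix(m)
  if (any(is.na(d)))
    stop("distance matrix has missing entries (disconnected site pairs); ",
         "cluster each basin separately")
  hc <- hclust(as.dist(d), method = "ward.D2")
  n <- nrow(d)
  h <- hc$height
  autoK <- identical(k, "auto")
  if (autoK) {
    if (diff(range(h)) < sqrt(.Machine$double.eps) * max(1, max(h))) {
      warning("all merge heights equal: no cluster structure, k forced to 1")
      k <- 1L
    } else {
      gaps <- vapply(seq_len(n - 2), function(i) {
        if (h[i] <= 0) { if (h[i + 1] > 0) Inf else 1 } else h[i + 1] / h[i]
      }, 1)
      k <- n - which.max(gaps)
    }
  }
  k <- as.integer(k)
  assign <- cutree(hc, k = k)
  new("ClusterPartition", hclust = hc, k = k,
      assignment = setNames(as.integer(assign), hc$labels %||% rownames(d)),
      heights = h, autoK = autoK)
}

#' Delineate the river network of a population cluster
#'
#' The cluster's network is the union, over its member sites, of (i) all
#' channel cells upstream of the site and (ii) the downstream cells from
#' the site to the confluence where its stream joins a larger river that
#' carries no cluster member: walking downstream, the walk stops at the
#' first junction where another inflowing branch has strictly greater flow
#' accumulation and no member site upstream (that junction cell belongs to
#' the main river, not the cluster).
#'
#' @param network a [RiverNetwork-class].
#' @param sites channel-cell positions of the cluster's member sites.
#' @return sorted integer positions of the cluster's cells.
#' @export
delineateClusterNetwork <- function(network, sites) {
  if (!length(sites)) stop("cluster has no member sites")
  children <- .networkChildren(network)
  memberChain <- unique(unlist(lapply(sites, function(s)
    .chainToOutlet(network, s))))
  ## connectivity check: all sites must share an outlet
  outlets <- vapply(sites, function(s) {
    ch <- .chainToOutlet(network, s); ch[length(ch)]
  }, 1L)
  if (length(unique(outlets)) > 1)
    stop("cluster sites span disconnected trees")
  cells <- unlist(lapply(sites, function(s)
    .upstreamChannel(network, s, children)))
  for (s in sites) {
    u <- s
    repeat {
      d <- network@downstream[u]
      if (is.na(d)) break
      inflows <- setdiff(children[[d]], u)
      main <- inflows[network@accumulation[inflows] > network@accumulation[u]]
      if (length(main) && !any(main %in% memberChain)) break
      cells <- c(cells, d)
      u <- d
    }
  }
  sort(unique(cells))
}

#' Connector cells between clusters
#'
#' All channel cells lying on a path between sites of different clusters,
#' minus the cells already claimed by a cluster network: the river sectors
#' populations must traverse to exchange migrants between clusters.
#'
#' @param network a [RiverNetwork-class].
#' @param sites named positions of all sites.
#' @param assignment cluster id per site (same order/names as sites).
#' @param clusterCells list of per-cluster cell sets from
#'   [delineateClusterNetwork()].
#' @return sorted integer positions.
#' @export
connectorCells <- function(network, sites, assignment, clusterCells) {
  onPath <- integer(0)
  ns <- length(sites)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (assignment[i] == assignment[j]) next
      p <- tryCatch(pathBetween(network, sites[i], sites[j]),
                    error = function(e) integer(0))
      onPath <- union(onPath, p)
    }
  }
  sort(setdiff(onPath, unlist(clusterCells)))
}

## ---- GeoJSON polygons + point-in-polygon overlay ----

#' Read polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon/MultiPolygon
#' geometries. Returned as a list of polygons, each a list of rings
#' (two-column coordinate matrices; first ring exterior, others holes under
#' the even-odd rule).
#'
#' @param path GeoJSON file.
#' @return list of polygons.
#' @export
readGeoJSONPolygons <- function(path) {
  gj <- fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type %||% "",
    FeatureCollection = lapply(gj$features, function(f) f$geometry),
    Feature = list(gj$geometry),
    list(gj))
  polys <- list()
  for (g in geoms) {
    ringify <- function(rings) lapply(rings, function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
    if (identical(g$type, "Polygon")) {
      polys[[length(polys) + 1L]] <- ringify(g$coordinates)
    } else if (identical(g$type, "MultiPolygon")) {
      for (p in g$coordinates) polys[[length(polys) + 1L]] <- ringify(p)
    } else {
      stop("unsupported geometry type: ", g$type %||% "<none>")
    }
  }
  polys
}

#' Write polygons to GeoJSON
#' @param polys list of polygons (lists of ring matrices).
#' @param path output file.
#' @export
writeGeoJSONPolygons <- function(polys, path) {
  features <- lapply(polys, function(p) list(
    type = "Feature", properties = list(),
    geometry = list(type = "Polygon",
      coordinates = lapply(p, function(ring)
        lapply(seq_len(nrow(ring)), function(i)
          c(ring[i, 1], ring[i, 2]))))))
  write_json(list(type = "FeatureCollection", features = features), path,
             auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## even-odd ray casting; px, py vectors, one ring
.pointsInRing <- function(px, py, ring) {
  vx <- ring[, 1]; vy <- ring[, 2]
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) n <- n - 1L # drop closing vertex
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xin <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xin))
    }
    j <- i
  }
  inside
}

.validRing <- function(ring) {
  is.matrix(ring) && ncol(ring) == 2 && nrow(ring) >= 4 &&
    all(is.finite(ring))
}

#' Overlay protected-area polygons on a network
#'
#' A channel cell is flagged as protected when its centre lies inside any
#' polygon (even-odd rule, so holes are respected). Cell-centre membership
#' is the natural counterpart of per-cell network assignment; partial-area
#' coverage is deliberately not modelled.
#'
#' @param network a [RiverNetwork-class].
#' @param polys list of polygons ([readGeoJSONPolygons()] /
#'   [generateProtectedAreas()]).
#' @return logical vector, one flag per channel cell.
#' @export
paOverlay <- function(network, polys) {
  bad <- which(!vapply(polys, function(p) all(vapply(p, .validRing, TRUE)),
                       TRUE))
  if (length(bad))
    stop("invalid polygon geometry (rings must be closed coordinate ",
         "matrices with >= 4 vertices): polygons ",
         paste(bad, collapse = ", "))
  xy <- .cellXY(network@cells, network@dims, network@cellSize)
  flags <- rep(FALSE, nrow(xy))
  for (p in polys) {
    inP <- rep(FALSE, nrow(xy))
    for (ring in p) # even-odd across rings: holes toggle membership off
      inP <- xor(inP, .pointsInRing(xy[, 1], xy[, 2], ring))
    flags <- flags | inP
  }
  flags
}

#' Compare ecological costs of two cell groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the aggregate
#' ecological costs of two disjoint cell sets, e.g. within-cluster versus
#' connector cells, or inside versus outside protected areas. The exact
#' distribution is used for small tie-free groups (both n <= 20), the
#' tie-corrected normal approximation otherwise.
#'
#' @param costsA,costsB numeric cost samples (non-empty).
#' @return list: \code{U} (rank-sum statistic of the first sample),
#'   \code{p} (two-sided), \code{exact}.
#' @export
compareCosts <- function(costsA, costsB) {
  if (!length(costsA) || !length(costsB)) stop("both groups must be non-empty")
  exact <- length(costsA) <= 20 && length(costsB) <= 20 &&
    !anyDuplicated(c(costsA, costsB))
  wt <- suppressWarnings(
    wilcox.test(costsA, costsB, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Per-cluster summary of the fragmented network
#'
#' One row per cluster, plus an \code{All} row (union of the cluster
#' networks) and a \code{Connect} row (inter-cluster connector network).
#' Columns: cell count, percent suitable (zero ecological cost), percent
#' inside protected areas, mean ecological cost, and the percent of cells
#' with positive cost for each variable.
#'
#' @param clusterCells named list of per-cluster cell positions.
#' @param connector connector cell positions.
#' @param cf a [CostField-class].
#' @param paFlags logical per channel cell ([paOverlay()]); NULL for no PA
#'   columns.
#' @return data.frame, one row per cluster + All + Connect.
#' @export
summaryTable <- function(clusterCells, connector, cf, paFlags = NULL) {
  rowFor <- function(name, cells) {
    if (!length(cells))
      return(data.frame(cluster = name, n_cells = 0L, pct_suitable = NA,
                        pct_pa = NA, mean_cost = NA,
                        t(setNames(rep(NA_real_, ncol(cf@costs)),
                                   paste0("pct_", colnames(cf@costs))))))
    vc <- variableContribution(cf, cells)
    data.frame(cluster = name, n_cells = length(cells),
               pct_suitable = 100 * mean(cf@total[cells] == 0),
               pct_pa = if (is.null(paFlags)) NA_real_
                        else 100 * mean(paFlags[cells]),
               mean_cost = vc$meanCost,
               t(setNames(vc$pctPositive,
                          paste0("pct_", names(vc$pctPositive)))))
  }
  nm <- names(clusterCells) %||% as.character(seq_along(clusterCells))
  rows <- lapply(seq_along(clusterCells), function(i)
    rowFor(nm[i], clusterCells[[i]]))
  allCells <- sort(unique(unlist(clusterCells)))
  rows <- c(rows, list(rowFor("All", allCells), rowFor("Connect", connector)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
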