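## Grid-density cluster masking and cluster occupancy / residence analysis.

.binIndex <- function(P, origin, binSize) {
  idx <- floor(sweep(P, 2, origin, "-") / binSize)
  storage.mode(idx) <- "integer"
  idx
}

.binKey <- function(idx) {
  apply(idx, 1, paste, collapse = ",")
}

#' Detect high-density clusters by grid binning
#'
#' Divides the pattern's box into cubic bins of side `binSize`, masks bins
#' holding at least `minCountPerBin` cells, joins masked bins into connected
#' components under full (face + edge + corner) adjacency, and discards
#' components whose total cell count is below `minCellsPerCluster`.
#'
#' @param pattern a [PointPattern-class].
#' @param binSize bin side length in μm.
#' @param minCountPerBin density threshold per bin (default 3).
#' @param minCellsPerCluster minimum cells (in core bins) for a retained
#'   cluster (default the bin threshold).
#' @return A [ClusterMask-class]; the per-cluster cell counts include border
#'   cells (see [maskMembership()]).
#' @examples
#' pp <- genPointPattern(SpatialSimConfig(seed = 9))
#' detectClusters(pp, binSize = 25)
#' @export
detectClusters <- function(pattern, binSize, minCountPerBin = 3,
                           minCellsPerCluster = minCountPerBin) {
  stopifnot(is(pattern, "PointPattern"))
  if (!.isPositive(binSize)) .stopf("binSize must be positive")
  d <- ncol(pattern@coords)
  empty <- new("ClusterMask", origin = rep(0, d), binSize = binSize,
               dims = as.integer(d),
               bins = matrix(integer(0), 0, d), clusterId = integer(0),
               clusterCells = integer(0))
  if (!nPoints(pattern)) return(empty)
  idx <- .binIndex(pattern@coords, rep(0, d), binSize)
  key <- .binKey(idx)
  counts <- table(key)
  keep <- names(counts)[counts >= minCountPerBin]
  if (!length(keep)) return(empty)
  bins <- do.call(rbind, lapply(strsplit(keep, ","), as.integer))

  ## connected components under Moore (face+edge+corner) adjacency
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  lut <- seq_len(nrow(bins))
  names(lut) <- keep
  edges <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
    nb <- sweep(bins, 2, offs[o, ], "+")
    hit <- lut[.binKey(nb)]
    ok <- !is.na(hit)
    cbind(which(ok), unname(hit[ok]))
  }))
  g <- igraph::make_empty_graph(n = nrow(bins), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  compId <- as.integer(igraph::components(g)$membership)

  ## total cells per component, then drop small components
  cellComp <- compId[lut[key]]
  perComp <- table(cellComp[!is.na(cellComp)])
  keepComp <- as.integer(names(perComp)[perComp >= minCellsPerCluster])
  sel <- compId %in% keepComp
  bins <- bins[sel, , drop = FALSE]
  compId <- compId[sel]
  newId <- match(compId, sort(unique(compId)))
  mask <- new("ClusterMask", origin = rep(0, d), binSize = binSize,
              dims = as.integer(d), bins = bins,
              clusterId = as.integer(newId),
              clusterCells = integer(length(unique(newId))))
  ## per-cluster cell counts include border cells (cells in bins adjacent
  ## to a cluster's core bins)
  member <- maskMembership(pattern@coords, mask)
  cells <- table(factor(member, levels = seq_along(unique(newId))))
  mask@clusterCells <- stats::setNames(as.integer(cells), names(cells))
  mask
}

#' Which points fall inside a cluster mask
#'
#' A point belongs to a cluster when its bin is one of the cluster's core
#' (masked) bins or, with `border = TRUE` (the default), when its bin is
#' directly adjacent to one — the usual border-point treatment of
#' density-based clustering, which lets the cluster surface extend half a
#' bin beyond the above-threshold core. Points adjacent to several clusters
#' are assigned the lowest cluster id (deterministic).
#'
#' @param coords numeric coordinate matrix (μm), or a [PointPattern-class].
#' @param mask a [ClusterMask-class].
#' @param border also accept bins adjacent to a core bin (default TRUE).
#' @return integer vector: the cluster id per point (NA when outside).
#' @export
maskMembership <- function(coords, mask, border = TRUE) {
  stopifnot(is(mask, "ClusterMask"))
  if (is(coords, "PointPattern")) coords <- coords@coords
  coords <- as.matrix(coords)
  if (ncol(coords) < mask@dims)
    .stopf("maskMembership: coordinate dimensionality below the mask's")
  coords <- coords[, seq_len(mask@dims), drop = FALSE]
  if (!nrow(mask@bins))
    return(rep(NA_integer_, nrow(coords)))
  idx <- .binIndex(coords, mask@origin, mask@binSize)
  maskKey <- .binKey(mask@bins)
  out <- mask@clusterId[match(.binKey(idx), maskKey)]
  if (border && anyNA(out)) {
    d <- mask@dims
    offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
    offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
    unres <- which(is.na(out))
    best <- rep(NA_integer_, length(unres))
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(idx[unres, , drop = FALSE], 2, offs[o, ], "+")
      hit <- mask@clusterId[match(.binKey(nb), maskKey)]
      best <- pmin(best, hit, na.rm = TRUE)
    }
    out[unres] <- best
  }
  out
}

#' Cluster occupancy and residence of tracked cells
#'
#' Per frame, the fraction of each group's cells lying inside any masked
#' bin; per cell, the total time spent inside (frames inside times the frame
#' interval) and the corresponding fraction of its observed frames.
#'
#' @param tracks a [TrackSet-class] sharing the mask's coordinate frame.
#' @param mask a [ClusterMask-class].
#' @param group name of the frame column defining cell groups (default
#'   `"phenotype"`; any constant-per-track column works).
#' @return list with `occupancy` (data.frame: `t_min`, `group`,
#'   `fraction_inside`, `n_cells`), `residence` (data.frame: `track_id`,
#'   `group`, `minutes_inside`, `fraction_inside`), and `groupMeans`
#'   (mean occupancy fraction per group across frames).
#' @export
clusterOccupancy <- function(tracks, mask, group = "phenotype") {
  stopifnot(is(tracks, "TrackSet"), is(mask, "ClusterMask"))
  fr <- tracks@frames
  if (!nrow(fr)) .stopf("clusterOccupancy: empty track set")
  cc <- .trackCoordCols(fr)
  if (length(cc) < mask@dims)
    .stopf("clusterOccupancy: track dimensionality below the mask's")
  grp <- if (group %in% names(fr)) fr[[group]] else rep("all", nrow(fr))
  inside <- !is.na(maskMembership(as.matrix(fr[, cc, drop = FALSE]), mask))
  occ <- aggregate(inside, by = list(t_min = fr$t_min, group = grp),
                   FUN = mean)
  ncell <- aggregate(inside, by = list(t_min = fr$t_min, group = grp),
                     FUN = length)
  occ <- data.frame(t_min = occ$t_min, group = occ$group,
                    fraction_inside = occ$x, n_cells = ncell$x)
  occ <- occ[order(occ$group, occ$t_min), ]
  rownames(occ) <- NULL
  resid <- do.call(rbind, lapply(split(seq_len(nrow(fr)), fr$track_id),
    function(i) {
      data.frame(track_id = fr$track_id[i[1L]], group = grp[i[1L]],
                 minutes_inside = sum(inside[i]) * tracks@interval,
                 fraction_inside = mean(inside[i]))
    }))
  rownames(resid) <- NULL
  list(occupancy = occ, residence = resid,
       groupMeans = tapply(occ$fraction_inside, occ$group, mean))
}
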