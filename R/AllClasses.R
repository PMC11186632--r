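## S4 containers for the analysis objects.

#' PointPattern: a labeled spatial point pattern in a bounded box
#'
#' Static positions (in micrometers) of cells carrying a subset label
#' ("bulk" or "llpc" in the motivating application), inside a rectangular
#' region anchored at the origin.
#'
#' @slot coords numeric matrix, one row per cell, 2 or 3 coordinate columns
#'   (`x_um`, `y_um`[, `z_um`]).
#' @slot subset character vector of per-cell subset labels.
#' @slot extent numeric vector of box side lengths per axis (μm); the region
#'   is `[0, extent]` on each axis.
#' @slot info list of provenance metadata (e.g. ground-truth cluster parent
#'   coordinates for simulated patterns).
#' @exportClass PointPattern
setClass("PointPattern",
  slots = c(coords = "matrix", subset = "character", extent = "numeric",
            info = "list"),
  prototype = prototype(coords = matrix(numeric(0), 0, 3,
                                        dimnames = list(NULL, c("x_um", "y_um", "z_um"))),
                        subset = character(0), extent = c(1, 1, 1),
                        info = list()))

setValidity("PointPattern", function(object) {
  msg <- character(0)
  d <- ncol(object@coords)
  if (!d %in% c(2L, 3L)) msg <- c(msg, "coords must have 2 or 3 columns")
  if (length(object@extent) != d)
    msg <- c(msg, "extent length must equal coordinate dimensionality")
  if (any(!is.finite(object@extent)) || any(object@extent <= 0))
    msg <- c(msg, "extent must be positive and finite")
  if (length(object@subset) != nrow(object@coords))
    msg <- c(msg, "one subset label per point required")
  if (nrow(object@coords) > 0) {
    if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
    else {
      lo <- apply(object@coords, 2, min)
      hi <- apply(object@coords, 2, max)
      if (any(lo < -1e-9) || any(hi > object@extent + 1e-9))
        msg <- c(msg, "points must lie inside [0, extent] on every axis")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PointPattern
#'
#' @param coords numeric matrix of positions in μm (columns = axes).
#' @param subset character vector of per-point subset labels (recycled if
#'   scalar).
#' @param extent box side lengths per axis in μm.
#' @param info optional provenance list.
#' @return A [PointPattern-class] object.
#' @examples
#' pp <- PointPattern(matrix(runif(20, 0, 100), 10, 2), "bulk", c(100, 100))
#' nPoints(pp)
#' @export
PointPattern <- function(coords, subset, extent, info = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- .axisNames(ncol(coords))
  if (length(subset) == 1L) subset <- rep(subset, nrow(coords))
  new("PointPattern", coords = coords, subset = as.character(subset),
      extent = as.numeric(extent), info = info)
}

#' TrackSet: time-lapse cell tracks
#'
#' Per-frame positions (μm) and two fluorescence channel intensities for a
#' collection of tracked cells imaged at a common frame interval.
#'
#' @slot frames data.frame with columns `track_id`, `t_min`, `x_um`, `y_um`
#'   (optionally `z_um`), `ch_yfp`, `ch_tomato`, and optionally `phenotype`
#'   (ground-truth label for simulated tracks) plus free metadata columns.
#' @slot interval nominal frame interval in minutes.
#' @exportClass TrackSet
setClass("TrackSet",
  slots = c(frames = "data.frame", interval = "numeric"),
  prototype = prototype(frames = data.frame(track_id = character(0),
                                            t_min = numeric(0),
                                            x_um = numeric(0),
                                            y_um = numeric(0),
                                            ch_yfp = numeric(0),
                                            ch_tomato = numeric(0)),
                        interval = 3))

setValidity("TrackSet", function(object) {
  fr <- object@frames
  need <- c("track_id", "t_min", "x_um", "y_um", "ch_yfp", "ch_tomato")
  miss <- setdiff(need, names(fr))
  if (length(miss))
    return(paste("missing frame columns:", paste(miss, collapse = ", ")))
  if (!.isPositive(object@interval)) return("interval must be a positive scalar")
  if (nrow(fr)) {
    bad <- vapply(split(fr$t_min, fr$track_id),
                  function(t) any(diff(t) <= 0), logical(1))
    if (any(bad))
      return(paste("non-increasing frame times in track(s):",
                   paste(names(bad)[bad], collapse = ", ")))
  }
  TRUE
})

#' Construct a TrackSet
#'
#' @param frames data.frame of per-frame observations (see
#'   [TrackSet-class]). Rows are sorted by track and time.
#' @param interval nominal frame interval in minutes (default 3).
#' @return A [TrackSet-class] object.
#' @export
TrackSet <- function(frames, interval = 3) {
  frames <- as.data.frame(frames)
  if (nrow(frames))
    frames <- frames[order(frames$track_id, frames$t_min), , drop = FALSE]
  rownames(frames) <- NULL
  new("TrackSet", frames = frames, interval = as.numeric(interval))
}

#' ClusterMask: high-density regions of a point pattern
#'
#' Grid-based occupancy mask: the region is divided into cubic bins of side
#' `binSize` anchored at `origin`; bins whose cell count reaches a threshold
#' are masked and joined into connected components ("clusters") under full
#' (face + edge + corner) adjacency.
#'
#' @slot origin numeric grid origin per axis (μm).
#' @slot binSize bin side length (μm).
#' @slot dims dimensionality (2 or 3).
#' @slot bins integer matrix of occupied bin indices (one row per masked bin).
#' @slot clusterId integer cluster membership per masked bin row.
#' @slot clusterCells integer vector of cell counts per retained cluster.
#' @exportClass ClusterMask
setClass("ClusterMask",
  slots = c(origin = "numeric", binSize = "numeric", dims = "integer",
            bins = "matrix", clusterId = "integer", clusterCells = "integer"))

setValidity("ClusterMask", function(object) {
  if (!.isPositive(object@binSize)) return("binSize must be positive")
  if (!object@dims %in% c(2L, 3L)) return("dims must be 2 or 3")
  if (ncol(object@bins) != object@dims && nrow(object@bins) > 0)
    return("bin index matrix must have dims columns")
  if (length(object@clusterId) != nrow(object@bins))
    return("one clusterId per masked bin required")
  TRUE
})

#' DecaySeries: fate-labeled cohort counts over time
#'
#' Absolute counts of a labeled cell cohort observed at a series of days
#' post labeling, optionally replicated (one count per animal per day).
#'
#' @slot data data.frame with columns `day`, `count`, `replicate_id`, and
#'   optionally `tissue` and `age_group`.
#' @exportClass DecaySeries
setClass("DecaySeries", slots = c(data = "data.frame"))

setValidity("DecaySeries", function(object) {
  d <- object@data
  miss <- setdiff(c("day", "count", "replicate_id"), names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (any(!is.finite(d$day)) || any(!is.finite(d$count)))
      return("day and count must be finite")
    if (any(d$count < 0)) return("counts must be non-negative")
  }
  TRUE
})

#' Construct a DecaySeries
#'
#' @param day numeric vector of days post labeling.
#' @param count numeric vector of cohort counts.
#' @param replicate_id replicate identifiers (default a single replicate).
#' @param tissue,age_group optional metadata (recycled).
#' @return A [DecaySeries-class] object.
#' @export
DecaySeries <- function(day, count, replicate_id = "r1", tissue = NA_character_,
                        age_group = NA_character_) {
  d <- data.frame(day = as.numeric(day), count = as.numeric(count),
                  replicate_id = as.character(replicate_id),
                  tissue = as.character(tissue),
                  age_group = as.character(age_group))
  d <- d[order(d$day, d$replicate_id), , drop = FALSE]
  rownames(d) <- NULL
  new("DecaySeries", data = d)
}

#' DecayFit: fitted one-phase decay model
#'
#' Parameters of the model `count(t) = (n0 - plateau) * exp(-k * t) + plateau`
#' fitted to a [DecaySeries-class]; the half-life is `t_1/2 = ln(2) / k`.
#'
#' @slot n0 fitted initial count.
#' @slot k decay rate per day (non-negative).
#' @slot plateau fitted or fixed long-term count.
#' @slot tHalf half-life in days (`Inf` when k is at machine scale).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot plateauMode "zero" (plateau fixed at 0) or "free".
#' @slot nObs number of observations used.
#' @exportClass DecayFit
setClass("DecayFit",
  slots = c(n0 = "numeric", k = "numeric", plateau = "numeric",
            tHalf = "numeric", rss = "numeric", converged = "logical",
            plateauMode = "character", nObs = "integer"))

setValidity("DecayFit", function(object) {
  if (object@converged && object@k < 0) return("k must be non-negative at a solution")
  if (object@converged && object@k > 0 && object@tHalf <= 0)
    return("tHalf must be positive when k > 0")
  TRUE
})

#' RepertoireSample: clones of one BCR repertoire sample
#'
#' Heavy-chain clones of a single sorted sample, defined by the combination
#' of V gene (allele suffix dropped) and exact CDR3 amino-acid sequence,
#' together with the sample's biological metadata.
#'
#' @slot sampleId sample identifier.
#' @slot mouseId animal identifier (required for public-clone logic).
#' @slot tissue "BM" or "spleen".
#' @slot subset "llpc" or "bulk".
#' @slot timepoint days post labeling treatment.
#' @slot ageGroup "young" or "middle-aged".
#' @slot clones data.frame with columns `clone_key`, `v_gene`, `junction_aa`,
#'   `isotype`, `size`, `n_seqs` and list-columns `seq_ids`, `seq_mutations`,
#'   `seq_v_lengths`, `seq_alleles` holding the member sequences.
#' @slot dropped named integer vector logging rows dropped during clone
#'   construction (missing CDR3, non-IGH locus, size filter).
#' @exportClass RepertoireSample
setClass("RepertoireSample",
  slots = c(sampleId = "character", mouseId = "character", tissue = "character",
            subset = "character", timepoint = "numeric", ageGroup = "character",
            clones = "data.frame", dropped = "integer"))

setValidity("RepertoireSample", function(object) {
  if (length(object@mouseId) != 1L || is.na(object@mouseId) ||
      !nzchar(object@mouseId))
    return("mouseId is required")
  cl <- object@clones
  need <- c("clone_key", "v_gene", "junction_aa", "isotype", "size")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    return(paste("missing clone columns:", paste(miss, collapse = ", ")))
  if (nrow(cl)) {
    if (anyDuplicated(cl$clone_key))
      return("clone keys must be unique within a sample")
    if (any(cl$size < 1)) return("clone sizes must be >= 1")
  }
  TRUE
})

#' PublicCloneCatalog: clones shared across mice
#'
#' Clone keys found in at least two samples coming from at least two
#' distinct mice, with their occurrence lists and total abundance.
#'
#' @slot entries data.frame with columns `clone_key`, `n_samples`, `n_mice`,
#'   `total_size`.
#' @slot occurrences data.frame with columns `clone_key`, `sample_id`,
#'   `mouse_id`, `subset`, `size`.
#' @exportClass PublicCloneCatalog
setClass("PublicCloneCatalog",
  slots = c(entries = "data.frame", occurrences = "data.frame"))

setValidity("PublicCloneCatalog", function(object) {
  e <- object@entries
  if (nrow(e) && (any(e$n_samples < 2) || any(e$n_mice < 2)))
    return("every public clone must span >=2 samples from >=2 mice")
  TRUE
})
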