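## Generics, accessors and show methods.

#' Number of points in a pattern
#' @param x a [PointPattern-class].
#' @return integer count.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointPattern", function(x) nrow(x@coords))

#' Point coordinates (μm)
#' @param x a [PointPattern-class].
#' @return numeric matrix of positions.
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname spotCoords
#' @export
setMethod("spotCoords", "PointPattern", function(x) x@coords)

#' Per-point subset labels
#' @param x a [PointPattern-class].
#' @return character vector.
#' @export
setGeneric("subsetLabels", function(x) standardGeneric("subsetLabels"))

#' @rdname subsetLabels
#' @export
setMethod("subsetLabels", "PointPattern", function(x) x@subset)

#' Bounding-box side lengths (μm)
#' @param x a [PointPattern-class].
#' @return numeric vector, one entry per axis.
#' @export
setGeneric("boxExtent", function(x) standardGeneric("boxExtent"))

#' @rdname boxExtent
#' @export
setMethod("boxExtent", "PointPattern", function(x) x@extent)

#' Provenance metadata of a simulated pattern
#' @param x a [PointPattern-class].
#' @return list (e.g. with element `parents` for clustered simulations).
#' @export
setGeneric("patternInfo", function(x) standardGeneric("patternInfo"))

#' @rdname patternInfo
#' @export
setMethod("patternInfo", "PointPattern", function(x) x@info)

setMethod("show", "PointPattern", function(object) {
  tab <- table(object@subset)
  cat(sprintf("PointPattern: %d points in %dD box [%s] um\n",
              nrow(object@coords), ncol(object@coords),
              paste(format(object@extent), collapse = " x ")))
  if (length(tab))
    cat("  subsets:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
})

#' Per-frame track table
#' @param x a [TrackSet-class].
#' @return data.frame of frames.
#' @export
setGeneric("trackFrames", function(x) standardGeneric("trackFrames"))

#' @rdname trackFrames
#' @export
setMethod("trackFrames", "TrackSet", function(x) x@frames)

#' Number of tracks
#' @param x a [TrackSet-class].
#' @return integer count.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname nTracks
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@frames$track_id)))

#' Nominal frame interval (minutes)
#' @param x a [TrackSet-class].
#' @return numeric scalar.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@interval)

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks, %d frames, interval %g min\n",
              nTracks(object), nrow(object@frames), object@interval))
})

#' Number of retained clusters in a mask
#' @param x a [ClusterMask-class].
#' @return integer count.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname nClusters
#' @export
setMethod("nClusters", "ClusterMask", function(x) length(x@clusterCells))

#' Cell counts per cluster
#' @param x a [ClusterMask-class].
#' @return named integer vector.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterMask", function(x) x@clusterCells)

setMethod("show", "ClusterMask", function(object) {
  cat(sprintf("ClusterMask: %d occupied %gum bins in %d cluster(s)\n",
              nrow(object@bins), object@binSize, nClusters(object)))
})

#' Long-format decay observations
#' @param x a [DecaySeries-class].
#' @return data.frame with day, count, replicate_id and metadata columns.
#' @export
setGeneric("decayData", function(x) standardGeneric("decayData"))

#' @rdname decayData
#' @export
setMethod("decayData", "DecaySeries", function(x) x@data)

setMethod("show", "DecaySeries", function(object) {
  d <- object@data
  cat(sprintf("DecaySeries: %d observations, %d timepoint(s), %d replicate(s)\n",
              nrow(d), length(unique(d$day)), length(unique(d$replicate_id))))
})

#' Fitted half-life (days)
#' @param x a [DecayFit-class].
#' @return numeric scalar; `Inf` when the decay rate is at machine scale.
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname halfLife
#' @export
setMethod("halfLife", "DecayFit", function(x) x@tHalf)

#' Fitted decay rate (per day)
#' @param x a [DecayFit-class].
#' @return numeric scalar.
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @rdname decayRate
#' @export
setMethod("decayRate", "DecayFit", function(x) x@k)

#' Fit coefficients as a named vector
#' @param object a [DecayFit-class].
#' @param ... ignored.
#' @return named numeric vector (n0, k, plateau, t_half, rss).
#' @export
setMethod("coef", "DecayFit", function(object, ...) {
  c(n0 = object@n0, k = object@k, plateau = object@plateau,
    t_half = object@tHalf, rss = object@rss)
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit (plateau %s): n0 = %.4g, k = %.4g /day, t1/2 = %.4g days%s\n",
    object@plateauMode, object@n0, object@k, object@tHalf,
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

#' Clone table of a repertoire sample
#' @param x a [RepertoireSample-class].
#' @return data.frame of clones.
#' @export
setGeneric("cloneTable", function(x) standardGeneric("cloneTable"))

#' @rdname cloneTable
#' @export
setMethod("cloneTable", "RepertoireSample", function(x) x@clones)

#' Number of clones in a sample
#' @param x a [RepertoireSample-class].
#' @return integer count.
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @rdname nClones
#' @export
setMethod("nClones", "RepertoireSample", function(x) nrow(x@clones))

#' Sample metadata as a one-row data.frame
#' @param x a [RepertoireSample-class].
#' @return data.frame with sample_id, mouse_id, tissue, subset,
#'   timepoint_day, age_group.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "RepertoireSample", function(x) {
  data.frame(sample_id = x@sampleId, mouse_id = x@mouseId, tissue = x@tissue,
             subset = x@subset, timepoint_day = x@timepoint,
             age_group = x@ageGroup)
})

setMethod("show", "RepertoireSample", function(object) {
  cat(sprintf("RepertoireSample %s (mouse %s, %s %s, day %g, %s): %d clones\n",
              object@sampleId, object@mouseId, object@tissue, object@subset,
              object@timepoint, object@ageGroup, nrow(object@clones)))
  if (any(object@dropped > 0))
    cat("  dropped rows:",
        paste(sprintf("%s=%d", names(object@dropped), object@dropped),
              collapse = ", "), "\n")
})

#' Public clone keys
#' @param x a [PublicCloneCatalog-class].
#' @return character vector of clone keys.
#' @export
setGeneric("publicKeys", function(x) standardGeneric("publicKeys"))

#' @rdname publicKeys
#' @export
setMethod("publicKeys", "PublicCloneCatalog", function(x) x@entries$clone_key)

#' Catalog entry table
#' @param x a [PublicCloneCatalog-class].
#' @return data.frame (clone_key, n_samples, n_mice, total_size).
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))

#' @rdname catalogEntries
#' @export
setMethod("catalogEntries", "PublicCloneCatalog", function(x) x@entries)

#' Per-sample occurrences of public clones
#' @param x a [PublicCloneCatalog-class].
#' @return data.frame (clone_key, sample_id, mouse_id, subset, size).
#' @export
setGeneric("catalogOccurrences", function(x) standardGeneric("catalogOccurrences"))

#' @rdname catalogOccurrences
#' @export
setMethod("catalogOccurrences", "PublicCloneCatalog", function(x) x@occurrences)

setMethod("show", "PublicCloneCatalog", function(object) {
  cat(sprintf("PublicCloneCatalog: %d public clone(s) across %d occurrence(s)\n",
              nrow(object@entries), nrow(object@occurrences)))
})
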