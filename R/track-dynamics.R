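## Per-track motility statistics, ensemble mean-squared displacement,
## fast-mover fractions and intensity-ratio subset classification.

#' Split tracks at imaging gaps
#'
#' A gap is a frame-to-frame time difference exceeding
#' `maxGapFactor * frameInterval`. Each maximal contiguous run of frames
#' becomes its own track (suffix `_s<i>`), so velocity statistics never
#' bridge unobserved motion.
#'
#' @param tracks a [TrackSet-class].
#' @param maxGapFactor multiple of the nominal interval above which a step is
#'   treated as a gap (default 1.5).
#' @return A [TrackSet-class] with gap-free tracks.
#' @export
splitTrackGaps <- function(tracks, maxGapFactor = 1.5) {
  stopifnot(is(tracks, "TrackSet"))
  fr <- tracks@frames
  if (!nrow(fr)) return(tracks)
  lim <- maxGapFactor * tracks@interval
  seg <- unlist(lapply(split(fr$t_min, fr$track_id), function(t) {
    cumsum(c(1L, diff(t) > lim))
  }), use.names = FALSE)
  ## split() orders groups by factor level; reorder rows to match
  fr <- fr[order(fr$track_id, fr$t_min), , drop = FALSE]
  nseg <- stats::ave(seg, fr$track_id, FUN = max)
  fr$track_id <- ifelse(nseg > 1L, sprintf("%s_s%d", fr$track_id, seg),
                        fr$track_id)
  TrackSet(fr, interval = tracks@interval)
}

.trackCoordCols <- function(fr) intersect(c("x_um", "y_um", "z_um"), names(fr))

#' Per-track motility statistics
#'
#' For every track: path length (sum of consecutive-frame Euclidean
#' displacements), duration, track velocity (path length / duration), track
#' displacement velocity (net start-to-end displacement / duration), and the
#' mean over frames of the YFP/TdTomato intensity ratio.
#'
#' @param tracks a [TrackSet-class]; every track needs at least 2 frames and
#'   strictly increasing times.
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `duration_min`, `path_length_um`, `displacement_um`,
#'   `track_velocity` and `displacement_velocity` (μm/min), `mean_ratio`,
#'   plus `phenotype` when present in the input.
#' @examples
#' ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 2, motile = 2),
#'                                nFrames = 6, seed = 7))
#' trackStatistics(ts)
#' @export
trackStatistics <- function(tracks) {
  stopifnot(is(tracks, "TrackSet"))
  fr <- tracks@frames
  if (!nrow(fr)) .stopf("trackStatistics: empty track set")
  if (any(fr$ch_tomato <= 0))
    .stopf("trackStatistics: non-positive TdTomato intensity; ratio undefined")
  cc <- .trackCoordCols(fr)
  byTrack <- split(fr, fr$track_id)
  short <- names(byTrack)[vapply(byTrack, nrow, integer(1)) < 2L]
  if (length(short))
    .stopf("trackStatistics: <2 frames for track(s) %s; statistic undefined",
           paste(short, collapse = ", "))
  rows <- lapply(byTrack, function(tf) {
    P <- as.matrix(tf[, cc, drop = FALSE])
    dur <- tf$t_min[nrow(tf)] - tf$t_min[1L]
    path <- sum(sqrt(rowSums(diff(P)^2)))
    disp <- sqrt(sum((P[nrow(P), ] - P[1L, ])^2))
    out <- data.frame(track_id = tf$track_id[1L], n_frames = nrow(tf),
                      duration_min = dur, path_length_um = path,
                      displacement_um = disp,
                      track_velocity = path / dur,
                      displacement_velocity = disp / dur,
                      mean_ratio = mean(tf$ch_yfp / tf$ch_tomato))
    if ("phenotype" %in% names(tf)) out$phenotype <- tf$phenotype[1L]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ensemble mean-squared displacement
#'
#' Per track, the time-averaged squared displacement over all overlapping
#' frame pairs at each lag (a multiple of the frame interval); the ensemble
#' curve is the unweighted mean of the per-track curves at each lag, so long
#' tracks do not dominate.
#'
#' @param tracks a [TrackSet-class]; frames must sit on a regular grid at the
#'   nominal interval (within 1% tolerance).
#' @param maxLag largest lag in minutes (default: longest track span).
#' @param perTrack if TRUE also return the per-track MSD matrix.
#' @return data.frame with `lag_min`, `msd_um2`, `n_tracks` (tracks
#'   contributing) and `n_pairs` (total frame pairs); when `perTrack`, a list
#'   with elements `ensemble` and `perTrack`.
#' @examples
#' ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 0, motile = 20),
#'                                nFrames = 10, seed = 2))
#' head(msdCurve(ts, maxLag = 9))
#' @export
msdCurve <- function(tracks, maxLag = NULL, perTrack = FALSE) {
  stopifnot(is(tracks, "TrackSet"))
  fr <- tracks@frames
  if (!nrow(fr)) .stopf("msdCurve: empty track set")
  dt <- tracks@interval
  cc <- .trackCoordCols(fr)
  byTrack <- split(fr, fr$track_id)
  spans <- vapply(byTrack, function(tf) diff(range(tf$t_min)), numeric(1))
  if (is.null(maxLag)) maxLag <- max(spans)
  if (maxLag < dt) .stopf("msdCurve: maxLag below one frame interval")
  steps <- unlist(lapply(byTrack, function(tf) diff(tf$t_min)), use.names = FALSE)
  if (any(abs(steps - dt) > 0.01 * dt))
    .stopf("msdCurve: tracks do not share the nominal frame interval")
  nmax <- floor(maxLag / dt + 1e-9)
  M <- matrix(NA_real_, length(byTrack), nmax)
  NP <- matrix(0, length(byTrack), nmax)
  for (i in seq_along(byTrack)) {
    P <- as.matrix(byTrack[[i]][, cc, drop = FALSE])
    f <- nrow(P)
    for (n in seq_len(min(nmax, f - 1L))) {
      D <- P[(1L + n):f, , drop = FALSE] - P[seq_len(f - n), , drop = FALSE]
      M[i, n] <- mean(rowSums(D^2))
      NP[i, n] <- f - n
    }
  }
  ens <- data.frame(
    lag_min = c(0, seq_len(nmax) * dt),
    msd_um2 = c(0, colMeans(M, na.rm = TRUE)),
    n_tracks = c(length(byTrack), colSums(!is.na(M))),
    n_pairs = c(sum(vapply(byTrack, nrow, integer(1))), colSums(NP)))
  if (!perTrack) return(ens)
  rownames(M) <- names(byTrack)
  colnames(M) <- sprintf("lag_%g", seq_len(nmax) * dt)
  list(ensemble = ens, perTrack = M)
}

#' Fraction of fast-moving cells
#'
#' Fraction of tracks whose track velocity strictly exceeds the threshold
#' (default 1 μm/min; a cell at exactly the threshold is not fast).
#'
#' @param stats data.frame from [trackStatistics()].
#' @param threshold velocity threshold in μm/min.
#' @return fraction in \[0, 1\].
#' @export
fastFraction <- function(stats, threshold = 1.0) {
  if (!NROW(stats)) .stopf("fastFraction: empty statistics table")
  mean(stats$track_velocity > threshold)
}

#' Classify tracks into subsets by intensity ratio
#'
#' Cells whose track-mean YFP/TdTomato ratio falls below the threshold are
#' labeled `llpc_bright` (bright TdTomato pushes the ratio down); cells at or
#' above the threshold are labeled `bulk_dim`.
#'
#' @param stats data.frame from [trackStatistics()] (column `mean_ratio`).
#' @param threshold ratio threshold (default 1.02).
#' @return the input with an added `subset_label` column.
#' @export
classifyByRatio <- function(stats, threshold = 1.02) {
  if (!NROW(stats)) .stopf("classifyByRatio: empty statistics table")
  if (any(!is.finite(stats$mean_ratio)) || any(stats$mean_ratio <= 0))
    .stopf("classifyByRatio: mean_ratio must be finite and positive")
  stats$subset_label <- ifelse(stats$mean_ratio < threshold,
                               "llpc_bright", "bulk_dim")
  stats
}
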