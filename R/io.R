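## Plain-text readers and writers: CSV for tracks, point patterns and decay
## series; AIRR-style TSV for rearrangements. Readers validate the schema
## and report offending lines by number (header = line 1).

.readTable <- function(path, sep) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing mandatory column(s): %s", path,
           paste(miss, collapse = ", "))
}

.checkNumeric <- function(df, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      .stopf("%s: non-numeric value in column '%s' at line %d", path, col,
             bad[1L] + 1L)
    na <- which(is.na(df[[col]]))
    if (length(na))
      .stopf("%s: missing value in column '%s' at line %d", path, col,
             na[1L] + 1L)
    df[[col]] <- v
  }
  df
}

#' Write / read a point pattern as CSV
#'
#' Columns `x_um`, `y_um`(, `z_um`), `subset`.
#'
#' @param pattern a [PointPattern-class].
#' @param path file path.
#' @return `writePoints` returns `path` invisibly.
#' @export
writePoints <- function(pattern, path) {
  stopifnot(is(pattern, "PointPattern"))
  df <- as.data.frame(pattern@coords)
  df$subset <- pattern@subset
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param extent box side lengths per axis; when `NULL` the per-axis maxima
#'   of the data are used.
#' @return `readPoints` returns a [PointPattern-class].
#' @rdname writePoints
#' @export
readPoints <- function(path, extent = NULL) {
  df <- .readTable(path, sep = ",")
  .requireColumns(df, c("x_um", "y_um", "subset"), path)
  if (!nrow(df)) {
    warning(sprintf("%s: header-only file, empty pattern", path))
    d <- if ("z_um" %in% names(df)) 3L else 2L
    return(PointPattern(matrix(numeric(0), 0, d), character(0),
                        extent = if (is.null(extent)) rep(1, d) else extent))
  }
  cc <- intersect(c("x_um", "y_um", "z_um"), names(df))
  df <- .checkNumeric(df, cc, path)
  P <- as.matrix(df[, cc, drop = FALSE])
  if (is.null(extent)) extent <- apply(P, 2, max)
  PointPattern(P, as.character(df$subset), extent)
}

#' Write / read cell tracks as CSV
#'
#' Columns `track_id`, `t_min`, `x_um`, `y_um`(, `z_um`), `ch_yfp`,
#' `ch_tomato`(, `phenotype`).
#'
#' @param tracks a [TrackSet-class].
#' @param path file path.
#' @return `writeTracks` returns `path` invisibly.
#' @export
writeTracks <- function(tracks, path) {
  stopifnot(is(tracks, "TrackSet"))
  utils::write.csv(tracks@frames, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param interval nominal frame interval in minutes; when `NULL` the median
#'   frame-to-frame difference is used.
#' @return `readTracks` returns a [TrackSet-class].
#' @rdname writeTracks
#' @export
readTracks <- function(path, interval = NULL) {
  df <- .readTable(path, sep = ",")
  .requireColumns(df, c("track_id", "t_min", "x_um", "y_um", "ch_yfp",
                        "ch_tomato"), path)
  if (!nrow(df)) {
    warning(sprintf("%s: header-only file, empty track set", path))
    return(TrackSet(df, interval = if (is.null(interval)) 3 else interval))
  }
  num <- intersect(c("t_min", "x_um", "y_um", "z_um", "ch_yfp", "ch_tomato"),
                   names(df))
  df <- .checkNumeric(df, num, path)
  dup <- stats::ave(df$t_min, df$track_id, FUN = function(t) duplicated(t))
  if (any(dup > 0)) {
    i <- which(dup > 0)[1L]
    .stopf("%s: duplicate frame time for track '%s' at line %d", path,
           df$track_id[i], i + 1L)
  }
  if (is.null(interval)) {
    steps <- unlist(lapply(split(df$t_min, df$track_id),
                           function(t) diff(sort(t))), use.names = FALSE)
    interval <- if (length(steps)) stats::median(steps) else 3
  }
  TrackSet(df, interval = interval)
}

#' Write / read a decay series as CSV
#'
#' Columns `day`, `count`, `replicate_id`, `tissue`, `age_group`.
#'
#' @param series a [DecaySeries-class].
#' @param path file path.
#' @return `writeDecay` returns `path` invisibly.
#' @export
writeDecay <- function(series, path) {
  stopifnot(is(series, "DecaySeries"))
  utils::write.csv(series@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @return `readDecay` returns a [DecaySeries-class].
#' @rdname writeDecay
#' @export
readDecay <- function(path) {
  df <- .readTable(path, sep = ",")
  .requireColumns(df, c("day", "count", "replicate_id"), path)
  if (!nrow(df)) {
    warning(sprintf("%s: header-only file, empty series", path))
    return(new("DecaySeries",
               data = data.frame(day = numeric(0), count = numeric(0),
                                 replicate_id = character(0))))
  }
  df <- .checkNumeric(df, c("day", "count"), path)
  DecaySeries(df$day, df$count, df$replicate_id,
              tissue = if ("tissue" %in% names(df)) df$tissue else NA,
              age_group = if ("age_group" %in% names(df)) df$age_group else NA)
}

#' Write / read AIRR-style rearrangement rows as TSV
#'
#' Standard AIRR Rearrangement field names where a standard field exists
#' (`sequence_id`, `locus`, `v_call`, `c_call`, `junction_aa`,
#' `duplicate_count`, `v_sequence_length`); `mutation_count` and `sample_id`
#' are extension columns.
#'
#' @param rearrangements data.frame of rows.
#' @param path file path.
#' @return `writeAIRR` returns `path` invisibly.
#' @export
writeAIRR <- function(rearrangements, path) {
  utils::write.table(rearrangements, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @return `readAIRR` returns the validated data.frame of rows.
#' @rdname writeAIRR
#' @export
readAIRR <- function(path) {
  df <- .readTable(path, sep = "\t")
  .requireColumns(df, c("v_call", "junction_aa", "duplicate_count"), path)
  if (!nrow(df)) {
    warning(sprintf("%s: header-only file, no rearrangements", path))
    return(df)
  }
  num <- intersect(c("duplicate_count", "mutation_count", "v_sequence_length"),
                   names(df))
  .checkNumeric(df, num, path)
}

#' Read per-sample metadata CSV
#'
#' Columns `sample_id`, `mouse_id`, `tissue`, `subset`, `timepoint_day`,
#' `age_group`.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTable(path, sep = ",")
  .requireColumns(df, c("sample_id", "mouse_id", "tissue", "subset"), path)
  df
}

#' Write a cluster mask as CSV bins plus a JSON header
#'
#' @param mask a [ClusterMask-class].
#' @param csvPath path for the occupied-bin table (`cluster_id` + one index
#'   column per axis).
#' @param jsonPath path for the header (origin, bin size, connectivity).
#' @return `csvPath` invisibly.
#' @export
writeClusterMask <- function(mask, csvPath, jsonPath) {
  stopifnot(is(mask, "ClusterMask"))
  bins <- as.data.frame(mask@bins)
  names(bins) <- paste0("bin_", c("x", "y", "z")[seq_len(mask@dims)])
  bins <- cbind(data.frame(cluster_id = mask@clusterId), bins)
  utils::write.csv(bins, csvPath, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(origin = mask@origin, bin_size_um = mask@binSize, dims = mask@dims,
         connectivity = "moore (face+edge+corner)",
         cluster_cells = as.list(stats::setNames(as.integer(mask@clusterCells),
                                                 names(mask@clusterCells)))),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csvPath)
}
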