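# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# A TrackSet holding a single track that visits the given positions at the
# given times, with flat channel intensities.
makeTrack <- function(positions, t = NULL, interval = 3, id = "t1",
                      yfp = 1, tomato = 1) {
  P <- as.matrix(positions)
  if (is.null(t)) t <- seq(0, by = interval, length.out = nrow(P))
  df <- data.frame(track_id = id, t_min = t)
  colnames(P) <- c("x_um", "y_um", "z_um")[seq_len(ncol(P))]
  df <- cbind(df, as.data.frame(P))
  df$ch_yfp <- yfp
  df$ch_tomato <- tomato
  TrackSet(df, interval = interval)
}

mergeTracks <- function(...) {
  sets <- list(...)
  TrackSet(do.call(rbind, lapply(sets, trackFrames)),
           interval = frameInterval(sets[[1]]))
}

# Brute-force time-averaged MSD over all frame pairs (independent oracle).
bruteMSD <- function(tracks, maxLag) {
  fr <- trackFrames(tracks)
  dt <- frameInterval(tracks)
  cc <- intersect(c("x_um", "y_um", "z_um"), names(fr))
  nmax <- floor(maxLag / dt + 1e-9)
  per <- lapply(split(fr, fr$track_id), function(tf) {
    P <- as.matrix(tf[, cc, drop = FALSE])
    f <- nrow(P)
    vapply(seq_len(nmax), function(n) {
      if (n >= f) return(NA_real_)
      acc <- 0
      for (i in seq_len(f - n)) acc <- acc + sum((P[i + n, ] - P[i, ])^2)
      acc / (f - n)
    }, numeric(1))
  })
  M <- do.call(rbind, per)
  c(0, colMeans(M, na.rm = TRUE))
}

# Exhaustive kNN mean-distance oracle via the full distance matrix.
bruteKnnMean <- function(coords, queryIdx, k) {
  D <- as.matrix(stats::dist(coords))
  vapply(queryIdx, function(i) {
    d <- D[i, -i]
    mean(sort(d)[seq_len(k)])
  }, numeric(1))
}

# A RepertoireSample built directly from simple clone descriptions.
makeSample <- function(keys, sizes = 20, isotypes = "IgA", mouse = "m01",
                       sample_id = "s1", subset = "llpc", tissue = "BM",
                       mutations = 0, v_length = 300) {
  n <- length(keys)
  sizes <- rep_len(sizes, n)
  isotypes <- rep_len(isotypes, n)
  mutations <- rep_len(mutations, n)
  vg <- sub("_.*$", "", keys)
  rows <- data.frame(
    sequence_id = sprintf("%s_q%03d", sample_id, seq_len(n)),
    sample_id = sample_id, locus = "IGH",
    v_call = paste0(vg, "*01"),
    c_call = isotypes,
    junction_aa = sub("^[^_]*_", "", keys),
    duplicate_count = sizes, mutation_count = mutations,
    v_sequence_length = v_length)
  buildClones(rows, min_size = 1,
              metadata = data.frame(sample_id = sample_id, mouse_id = mouse,
                                    tissue = tissue, subset = subset,
                                    timepoint_day = 90, age_group = "young"))
}

# Hand-stepped Benjamini-Hochberg procedure (independent of p.adjust).
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
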