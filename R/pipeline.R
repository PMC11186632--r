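## Pipeline runner binding the stages into reproducible, manifest-stamped
## runs. Each subcommand reads plain-text inputs, runs the corresponding
## analysis with the thresholds defaulted to the study values (k = 20
## neighbors, fast threshold 1 μm/min, ratio threshold 1.02, clone size
## filter 10, 95% confidence / 5% margin), and writes result tables whose
## bytes depend only on the configuration and seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

.asNamedNumeric <- function(x) if (is.list(x)) unlist(x) else x

.spatialCfg <- function(lst, seed) {
  args <- list(seed = seed)
  if (!is.null(lst$boxExtent)) args$boxExtent <- as.numeric(unlist(lst$boxExtent))
  if (!is.null(lst$nCells)) args$nCells <- .asNamedNumeric(lst$nCells)
  for (f in c("process", "nParents", "offspringSd", "llpcClusterAffinity"))
    if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
  do.call(SpatialSimConfig, args)
}

.trackCfg <- function(lst, seed) {
  args <- list(seed = seed)
  for (f in c("nTracks", "stepSd", "arrestProb"))
    if (!is.null(lst[[f]])) args[[f]] <- .asNamedNumeric(lst[[f]])
  if (!is.null(lst$channelMeans))
    args$channelMeans <- lapply(lst$channelMeans, .asNamedNumeric)
  if (!is.null(lst$boxExtent)) args$boxExtent <- as.numeric(unlist(lst$boxExtent))
  for (f in c("frameInterval", "nFrames", "channelSd", "dims"))
    if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
  do.call(TrackSimConfig, args)
}

.decayCfg <- function(lst, seed) {
  args <- list(seed = seed)
  if (!is.null(lst$timepoints)) args$timepoints <- as.numeric(unlist(lst$timepoints))
  for (f in c("n0", "tHalf", "plateau", "noiseCv", "nReplicates"))
    if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
  do.call(DecaySimConfig, args)
}

.repertoireCfg <- function(lst, seed) {
  args <- list(seed = seed)
  if (!is.null(lst$samplesPerMouse))
    args$samplesPerMouse <- do.call(rbind, lapply(lst$samplesPerMouse,
      function(r) data.frame(tissue = r$tissue, subset = r$subset)))
  if (!is.null(lst$isotypeProbs))
    args$isotypeProbs <- lapply(lst$isotypeProbs, .asNamedNumeric)
  if (!is.null(lst$mutationMean)) args$mutationMean <- .asNamedNumeric(lst$mutationMean)
  if (!is.null(lst$vGenes)) args$vGenes <- as.character(unlist(lst$vGenes))
  for (f in c("nMice", "nClonesPerSample", "zipfExponent", "nPublicClones",
              "publicLlpcBias", "vLength", "timepoint", "ageGroup"))
    if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
  do.call(RepertoireSimConfig, args)
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  basename(path)
}

.runSimulate <- function(config, out, seed) {
  pp <- genPointPattern(.spatialCfg(config$spatial %||% list(), seed))
  tr <- genTracks(.trackCfg(config$tracks %||% list(), seed + 1))
  dc <- genDecayCohort(.decayCfg(config$decay %||% list(), seed + 2))
  rp <- genRepertoire(.repertoireCfg(config$repertoire %||% list(), seed + 3))
  writePoints(pp, file.path(out, "points.csv"))
  writeTracks(tr, file.path(out, "tracks.csv"))
  writeDecay(dc, file.path(out, "decay.csv"))
  writeAIRR(rp$rearrangements, file.path(out, "repertoire.tsv"))
  utils::write.csv(rp$metadata, file.path(out, "sample_metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(rp$publicClones, file.path(out, "public_clones.txt"))
  list(files = c("points.csv", "tracks.csv", "decay.csv", "repertoire.tsv",
                 "sample_metadata.csv", "public_clones.txt"),
       summary = list(n_points = nPoints(pp), n_tracks = nTracks(tr),
                      n_decay_rows = nrow(decayData(dc)),
                      n_rearrangements = nrow(rp$rearrangements),
                      n_public_clones = length(rp$publicClones)))
}

.runTracks <- function(config, out, seed) {
  tr <- readTracks(config$input, interval = config$interval %||% NULL)
  tr <- splitTrackGaps(tr, maxGapFactor = config$maxGapFactor %||% 1.5)
  st <- trackStatistics(tr)
  st <- classifyByRatio(st, threshold = config$ratioThreshold %||% 1.02)
  ms <- msdCurve(tr, maxLag = config$maxLag %||% NULL)
  utils::write.csv(st, file.path(out, "track_stats.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(ms, file.path(out, "msd.csv"), row.names = FALSE,
                   quote = FALSE)
  thr <- config$fastThreshold %||% 1.0
  ff <- lapply(split(st, st$subset_label), fastFraction, threshold = thr)
  s <- .writeJSON(list(fast_threshold_um_min = thr,
                       fast_fraction = ff,
                       n_tracks = nrow(st)),
                  file.path(out, "track_summary.json"))
  list(files = c("track_stats.csv", "msd.csv", s),
       summary = list(n_tracks = nrow(st)))
}

.runSpatial <- function(config, out, seed) {
  pp <- readPoints(config$input,
                   extent = if (!is.null(config$extent))
                     as.numeric(unlist(config$extent)) else NULL)
  k <- config$k %||% 20
  dims <- config$dims %||% 2
  nn <- do.call(rbind, lapply(unique(subsetLabels(pp)), function(su) {
    res <- subsampledNN(pp, su, k = k,
                        nIterations = config$nIterations %||% 2,
                        seed = seed, confidence = config$confidence %||% 0.95,
                        margin = config$margin %||% 0.05, dims = dims)
    cbind(data.frame(subset = su), res$perCell,
          data.frame(sample_size = res$sampleSize,
                     population = res$populationSize))
  }))
  utils::write.csv(nn, file.path(out, "nn_results.csv"), row.names = FALSE,
                   quote = FALSE)
  mask <- detectClusters(pp, binSize = config$binSize %||% 25,
                         minCountPerBin = config$minCountPerBin %||% 3,
                         minCellsPerCluster = config$minCellsPerCluster %||%
                           (config$minCountPerBin %||% 3))
  writeClusterMask(mask, file.path(out, "cluster_bins.csv"),
                   file.path(out, "cluster_header.json"))
  pooled <- tapply(nn$mean_nn_um, nn$subset, mean)
  s <- .writeJSON(list(k = k, dims = dims,
                       pooled_mean_nn_um = as.list(pooled),
                       n_clusters = nClusters(mask)),
                  file.path(out, "spatial_summary.json"))
  list(files = c("nn_results.csv", "cluster_bins.csv", "cluster_header.json", s),
       summary = list(n_clusters = nClusters(mask)))
}

.runDecay <- function(config, out, seed) {
  ds <- readDecay(config$input)
  fit <- fitOnePhaseDecay(ds, plateau_mode = config$plateauMode %||% "zero")
  s <- .writeJSON(list(n0 = fit@n0, k_per_day = fit@k, plateau = fit@plateau,
                       t_half_days = if (is.finite(fit@tHalf)) fit@tHalf else "Inf",
                       rss = fit@rss, converged = fit@converged,
                       plateau_mode = fit@plateauMode, n_obs = fit@nObs),
                  file.path(out, "decay_fit.json"))
  list(files = s, summary = list(t_half_days = fit@tHalf))
}

.runRepertoire <- function(config, out, seed) {
  rows <- readAIRR(config$input)
  meta <- readSampleMetadata(config$metadata)
  minSize <- config$minSize %||% 10
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    buildClones(rows[rows$sample_id == meta$sample_id[i], , drop = FALSE],
                min_size = minSize, metadata = meta[i, ])
  })
  names(samples) <- meta$sample_id
  samples <- Filter(nClones, samples)

  cloneTab <- do.call(rbind, lapply(samples, function(s) {
    cl <- cloneTable(s)
    data.frame(sample_id = s@sampleId, clone_key = cl$clone_key,
               v_gene = cl$v_gene, junction_aa = cl$junction_aa,
               isotype = cl$isotype, size = cl$size, n_seqs = cl$n_seqs)
  }))
  utils::write.table(cloneTab, file.path(out, "clone_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  div <- data.frame(sample_id = names(samples),
                    n_clones = vapply(samples, nClones, integer(1)),
                    chao1 = vapply(samples, chao1, numeric(1)))
  utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE,
                   quote = FALSE)

  ids <- names(samples)
  ov <- do.call(rbind, lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(seq_along(ids), function(j) {
      if (j <= i) return(NULL)
      data.frame(sample_a = ids[i], sample_b = ids[j],
                 jaccard_pct = overlapFraction(samples[[i]], samples[[j]]))
    }))
  }))
  if (is.null(ov)) ov <- data.frame(sample_a = character(0),
                                    sample_b = character(0),
                                    jaccard_pct = numeric(0))
  utils::write.csv(ov, file.path(out, "overlap.csv"), row.names = FALSE,
                   quote = FALSE)

  pcat <- findPublicClones(samples)
  utils::write.table(catalogEntries(pcat), file.path(out, "public_entries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(catalogOccurrences(pcat),
                     file.path(out, "public_occurrences.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  shm <- do.call(rbind, lapply(names(samples), function(sid) {
    cbind(data.frame(sample_id = sid), shmPerAllele(samples[[sid]], seed = seed))
  }))
  utils::write.csv(shm, file.path(out, "shm_per_allele.csv"),
                   row.names = FALSE, quote = FALSE)

  ## paired llpc-vs-bulk comparisons within mouse and tissue, BH-adjusted
  key <- paste(meta$mouse_id, meta$tissue)
  cmp <- list()
  for (kk in unique(key)) {
    sub <- meta[key == kk, ]
    a <- sub$sample_id[sub$subset == "llpc"]
    b <- sub$sample_id[sub$subset == "bulk"]
    if (length(a) == 1 && length(b) == 1 &&
        a %in% names(samples) && b %in% names(samples))
      cmp[[paste0(kk, ": llpc_vs_bulk")]] <-
        list(a = shmPerAllele(samples[[a]], seed = seed),
             b = shmPerAllele(samples[[b]], seed = seed))
  }
  files <- c("clone_table.tsv", "diversity.csv", "overlap.csv",
             "public_entries.tsv", "public_occurrences.tsv",
             "shm_per_allele.csv")
  if (length(cmp)) {
    tests <- pairedAlleleFamily(cmp)
    utils::write.csv(tests, file.path(out, "shm_tests.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "shm_tests.csv")
  }
  enr <- if (nrow(catalogEntries(pcat)))
    topPublicEnrichment(pcat, samples, n_top = config$nTop %||% 100,
                        target_subset = config$targetSubset %||% "llpc")
  else list(topFraction = NA, baselineFraction = NA, nTopUsed = 0)
  s <- .writeJSON(list(min_size = minSize,
                       n_samples = length(samples),
                       n_public_clones = nrow(catalogEntries(pcat)),
                       top_public_fraction_in_target = enr$topFraction,
                       baseline_fraction_in_target = enr$baselineFraction,
                       n_top_used = enr$nTopUsed),
                  file.path(out, "repertoire_summary.json"))
  list(files = c(files, s),
       summary = list(n_samples = length(samples),
                      n_public = nrow(catalogEntries(pcat))))
}

#' Run a pipeline subcommand
#'
#' Dispatches to one of the five stages (`simulate`, `tracks`, `spatial`,
#' `decay`, `repertoire`), writes its result tables under `out`, and stamps
#' a machine-readable `manifest.json` (configuration echo, seed, package and
#' R versions, input checksums, output checksums, timestamp). Outputs other
#' than the manifest are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param subcommand one of `"simulate"`, `"tracks"`, `"spatial"`,
#'   `"decay"`, `"repertoire"`.
#' @param config named list of parameters, or the path of a YAML file
#'   holding one. Input paths live in `config$input` (plus
#'   `config$metadata` for `repertoire`).
#' @param out output directory (created if missing).
#' @param seed integer seed; mandatory for stochastic subcommands
#'   (`simulate`, `spatial`, `repertoire`); may also come from
#'   `config$seed`.
#' @return Invisibly, a list with `files` (written result files) and
#'   `summary`.
#' @export
runPipeline <- function(subcommand = c("simulate", "tracks", "spatial",
                                       "decay", "repertoire"),
                        config = list(), out, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  seed <- seed %||% config$seed
  if (is.null(seed) && subcommand %in% c("simulate", "spatial", "repertoire"))
    .stopf("subcommand '%s' is stochastic and requires an explicit seed",
           subcommand)
  seed <- if (is.null(seed)) 0L else as.integer(seed)
  if (subcommand != "simulate" && is.null(config$input))
    .stopf("subcommand '%s' requires an input path in config$input",
           subcommand)
  if (subcommand == "repertoire" && is.null(config$metadata))
    .stopf("subcommand 'repertoire' requires a metadata path in config$metadata")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- unlist(config[intersect(c("input", "metadata"), names(config))])
  for (p in inputs) if (!file.exists(p)) .stopf("missing input file: %s", p)

  res <- switch(subcommand,
                simulate = .runSimulate(config, out, seed),
                tracks = .runTracks(config, out, seed),
                spatial = .runSpatial(config, out, seed),
                decay = .runDecay(config, out, seed),
                repertoire = .runRepertoire(config, out, seed))

  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config,
    package = "pcdyn",
    package_version = as.character(utils::packageVersion("pcdyn")),
    r_version = as.character(getRversion()),
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    else list(),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, res$files))), res$files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(res)
}
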