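## Seeded synthetic-data generators. Each generator is a pure function of its
## configuration object (including the seed) and returns ground truth
## alongside the data, so every downstream statistic can be tested against a
## known answer.

#' Simulate a two-subset spatial point pattern
#'
#' Places "bulk" and "llpc" cells in a rectangular box, either completely
#' spatially randomly (CSR) or by a parent-offspring (Thomas-like) clustered
#' process. Under the clustered process bulk cells are all offspring, while
#' each llpc cell is clustered offspring with probability
#' `llpcClusterAffinity` and uniform otherwise. Offspring landing outside the
#' box are resampled around their parent.
#'
#' @param config a [SpatialSimConfig-class].
#' @return A [PointPattern-class]; `patternInfo(x)$parents` holds the
#'   ground-truth cluster parent coordinates (clustered process only) and
#'   `patternInfo(x)$clustered` a per-point logical flag.
#' @examples
#' pp <- genPointPattern(SpatialSimConfig(seed = 1))
#' table(subsetLabels(pp))
#' @export
genPointPattern <- function(config) {
  stopifnot(is(config, "SpatialSimConfig"))
  validObject(config)
  d <- length(config@boxExtent)
  ext <- config@boxExtent
  withSeed(config@seed, {
    uniformIn <- function(n) {
      m <- matrix(runif(n * d), n, d)
      sweep(m, 2, ext, "*")
    }
    parents <- if (config@process == "clustered") uniformIn(config@nParents)
               else matrix(numeric(0), 0, d)
    offspringOf <- function(n) {
      if (n == 0L) return(matrix(numeric(0), 0, d))
      pid <- sample.int(nrow(parents), n, replace = TRUE)
      pos <- parents[pid, , drop = FALSE] +
        matrix(rnorm(n * d, sd = config@offspringSd), n, d)
      ## resample (not clip) points that fell outside the box
      repeat {
        out <- which(apply(pos < 0 | pos > matrix(ext, n, d, byrow = TRUE), 1, any))
        if (!length(out)) break
        pos[out, ] <- parents[pid[out], , drop = FALSE] +
          matrix(rnorm(length(out) * d, sd = config@offspringSd), length(out), d)
      }
      pos
    }
    nb <- as.integer(config@nCells[["bulk"]])
    nl <- as.integer(config@nCells[["llpc"]])
    if (config@process == "csr") {
      bulk <- uniformIn(nb)
      llpc <- uniformIn(nl)
      clustered <- rep(FALSE, nb + nl)
    } else {
      bulk <- offspringOf(nb)
      inCluster <- runif(nl) < config@llpcClusterAffinity
      llpc <- matrix(NA_real_, nl, d)
      if (any(inCluster)) llpc[inCluster, ] <- offspringOf(sum(inCluster))
      if (any(!inCluster)) llpc[!inCluster, ] <- uniformIn(sum(!inCluster))
      clustered <- c(rep(TRUE, nb), inCluster)
    }
    PointPattern(rbind(bulk, llpc),
                 c(rep("bulk", nb), rep("llpc", nl)), ext,
                 info = list(parents = parents, clustered = clustered,
                             process = config@process, seed = config@seed))
  })
}

#' Simulate two-phenotype cell tracks
#'
#' Generates arrested Gaussian random-walk tracks for each phenotype
#' ("sessile" emulating long-lived plasma cells, "motile" emulating the bulk
#' pool by default), with per-frame YFP and TdTomato channel intensities
#' drawn around phenotype-specific means.
#'
#' @param config a [TrackSimConfig-class].
#' @return A [TrackSet-class] whose frame table carries the ground-truth
#'   `phenotype` column.
#' @examples
#' ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 3, motile = 3),
#'                                nFrames = 5, seed = 1))
#' nTracks(ts)
#' @export
genTracks <- function(config) {
  stopifnot(is(config, "TrackSimConfig"))
  validObject(config)
  d <- as.integer(config@dims)
  nf <- as.integer(config@nFrames)
  dt <- config@frameInterval
  ext <- config@boxExtent[seq_len(d)]
  withSeed(config@seed, {
    parts <- lapply(names(config@nTracks), function(ph) {
      n <- as.integer(config@nTracks[[ph]])
      if (n == 0L) return(NULL)
      start <- sweep(matrix(runif(n * d), n, d), 2, ext, "*")
      ## steps: array [nf-1, n, d]; arrested frames take a zero step
      steps <- array(rnorm((nf - 1L) * n * d, sd = config@stepSd[[ph]]),
                     dim = c(nf - 1L, n, d))
      arrest <- matrix(runif((nf - 1L) * n) < config@arrestProb[[ph]],
                       nf - 1L, n)
      for (ax in seq_len(d)) steps[, , ax][arrest] <- 0
      pos <- array(0, dim = c(nf, n, d))
      for (ax in seq_len(d)) {
        pos[1L, , ax] <- start[, ax]
        if (nf > 1L)
          pos[-1L, , ax] <- matrix(start[, ax], nf - 1L, n, byrow = TRUE) +
            apply(steps[, , ax, drop = FALSE], 2, cumsum)
      }
      mu <- config@channelMeans[[ph]]
      yfp <- pmax(matrix(rnorm(nf * n, mu[["yfp"]], config@channelSd), nf, n),
                  1e-3)
      tom <- pmax(matrix(rnorm(nf * n, mu[["tomato"]], config@channelSd), nf, n),
                  1e-3)
      df <- data.frame(
        track_id = rep(sprintf("%s_%04d", ph, seq_len(n)), each = nf),
        phenotype = ph,
        t_min = rep(seq(0, by = dt, length.out = nf), times = n))
      coords <- do.call(cbind, lapply(seq_len(d), function(ax) as.vector(pos[, , ax])))
      colnames(coords) <- .axisNames(d)
      cbind(df, as.data.frame(coords),
            data.frame(ch_yfp = as.vector(yfp), ch_tomato = as.vector(tom)))
    })
    TrackSet(do.call(rbind, parts), interval = dt)
  })
}

#' Simulate a fate-labeled decaying cohort
#'
#' Expected counts follow `(n0 - plateau) * 2^(-t/tHalf) + plateau`; each
#' replicate observation multiplies the expectation by mean-one lognormal
#' noise with coefficient of variation `noiseCv` (exactly the expectation
#' when `noiseCv = 0`).
#'
#' @param config a [DecaySimConfig-class].
#' @param tissue,age_group optional metadata stamped on the series.
#' @return A [DecaySeries-class] with `nReplicates` counts per timepoint.
#' @examples
#' ds <- genDecayCohort(DecaySimConfig(noiseCv = 0, nReplicates = 1, seed = 1))
#' decayData(ds)
#' @export
genDecayCohort <- function(config, tissue = NA_character_,
                           age_group = NA_character_) {
  stopifnot(is(config, "DecaySimConfig"))
  validObject(config)
  tp <- config@timepoints
  mu <- (config@n0 - config@plateau) * 2^(-tp / config@tHalf) + config@plateau
  nrep <- as.integer(config@nReplicates)
  withSeed(config@seed, {
    if (config@noiseCv > 0) {
      s2 <- log(1 + config@noiseCv^2)
      ## meanlog = -s2/2 makes the noise factor mean-one (unbiased counts)
      fac <- matrix(stats::rlnorm(length(tp) * nrep, meanlog = -s2 / 2,
                                  sdlog = sqrt(s2)), length(tp), nrep)
    } else {
      fac <- matrix(1, length(tp), nrep)
    }
    counts <- as.vector(mu * fac)
    DecaySeries(day = rep(tp, times = nrep), count = counts,
                replicate_id = rep(sprintf("r%03d", seq_len(nrep)), each = length(tp)),
                tissue = tissue, age_group = age_group)
  })
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randomCdr3 <- function(n) {
  len <- sample(8:20, n, replace = TRUE)
  vapply(len, function(l) paste(sample(.AA, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate a multi-mouse BCR repertoire with spiked public clones
#'
#' Generates AIRR-style heavy-chain rearrangement rows per sample (one or two
#' sequences per clone), with Zipf-distributed clone sizes, subset-specific
#' isotype mixtures and Poisson mutation loads, then spikes
#' `nPublicClones` clone keys into samples of at least two distinct mice.
#' Background clone keys are globally unique by construction, so the spiked
#' list is the exact ground truth for public-clone detection.
#'
#' @param config a [RepertoireSimConfig-class].
#' @return A list with elements `rearrangements` (data.frame of AIRR-style
#'   rows), `metadata` (per-sample data.frame), `samples` (list of
#'   [RepertoireSample-class] built without a size filter), and
#'   `publicClones` (character vector of spiked clone keys).
#' @examples
#' sim <- genRepertoire(RepertoireSimConfig(nClonesPerSample = 50, seed = 1))
#' length(sim$publicClones)
#' @export
genRepertoire <- function(config) {
  stopifnot(is(config, "RepertoireSimConfig"))
  validObject(config)
  spm <- config@samplesPerMouse
  nper <- as.integer(config@nClonesPerSample)
  withSeed(config@seed, {
    meta <- do.call(rbind, lapply(seq_len(config@nMice), function(m) {
      data.frame(sample_id = sprintf("m%02d_%s_%s", m, spm$tissue, spm$subset),
                 mouse_id = sprintf("m%02d", m), tissue = spm$tissue,
                 subset = spm$subset, timepoint_day = config@timepoint,
                 age_group = config@ageGroup)
    }))
    rownames(meta) <- NULL

    usedKeys <- character(0)
    uniqueCdr3 <- function(vg, n) {
      cdr3 <- .randomCdr3(n)
      repeat {
        key <- paste(sub("\\*.*$", "", vg), cdr3, sep = "_")
        dup <- duplicated(key) | key %in% usedKeys
        if (!any(dup)) break
        cdr3[dup] <- .randomCdr3(sum(dup))
      }
      usedKeys <<- c(usedKeys, paste(sub("\\*.*$", "", vg), cdr3, sep = "_"))
      cdr3
    }

    zw <- seq_len(nper)^(-config@zipfExponent)
    perSample <- lapply(seq_len(nrow(meta)), function(i) {
      sm <- meta[i, ]
      vall <- sample(config@vGenes, nper, replace = TRUE)
      cdr3 <- uniqueCdr3(vall, nper)
      ## sizes: 1 + multinomial against shuffled Zipf weights -> guaranteed
      ## positive, heavy-tailed, with singletons/doubletons in the tail
      size <- 1L + as.integer(stats::rmultinom(1, 19L * nper, prob = sample(zw)))
      iso <- sample(c("IgM", "IgG", "IgA"), nper, replace = TRUE,
                    prob = config@isotypeProbs[[paste(sm$tissue, sm$subset, sep = ".")]])
      mut <- stats::rpois(nper, config@mutationMean[[sm$subset]])
      data.frame(sample_id = sm$sample_id, v_call = vall, junction_aa = cdr3,
                 c_call = iso, duplicate_count = size, mutation_count = mut,
                 v_sequence_length = config@vLength, locus = "IGH",
                 public = FALSE)
    })

    ## spike public clones: overwrite one background clone's key per chosen
    ## sample so clone counts per sample are conserved exactly
    publicKeys <- character(0)
    if (config@nPublicClones > 0) {
      pv <- sample(config@vGenes, config@nPublicClones, replace = TRUE)
      pc <- uniqueCdr3(pv, config@nPublicClones)
      publicKeys <- paste(sub("\\*.*$", "", pv), pc, sep = "_")
      for (p in seq_len(config@nPublicClones)) {
        nm <- sample(2:min(config@nMice, 4), 1)
        mice <- sample(sprintf("m%02d", seq_len(config@nMice)), nm)
        for (mid in mice) {
          cand <- which(meta$mouse_id == mid)
          isLl <- meta$subset[cand] == "llpc"
          pick <- if (any(isLl) && stats::runif(1) < config@publicLlpcBias)
            sample(rep(cand[isLl], 2), 1) else sample(rep(cand, 2), 1)
          rows <- perSample[[pick]]
          free <- which(!rows$public)
          j <- sample(rep(free, 2), 1)
          rows$v_call[j] <- pv[p]
          rows$junction_aa[j] <- pc[p]
          rows$duplicate_count[j] <- rows$duplicate_count[j] + 10L +
            stats::rpois(1, 15)
          rows$public[j] <- TRUE
          perSample[[pick]] <- rows
        }
      }
    }

    ## split ~10% of clones into two member sequences (second allele of the
    ## same gene where available) to exercise representative sampling
    rear <- do.call(rbind, lapply(perSample, function(rows) {
      n <- nrow(rows)
      split2 <- stats::runif(n) < 0.1 & rows$duplicate_count >= 2
      base <- rows
      base$seq_rank <- 1L
      extra <- rows[split2, , drop = FALSE]
      if (nrow(extra)) {
        extra$seq_rank <- 2L
        cut <- pmax(1L, extra$duplicate_count %/% 3L)
        base$duplicate_count[split2] <- base$duplicate_count[split2] - cut
        extra$duplicate_count <- cut
        extra$mutation_count <- stats::rpois(nrow(extra),
                                             pmax(extra$mutation_count, 0.5))
      }
      rbind(base, extra)
    }))
    rear <- rear[order(rear$sample_id, rear$v_call, rear$junction_aa,
                       rear$seq_rank), ]
    rear$sequence_id <- sprintf("%s_seq%05d", rear$sample_id,
                                stats::ave(seq_len(nrow(rear)), rear$sample_id,
                                           FUN = seq_along))
    rear$public <- NULL
    rear$seq_rank <- NULL
    rownames(rear) <- NULL
    rear <- rear[, c("sequence_id", "sample_id", "locus", "v_call", "c_call",
                     "junction_aa", "duplicate_count", "mutation_count",
                     "v_sequence_length")]

    samples <- lapply(seq_len(nrow(meta)), function(i) {
      buildClones(rear[rear$sample_id == meta$sample_id[i], ], min_size = 1,
                  metadata = meta[i, ])
    })
    names(samples) <- meta$sample_id
    list(rearrangements = rear, metadata = meta, samples = samples,
         publicClones = sort(publicKeys))
  })
}
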