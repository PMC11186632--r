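## Simulation configuration objects. Every generator is a pure function of
## its config, including the (mandatory, explicit) seed.

#' Configuration for spatial point-pattern simulation
#'
#' Defines a two-subset ("bulk" / "llpc") point pattern in a rectangular box,
#' either completely spatially random (CSR) or clustered by a parent-offspring
#' (Thomas-like) process: cluster parents are uniform in the box and offspring
#' scatter isotropically around them with Gaussian standard deviation
#' `offspringSd`; offspring falling outside the box are resampled rather than
#' clipped, to avoid boundary density artifacts.
#'
#' @slot boxExtent box side lengths per axis in μm (length 2 or 3).
#' @slot nCells named integer vector `c(bulk=, llpc=)` of cells per subset.
#' @slot process "csr" or "clustered".
#' @slot nParents number of cluster parents (clustered process).
#' @slot offspringSd Gaussian scatter of offspring around parents (μm).
#' @slot llpcClusterAffinity probability in \[0,1\] that an llpc cell is placed
#'   as clustered offspring rather than uniformly (clustered process only).
#' @slot seed integer RNG seed.
#' @exportClass SpatialSimConfig
setClass("SpatialSimConfig",
  slots = c(boxExtent = "numeric", nCells = "numeric", process = "character",
            nParents = "numeric", offspringSd = "numeric",
            llpcClusterAffinity = "numeric", seed = "numeric"))

setValidity("SpatialSimConfig", function(object) {
  msg <- character(0)
  if (!length(object@boxExtent) %in% c(2L, 3L) || any(object@boxExtent <= 0) ||
      any(!is.finite(object@boxExtent)))
    msg <- c(msg, "boxExtent must be 2 or 3 positive lengths")
  if (!all(c("bulk", "llpc") %in% names(object@nCells)) ||
      any(object@nCells < 0))
    msg <- c(msg, "nCells must be a named non-negative vector with 'bulk' and 'llpc'")
  if (!object@process %in% c("csr", "clustered"))
    msg <- c(msg, "process must be 'csr' or 'clustered'")
  if (!.isCount(object@nParents, min = 1L))
    msg <- c(msg, "nParents must be a positive integer")
  if (!(is.numeric(object@offspringSd) && object@offspringSd >= 0))
    msg <- c(msg, "offspringSd must be non-negative")
  if (!.isProb(object@llpcClusterAffinity))
    msg <- c(msg, "llpcClusterAffinity must be in [0,1]")
  if (!.isCount(abs(object@seed)))
    msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

#' @param boxExtent,nCells,process,nParents,offspringSd,llpcClusterAffinity,seed
#'   see the corresponding slots.
#' @return A validated `SpatialSimConfig`.
#' @rdname SpatialSimConfig-class
#' @export
SpatialSimConfig <- function(boxExtent = c(500, 500, 100),
                             nCells = c(bulk = 400, llpc = 100),
                             process = c("clustered", "csr"),
                             nParents = 15, offspringSd = 15,
                             llpcClusterAffinity = 0.8, seed) {
  process <- match.arg(process)
  new("SpatialSimConfig", boxExtent = as.numeric(boxExtent),
      nCells = nCells, process = process, nParents = nParents,
      offspringSd = offspringSd, llpcClusterAffinity = llpcClusterAffinity,
      seed = seed)
}

#' Configuration for two-phenotype track simulation
#'
#' Tracks are isotropic Gaussian random walks observed every `frameInterval`
#' minutes; at each frame a cell is arrested (zero step) with its phenotype's
#' `arrestProb`, otherwise it takes an independent Gaussian step per axis.
#' Channel intensities (YFP, TdTomato) are drawn per frame around
#' phenotype-specific means, providing a ratio signal for subset
#' classification.
#'
#' @slot nTracks named vector `c(sessile=, motile=)` of tracks per phenotype.
#' @slot frameInterval minutes between frames (default 3, the imaging cadence).
#' @slot nFrames frames per track (>= 2).
#' @slot stepSd named per-phenotype per-axis step s.d. in μm per frame.
#' @slot arrestProb named per-phenotype zero-step probability.
#' @slot channelMeans list with one `c(yfp=, tomato=)` pair per phenotype.
#' @slot channelSd per-frame Gaussian intensity noise s.d.
#' @slot boxExtent box for uniform starting positions (μm).
#' @slot dims 2 or 3.
#' @slot seed integer RNG seed.
#' @exportClass TrackSimConfig
setClass("TrackSimConfig",
  slots = c(nTracks = "numeric", frameInterval = "numeric", nFrames = "numeric",
            stepSd = "numeric", arrestProb = "numeric", channelMeans = "list",
            channelSd = "numeric", boxExtent = "numeric", dims = "numeric",
            seed = "numeric"))

setValidity("TrackSimConfig", function(object) {
  msg <- character(0)
  ph <- names(object@nTracks)
  if (is.null(ph) || any(!nzchar(ph)) || any(object@nTracks < 0))
    msg <- c(msg, "nTracks must be a named non-negative vector")
  if (!.isPositive(object@frameInterval))
    msg <- c(msg, "frameInterval must be > 0")
  if (!.isCount(object@nFrames, min = 2L))
    msg <- c(msg, "nFrames must be an integer >= 2")
  if (!all(ph %in% names(object@stepSd)) || any(object@stepSd < 0))
    msg <- c(msg, "stepSd must be non-negative with one entry per phenotype")
  if (!all(ph %in% names(object@arrestProb)) ||
      !all(vapply(object@arrestProb, .isProb, logical(1))))
    msg <- c(msg, "arrestProb must be probabilities with one entry per phenotype")
  if (!all(ph %in% names(object@channelMeans)))
    msg <- c(msg, "channelMeans must have one (yfp, tomato) pair per phenotype")
  if (!object@dims %in% c(2, 3)) msg <- c(msg, "dims must be 2 or 3")
  if (length(msg)) msg else TRUE
})

#' @param nTracks,frameInterval,nFrames,stepSd,arrestProb,channelMeans,channelSd,boxExtent,dims,seed
#'   see the corresponding slots.
#' @return A validated `TrackSimConfig`.
#' @rdname TrackSimConfig-class
#' @export
TrackSimConfig <- function(nTracks = c(sessile = 100, motile = 100),
                           frameInterval = 3, nFrames = 20,
                           stepSd = c(sessile = 0.2, motile = 2.0),
                           arrestProb = c(sessile = 0.5, motile = 0),
                           channelMeans = list(
                             sessile = c(yfp = 0.85, tomato = 1.0),
                             motile = c(yfp = 1.25, tomato = 1.0)),
                           channelSd = 0.03,
                           boxExtent = c(500, 500, 100), dims = 3, seed) {
  new("TrackSimConfig", nTracks = nTracks, frameInterval = frameInterval,
      nFrames = nFrames, stepSd = stepSd, arrestProb = arrestProb,
      channelMeans = channelMeans, channelSd = channelSd,
      boxExtent = as.numeric(boxExtent), dims = dims, seed = seed)
}

#' Configuration for labeled-cohort decay simulation
#'
#' Expected counts follow the one-phase decay
#' `(n0 - plateau) * 2^(-t / tHalf) + plateau`; observed counts multiply the
#' expectation by mean-one lognormal noise with coefficient of variation
#' `noiseCv`, keeping counts positive and unbiased.
#'
#' @slot n0 initial cohort count.
#' @slot tHalf half-life in days (> 0).
#' @slot plateau long-term count (default 0).
#' @slot timepoints observation days, strictly increasing.
#' @slot noiseCv coefficient of variation of the multiplicative noise.
#' @slot nReplicates replicates (animals) per timepoint.
#' @slot seed integer RNG seed.
#' @exportClass DecaySimConfig
setClass("DecaySimConfig",
  slots = c(n0 = "numeric", tHalf = "numeric", plateau = "numeric",
            timepoints = "numeric", noiseCv = "numeric", nReplicates = "numeric",
            seed = "numeric"))

setValidity("DecaySimConfig", function(object) {
  msg <- character(0)
  if (!.isPositive(object@tHalf)) msg <- c(msg, "tHalf must be > 0")
  if (object@n0 < 0 || object@plateau < 0)
    msg <- c(msg, "n0 and plateau must be non-negative")
  if (!length(object@timepoints) || any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be non-empty and strictly increasing")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be non-negative")
  if (!.isCount(object@nReplicates, min = 1L))
    msg <- c(msg, "nReplicates must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param n0,tHalf,plateau,timepoints,noiseCv,nReplicates,seed see the
#'   corresponding slots.
#' @return A validated `DecaySimConfig`.
#' @rdname DecaySimConfig-class
#' @export
DecaySimConfig <- function(n0 = 50000, tHalf = 58, plateau = 0,
                           timepoints = c(5, 30, 90, 150), noiseCv = 0.2,
                           nReplicates = 6, seed) {
  new("DecaySimConfig", n0 = n0, tHalf = tHalf, plateau = plateau,
      timepoints = as.numeric(timepoints), noiseCv = noiseCv,
      nReplicates = nReplicates, seed = seed)
}

#' Configuration for BCR repertoire simulation
#'
#' Each sample carries `nClonesPerSample` heavy-chain clones with sizes
#' `1 + multinomial` draws against Zipf (rank^-s) weights, giving heavy-tailed
#' abundances with singletons and doubletons. `nPublicClones` clone keys are
#' spiked into samples of at least two distinct mice (preferring llpc-labeled
#' samples with probability `publicLlpcBias`) by overwriting a background
#' clone's key, so per-sample clone counts stay exactly as configured; spiked
#' occurrences receive a duplicate-count boost so they survive the default
#' clone-size filter.
#'
#' @slot nMice number of mice.
#' @slot samplesPerMouse data.frame with columns `tissue` and `subset`, one
#'   row per sample collected from each mouse.
#' @slot nClonesPerSample clones simulated per sample.
#' @slot zipfExponent power-law exponent of clone abundances.
#' @slot nPublicClones clone keys spiked across mice.
#' @slot publicLlpcBias probability a public occurrence targets an llpc sample.
#' @slot isotypeProbs named list `"<tissue>.<subset>"` -> simplex over
#'   c(IgM, IgG, IgA).
#' @slot mutationMean named per-subset Poisson mean of V-region mutations.
#' @slot vGenes character vector of IGHV allele names (e.g. "IGHV1-12*01").
#' @slot vLength V-region length in nucleotides (default 300).
#' @slot timepoint,ageGroup metadata applied to all samples.
#' @slot seed integer RNG seed.
#' @exportClass RepertoireSimConfig
setClass("RepertoireSimConfig",
  slots = c(nMice = "numeric", samplesPerMouse = "data.frame",
            nClonesPerSample = "numeric", zipfExponent = "numeric",
            nPublicClones = "numeric", publicLlpcBias = "numeric",
            isotypeProbs = "list", mutationMean = "numeric",
            vGenes = "character", vLength = "numeric", timepoint = "numeric",
            ageGroup = "character", seed = "numeric"))

setValidity("RepertoireSimConfig", function(object) {
  msg <- character(0)
  if (!.isCount(object@nMice, min = 1L)) msg <- c(msg, "nMice must be >= 1")
  if (!all(c("tissue", "subset") %in% names(object@samplesPerMouse)))
    msg <- c(msg, "samplesPerMouse needs 'tissue' and 'subset' columns")
  if (!.isCount(object@nClonesPerSample, min = 1L))
    msg <- c(msg, "nClonesPerSample must be >= 1")
  if (object@zipfExponent <= 0) msg <- c(msg, "zipfExponent must be > 0")
  if (!.isCount(object@nPublicClones)) msg <- c(msg, "nPublicClones must be >= 0")
  if (object@nPublicClones > 0 && object@nMice < 2)
    msg <- c(msg, "public clones require at least 2 mice")
  if (!.isProb(object@publicLlpcBias))
    msg <- c(msg, "publicLlpcBias must be in [0,1]")
  groups <- unique(paste(object@samplesPerMouse$tissue,
                         object@samplesPerMouse$subset, sep = "."))
  for (g in groups) {
    p <- object@isotypeProbs[[g]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, sprintf("isotypeProbs[['%s']] must be a simplex", g))
  }
  subs <- unique(object@samplesPerMouse$subset)
  if (!all(subs %in% names(object@mutationMean)) || any(object@mutationMean < 0))
    msg <- c(msg, "mutationMean needs a non-negative entry per subset")
  if (!length(object@vGenes)) msg <- c(msg, "vGenes must be non-empty")
  if (!.isPositive(object@vLength)) msg <- c(msg, "vLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nMice,samplesPerMouse,nClonesPerSample,zipfExponent,nPublicClones,publicLlpcBias,isotypeProbs,mutationMean,vGenes,vLength,timepoint,ageGroup,seed
#'   see the corresponding slots.
#' @return A validated `RepertoireSimConfig`.
#' @rdname RepertoireSimConfig-class
#' @export
RepertoireSimConfig <- function(
    nMice = 4,
    samplesPerMouse = data.frame(
      tissue = c("BM", "BM", "spleen", "spleen"),
      subset = c("llpc", "bulk", "llpc", "bulk")),
    nClonesPerSample = 300, zipfExponent = 1.5, nPublicClones = 25,
    publicLlpcBias = 0.75,
    isotypeProbs = list(
      BM.llpc = c(IgM = 0.15, IgG = 0.20, IgA = 0.65),
      BM.bulk = c(IgM = 0.20, IgG = 0.25, IgA = 0.55),
      spleen.llpc = c(IgM = 0.45, IgG = 0.15, IgA = 0.40),
      spleen.bulk = c(IgM = 0.30, IgG = 0.35, IgA = 0.35)),
    mutationMean = c(llpc = 2, bulk = 6),
    vGenes = sprintf("IGHV%d-%d*0%d", rep(1:5, each = 3), rep(1:3, 5),
                     rep(1:2, length.out = 15)),
    vLength = 300, timepoint = 90, ageGroup = "young", seed) {
  new("RepertoireSimConfig", nMice = nMice, samplesPerMouse = samplesPerMouse,
      nClonesPerSample = nClonesPerSample, zipfExponent = zipfExponent,
      nPublicClones = nPublicClones, publicLlpcBias = publicLlpcBias,
      isotypeProbs = isotypeProbs, mutationMean = mutationMean,
      vGenes = vGenes, vLength = vLength, timepoint = timepoint,
      ageGroup = ageGroup, seed = seed)
}
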