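# Generators: determinism, conservation of configured counts, and fidelity
# of the emulated statistical structure.

test_that("point-pattern generator respects bounds, counts and empty case", {
  empty <- genPointPattern(SpatialSimConfig(nCells = c(bulk = 0, llpc = 0),
                                            seed = 1))
  expect_equal(nPoints(empty), 0)

  cfg <- SpatialSimConfig(boxExtent = c(500, 500, 500),
                          nCells = c(bulk = 400, llpc = 100),
                          process = "csr", seed = 7)
  pp <- genPointPattern(cfg)
  expect_equal(unname(table(subsetLabels(pp))[c("bulk", "llpc")]),
               c(400L, 100L), ignore_attr = TRUE)
  expect_true(all(spotCoords(pp) >= 0) && all(spotCoords(pp) <= 500))

  clus <- genPointPattern(SpatialSimConfig(process = "clustered", seed = 7))
  expect_true(all(spotCoords(clus) >= 0))
  expect_true(all(sweep(spotCoords(clus), 2, boxExtent(clus), "<=")))
})

test_that("clustered patterns have smaller mean 20-NN distance than CSR", {
  base <- list(boxExtent = c(500, 500, 500), nCells = c(bulk = 300, llpc = 100))
  clus <- genPointPattern(do.call(SpatialSimConfig,
    c(base, list(process = "clustered", offspringSd = 10, seed = 11))))
  csr <- genPointPattern(do.call(SpatialSimConfig,
    c(base, list(process = "csr", seed = 11))))
  mClus <- mean(knnMeanDistance(clus, seq_len(nPoints(clus)), k = 20, dims = 3))
  mCsr <- mean(knnMeanDistance(csr, seq_len(nPoints(csr)), k = 20, dims = 3))
  expect_lt(mClus, mCsr)
})

test_that("mean 20-NN distance shrinks as offspring scatter tightens", {
  ms <- vapply(c(40, 20, 10), function(sd) {
    pp <- genPointPattern(SpatialSimConfig(boxExtent = c(500, 500, 500),
                                           offspringSd = sd, seed = 3))
    mean(knnMeanDistance(pp, seq_len(nPoints(pp)), k = 20, dims = 3))
  }, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("generators are pure functions of their config seed", {
  cfg <- SpatialSimConfig(seed = 5)
  expect_identical(genPointPattern(cfg), genPointPattern(cfg))
  tcfg <- TrackSimConfig(nTracks = c(sessile = 20, motile = 20), seed = 5)
  expect_identical(trackFrames(genTracks(tcfg)), trackFrames(genTracks(tcfg)))
  dcfg <- DecaySimConfig(seed = 5)
  expect_identical(genDecayCohort(dcfg), genDecayCohort(dcfg))
  rcfg <- RepertoireSimConfig(nClonesPerSample = 50, seed = 5)
  expect_identical(genRepertoire(rcfg)$rearrangements,
                   genRepertoire(rcfg)$rearrangements)
  # and they leave the caller's RNG stream untouched
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(genPointPattern(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("degenerate track config yields stationary tracks", {
  ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 5, motile = 0),
                                 stepSd = c(sessile = 0, motile = 1),
                                 arrestProb = c(sessile = 1, motile = 0),
                                 nFrames = 8, seed = 2))
  st <- trackStatistics(ts)
  expect_equal(st$track_velocity, rep(0, 5))
  expect_equal(st$displacement_velocity, rep(0, 5))
})

test_that("motile phenotype is faster than sessile on generated tracks", {
  ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 200, motile = 200),
                                 stepSd = c(sessile = 0.2, motile = 2.0),
                                 seed = 13))
  st <- trackStatistics(ts)
  mv <- tapply(st$track_velocity, st$phenotype, mean)
  expect_gt(mv[["motile"]], mv[["sessile"]])
})

test_that("decay generator matches the closed form and is unbiased", {
  exact <- genDecayCohort(DecaySimConfig(n0 = 1000, tHalf = 60, plateau = 0,
                                         timepoints = c(0.001, 30, 60),
                                         noiseCv = 0, nReplicates = 1,
                                         seed = 1))
  d <- decayData(exact)
  expect_equal(d$count[d$day == 60], 500, tolerance = 1e-9)
  at0 <- genDecayCohort(DecaySimConfig(n0 = 1000, tHalf = 60,
                                       timepoints = c(0, 30), noiseCv = 0,
                                       nReplicates = 1, seed = 1))
  expect_equal(decayData(at0)$count[1], 1000)

  # noiseless limit reproduces the exponential to 1e-9 relative error
  tp <- c(5, 30, 90, 150)
  mu <- 1000 * 2^(-tp / 60)
  nl <- genDecayCohort(DecaySimConfig(n0 = 1000, tHalf = 60, timepoints = tp,
                                      noiseCv = 0, nReplicates = 1, seed = 1))
  expect_equal(decayData(nl)$count, mu, tolerance = 1e-9)

  # mean-one lognormal noise: replicate means within 5% of noiseless value
  noisy <- genDecayCohort(DecaySimConfig(n0 = 1000, tHalf = 60, timepoints = tp,
                                         noiseCv = 0.2, nReplicates = 500,
                                         seed = 4))
  dm <- tapply(decayData(noisy)$count, decayData(noisy)$day, mean)
  expect_true(all(abs(dm[as.character(tp)] / mu - 1) < 0.05))
})

test_that("repertoire generator conserves counts and spikes exact public set", {
  cfg <- RepertoireSimConfig(nClonesPerSample = 120, nPublicClones = 25,
                             seed = 21)
  sim <- genRepertoire(cfg)
  expect_equal(length(sim$samples), 16)  # 4 mice x 4 samples
  expect_true(all(vapply(sim$samples, nClones, integer(1)) == 120))
  expect_equal(length(sim$publicClones), 25)

  detected <- publicKeys(findPublicClones(sim$samples))
  expect_setequal(detected, sim$publicClones)

  none <- genRepertoire(RepertoireSimConfig(nClonesPerSample = 60,
                                            nPublicClones = 0, seed = 21))
  expect_equal(nrow(catalogEntries(findPublicClones(none$samples))), 0)
})

test_that("llpc samples carry fewer mutations than bulk samples", {
  sim <- genRepertoire(RepertoireSimConfig(nClonesPerSample = 400,
                                           mutationMean = c(llpc = 2, bulk = 6),
                                           nPublicClones = 0, seed = 8))
  freq <- vapply(sim$samples, function(s) {
    mean(shmPerAllele(s, seed = 1)$mean_freq)
  }, numeric(1))
  subs <- vapply(sim$samples, function(s) sampleInfo(s)$subset, character(1))
  expect_lt(mean(freq[subs == "llpc"]), mean(freq[subs == "bulk"]))
})

test_that("config validation rejects malformed parameters", {
  expect_error(SpatialSimConfig(boxExtent = c(-1, 10, 10), seed = 1),
               "boxExtent")
  expect_error(SpatialSimConfig(llpcClusterAffinity = 1.2, seed = 1),
               "llpcClusterAffinity")
  expect_error(TrackSimConfig(nFrames = 1, seed = 1), "nFrames")
  expect_error(DecaySimConfig(tHalf = 0, seed = 1), "tHalf")
  expect_error(DecaySimConfig(timepoints = c(5, 5, 30), seed = 1),
               "timepoints")
  expect_error(RepertoireSimConfig(
    isotypeProbs = list(BM.llpc = c(IgM = 0.5, IgG = 0.4, IgA = 0.4)),
    seed = 1), "simplex")
})
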