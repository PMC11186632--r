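# Nearest-neighbor statistic, survey sample size, subsampling, cluster
# masking and occupancy.

test_that("knn mean distance matches hand-computable geometries", {
  # query at origin, 3 reference points all at distance 2
  P <- rbind(c(0, 0), c(2, 0), c(0, 2), c(0, -2))  # 3 refs at distance 2
  pp <- PointPattern(P + 10, "bulk", extent = c(20, 20))
  expect_equal(unname(knnMeanDistance(pp, 1, k = 3)), 2)

  # reference points at distances 1..25 on one axis: mean of 20 nearest = 10.5
  P <- cbind(c(0, 1:25), 0)
  pp <- PointPattern(P, "bulk", extent = c(25, 1e-6) + 1)
  expect_equal(unname(knnMeanDistance(pp, 1, k = 20)), mean(1:20))
})

test_that("knn mean distance equals the exhaustive oracle in 2D and 3D", {
  for (d in 2:3) {
    set.seed(100 + d)
    n <- 200
    P <- matrix(runif(n * d, 0, 500), n, d)
    pp <- PointPattern(P, "bulk", extent = rep(500, d))
    got <- knnMeanDistance(pp, seq_len(n), k = 20, dims = d)
    want <- bruteKnnMean(P, seq_len(n), k = 20)
    expect_lt(max(abs(unname(got) - want)), 1e-9)
  }
})

test_that("knn errors when too few eligible reference points", {
  pp <- PointPattern(matrix(runif(20), 10, 2), "bulk", c(1, 1))
  expect_error(knnMeanDistance(pp, 1, k = 10), "eligible")
})

test_that("the 2D default drops the depth axis", {
  P <- cbind(c(0, 3, 4), c(0, 0, 0), c(0, 100, 200))
  pp <- PointPattern(P, "bulk", extent = c(10, 1e-6, 200) + 1)
  # in-plane distances from point 1 are 3 and 4
  expect_equal(unname(knnMeanDistance(pp, 1, k = 2, dims = 2)), 3.5)
  expect_gt(unname(knnMeanDistance(pp, 1, k = 2, dims = 3)), 50)
})

test_that("required sample size follows Cochran with finite-population correction", {
  expect_identical(requiredSampleSize(1000), 278L)
  expect_identical(requiredSampleSize(100), 80L)
  expect_identical(requiredSampleSize(10), 10L)  # capped at the population
  # non-decreasing in population, bounded by ceil(n0) = 385 at 95%/5%
  sizes <- vapply(c(10, 50, 100, 500, 1000, 1e4, 1e6), requiredSampleSize,
                  integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_true(all(sizes <= 385L))
  expect_error(requiredSampleSize(0), "population")
  expect_error(requiredSampleSize(100, margin = 0), "margin")
  expect_error(requiredSampleSize(100, confidence = 1), "confidence")
})

test_that("subsampled NN is exhaustive for small populations and seeded", {
  pp <- genPointPattern(SpatialSimConfig(nCells = c(bulk = 150, llpc = 10),
                                         seed = 2))
  res <- subsampledNN(pp, "llpc", seed = 9)
  # population 10 <= required sample size: every cell selected each iteration
  expect_equal(res$sampleSize, 10)
  llpcIdx <- which(subsetLabels(pp) == "llpc")
  for (it in 1:2)
    expect_setequal(res$perCell$cell_index[res$perCell$iteration == it],
                    llpcIdx)
  res2 <- subsampledNN(pp, "llpc", seed = 9)
  expect_identical(res, res2)
  # a population above the required sample size is genuinely subsampled,
  # so different seeds select different cells
  b9 <- subsampledNN(pp, "bulk", seed = 9)
  expect_lt(b9$sampleSize, b9$populationSize)
  expect_identical(b9, subsampledNN(pp, "bulk", seed = 9))
  expect_false(identical(b9$perCell, subsampledNN(pp, "bulk", seed = 10)$perCell))
})

test_that("subsampled statistic discriminates clustered from CSR patterns", {
  base <- list(boxExtent = c(500, 500, 100),
               nCells = c(bulk = 400, llpc = 120))
  clus <- genPointPattern(do.call(SpatialSimConfig,
    c(base, list(process = "clustered", seed = 41))))
  csr <- genPointPattern(do.call(SpatialSimConfig,
    c(base, list(process = "csr", seed = 41))))
  a <- subsampledNN(clus, "llpc", seed = 1)$pooledMean
  b <- subsampledNN(csr, "llpc", seed = 1)$pooledMean
  expect_lt(a, b)
  # and the subsampled value tracks the full-population statistic
  full <- mean(knnMeanDistance(clus, "llpc"))
  expect_lt(abs(a - full) / full, 0.25)
})

test_that("cluster detection handles empty and sub-threshold patterns", {
  empty <- PointPattern(matrix(numeric(0), 0, 3), character(0),
                        rep(500, 3))
  expect_equal(nClusters(detectClusters(empty, binSize = 20)), 0)
  lone <- PointPattern(matrix(c(250, 250, 250), 1), "bulk", rep(500, 3))
  expect_equal(nClusters(detectClusters(lone, binSize = 20,
                                        minCountPerBin = 3)), 0)
})

test_that("a dense blob plus sparse background yields one cluster", {
  set.seed(77)
  blob <- matrix(rnorm(200 * 3, mean = 250, sd = 10), 200, 3)
  bg <- matrix(runif(20 * 3, 0, 500), 20, 3)
  pp <- PointPattern(rbind(blob, bg), c(rep("blob", 200), rep("bg", 20)),
                     rep(500, 3))
  mask <- detectClusters(pp, binSize = 20, minCountPerBin = 3)
  expect_equal(nClusters(mask), 1)
  member <- maskMembership(blob, mask)
  expect_gte(mean(!is.na(member)), 0.95)
})

test_that("cluster masking is translation-equivariant up to bin alignment", {
  set.seed(5)
  blob <- matrix(rnorm(150 * 3, mean = 100, sd = 8), 150, 3)
  pp1 <- PointPattern(blob, "bulk", rep(500, 3))
  shift <- 40  # an exact multiple of the bin size
  pp2 <- PointPattern(blob + shift, "bulk", rep(500, 3))
  m1 <- detectClusters(pp1, binSize = 20, minCountPerBin = 3)
  m2 <- detectClusters(pp2, binSize = 20, minCountPerBin = 3)
  expect_equal(m2@bins, m1@bins + as.integer(shift / 20))
  expect_equal(clusterSizes(m1), clusterSizes(m2))
})

test_that("occupancy and residence follow frame membership exactly", {
  set.seed(6)
  blob <- matrix(rnorm(100 * 3, mean = 250, sd = 8), 100, 3)
  pp <- PointPattern(blob, "bulk", rep(500, 3))
  mask <- detectClusters(pp, binSize = 20, minCountPerBin = 3)

  inside <- makeTrack(matrix(250, 10, 3), id = "in")
  outside <- makeTrack(matrix(10, 10, 3), id = "out")
  # 5 of 10 frames inside at 3-min interval
  half <- makeTrack(rbind(matrix(250, 5, 3), matrix(10, 5, 3)), id = "half")
  occ <- clusterOccupancy(mergeTracks(inside, outside, half), mask,
                          group = "none")
  r <- occ$residence
  expect_equal(r$minutes_inside[r$track_id == "in"], 30)
  expect_equal(r$fraction_inside[r$track_id == "in"], 1)
  expect_equal(r$minutes_inside[r$track_id == "out"], 0)
  expect_equal(r$minutes_inside[r$track_id == "half"], 15)
  expect_equal(r$fraction_inside[r$track_id == "half"], 0.5)
  # per-frame fractions bounded and complementary
  expect_true(all(occ$occupancy$fraction_inside >= 0 &
                  occ$occupancy$fraction_inside <= 1))
})
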