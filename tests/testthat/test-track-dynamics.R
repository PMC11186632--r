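# Per-track motility statistics, MSD and classification.

test_that("track statistics handle stationary, collinear and closed paths", {
  still <- makeTrack(rbind(c(1, 2, 3), c(1, 2, 3)))
  st <- trackStatistics(still)
  expect_equal(st$track_velocity, 0)
  expect_equal(st$displacement_velocity, 0)

  line <- makeTrack(cbind(seq(0, 30, by = 3), 0, 0))  # 10 steps of 3 um / 3 min
  st <- trackStatistics(line)
  expect_equal(st$track_velocity, 1)
  expect_equal(st$displacement_velocity, 1)

  square <- makeTrack(rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3), c(0, 0)))
  st <- trackStatistics(square)  # perimeter 12 um in 12 min
  expect_equal(st$track_velocity, 1)
  expect_equal(st$displacement_velocity, 0)
})

test_that("displacement velocity never exceeds track velocity", {
  ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 50, motile = 50),
                                 seed = 31))
  st <- trackStatistics(ts)
  expect_true(all(st$displacement_velocity <= st$track_velocity + 1e-12))
  expect_true(all(st$path_length_um >= 0 & st$displacement_um >= 0))
})

test_that("tracks with fewer than two frames or bad times are rejected", {
  one <- makeTrack(matrix(c(0, 0, 0), 1))
  expect_error(trackStatistics(one), "<2 frames")
  bad <- data.frame(track_id = "t1", t_min = c(0, 3, 3), x_um = 0, y_um = 0,
                    ch_yfp = 1, ch_tomato = 1)
  expect_error(TrackSet(bad), "non-increasing")
})

test_that("msd matches closed forms and a brute-force pair loop", {
  still <- mergeTracks(makeTrack(matrix(0, 5, 3)),
                       makeTrack(matrix(1, 5, 3), id = "t2"))
  expect_true(all(msdCurve(still, maxLag = 12)$msd_um2 == 0))

  # ballistic track at 2 um/min: msd(tau) = 4 tau^2
  bal <- makeTrack(cbind(seq(0, 60, by = 6), 0, 0))
  ms <- msdCurve(bal, maxLag = 30)
  expect_equal(ms$msd_um2, 4 * ms$lag_min^2, tolerance = 1e-12)

  # implementation equals the exhaustive double loop on short random tracks
  set.seed(42)
  tracks <- mergeTracks(
    makeTrack(matrix(rnorm(20 * 3, sd = 2), 20, 3), id = "a"),
    makeTrack(matrix(rnorm(15 * 3, sd = 2), 15, 3)[seq_len(15), ], id = "b"),
    makeTrack(matrix(rnorm(8 * 3, sd = 2), 8, 3), id = "c"))
  ms <- msdCurve(tracks, maxLag = 21)
  expect_equal(ms$msd_um2, bruteMSD(tracks, 21), tolerance = 1e-12)
})

test_that("msd rejects empty input and sub-interval lags", {
  expect_error(msdCurve(TrackSet(data.frame(
    track_id = character(0), t_min = numeric(0), x_um = numeric(0),
    y_um = numeric(0), ch_yfp = numeric(0), ch_tomato = numeric(0)))),
    "empty")
  bal <- makeTrack(cbind(0:4 * 3, 0, 0))
  expect_error(msdCurve(bal, maxLag = 1), "below one frame interval")
})

test_that("fast fraction counts strict exceedances only", {
  st <- data.frame(track_velocity = c(0.2, 0.5, 0.9))
  expect_equal(fastFraction(st), 0)
  st <- data.frame(track_velocity = c(0.5, 1.5, 2.0, 0.9))
  expect_equal(fastFraction(st), 0.5)
  expect_equal(fastFraction(data.frame(track_velocity = 1.0)), 0)
  expect_error(fastFraction(data.frame()), "empty")
})

test_that("fast fraction is permutation-invariant and monotone in threshold", {
  set.seed(1)
  st <- data.frame(track_velocity = rexp(50))
  perm <- st[sample.int(50), , drop = FALSE]
  expect_equal(fastFraction(st), fastFraction(perm))
  thr <- seq(0, 3, by = 0.25)
  ff <- vapply(thr, function(t) fastFraction(st, t), numeric(1))
  expect_true(all(diff(ff) <= 0))
})

test_that("ratio classification uses the documented threshold convention", {
  st <- data.frame(mean_ratio = c(0.80, 1.50, 1.02))
  lab <- classifyByRatio(st)$subset_label
  expect_equal(lab, c("llpc_bright", "bulk_dim", "bulk_dim"))
  expect_error(classifyByRatio(data.frame(mean_ratio = c(1, NA))), "finite")
})

test_that("well-separated channel means give perfect subset recovery", {
  # channel means 0.85 vs 1.25 with sd 0.03: separation > 5 sd
  ts <- genTracks(TrackSimConfig(nTracks = c(sessile = 150, motile = 150),
                                 channelSd = 0.03, seed = 17))
  st <- classifyByRatio(trackStatistics(ts))
  expect_true(all(st$subset_label[st$phenotype == "sessile"] == "llpc_bright"))
  expect_true(all(st$subset_label[st$phenotype == "motile"] == "bulk_dim"))
})

test_that("gap splitting separates segments and keeps elapsed time honest", {
  df <- data.frame(track_id = "g1",
                   t_min = c(0, 3, 6, 30, 33, 36),
                   x_um = c(0, 3, 6, 100, 103, 106), y_um = 0, z_um = 0,
                   ch_yfp = 1, ch_tomato = 1)
  split <- splitTrackGaps(TrackSet(df, interval = 3))
  expect_equal(nTracks(split), 2)
  st <- trackStatistics(split)
  expect_equal(st$track_velocity, c(1, 1))  # no bridging across the gap
})

test_that("non-positive tomato intensity is an input error", {
  bad <- makeTrack(rbind(c(0, 0), c(1, 1)), tomato = 0)
  expect_error(trackStatistics(bad), "TdTomato")
})
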