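# Clone construction, diversity, overlap, public clones, isotypes, SHM and
# paired testing.

test_that("clone building groups by gene-level key and filters by size", {
  expect_equal(nClones(buildClones(data.frame())), 0)

  rows <- data.frame(
    v_call = c("IGHV1-1*01", "IGHV1-1*01", "IGHV2-3*01", "IGHV4-1*01"),
    junction_aa = c("CARWAY", "CARWAY", "CGGF", "CTTS"),
    duplicate_count = c(6, 6, 9, 4), locus = "IGH")
  s <- buildClones(rows, min_size = 10)
  # summed sizes per key: 12, 9, 4 -> one clone survives the size-10 filter
  expect_equal(nClones(s), 1)
  expect_equal(cloneTable(s)$clone_key, "IGHV1-1_CARWAY")
  expect_equal(s@dropped[["below_min_size"]], 2L)

  # allele suffixes *01 / *02 merge into one gene-level clone
  rows <- data.frame(v_call = c("IGHV8-9*01", "IGHV8-9*02"),
                     junction_aa = "CARDY", duplicate_count = c(7, 5))
  s <- buildClones(rows, min_size = 10)
  expect_equal(nClones(s), 1)
  expect_equal(cloneTable(s)$size, 12)
  expect_equal(cloneTable(s)$n_seqs, 2L)
})

test_that("rows without CDR3 or outside IGH are dropped and logged", {
  rows <- data.frame(
    v_call = c("IGHV1-1*01", "IGHV1-1*01", "IGKV1-1*01", "IGHV3-3*01"),
    junction_aa = c("CARWAY", NA, "CQQY", ""),
    duplicate_count = 20,
    locus = c("IGH", "IGH", "IGK", "IGH"))
  s <- buildClones(rows, min_size = 1)
  expect_equal(nClones(s), 1)
  expect_equal(s@dropped[["missing_cdr3"]], 2L)
  expect_equal(s@dropped[["non_igh"]], 1L)
})

test_that("clone building is idempotent through the row representation", {
  sim <- genRepertoire(RepertoireSimConfig(nClonesPerSample = 80, seed = 14))
  s <- sim$samples[[3]]
  rebuilt <- buildClones(asRearrangements(s), min_size = 1,
                         metadata = sampleInfo(s))
  expect_equal(cloneTable(rebuilt)$clone_key, cloneTable(s)$clone_key)
  expect_equal(cloneTable(rebuilt)$size, cloneTable(s)$size)
  expect_equal(cloneTable(rebuilt)$n_seqs, cloneTable(s)$n_seqs)
})

test_that("chao1 follows the singleton/doubleton formula", {
  expect_equal(chao1(c(3, 4, 5, 6)), 4)          # f1 = f2 = 0
  expect_equal(chao1(c(1, 1, 1, 2, 2, 3)), 8.25) # 6 + 9/4
  expect_equal(chao1(c(1, 2, 3)), 3.5)           # 3 + 1/2
  expect_equal(chao1(c(1, 1, 3)), 4)             # f2 = 0 branch: 3 + 1
  expect_error(chao1(numeric(0)), "empty")
  # Chao1 never falls below observed richness
  set.seed(2)
  for (i in 1:20) {
    sizes <- sample(1:5, 30, replace = TRUE)
    expect_gte(chao1(sizes), length(sizes))
  }
})

test_that("overlap percentage supports all denominator conventions", {
  a <- makeSample(sprintf("IGHV1-1_A%02d", 1:10))
  b <- makeSample(c(sprintf("IGHV1-1_A%02d", 1:4),
                    sprintf("IGHV2-1_B%02d", 1:4)), sample_id = "s2",
                  mouse = "m02")
  expect_equal(overlapFraction(a, b), 100 * 4 / 14)
  expect_equal(overlapFraction(a, b, mode = "first"), 40)
  expect_equal(overlapFraction(a, b, mode = "min"), 50)
  expect_equal(overlapFraction(a, a), 100)
  expect_equal(overlapFraction(b, a), overlapFraction(a, b))       # jaccard
  expect_equal(overlapFraction(b, a, "min"), overlapFraction(a, b, "min"))
  disjoint <- makeSample(sprintf("IGHV3-1_C%02d", 1:6), sample_id = "s3",
                         mouse = "m03")
  expect_equal(overlapFraction(a, disjoint), 0)
})

test_that("public clones require two samples from two distinct mice", {
  oneMouse <- list(makeSample("IGHV1-1_SHARED", mouse = "m01", sample_id = "a"),
                   makeSample("IGHV1-1_SHARED", mouse = "m01", sample_id = "b"))
  expect_equal(nrow(catalogEntries(findPublicClones(oneMouse))), 0)

  twoMice <- list(makeSample(c("IGHV1-1_SHARED", "IGHV1-1_PRIVA"),
                             mouse = "m01", sample_id = "a"),
                  makeSample(c("IGHV1-1_SHARED", "IGHV1-1_PRIVB"),
                             mouse = "m02", sample_id = "b"))
  cat2 <- findPublicClones(twoMice)
  expect_equal(publicKeys(cat2), "IGHV1-1_SHARED")
  expect_equal(catalogEntries(cat2)$n_mice, 2L)
})

test_that("removing a mouse never adds public clones", {
  sim <- genRepertoire(RepertoireSimConfig(nClonesPerSample = 100,
                                           nPublicClones = 15, seed = 33))
  full <- publicKeys(findPublicClones(sim$samples))
  mice <- vapply(sim$samples, function(s) sampleInfo(s)$mouse_id, character(1))
  for (m in unique(mice)) {
    reduced <- publicKeys(findPublicClones(sim$samples[mice != m]))
    expect_true(all(reduced %in% full))
  }
})

test_that("top-public enrichment fractions come from construction", {
  # 30 public clones; exactly 12 occur in an llpc sample
  keysLl <- sprintf("IGHV1-1_PUB%03d", 1:12)
  keysBk <- sprintf("IGHV2-1_PUB%03d", 13:30)
  sA <- makeSample(c(keysLl, keysBk), sizes = 30, mouse = "m01",
                   sample_id = "a", subset = "bulk")
  sB <- makeSample(keysBk, sizes = 30, mouse = "m02", sample_id = "b",
                   subset = "bulk")
  sC <- makeSample(keysLl, sizes = 30, mouse = "m02", sample_id = "c",
                   subset = "llpc")
  samples <- list(sA, sB, sC)
  pc <- findPublicClones(samples)
  enr <- topPublicEnrichment(pc, samples, n_top = 30)
  expect_equal(enr$topFraction, 12 / 30)
  expect_equal(enr$baselineFraction, 12 / 30)
  expect_equal(enr$nTopUsed, 30)
  # when every clone sits in a target-subset sample the fraction is 1
  allIn <- topPublicEnrichment(pc, samples, n_top = 30,
                               target_subset = "bulk")
  expect_equal(allIn$topFraction, 1)
})

test_that("isotype composition is a simplex under both weightings", {
  s <- makeSample(sprintf("IGHV1-1_K%02d", 1:10),
                  isotypes = c(rep("IgM", 2), rep("IgA", 6), rep("IgG", 2)),
                  sizes = 1)
  expect_equal(isotypeComposition(s),
               c(IgA = 0.6, IgG = 0.2, IgM = 0.2))
  one <- makeSample("IGHV1-1_ONLY", isotypes = "IgA")
  expect_equal(isotypeComposition(one), c(IgA = 1))
  # read weighting shifts mass toward a single dominant IgM clone
  s2 <- makeSample(sprintf("IGHV1-1_K%02d", 1:10),
                   isotypes = c("IgM", rep("IgA", 9)),
                   sizes = c(1000, rep(10, 9)))
  expect_gt(isotypeComposition(s2, weight = "reads")[["IgM"]],
            isotypeComposition(s2, weight = "clones")[["IgM"]])
  expect_equal(sum(isotypeComposition(s2, weight = "reads")), 1)
})

test_that("per-allele SHM averages representative frequencies", {
  s0 <- makeSample(sprintf("IGHV1-1_M%02d", 1:5), mutations = 0)
  expect_true(all(shmPerAllele(s0, seed = 1)$mean_freq == 0))

  s1 <- makeSample("IGHV1-1_SINGLE", mutations = 6, v_length = 300)
  expect_equal(shmPerAllele(s1, seed = 1)$mean_freq, 0.02)

  s2 <- makeSample(c("IGHV1-1_A", "IGHV1-1_B"), mutations = c(6, 12),
                   v_length = 300)
  expect_equal(shmPerAllele(s2, seed = 1)$mean_freq, 0.03)
  # reproducible under a fixed seed
  expect_identical(shmPerAllele(s2, seed = 4), shmPerAllele(s2, seed = 4))
})

test_that("SHM representative sampling is unbiased over seeds", {
  # one clone with two member sequences at different mutation loads
  rows <- data.frame(v_call = "IGHV1-1*01", junction_aa = "CARX",
                     duplicate_count = c(10, 10), mutation_count = c(0, 12),
                     v_sequence_length = 300, locus = "IGH")
  s <- buildClones(rows, min_size = 1)
  vals <- vapply(1:1000, function(sd) shmPerAllele(s, seed = sd)$mean_freq,
                 numeric(1))
  expect_equal(mean(vals), mean(c(0, 12)) / 300, tolerance = 0.1)
})

test_that("paired allele test matches the closed-form t statistic", {
  alleles <- c("IGHV1-1*01", "IGHV2-1*01", "IGHV3-1*01")
  a <- data.frame(v_allele = alleles, mean_freq = c(0.05, 0.06, 0.07))
  b <- data.frame(v_allele = alleles, mean_freq = c(0.04, 0.04, 0.04))
  # differences {0.01, 0.02, 0.03}: t = mean/ (sd/sqrt(3)) = 3.464..., df 2
  r <- pairedAlleleTest(a, b)
  expect_equal(r$t, 0.02 / (sd(c(0.01, 0.02, 0.03)) / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-r$t, df = 2), tolerance = 1e-12)
  expect_equal(r$p, 0.0742, tolerance = 1e-2)

  expect_equal(pairedAlleleTest(a, a)[c("t", "p")], list(t = 0, p = 1))
  # unmatched alleles are discarded; < 2 matches flags the comparison
  b2 <- data.frame(v_allele = c("IGHV1-1*01", "IGHV9-9*01"),
                   mean_freq = c(0.01, 0.02))
  expect_equal(pairedAlleleTest(a, b2)$flag, "too_few_alleles")
  # constant non-zero differences: degenerate, no p reported
  b3 <- data.frame(v_allele = alleles, mean_freq = c(0.04, 0.05, 0.06))
  expect_equal(pairedAlleleTest(a, b3)$flag, "zero_variance")
  expect_true(is.na(pairedAlleleTest(a, b3)$p))
})

test_that("family-wise BH adjustment matches the hand-stepped procedure", {
  alleles <- sprintf("IGHV%d-1*01", 1:6)
  mk <- function(shift, noise) {
    list(a = data.frame(v_allele = alleles,
                        mean_freq = 0.05 + shift + noise),
         b = data.frame(v_allele = alleles, mean_freq = 0.05))
  }
  set.seed(8)
  fam <- list(c1 = mk(0.010, rnorm(6, 0, 0.004)),
              c2 = mk(0.004, rnorm(6, 0, 0.004)),
              c3 = mk(0.000, rnorm(6, 0, 0.004)))
  res <- pairedAlleleFamily(fam)
  expect_equal(res$p_adj, bruteBH(res$p), tolerance = 1e-12)
  expect_true(all(res$p_adj <= 1))
  expect_true(all(res$p_adj >= res$p))
  # the spec-level example: raw {0.01, 0.02, 0.04} -> {0.03, 0.03, 0.04}
  expect_equal(bruteBH(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
})
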