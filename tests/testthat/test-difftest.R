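test_that("exact signed-rank p values match brute-force enumeration", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    dw <- runif(n, 0, 0.5)
    db <- dw + rnorm(n, 0.05, 0.2)
    if (sample(2, 1) == 1)   # force ties in |differences| sometimes
      db[2] <- dw[2] + (db[1] - dw[1])
    got <- wilcoxonSignedRankOneSided(dw, db)
    expect_equal(got$p, bruteForceSignedRankP(db - dw),
                 info = paste("case", i))
  }
})

test_that("tie-free exact p values agree with the reference implementation", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    diffs <- rnorm(n)
    ref <- suppressWarnings(
      stats::wilcox.test(diffs, alternative = "greater", exact = TRUE))
    got <- wilcoxonSignedRankOneSided(rep(0, n), diffs)
    expect_equal(got$p, ref$p.value)
  }
})

test_that("all-positive differences give the 2^-n p value", {
  expect_equal(wilcoxonSignedRankOneSided(rep(0.1, 5),
                                          seq(0.2, 0.6, 0.1))$p, 1 / 32)
  expect_equal(wilcoxonSignedRankOneSided(rep(0.1, 4),
                                          seq(0.2, 0.5, 0.1))$p, 0.0625)
  # so no region with fewer than 5 pairs can reach significance at 0.05
  smallest <- which(vapply(1:8, function(n)
    wilcoxonSignedRankOneSided(rep(0, n), seq_len(n))$p, numeric(1)) < 0.05)
  expect_equal(min(smallest), 5L)
})

test_that("zero differences and missing pairs are handled", {
  same <- wilcoxonSignedRankOneSided(c(0.1, 0.2), c(0.1, 0.2))
  expect_equal(same$p, 1)
  na <- wilcoxonSignedRankOneSided(c(0.1, NA, 0.2), c(0.5, 0.3, NA))
  expect_equal(na$n, 1L)
  empty <- wilcoxonSignedRankOneSided(c(NA, NA), c(1, 2))
  expect_true(is.na(empty$p))
  expect_error(wilcoxonSignedRankOneSided(1:3, 1:4), "equal length")
})

test_that("large samples switch to the continuity-corrected normal tail", {
  set.seed(43)
  diffs <- rnorm(40, 0.3)
  got <- wilcoxonSignedRankOneSided(rep(0, 40), diffs)
  ref <- stats::wilcox.test(diffs, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # the switch point is configurable
  exact <- wilcoxonSignedRankOneSided(rep(0, 40), diffs,
                                      exactLimit = 50L)
  expect_false(identical(exact$p, got$p))
})

test_that("BH adjustment is the standard step-up applied to the pooled family", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(0.42), 0.42)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(30)
  idx <- sample(30)
  expect_equal(bhAdjust(p)[idx], bhAdjust(p[idx]))
  withNA <- bhAdjust(c(0.01, NA, 0.04))
  expect_true(is.na(withNA[2]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("guided testing applies quality, median and bound rules", {
  dsp <- methods::new("DScoreProfiles", transcript = "tx",
                      dWithin = rep(0.1, 40),
                      dBetween = c(rep(0.5, 20), rep(0.05, 20)))
  dsps <- list(tx = dsp)

  strong <- data.frame(transcript_id = "tx", start = 5, end = 15)
  res <- guidedTest(strong, dsps, mA = 2, mB = 2)
  expect_equal(res$n_pairs, 11)
  expect_equal(res$p_value, 2^-11)
  expect_equal(res$q_value, res$p_value)
  expect_true(res$significant)

  # median delta-d <= 0: reported but never significant
  negative <- data.frame(transcript_id = "tx", start = 25, end = 35)
  resNeg <- guidedTest(negative, dsps, mA = 2, mB = 2)
  expect_equal(nrow(resNeg), 1L)
  expect_false(resNeg$significant)

  # failing the quality threshold excludes the region from testing
  noisy <- methods::new("DScoreProfiles", transcript = "tx",
                        dWithin = rep(0.6, 40), dBetween = rep(0.9, 40))
  resQ <- guidedTest(strong, list(tx = noisy), mA = 2, mB = 2)
  expect_equal(nrow(resQ), 0L)

  expect_error(guidedTest(data.frame(transcript_id = "tx", start = 30,
                                     end = 45), dsps, 2, 2), "bounds")
})

test_that("pooled-per-transcript mode tests one family per transcript", {
  dsp <- methods::new("DScoreProfiles", transcript = "tx",
                      dWithin = rep(0.1, 40), dBetween = rep(0.4, 40))
  cand <- data.frame(transcript_id = "tx", start = c(1, 30),
                     end = c(10, 39), mean_d_within = 0.1)
  pooled <- testRegions(cand, list(tx = dsp), pooledPerTranscript = TRUE)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$n_pairs, 20)
  separate <- testRegions(cand, list(tx = dsp))
  expect_equal(nrow(separate), 2L)
})

test_that("de novo discovery separates a strong planted block from null data", {
  rs <- makeDiffSet()
  res <- runDStruct(rs, l = 11)
  expect_gte(nrow(res), 1L)
  hit <- res[res$significant, ]
  expect_gte(nrow(hit), 1L)
  # the top region overlaps the planted block 21..40
  expect_true(any(pmin(hit$end, 40) - pmax(hit$start, 21) >= 0))

  null <- makeNullSet()
  resNull <- runDStruct(null, l = 11)
  expect_equal(sum(resNull$significant), 0L)
})

test_that("run orchestration is deterministic and sorted", {
  rs <- makeDiffSet()
  r1 <- runDStruct(rs, l = 5)
  r2 <- runDStruct(rs, l = 5)
  expect_equal(r1, r2)
  expect_true(!is.unsorted(r1$q_value))
  expect_error(runDStruct(makeNullSet(samples = c("A1", "B1")), l = 5),
               "at least 3")
})
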