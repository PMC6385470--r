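test_that("smoothed PARS scores follow the 5-nt pseudocounted window", {
  zero <- smoothedPARS(rep(0, 8), rep(0, 8))
  expect_true(all(is.na(zero[c(1, 2, 7, 8)])))
  expect_equal(zero[3:6], rep(0, 4))

  asym <- smoothedPARS(rep(5, 9), rep(0, 9))
  expect_equal(asym[5], log2(10) - log2(5))

  v1 <- rpois(20, 10); s1 <- rpois(20, 10)
  expect_equal(smoothedPARS(v1, s1), -smoothedPARS(s1, v1))
  expect_error(smoothedPARS(1:4, 1:4), "at least 5")
  expect_error(smoothedPARS(1:6, 1:5), "equal length")
  expect_error(smoothedPARS(c(-1, 1:5), rep(0, 6)), "non-negative")
})

test_that("the structural-change score is the mean over the variant window", {
  expect_equal(vSNV(rep(0, 9), 5), 0)
  expect_equal(vSNV(c(NA, NA, 1, 2, 3, 4, 5, NA), 5), 3)
  expect_error(vSNV(rep(1, 9), 2), "out of bounds")
  expect_error(vSNV(c(NA, 1, 1, 1, 1), 3), "undefined")
})

test_that("permutation p values behave at the extremes and reproduce", {
  const <- c(NA, NA, rep(2, 9), NA, NA)
  res <- permutationPValue(const, 7, nPerm = 100, seed = 1)
  expect_equal(res$p, 0)   # strict inequality, all v_null equal v_SNV

  maxed <- c(NA, NA, 5, 5, 5, 5, 5, 0.1, 0.1, 0.1, 0.1, 0.1, NA, NA)
  resMax <- permutationPValue(maxed, 5, nPerm = 200, seed = 2)
  expect_equal(resMax$vSnv, 5)
  expect_lt(resMax$p, 0.05)

  few <- c(NA, NA, 1, 1, 1, 0, 0, NA, NA)
  expect_true(is.na(permutationPValue(few, 5, seed = 3)$p))

  r1 <- permutationPValue(maxed, 5, nPerm = 300, seed = 9)
  r2 <- permutationPValue(maxed, 5, nPerm = 300, seed = 9)
  expect_identical(r1, r2)
})

test_that("permutation p converges to the full-enumeration value", {
  delta <- c(NA, NA, 0.3, 1.2, 0.4, 2.1, 0.9, 0.2, 1.5, NA, NA)
  k <- 6
  nz <- which(!is.na(delta) & delta != 0)
  vals <- delta[nz]
  # exact p over all 7! arrangements of the non-zero values
  allPerms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allPerms(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  vobs <- vSNV(delta, k)
  vnull <- vapply(allPerms(vals), function(p) {
    d <- delta; d[nz] <- p; vSNV(d, k)
  }, numeric(1))
  exact <- mean(vnull > vobs)
  mc <- permutationPValue(delta, k, nPerm = 4000, seed = 4)$p
  expect_equal(mc, exact, tolerance = 3 * sqrt(exact * (1 - exact) / 4000))
})

test_that("riboSNitch classification is a strict conjunction", {
  expect_false(classifyRiboSNitch(0.9, 0.001, 0.01, 100, 2))
  expect_false(classifyRiboSNitch(2, 0.2, 0.01, 100, 2))
  expect_false(classifyRiboSNitch(2, 0.001, 0.5, 100, 2))
  expect_false(classifyRiboSNitch(2, 0.001, 0.01, 1, 2))
  expect_false(classifyRiboSNitch(2, 0.001, 0.01, 100, 0.01))
  expect_true(classifyRiboSNitch(2, 0.001, 0.01, 100, 2))
  expect_false(classifyRiboSNitch(2, NA, NA, 100, 2))
})

test_that("variant filters deduplicate and enforce window coverage", {
  mkCounts <- function(level)
    list(tx1 = list(v1 = rep(level, 30), s1 = rep(level, 30)),
         tx2 = list(v1 = rep(level, 30), s1 = rep(level, 30)),
         low = list(v1 = rep(2, 30), s1 = rep(2, 30)))
  counts <- list(father = mkCounts(10), mother = mkCounts(10),
                 child = mkCounts(10))
  variants <- data.frame(
    transcript_id = c("tx1", "tx2", "low"),
    position = c(15L, 15L, 15L),
    locus = c("chr1:100", "chr1:100", "chr2:50"))
  kept <- filterVariants(variants, counts)
  # tx1/tx2 share a locus with identical windows -> collapsed; low coverage
  # (mean 4 + 4 = 8 < 10) -> dropped
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$transcript_id, "tx1")
  expect_equal(kept$window_mean_count, 20)

  # borderline: mean count just below 10 in one cell line is excluded
  counts$child$tx1$v1 <- rep(4, 30)
  counts$child$tx1$s1 <- rep(5, 30)   # window mean 9 < 10
  keptB <- filterVariants(variants[1, ], counts)
  expect_equal(nrow(keptB), 0L)
})

test_that("the full variant scorer flags a planted structure change", {
  set.seed(7)
  n <- 41
  base_v1 <- rpois(n, 30); base_s1 <- rpois(n, 30)
  alt_v1 <- base_v1; alt_s1 <- base_s1
  alt_v1[17:25] <- alt_v1[17:25] + 120   # strong local pairing gain
  counts1 <- list(tx = list(v1 = base_v1, s1 = base_s1))
  counts2 <- list(tx = list(v1 = alt_v1, s1 = alt_s1))
  variants <- data.frame(transcript_id = "tx", position = 21L)
  res <- strucDiffTable(variants, counts1, counts2, nPerm = 500, seed = 8)
  expect_gt(res$v_snv, 1)
  expect_lt(res$p_value, 0.05)
  expect_true(res$ribosnitch)

  # identical profiles give a zero change score
  resNull <- strucDiffTable(variants, counts1, counts1, nPerm = 100,
                            seed = 9)
  expect_equal(resNull$v_snv, 0)
  expect_false(resNull$ribosnitch)
})

test_that("permuting smoothed profiles understates the true null spread", {
  # smoothing correlates neighbouring delta values; permutation destroys
  # that correlation, so v_null is narrower than the sampling spread of
  # the score under the true generating process
  set.seed(10)
  n <- 61; k <- 31
  sampleScore <- function() {
    c1 <- list(v1 = rpois(n, 20), s1 = rpois(n, 20))
    c2 <- list(v1 = rpois(n, 20), s1 = rpois(n, 20))
    delta <- abs(smoothedPARS(c1$v1, c1$s1) - smoothedPARS(c2$v1, c2$s1))
    vSNV(delta, k)
  }
  trueSpread <- sd(replicate(200, sampleScore()))
  c1 <- list(v1 = rpois(n, 20), s1 = rpois(n, 20))
  c2 <- list(v1 = rpois(n, 20), s1 = rpois(n, 20))
  delta <- abs(smoothedPARS(c1$v1, c1$s1) - smoothedPARS(c2$v1, c2$s1))
  nz <- which(!is.na(delta) & delta != 0)
  vnull <- replicate(200, {
    d <- delta; d[nz] <- sample(delta[nz]); vSNV(d, k)
  })
  expect_lt(sd(vnull), trueSpread)
})
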