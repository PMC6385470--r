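test_that("ensembles are unique, reproducible and honestly paired", {
  e1 <- sampleEnsemble(60, 20, seed = 5)
  e2 <- sampleEnsemble(60, 20, seed = 5)
  expect_identical(e1@pairing, e2@pairing)
  expect_equal(nrow(e1@pairing), 20L)
  expect_equal(anyDuplicated(apply(e1@pairing, 1, paste, collapse = "")),
               0L)
  # stems are placed as runs of at least 3 paired nucleotides
  runs <- apply(e1@pairing, 1, function(v) {
    r <- rle(v); min(r$lengths[r$values]) })
  expect_true(all(runs >= 3))
  expect_error(sampleEnsemble(60, 5), "at least 6")

  db <- c("((((...))))", "..((....)).", "...........")
  fromDb <- ensembleFromDotBracket(db)
  expect_equal(dim(fromDb@pairing), c(3L, 11L))
  expect_equal(sum(fromDb@pairing[3, ]), 0)
})

test_that("group weights sum to one with disjoint dominant sets", {
  ens <- sampleEnsemble(60, 25, seed = 6)
  w <- assignWeights(ens, seed = 7)
  expect_equal(sum(w$A), 1)
  expect_equal(sum(w$B), 1)
  expect_true(all(w$A >= 0) && all(w$B >= 0))
  expect_length(intersect(w$dominantA, w$dominantB), 0L)
  expect_false(ens@mfeIndex %in% c(w$dominantA, w$dominantB))

  wMfe <- assignWeights(ens, mfeWeight = 0.4, seed = 7)
  expect_equal(wMfe$A[ens@mfeIndex], 0.4)
  expect_equal(sum(wMfe$A), 1)

  tiny <- ensembleFromDotBracket(c("(((...)))..", "..........."))
  expect_error(assignWeights(tiny), "disjoint")
})

test_that("raising the shared MFE weight drives the groups together", {
  ens <- sampleEnsemble(60, 25, seed = 8)
  P <- structureReactivities(ens, seed = 9)
  lo <- assignWeights(ens, mfeWeight = 0, seed = 10)
  hi <- assignWeights(ens, mfeWeight = 0.98, seed = 10)
  corLo <- cor(as.numeric(P %*% lo$A), as.numeric(P %*% lo$B))
  corHi <- cor(as.numeric(P %*% hi$A), as.numeric(P %*% hi$B))
  expect_gt(corHi, 0.99)
  expect_gt(corHi, corLo)
})

test_that("weight perturbation conserves mass and scales with noise", {
  w <- c(0.5, 0.3, 0.2)
  expect_identical(perturbWeights(w, 0), w)
  set.seed(11)
  p <- perturbWeights(w, 0.5)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # larger noise -> larger expected distance from the original
  dist <- function(ns) {
    set.seed(12)
    mean(replicate(200, sum(abs(perturbWeights(w, ns) - w))))
  }
  expect_lt(dist(0.1), dist(1))
  expect_error(perturbWeights(w, -1), ">= 0")
})

test_that("emitted profiles are the ensemble-weighted average of structures", {
  db <- ensembleFromDotBracket(c("((((...))))", "..........."))
  degenerate <- emissionModel(pairedMeanlog = log(0.2), pairedSdlog = 0,
                              unpairedMeanlog = log(2), unpairedSdlog = 0)
  one <- emitProfile(db, c(1, 0), degenerate)
  expect_equal(one, ifelse(db@pairing[1, ], 0.2, 2))
  half <- emitProfile(db, c(0.5, 0.5), degenerate)
  expect_equal(half, ifelse(db@pairing[1, ], 1.1, 2))

  masked <- emitProfile(db, c(1, 0), degenerate,
                        sequence = "GGGGGGGGGGG")
  expect_true(all(is.na(masked)))
  expect_error(emitProfile(db, c(0.7, 0.7), degenerate), "sum to 1")

  # shared per-structure profiles make replicates correlated
  ens <- sampleEnsemble(60, 20, seed = 13)
  P <- structureReactivities(ens, seed = 14)
  w <- assignWeights(ens, seed = 15)
  set.seed(16)
  a1 <- emitProfile(ens, perturbWeights(w$A, 0.3), structureProfiles = P)
  a2 <- emitProfile(ens, perturbWeights(w$A, 0.3), structureProfiles = P)
  b1 <- emitProfile(ens, perturbWeights(w$B, 0.3), structureProfiles = P)
  expect_gt(cor(a1, a2), cor(a1, b1))
})

test_that("count back-calculation inverts the reactivity pipeline", {
  r <- c(0.1, 0.2, 0.3, 0.4)
  cp <- backCalculateCounts(r, hitRate = sum(r),
                            treatedCoverage = rep(1000, 4),
                            untreatedCount = rep(0, 4),
                            untreatedCoverage = rep(1000, 4))
  expect_equal(cp$treated_count, round(1000 * r))

  # zero-signal positions carry background only
  cpBg <- backCalculateCounts(c(0, 1), hitRate = 1,
                              treatedCoverage = c(500, 500),
                              untreatedCount = c(5, 5),
                              untreatedCoverage = c(500, 500))
  expect_equal(cpBg$treated_count[1], 5)

  # round trip at high coverage with constant background
  set.seed(17)
  prof <- normalize28(rlnorm(60))$values
  cov <- rep(20000L, 60)
  cpRt <- backCalculateCounts(prof, hitRate = 1.5,
                              treatedCoverage = cov,
                              untreatedCount = rep(200L, 60),
                              untreatedCoverage = cov)
  rec <- reactivityFromCounts(cpRt)$values
  expect_equal(rec, normalize28(prof)$values, tolerance = 0.02)

  expect_error(backCalculateCounts(c(0, 0), 1, c(10, 10), c(0, 0),
                                   c(10, 10)), "zero")
  expect_error(backCalculateCounts(c(1, 2), 0, c(10, 10), c(0, 0),
                                   c(10, 10)), "positive")
})

test_that("generated datasets are reproducible with consistent truth", {
  s1 <- generateDataset(nTranscripts = 12, nDRR = 5, seed = 3)
  s2 <- generateDataset(nTranscripts = 12, nDRR = 5, seed = 3)
  expect_equal(SummarizedExperiment::assay(s1$reactivity),
               SummarizedExperiment::assay(s2$reactivity))
  expect_equal(s1$truth, s2$truth)

  expect_equal(nrow(s1$truth), 5L)
  expect_true(all(s1$truth$altered_start >= s1$truth$start))
  expect_true(all(s1$truth$altered_end <= s1$truth$end))
  len <- s1$truth$end - s1$truth$start + 1
  expect_true(all(len >= 50 & len <= 75))

  # DMS mode masks G/U everywhere
  m <- reactivityMatrix(s1$reactivity, "tx1")
  bases <- strsplit(s1$sequences[["tx1"]], "")[[1]]
  expect_true(all(is.na(m[bases %in% c("G", "U"), ])))
  expect_equal(unname(sampleGroups(s1$reactivity)), c("A", "B", "B"))

  # counts are returned per sample and match the transcript length
  expect_named(s1$counts, c("A1", "B1", "B2"))
  expect_length(s1$counts$A1$tx1$treated_count, 150L)

  null <- generateDataset(nTranscripts = 5, nDRR = 0, seed = 4)
  expect_equal(nrow(null$truth), 0L)
  expect_error(generateDataset(nTranscripts = 2, nDRR = 40, seed = 1),
               "packing")
})

test_that("planted regions show higher within- than between-group correlation", {
  sim <- generateDataset(nTranscripts = 30, nDRR = 15, seed = 5)
  within <- c(); between <- c()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    m <- reactivityMatrix(sim$reactivity, tr$transcript_id)
    sel <- tr$start:tr$end
    within <- c(within, cor(m[sel, "B1"], m[sel, "B2"],
                            use = "complete.obs"))
    between <- c(between, cor(m[sel, "A1"], m[sel, "B1"],
                              use = "complete.obs"))
  }
  expect_gt(mean(within), mean(between))
})

test_that("null datasets have essentially uncorrelated delta-d profiles", {
  sim <- generateDataset(nTranscripts = 25, nDRR = 0, seed = 6)
  plan <- planSubsets("A1", c("B1", "B2"))
  ac <- vapply(transcripts(sim$reactivity), function(tx) {
    dd <- deltaD(withinBetween(reactivityMatrix(sim$reactivity, tx),
                               plan, tx))
    dd <- dd[!is.na(dd)]
    if (length(dd) < 20) return(NA_real_)
    cor(dd[-1], dd[-length(dd)])
  }, numeric(1))
  expect_lt(abs(median(ac, na.rm = TRUE)), 0.1)
})
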