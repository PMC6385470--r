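# Small in-code fixtures shared across test files.

# Two-group set with a strong differential block and agreeing replicates
# elsewhere. Group B reactivities are flipped inside [from, to].
makeDiffSet <- function(n = 60, from = 21, to = 40, seed = 101,
                        noise = 0.05) {
  set.seed(seed)
  base <- stats::rlnorm(n, -1, 0.6)
  alt <- base
  alt[from:to] <- stats::rlnorm(to - from + 1, 0.7, 0.4)
  jitter <- function(x) pmax(x + stats::rnorm(n, 0, noise), 0.001)
  ReactivitySet(list(tx = cbind(A1 = jitter(base), A2 = jitter(base),
                                B1 = jitter(alt), B2 = jitter(alt))))
}

# Null set: all samples are independent jitters of one profile.
makeNullSet <- function(n = 80, seed = 202, noise = 0.1,
                        samples = c("A1", "A2", "B1", "B2")) {
  set.seed(seed)
  base <- stats::rlnorm(n, -0.5, 0.7)
  m <- vapply(samples, function(s)
    pmax(base + stats::rnorm(n, 0, noise), 0.001), numeric(n))
  colnames(m) <- samples
  ReactivitySet(list(tx = m))
}

# Exact one-sided signed-rank p by brute force over all 2^n sign vectors,
# with average ranks; independent oracle for the package's test.
bruteForceSignedRankP <- function(diffs) {
  diffs <- diffs[!is.na(diffs) & diffs != 0]
  n <- length(diffs)
  ranks <- rank(abs(diffs))
  w <- sum(ranks[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  stats <- apply(signs, 1L, function(s) sum(ranks[s]))
  mean(stats >= w)
}

# Brute-force subset plan oracle: for a GIVEN m, enumerate all size-m
# subsets and apply the printed maximal-heterogeneity filter.
bruteForceSubsets <- function(samplesA, samplesB, m) {
  all <- combn(c(samplesA, samplesB), m, simplify = FALSE)
  gA <- vapply(all, function(s) sum(s %in% samplesA), integer(1))
  gB <- m - gA
  hom <- all[gA == m | gB == m]
  mixed <- gA > 0 & gB > 0
  het <- gA * gB / m^2
  hetKeep <- all[mixed & het == max(het[mixed])]
  list(hom = hom, het = hetKeep)
}

canonicalSubsets <- function(subsets)
  sort(vapply(subsets, function(s) paste(sort(s), collapse = "+"),
              character(1)))
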