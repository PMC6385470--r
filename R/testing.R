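#' One-sided Wilcoxon signed-rank test for paired d scores
#'
#' Tests, for the paired per-nucleotide values of a candidate region,
#' whether \code{dBetween - dWithin} is shifted to positive values. Pairs
#' with either side missing are dropped, zero differences are dropped
#' before ranking, and tied absolute differences receive average ranks.
#' The exact null distribution of the positive-rank sum is computed by a
#' generating-function recursion (valid with average ranks) for up to
#' \code{exactLimit} pairs; beyond that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param dWithinRegion,dBetweenRegion paired numeric vectors.
#' @param exactLimit maximum n for the exact distribution (default 25).
#' @return list with \code{p} (NA if no testable pair remains), \code{n}
#'   (pairs remaining after dropping missing pairs) and \code{statistic}
#'   (positive-rank sum).
#' @examples
#' wilcoxonSignedRankOneSided(rep(0.1, 5), seq(0.2, 0.6, 0.1))$p  # 1/32
#' @export
wilcoxonSignedRankOneSided <- function(dWithinRegion, dBetweenRegion,
                                       exactLimit = 25L) {
  if (length(dWithinRegion) != length(dBetweenRegion))
    stop("paired vectors must have equal length")
  diffs <- dBetweenRegion - dWithinRegion
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  diffs <- diffs[diffs != 0]
  if (length(diffs) == 0L)
    return(list(p = if (n > 0L) 1 else NA_real_, n = n,
                statistic = NA_real_))
  ranks <- rank(abs(diffs))
  w <- sum(ranks[diffs > 0])
  nz <- length(diffs)
  p <- if (nz <= exactLimit) {
    exactSignedRankP(w, ranks)
  } else {
    mu <- nz * (nz + 1) / 4
    ties <- table(ranks)
    sigma2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
      sum(ties^3 - ties) / 48
    pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(p = min(p, 1), n = n, statistic = w)
}

# P(W+ >= w) where W+ is the sum of a random subset of `ranks` (each rank
# included independently with probability 1/2). Ranks are doubled so that
# average ranks (half-integers) become integers; the distribution is built
# by polynomial multiplication.
exactSignedRankP <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  coef <- numeric(total + 1L)  # coef[s + 1] = #subsets with doubled sum s
  coef[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), coef[seq_len(total + 1L - r)])
    coef <- coef + shifted
  }
  w2 <- as.integer(round(2 * w))
  sum(coef[seq.int(w2 + 1L, total + 1L)]) / 2^length(r2)
}

#' Benjamini-Hochberg adjustment of region p values
#'
#' Step-up FDR adjustment applied to the pooled set of candidate regions
#' from all transcripts (transcriptome-wide correction). Untestable regions
#' (\code{NA} p values) contribute nothing to the family and stay
#' \code{NA}.
#'
#' @param p numeric p values in [0, 1] (NA allowed).
#' @return q values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test candidate regions and control the FDR
#'
#' Applies the one-sided signed-rank test to each candidate region's paired
#' (d_within, d_between) values and BH-adjusts the p values across all
#' supplied regions. With \code{pooledPerTranscript = TRUE}, all candidate
#' pairs of a transcript are pooled into a single transcript-level test
#' (one row per transcript; this assesses significance at the transcript
#' level, not the region level).
#'
#' @param candidates data.frame with transcript_id, start, end,
#'   mean_d_within (from [findCandidates()] or user-supplied).
#' @param dsps named list of \linkS4class{DScoreProfiles}, keyed by
#'   transcript id.
#' @param alpha significance level on q values (default 0.05).
#' @param pooledPerTranscript pool candidates per transcript (default
#'   FALSE).
#' @param forceNonSignificant logical vector flagging regions that are
#'   reported but may not be called significant (guided-mode median rule).
#' @return data.frame with transcript_id, start, end, n_pairs,
#'   mean_d_within, p_value, q_value, significant; sorted by q value then
#'   coordinate.
#' @export
testRegions <- function(candidates, dsps, alpha = 0.05,
                        pooledPerTranscript = FALSE,
                        forceNonSignificant = NULL) {
  if (nrow(candidates) == 0L)
    return(emptyResults())
  if (is.null(forceNonSignificant))
    forceNonSignificant <- rep(FALSE, nrow(candidates))
  if (pooledPerTranscript) {
    res <- lapply(split(seq_len(nrow(candidates)),
                        candidates$transcript_id), function(idx) {
      tx <- candidates$transcript_id[idx[1L]]
      dsp <- dsps[[tx]]
      sel <- unlist(lapply(idx, function(i)
        seq.int(candidates$start[i], candidates$end[i])))
      wt <- wilcoxonSignedRankOneSided(dsp@dWithin[sel], dsp@dBetween[sel])
      data.frame(transcript_id = tx,
                 start = min(candidates$start[idx]),
                 end = max(candidates$end[idx]), n_pairs = wt$n,
                 mean_d_within = mean(dsp@dWithin[sel], na.rm = TRUE),
                 p_value = wt$p, forced = any(forceNonSignificant[idx]))
    })
    res <- do.call(rbind, res)
  } else {
    res <- candidates[, c("transcript_id", "start", "end"), drop = FALSE]
    stats <- lapply(seq_len(nrow(candidates)), function(i) {
      dsp <- dsps[[candidates$transcript_id[i]]]
      sel <- seq.int(candidates$start[i], candidates$end[i])
      wilcoxonSignedRankOneSided(dsp@dWithin[sel], dsp@dBetween[sel])
    })
    res$n_pairs <- vapply(stats, `[[`, numeric(1), "n")
    res$mean_d_within <- candidates$mean_d_within
    res$p_value <- vapply(stats, `[[`, numeric(1), "p")
    res$forced <- forceNonSignificant
  }
  res$q_value <- bhAdjust(res$p_value)
  res$significant <- !is.na(res$q_value) & res$q_value < alpha & !res$forced
  res$forced <- NULL
  res <- res[order(res$q_value, res$transcript_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

emptyResults <- function() {
  data.frame(transcript_id = character(), start = integer(),
             end = integer(), n_pairs = integer(),
             mean_d_within = numeric(), p_value = numeric(),
             q_value = numeric(), significant = logical())
}

#' Guided-mode testing of predefined candidate regions
#'
#' Screening is skipped; the user-supplied regions are quality-filtered
#' with the same minimum quality threshold as de novo discovery, and in
#' addition a region is only called a DRR if the median of its (unmasked)
#' \eqn{\Delta d} is positive - regions failing the median rule are still
#' reported, with \code{significant = FALSE}.
#'
#' @param regions data.frame with transcript_id, start, end.
#' @param dsps named list of \linkS4class{DScoreProfiles} keyed by
#'   transcript.
#' @param mA,mB replicate counts per group.
#' @param alpha significance level (default 0.05).
#' @param maxDWithin minimum quality threshold override.
#' @param pooledPerTranscript pool candidates per transcript.
#' @return result table as in [testRegions()].
#' @export
guidedTest <- function(regions, dsps, mA, mB, alpha = 0.05,
                       maxDWithin = defaultQualityThreshold(mA, mB),
                       pooledPerTranscript = FALSE) {
  if (nrow(regions) == 0L)
    return(emptyResults())
  for (i in seq_len(nrow(regions))) {
    dsp <- dsps[[regions$transcript_id[i]]]
    if (is.null(dsp))
      stop("no d-score profiles for transcript ", regions$transcript_id[i])
    n <- length(dsp@dWithin)
    if (regions$start[i] < 1L || regions$end[i] > n ||
        regions$start[i] > regions$end[i])
      stop("region outside transcript bounds: ",
           regions$transcript_id[i], ":", regions$start[i], "-",
           regions$end[i])
  }
  stats <- t(vapply(seq_len(nrow(regions)), function(i) {
    dsp <- dsps[[regions$transcript_id[i]]]
    sel <- seq.int(regions$start[i], regions$end[i])
    c(meanDW = mean(dsp@dWithin[sel], na.rm = TRUE),
      medianDelta = median(deltaD(dsp)[sel], na.rm = TRUE))
  }, numeric(2)))
  regions$mean_d_within <- stats[, "meanDW"]
  keep <- !is.na(regions$mean_d_within) & regions$mean_d_within < maxDWithin
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0L)
    return(emptyResults())
  force <- is.na(stats[keep, "medianDelta"]) |
    stats[keep, "medianDelta"] <= 0
  testRegions(regions, dsps, alpha = alpha,
              pooledPerTranscript = pooledPerTranscript,
              forceNonSignificant = force)
}
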