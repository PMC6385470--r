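#' Smoothed PARS scores
#'
#' Rolling 5-nt sums of pseudocounted V1 and S1 nuclease counts, combined
#' as a log2 ratio:
#' \eqn{\bar r_i = \log_2(\sum_{j=i-2}^{i+2}(V1_j+5)/5) -
#' \log_2(\sum_{j=i-2}^{i+2}(S1_j+5)/5)}.
#' Positions without a full 5-nt window (the two at each end) are
#' \code{NA}.
#'
#' @param v1,s1 non-negative count vectors of equal length >= 5.
#' @return smoothed PARS scores.
#' @examples
#' smoothedPARS(rep(0, 6), rep(0, 6))  # 0 at interior positions
#' @export
smoothedPARS <- function(v1, s1) {
  if (length(v1) != length(s1))
    stop("V1 and S1 vectors must have equal length")
  if (length(v1) < 5L)
    stop("need at least 5 nucleotides for the smoothing window")
  if (any(v1 < 0) || any(s1 < 0))
    stop("nuclease counts must be non-negative")
  winSum <- function(x)
    as.numeric(stats::filter(x, rep(1, 5), sides = 2))
  log2(winSum((v1 + 5) / 5)) - log2(winSum((s1 + 5) / 5))
}

#' Structural-change score around a variant
#'
#' The mean absolute difference of smoothed PARS scores over the five
#' nucleotides centered on the variant site k:
#' \eqn{v_{SNV} = (1/5)\sum_{i=k-2}^{k+2} \Delta\bar r_i}.
#'
#' @param deltaSmoothed vector of absolute differences
#'   \eqn{|\bar r_{i,1} - \bar r_{i,2}|} between the two individuals'
#'   smoothed PARS scores.
#' @param k 1-based variant position.
#' @return non-negative score.
#' @export
vSNV <- function(deltaSmoothed, k) {
  if (k - 2L < 1L || k + 2L > length(deltaSmoothed))
    stop("the 5-nt window around the variant is out of bounds")
  win <- deltaSmoothed[(k - 2L):(k + 2L)]
  if (anyNA(win))
    stop("the 5-nt window around the variant contains undefined scores")
  mean(win)
}

#' Permutation p value for a structural-change score
#'
#' The non-zero \eqn{\Delta\bar r} values are permuted \code{nPerm} times
#' (zero values and undefined edge positions stay in place), the null
#' score \eqn{v_{null}} is recomputed at the variant window for each
#' permutation, and the p value is the fraction of null scores strictly
#' greater than the observed score.
#'
#' @param deltaSmoothed absolute smoothed PARS score differences.
#' @param k variant position.
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{p}, \code{vSnv} and \code{nNonZero};
#'   \code{p} is \code{NA} (untestable) with fewer than 5 non-zero
#'   values.
#' @export
permutationPValue <- function(deltaSmoothed, k, nPerm = 1000L,
                              seed = NULL) {
  if (!is.null(seed))
    set.seed(seed)
  v <- vSNV(deltaSmoothed, k)
  nz <- which(!is.na(deltaSmoothed) & deltaSmoothed != 0)
  if (length(nz) < 5L)
    return(list(p = NA_real_, vSnv = v, nNonZero = length(nz)))
  vals <- deltaSmoothed[nz]
  vnull <- vapply(seq_len(nPerm), function(i) {
    perm <- deltaSmoothed
    perm[nz] <- vals[sample.int(length(vals))]
    vSNV(perm, k)
  }, numeric(1))
  list(p = mean(vnull > v), vSnv = v, nNonZero = length(nz))
}

#' Classify a variant region as a riboSNitch
#'
#' Conjunction of all criteria: significant p value and q value, a
#' structural-change score above 1, and adequate local coverage and
#' signal strength in the 11-nt window. The coverage and signal
#' thresholds are configurable because no canonical numeric values exist
#' for "high"; the defaults reuse the variant-filter coverage rule (mean
#' window count >= 10) and a minimum mean absolute smoothed score of 0.1.
#'
#' @param vSnv structural-change score.
#' @param p,q p and q values.
#' @param windowMeanCount mean (V1 + S1) count over the 11-nt window.
#' @param windowMeanSignal mean absolute smoothed PARS score over the
#'   window.
#' @param pMax,qMax significance thresholds (defaults 0.05 and 0.1).
#' @param minVSnv minimum score (default 1).
#' @param minCoverage,minSignal quality thresholds (defaults 10 and 0.1).
#' @return logical flag.
#' @export
classifyRiboSNitch <- function(vSnv, p, q, windowMeanCount,
                               windowMeanSignal, pMax = 0.05, qMax = 0.1,
                               minVSnv = 1, minCoverage = 10,
                               minSignal = 0.1) {
  !is.na(p) & !is.na(q) & p < pMax & q < qMax & vSnv > minVSnv &
    windowMeanCount >= minCoverage & windowMeanSignal >= minSignal
}

#' Filter and deduplicate candidate variants
#'
#' Applies the pre-analysis filters for PARS trio variants: variants at
#' the same genomic locus whose 11-nt count windows are identical across
#' all cell lines (duplicates from related transcript isoforms) are
#' collapsed to one, and a variant is excluded when the mean of
#' \eqn{V1_i + S1_i} over the 11-nt window centered on it is below
#' \code{minMeanCount} in any cell line.
#'
#' @param variants data.frame with columns \code{transcript_id},
#'   \code{position} and \code{locus} (genomic location key shared by
#'   duplicates).
#' @param counts named list (one entry per cell line) of named lists (one
#'   entry per transcript) with vectors \code{v1}, \code{s1}.
#' @param minMeanCount mean-count threshold (default 10).
#' @return the retained rows of \code{variants}, with a
#'   \code{window_mean_count} column (minimum across cell lines).
#' @export
filterVariants <- function(variants, counts, minMeanCount = 10) {
  if (nrow(variants) == 0L)
    return(cbind(variants, window_mean_count = numeric(0)))
  windowCounts <- function(cell, tx, k) {
    cc <- counts[[cell]][[tx]]
    if (is.null(cc))
      stop("no PARS counts for cell line ", cell, ", transcript ", tx)
    idx <- (k - 5L):(k + 5L)
    if (min(idx) < 1L || max(idx) > length(cc$v1))
      stop("11-nt window out of bounds for ", tx, ":", k)
    cc$v1[idx] + cc$s1[idx]
  }
  cells <- names(counts)
  wins <- lapply(seq_len(nrow(variants)), function(i)
    lapply(cells, windowCounts, tx = variants$transcript_id[i],
           k = variants$position[i]))
  sig <- vapply(wins, function(w)
    paste(unlist(w), collapse = ","), character(1))
  dupKey <- paste(variants$locus, sig)
  keepDedup <- !duplicated(dupKey)
  meanCounts <- vapply(wins, function(w)
    min(vapply(w, mean, numeric(1))), numeric(1))
  keep <- keepDedup & meanCounts >= minMeanCount
  out <- variants[keep, , drop = FALSE]
  out$window_mean_count <- meanCounts[keep]
  rownames(out) <- NULL
  out
}

#' Score variants with the smoothed-PARS permutation test
#'
#' Full riboSNitch scoring for a set of variants on one pair of
#' individuals: smoothed PARS scores per individual, absolute difference,
#' structural-change score at each variant, permutation p values,
#' BH-adjusted q values across all variants, and classification flags.
#'
#' @param variants data.frame with \code{transcript_id} and
#'   \code{position}.
#' @param counts1,counts2 named lists per transcript with vectors
#'   \code{v1}, \code{s1} for the two individuals.
#' @param nPerm permutations per variant (default 1000).
#' @param seed optional integer seed.
#' @param ... thresholds passed to [classifyRiboSNitch()].
#' @return data.frame with v_snv, p_value, q_value, ribosnitch.
#' @export
strucDiffTable <- function(variants, counts1, counts2, nPerm = 1000L,
                           seed = NULL, ...) {
  if (!is.null(seed))
    set.seed(seed)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    tx <- variants$transcript_id[i]
    k <- variants$position[i]
    c1 <- counts1[[tx]]
    c2 <- counts2[[tx]]
    if (is.null(c1) || is.null(c2))
      stop("no PARS counts for transcript ", tx)
    delta <- abs(smoothedPARS(c1$v1, c1$s1) - smoothedPARS(c2$v1, c2$s1))
    pr <- permutationPValue(delta, k, nPerm = nPerm)
    win <- (max(1L, k - 5L)):(min(length(c1$v1), k + 5L))
    data.frame(transcript_id = tx, position = k, v_snv = pr$vSnv,
               p_value = pr$p,
               window_mean_count = mean(c1$v1[win] + c1$s1[win] +
                                          c2$v1[win] + c2$s1[win]) / 2,
               window_mean_signal = mean(delta[win], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out$ribosnitch <- classifyRiboSNitch(out$v_snv, out$p_value,
                                       out$q_value,
                                       out$window_mean_count,
                                       out$window_mean_signal, ...)
  out
}
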