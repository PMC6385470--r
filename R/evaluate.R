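#' Power and observed FDR of reported regions against a known truth
#'
#' Power is the proportion of true regions overlapped by at least one
#' reported DRR; the observed FDR is the proportion of reported DRRs that
#' overlap no true region. Overlap means sharing at least
#' \code{minOverlap} nucleotides on the same transcript (default 1, the
#' any-overlap rule). With no reported DRRs the FDR is undefined
#' (\code{NA}).
#'
#' @param results result table (e.g. from [runDStruct()]); only rows with
#'   \code{significant == TRUE} count as reported DRRs unless the table
#'   has no \code{significant} column.
#' @param truth data.frame with transcript_id, start, end of the true
#'   regions.
#' @param minOverlap minimum shared nucleotides (default 1).
#' @return list with \code{power}, \code{fdr}, \code{nReported},
#'   \code{nTrue}.
#' @examples
#' truth <- data.frame(transcript_id = "tx", start = 10, end = 20)
#' hits <- data.frame(transcript_id = "tx", start = 18, end = 30)
#' evaluateCalls(hits, truth)  # power 1, fdr 0
#' @export
evaluateCalls <- function(results, truth, minOverlap = 1L) {
  if ("significant" %in% colnames(results))
    results <- results[!is.na(results$significant) & results$significant,
                       , drop = FALSE]
  overlaps <- function(a, b)
    a$transcript_id == b$transcript_id &
      pmin(a$end, b$end) - pmax(a$start, b$start) + 1L >= minOverlap
  hitTrue <- vapply(seq_len(nrow(truth)), function(i)
    nrow(results) > 0L &&
      any(overlaps(results, truth[i, , drop = FALSE])), logical(1))
  hitRep <- vapply(seq_len(nrow(results)), function(i)
    nrow(truth) > 0L &&
      any(overlaps(truth, results[i, , drop = FALSE])), logical(1))
  list(power = if (nrow(truth)) mean(hitTrue) else NA_real_,
       fdr = if (nrow(results)) mean(!hitRep) else NA_real_,
       nReported = nrow(results), nTrue = nrow(truth))
}
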