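#' Identify differentially reactive regions between two sample groups
#'
#' End-to-end differential reactivity analysis. Step 1 computes
#' per-nucleotide within- and between-group d-score profiles over the
#' sample subset plan. In de novo mode, step 2 masks \eqn{\Delta d} at
#' low-signal nucleotides, smooths it with a centered rolling mean of the
#' search length, extracts maximal positive runs as candidate regions,
#' trims and filters them, and applies the minimum quality threshold. In
#' guided mode the supplied regions replace step 2 (no masking or
#' smoothing), with the additional requirement of a positive median
#' \eqn{\Delta d}. Step 3 tests each surviving region with a one-sided
#' Wilcoxon signed-rank test and controls the FDR across all regions of
#' all transcripts with Benjamini-Hochberg.
#'
#' @param rs a \linkS4class{ReactivitySet}.
#' @param mode \code{"de-novo"} or \code{"guided"}.
#' @param l search length in nucleotides (default 11; ignored in guided
#'   mode).
#' @param alpha significance level on q values (default 0.05).
#' @param maxDWithin minimum quality threshold; defaults to 0.5 when both
#'   groups have >= 2 replicates and 0.2 otherwise.
#' @param regions data.frame of predefined candidate regions
#'   (transcript_id, start, end); required in guided mode.
#' @param signalThreshold low-signal masking threshold (default 0.1).
#' @param pooledPerTranscript pool all candidates of a transcript into one
#'   transcript-level test (default FALSE).
#' @param lessVariableGroupOnly experimental flag reserved for computing
#'   d_within from the less variable group only (as used when one group is
#'   known to be far noisier); not validated, currently ignored with a
#'   warning.
#' @return data.frame with one row per tested region: transcript_id,
#'   start, end, n_pairs, mean_d_within, p_value, q_value, significant
#'   (q < alpha). DRRs are the significant rows.
#' @examples
#' set.seed(1)
#' base <- rlnorm(60, -1, 0.6)
#' alt <- base; alt[21:40] <- rlnorm(20, 0.5, 0.6)
#' noisy <- function(x) pmax(x + rnorm(60, 0, 0.05), 0)
#' rs <- ReactivitySet(list(tx = cbind(A1 = noisy(base), A2 = noisy(base),
#'                                     B1 = noisy(alt), B2 = noisy(alt))))
#' runDStruct(rs, l = 11)
#' @export
runDStruct <- function(rs, mode = c("de-novo", "guided"), l = 11L,
                       alpha = 0.05, maxDWithin = NULL, regions = NULL,
                       signalThreshold = 0.1, pooledPerTranscript = FALSE,
                       lessVariableGroupOnly = FALSE) {
  mode <- match.arg(mode)
  if (lessVariableGroupOnly)
    warning("lessVariableGroupOnly is a documented stub and is ignored")
  grp <- sampleGroups(rs)
  samplesA <- names(grp)[grp == "A"]
  samplesB <- names(grp)[grp == "B"]
  if (length(samplesA) < 1L || length(samplesB) < 1L)
    stop("both groups must be represented among the samples")
  if (length(grp) < 3L)
    stop("need at least 3 samples in total")
  plan <- planSubsets(samplesA, samplesB)
  mA <- length(samplesA)
  mB <- length(samplesB)
  if (is.null(maxDWithin))
    maxDWithin <- defaultQualityThreshold(mA, mB)

  dsps <- list()
  candidates <- list()
  for (tx in transcripts(rs)) {
    m <- reactivityMatrix(rs, tx)
    dsp <- withinBetween(m, plan, transcript = tx)
    dsps[[tx]] <- dsp
    if (mode == "de-novo") {
      delta <- maskLowSignal(deltaD(dsp), m, threshold = signalThreshold)
      smoothed <- smoothDeltaD(delta, l)
      candidates[[tx]] <- findCandidates(smoothed, delta, m, l,
                                         dWithin = dsp@dWithin,
                                         transcript = tx)
    }
  }

  if (mode == "guided") {
    if (is.null(regions))
      stop("guided mode requires a 'regions' data.frame")
    res <- guidedTest(regions, dsps, mA, mB, alpha = alpha,
                      maxDWithin = maxDWithin,
                      pooledPerTranscript = pooledPerTranscript)
  } else {
    cand <- do.call(rbind, candidates)
    if (is.null(cand) || nrow(cand) == 0L)
      return(emptyResults())
    cand <- qualityFilter(cand, mA, mB, maxDWithin = maxDWithin)
    res <- testRegions(cand, dsps, alpha = alpha,
                       pooledPerTranscript = pooledPerTranscript)
  }
  attr(res, "dScoreProfiles") <- dsps
  attr(res, "plan") <- plan
  res
}
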