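#' Mask the differential signal at low-reactivity nucleotides
#'
#' Changes in the relative magnitude of very low reactivities are not
#' meaningful, so \eqn{\Delta d} is masked (set to \code{NA}) at
#' nucleotides where every sample has \eqn{|r| <} \code{threshold}
#' (missing reactivities count as below threshold). Applied on the
#' analysis-scale values as given, including signed PARS scores.
#'
#' @param delta numeric \eqn{\Delta d} vector.
#' @param profiles reactivity matrix (nucleotides x samples) aligned with
#'   \code{delta}.
#' @param threshold reactivity magnitude below which a sample is
#'   considered uninformative (default 0.1 on the normalized scale).
#' @return \code{delta} with low-signal positions masked.
#' @export
maskLowSignal <- function(delta, profiles, threshold = 0.1) {
  if (nrow(profiles) != length(delta))
    stop("profiles and delta must have equal length")
  if (threshold <= 0)
    return(delta)
  high <- abs(profiles) >= threshold
  high[is.na(high)] <- FALSE
  delta[rowSums(high) == 0L] <- NA_real_
  delta
}

#' Smooth a delta-d profile with a centered rolling mean
#'
#' Windows of length \code{l} are centered on each nucleotide and truncated
#' at the transcript ends, preserving the profile length so that run
#' coordinates map 1:1 to nucleotides. Missing values inside a window are
#' ignored; an all-missing window yields \code{NA}. The smoothed profile is
#' used only to construct candidate regions; statistical testing always
#' uses the unsmoothed profiles.
#'
#' @param delta numeric \eqn{\Delta d} vector (NA allowed).
#' @param l window length (the search length), >= 1.
#' @return smoothed vector of the same length.
#' @examples
#' smoothDeltaD(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
smoothDeltaD <- function(delta, l) {
  if (l < 1L)
    stop("search length l must be >= 1")
  if (l == 1L || length(delta) == 0L)
    return(delta)
  out <- zoo::rollapply(zoo::zoo(delta), width = l, align = "center",
                        partial = TRUE,
                        FUN = function(w) mean(w, na.rm = TRUE))
  out <- as.numeric(out)
  out[is.nan(out)] <- NA_real_
  out
}

#' Construct candidate regions from a smoothed delta-d profile
#'
#' Candidates are the maximal contiguous runs where the smoothed
#' \eqn{\Delta d} is strictly positive, of length >= \code{l} (a missing
#' smoothed value terminates a run). Runs of length >= 11 are trimmed from
#' both edges of nucleotides whose reactivity magnitude is below
#' \code{trimThreshold} in all samples; shorter runs are not trimmed, as
#' that costs power. Finally, runs must contain non-missing unsmoothed
#' \eqn{\Delta d} for at least 5 nucleotides when \code{l} > 5, or at least
#' \code{l} - 1 nucleotides when \code{l} <= 5.
#'
#' @param smoothed smoothed \eqn{\Delta d} (from [smoothDeltaD()]).
#' @param rawDelta unsmoothed, low-signal-masked \eqn{\Delta d}.
#' @param profiles reactivity matrix (nucleotides x samples).
#' @param l search length.
#' @param dWithin per-nucleotide within-group d scores, used to annotate
#'   each candidate's mean d_within (over non-missing positions).
#' @param transcript transcript id for the output.
#' @param trimThreshold edge-trim reactivity threshold (default 0.1).
#' @return data.frame with columns transcript_id, start, end,
#'   mean_d_within, n_informative; zero rows if no run qualifies.
#' @export
findCandidates <- function(smoothed, rawDelta, profiles, l, dWithin,
                           transcript = "transcript", trimThreshold = 0.1) {
  if (l < 1L)
    stop("search length l must be >= 1")
  pos <- !is.na(smoothed) & smoothed > 0
  runs <- positiveRuns(pos)
  runs <- runs[runs$end - runs$start + 1L >= l, , drop = FALSE]
  out <- list()
  if (nrow(runs)) {
    high <- abs(profiles) >= trimThreshold
    high[is.na(high)] <- FALSE
    anyHigh <- rowSums(high) > 0L
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      if (e - s + 1L >= 11L) {          # trim low-signal edges
        while (s <= e && !anyHigh[s]) s <- s + 1L
        while (e >= s && !anyHigh[e]) e <- e - 1L
        if (s > e) next
      }
      nInf <- sum(!is.na(rawDelta[s:e]))
      minInf <- if (l > 5L) 5L else l - 1L
      if (nInf < minInf) next
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = transcript, start = s, end = e,
        mean_d_within = mean(dWithin[s:e], na.rm = TRUE),
        n_informative = nInf)
    }
  }
  if (length(out)) do.call(rbind, out) else emptyCandidates()
}

emptyCandidates <- function() {
  data.frame(transcript_id = character(), start = integer(),
             end = integer(), mean_d_within = numeric(),
             n_informative = integer())
}

# Maximal runs of TRUE in a logical vector, as a data.frame(start, end).
positiveRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Minimum quality filter for candidate regions
#'
#' A region is tested only if its average within-group d score is below a
#' threshold, ensuring that replicates agree in the region. The default
#' threshold is 0.5 (mean SNR 1) when both groups have at least two
#' replicates, and the stricter 0.2 (mean SNR ~3) when one group has a
#' single sample, compensating for the unobservable within-group variation
#' in that group. The inequality is strict.
#'
#' @param candidates data.frame with a \code{mean_d_within} column.
#' @param mA,mB replicate counts per group (used for the default).
#' @param maxDWithin override for the threshold (default per the rule
#'   above).
#' @return the candidates passing the filter.
#' @export
qualityFilter <- function(candidates, mA, mB,
                          maxDWithin = defaultQualityThreshold(mA, mB)) {
  keep <- !is.na(candidates$mean_d_within) &
    candidates$mean_d_within < maxDWithin
  candidates[keep, , drop = FALSE]
}

#' @rdname qualityFilter
#' @export
defaultQualityThreshold <- function(mA, mB) {
  if (min(mA, mB) >= 2L) 0.5 else 0.2
}
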