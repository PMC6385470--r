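#' Per-nucleotide detection rates from counts and local coverage
#'
#' Detection rate = RT-stop detection count / local coverage, computed
#' separately for treated and untreated samples. Positions with zero
#' coverage are uninformative and returned as \code{NA}.
#'
#' @param counts a count profile as returned by [countProfile()].
#' @return list with numeric vectors \code{treated} and \code{untreated}.
#' @export
detectionRates <- function(counts) {
  rate <- function(k, cov) {
    r <- ifelse(cov > 0, k / cov, NA_real_)
    as.numeric(r)
  }
  list(treated = rate(counts$treated_count, counts$treated_coverage),
       untreated = rate(counts$untreated_count, counts$untreated_coverage))
}

#' Count profile constructor with validity checks
#'
#' @param transcript transcript id.
#' @param treated_count,untreated_count non-negative integer detection
#'   counts per nucleotide.
#' @param treated_coverage,untreated_coverage non-negative integer local
#'   coverages per nucleotide.
#' @return a list of class \code{CountProfile}.
#' @export
countProfile <- function(transcript, treated_count, treated_coverage,
                         untreated_count, untreated_coverage) {
  n <- length(treated_count)
  lens <- c(length(treated_coverage), length(untreated_count),
            length(untreated_coverage))
  if (any(lens != n))
    stop("count and coverage vectors must have equal length")
  if (any(c(treated_count, treated_coverage,
            untreated_count, untreated_coverage) < 0, na.rm = TRUE))
    stop("counts and coverages must be non-negative")
  if (any(treated_count > treated_coverage, na.rm = TRUE) ||
      any(untreated_count > untreated_coverage, na.rm = TRUE))
    stop("counts cannot exceed the corresponding coverage")
  structure(list(transcript = transcript,
                 treated_count = treated_count,
                 treated_coverage = treated_coverage,
                 untreated_count = untreated_count,
                 untreated_coverage = untreated_coverage),
            class = "CountProfile")
}

#' Raw reactivity from treated and untreated detection rates
#'
#' \eqn{r_{raw} = \max((r^+ - r^-)/(1 - r^-), 0)}: the background-corrected
#' modification rate, clamped at zero where the untreated rate exceeds the
#' treated rate (high background noise). Vectorized; \code{NA} propagates.
#'
#' @param treatedRate,untreatedRate detection rates in [0, 1].
#' @return non-negative raw reactivities.
#' @examples
#' rawReactivity(0.02, 0.01)  # 0.01/0.99
#' rawReactivity(0.01, 0.02)  # 0
#' @export
rawReactivity <- function(treatedRate, untreatedRate) {
  if (any(treatedRate < 0 | treatedRate > 1, na.rm = TRUE) ||
      any(untreatedRate < 0 | untreatedRate > 1, na.rm = TRUE))
    stop("detection rates must lie in [0, 1]")
  if (any(untreatedRate == 1, na.rm = TRUE))
    stop("untreated detection rate of 1 leaves no usable signal")
  pmax((treatedRate - untreatedRate) / (1 - untreatedRate), 0)
}

#' 2-8\% normalization of raw reactivities
#'
#' The top 2\% of (non-missing) reactivities are set aside as outliers and
#' the mean of the next 8\% is the normalization constant f; every value is
#' divided by f. Band sizes are \code{ceiling(0.02 n)} and
#' \code{ceiling(0.08 n)} over the n non-missing values, sorted in
#' descending order, which makes the bands deterministic and non-empty for
#' any n >= 1.
#'
#' @param values numeric vector of raw reactivities (NA allowed).
#' @return list with \code{values} (normalized, NA preserved) and \code{f}.
#' @examples
#' norm <- normalize28(1:100)
#' norm$f  # mean(91:98) = 94.5
#' @export
normalize28 <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L || all(values[ok] == 0))
    stop("cannot normalize: all reactivities missing or zero")
  srt <- sort(values[ok], decreasing = TRUE)
  nOut <- ceiling(0.02 * n)
  nBand <- ceiling(0.08 * n)
  band <- srt[seq.int(nOut + 1L, min(nOut + nBand, n))]
  f <- mean(band)
  if (!is.finite(f) || f <= 0)
    stop("cannot normalize: normalization constant is not positive")
  list(values = values / f, f = f)
}

#' PARS score from V1 and S1 nuclease counts
#'
#' \eqn{r = \log_2((V1 + 5)/(S1 + 5))}; the pseudocount of 5 prevents
#' overestimation at low coverage. Positive scores favour pairing (V1,
#' double-strand nuclease), negative scores favour single-strandedness.
#'
#' @param v1,s1 non-negative count vectors.
#' @return PARS scores (any real value).
#' @examples
#' parsScore(27, 11)  # 1
#' parsScore(0, 0)    # 0
#' @export
parsScore <- function(v1, s1) {
  if (any(v1 < 0, na.rm = TRUE) || any(s1 < 0, na.rm = TRUE))
    stop("nuclease counts must be non-negative")
  log2((v1 + 5) / (s1 + 5))
}

#' Standard error of a normalized reactivity
#'
#' \eqn{SE = (1/f)\sqrt{r^+/C^+ + r^-/C^-}} with f the 2-8\% normalization
#' constant: the sampling noise of the two detection-rate estimates,
#' propagated to the normalized scale. Utility for count-based protocols.
#'
#' @param treatedRate,untreatedRate detection rates.
#' @param treatedCov,untreatedCov positive local coverages.
#' @param f positive normalization constant.
#' @return non-negative standard errors.
#' @export
shapeStandardError <- function(treatedRate, untreatedRate,
                               treatedCov, untreatedCov, f) {
  if (any(treatedCov <= 0, na.rm = TRUE) ||
      any(untreatedCov <= 0, na.rm = TRUE))
    stop("coverages must be positive")
  if (any(f <= 0))
    stop("normalization constant must be positive")
  (1 / f) * sqrt(treatedRate / treatedCov + untreatedRate / untreatedCov)
}

#' Mask reactivities at bases the reagent does not probe
#'
#' Base-selective reagents (e.g. DMS, probing A and C) carry no information
#' at the other bases; their reactivities are masked as missing.
#'
#' @param values numeric reactivity vector.
#' @param sequence nucleotide string of the same length (characters in
#'   ACGUT; T is treated as U).
#' @param probedBases character vector of probed bases (default DMS:
#'   \code{c("A", "C")}).
#' @return \code{values} with unprobed positions set to \code{NA}.
#' @examples
#' maskBaseSelective(c(1, 2, 3, 4), "ACGU")  # 1 2 NA NA
#' @export
maskBaseSelective <- function(values, sequence, probedBases = c("A", "C")) {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  bases[bases == "T"] <- "U"
  if (length(bases) != length(values))
    stop("sequence length must match the profile length")
  probedBases <- toupper(probedBases)
  probedBases[probedBases == "T"] <- "U"
  values[!bases %in% probedBases] <- NA_real_
  values
}

#' Reactivity profile from a count profile
#'
#' Convenience pipeline: detection rates, background-corrected raw
#' reactivity, then 2-8\% normalization (optionally skipped when the
#' profile is to be pooled with other transcripts of the same sample
#' before normalizing).
#'
#' @param counts a [countProfile()].
#' @param normalize normalize within this profile (default TRUE).
#' @return list with \code{values} (reactivities), \code{raw} and \code{f}
#'   (NA when \code{normalize = FALSE}).
#' @export
reactivityFromCounts <- function(counts, normalize = TRUE) {
  rates <- detectionRates(counts)
  raw <- rawReactivity(rates$treated, rates$untreated)
  if (normalize) {
    norm <- normalize28(raw)
    list(values = norm$values, raw = raw, f = norm$f)
  } else {
    list(values = raw, raw = raw, f = NA_real_)
  }
}
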