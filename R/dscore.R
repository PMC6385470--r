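#' Dissimilarity (d) score of replicate reactivities at one nucleotide
#'
#' Quantifies the disagreement of a nucleotide's reactivities across a set of
#' samples as \eqn{d = (2/\pi)\arctan(\sigma/|\mu|)}, where \eqn{\sigma} is
#' the sample standard deviation (n-1 denominator) and \eqn{\mu} the mean.
#' The arctan transform bounds the otherwise unbounded absolute coefficient
#' of variation, so that d lies in [0, 1]: 0 when all samples agree exactly,
#' 1 in the limit of maximal discordance (\eqn{\mu = 0} with positive
#' spread, possible for signed PARS scores). When every value is exactly 0
#' the ratio is 0/0 and the d score is undefined (\code{NA}): zero
#' reactivities may be high-quality information or no information at all,
#' and treating them as perfect agreement leads to erroneous calls.
#'
#' @param x numeric vector of length >= 2, one reactivity per sample.
#' @return d score in [0, 1], or \code{NA} if all values are zero.
#' @examples
#' dScore(c(0.7, 0.7, 0.7))  # 0
#' dScore(c(1, -1))          # 1
#' dScore(c(1, 0))           # (2/pi) * atan(sqrt(2))
#' @export
dScore <- function(x) {
  if (length(x) < 2L)
    stop("need at least 2 reactivity values")
  if (anyNA(x))
    return(NA_real_)
  mu <- mean(x)
  sigma <- sd(x)
  if (mu == 0 && sigma == 0)
    return(NA_real_)
  if (mu == 0)
    return(1)
  (2 / pi) * atan(sigma / abs(mu))
}

# Row-wise d scores for a matrix (nucleotides x samples). A row with any
# missing value, or with all values zero, yields NA.
dScoreRows <- function(m) {
  k <- ncol(m)
  miss <- rowSums(is.na(m)) > 0L
  m0 <- m
  m0[is.na(m0)] <- 0
  mu <- rowSums(m0) / k
  sigma <- sqrt(pmax(rowSums((m0 - mu)^2), 0) / (k - 1L))
  d <- ifelse(mu == 0, ifelse(sigma == 0, NA_real_, 1),
              (2 / pi) * atan(sigma / abs(mu)))
  d[miss] <- NA_real_
  d
}

#' Within- and between-group d-score profiles for one transcript
#'
#' Computes the d score of every nucleotide for each subset in a
#' \linkS4class{SubsetPlan} and averages nucleotide-wise: the mean over
#' homogeneous subsets is the within-group variation \code{dWithin}, the
#' mean over heterogeneous subsets the between-group variation
#' \code{dBetween}. Subsets whose d score is missing at a nucleotide are
#' excluded from that nucleotide's mean; if no subset is available on a
#' side, that side is missing there.
#'
#' @param profiles numeric matrix of reactivities (nucleotides in rows,
#'   samples in columns, with sample ids as column names), or a
#'   \linkS4class{ReactivitySet} together with \code{transcript}.
#' @param plan a \linkS4class{SubsetPlan} built from these samples.
#' @param transcript transcript id, required when \code{profiles} is a
#'   \linkS4class{ReactivitySet}.
#' @return a \linkS4class{DScoreProfiles} object.
#' @examples
#' m <- cbind(A1 = c(1, 1), A2 = c(1, 1), B1 = c(3, 3), B2 = c(3, 3))
#' plan <- planSubsets(c("A1", "A2"), c("B1", "B2"))
#' dsp <- withinBetween(m, plan)
#' dWithin(dsp)   # 0, 0
#' dBetween(dsp)  # ~0.3918 at both positions
#' @export
withinBetween <- function(profiles, plan, transcript = "transcript") {
  if (methods::is(profiles, "ReactivitySet")) {
    m <- reactivityMatrix(profiles, transcript)
  } else {
    m <- profiles
  }
  ids <- unique(unlist(c(plan@homogeneous, plan@heterogeneous)))
  if (!all(ids %in% colnames(m)))
    stop("plan references samples absent from the profiles")
  subsetMean <- function(subsets) {
    ds <- vapply(subsets, function(s) dScoreRows(m[, s, drop = FALSE]),
                 numeric(nrow(m)))
    ds <- matrix(ds, nrow = nrow(m))
    avail <- rowSums(!is.na(ds))
    out <- rowMeans(ds, na.rm = TRUE)
    out[avail == 0L] <- NA_real_
    out
  }
  methods::new("DScoreProfiles", transcript = transcript,
               dWithin = subsetMean(plan@homogeneous),
               dBetween = subsetMean(plan@heterogeneous))
}

#' Convert between d scores and signal-to-noise ratios
#'
#' The d score redefines the replicate signal-to-noise ratio
#' \eqn{SNR = |\mu|/\sigma}: inverting the arctan transform gives
#' \eqn{SNR = 1/\tan(\pi d/2)}. Average d scores of 0.5 and 0.2 correspond
#' to mean SNR of 1 and ~3, the liberal and stringent replicate-quality
#' levels used by the minimum quality threshold.
#'
#' @param d d score(s) strictly inside (0, 1).
#' @param snr positive signal-to-noise ratio(s).
#' @return `snrFromD` returns the SNR; `dFromSNR` its exact inverse.
#' @examples
#' snrFromD(0.5)            # 1
#' round(snrFromD(0.2))     # 3
#' dFromSNR(snrFromD(0.3))  # 0.3
#' @export
snrFromD <- function(d) {
  if (any(d <= 0 | d >= 1))
    stop("d must be strictly inside (0, 1)")
  1 / tan(pi * d / 2)
}

#' @rdname snrFromD
#' @export
dFromSNR <- function(snr) {
  if (any(snr <= 0))
    stop("snr must be positive")
  (2 / pi) * atan(1 / snr)
}
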