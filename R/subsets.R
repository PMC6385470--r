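#' Plan homogeneous and heterogeneous sample subsets
#'
#' Builds the subset plan used to estimate within- and between-group
#' variation. Starting from \eqn{m = \max(m_A, m_B)}, all size-m subsets of
#' the pooled samples are considered; subsets drawn entirely from one group
#' are homogeneous, the rest heterogeneous. Among heterogeneous subsets only
#' those with the highest degree of heterogeneity \eqn{g_A g_B / m^2} are
#' retained. If the retained subsets are unbalanced (\eqn{g_A \neq g_B}),
#' m is reduced in decrements of 1 - but not below 3 - until balance is
#' achieved or the floor is reached; the floor only applies when the
#' starting m exceeds 3 (with e.g. 2 vs 1 samples, m stays 2). After any
#' reduction, homogeneous subsets are all size-m subsets drawn entirely
#' from either group.
#'
#' @param samplesA,samplesB character vectors of sample ids for groups A
#'   and B, or single integers giving the group sizes (ids are then
#'   generated as \code{A1..}, \code{B1..}).
#' @return a \linkS4class{SubsetPlan}.
#' @examples
#' planSubsets(2, 1)  # m = 2: {A1,A2} vs {A1,B1}, {A2,B1}
#' planSubsets(4, 4)  # m = 4: 36 heterogeneous subsets with gA = gB = 2
#' planSubsets(5, 1)  # m reduced 5 -> 4 -> 3
#' @export
planSubsets <- function(samplesA, samplesB) {
  if (is.numeric(samplesA) && length(samplesA) == 1L) {
    if (samplesA < 1) stop("both groups need at least one sample")
    samplesA <- paste0("A", seq_len(samplesA))
  }
  if (is.numeric(samplesB) && length(samplesB) == 1L) {
    if (samplesB < 1) stop("both groups need at least one sample")
    samplesB <- paste0("B", seq_len(samplesB))
  }
  mA <- length(samplesA)
  mB <- length(samplesB)
  if (mA < 1L || mB < 1L)
    stop("both groups need at least one sample")
  if (mA + mB < 3L)
    stop("need at least 3 samples in total; ",
         "within-group variation cannot be assessed from 1 vs 1")
  if (anyDuplicated(c(samplesA, samplesB)))
    stop("sample ids must be unique across groups")

  m <- max(mA, mB)
  repeat {
    het <- heterogeneousAt(samplesA, samplesB, m)
    if (het$gA == het$gB || m <= 3L)
      break
    m <- m - 1L
  }
  hom <- c(
    if (mA >= m) combn(samplesA, m, simplify = FALSE) else list(),
    if (mB >= m) combn(samplesB, m, simplify = FALSE) else list())
  methods::new("SubsetPlan", m = as.integer(m), homogeneous = hom,
               heterogeneous = het$subsets,
               gA = as.integer(het$gA), gB = as.integer(het$gB))
}

# All size-m subsets containing both groups, filtered to those with maximal
# heterogeneity gA*gB/m^2. Subsets attaining the maximum form at most two
# mirror splits (gA, gB) and (gB, gA); the unordered pair is reported with
# the larger count first.
heterogeneousAt <- function(samplesA, samplesB, m) {
  all <- combn(c(samplesA, samplesB), m, simplify = FALSE)
  gAs <- vapply(all, function(s) sum(s %in% samplesA), integer(1))
  gBs <- m - gAs
  mixed <- gAs > 0L & gBs > 0L
  if (!any(mixed))
    stop("no heterogeneous subset of size ", m, " exists")
  het <- gAs * gBs
  keep <- mixed & het == max(het[mixed])
  gA <- max(gAs[keep])
  list(subsets = all[keep], gA = max(gA, m - gA), gB = min(gA, m - gA))
}
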