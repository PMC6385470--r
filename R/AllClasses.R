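#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median p.adjust pnorm rnorm runif rlnorm sd setNames
#' @importFrom utils combn read.delim write.table
NULL

#' ReactivitySet: per-nucleotide reactivities for replicate samples
#'
#' Container for structure-probing reactivity profiles of one or more
#' transcripts, measured in replicate samples belonging to two groups
#' (\code{"A"} and \code{"B"}). Internally a
#' \linkS4class{SummarizedExperiment} whose rows are nucleotides (with
#' \code{rowData} columns \code{transcript_id} and \code{position}, 1-based,
#' 5'->3') and whose columns are samples (with \code{colData} column
#' \code{group}). Missing reactivities (masked bases, zero coverage) are
#' \code{NA}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @seealso [ReactivitySet()], [reactivityMatrix()], [sampleGroups()]
#' @export
setClass("ReactivitySet", contains = "SummarizedExperiment")

setValidity("ReactivitySet", function(object) {
  msg <- character()
  if (!"reactivity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reactivity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("transcript_id", "position") %in% colnames(rd)))
    msg <- c(msg, "rowData must have 'transcript_id' and 'position'")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must have 'group'")
  } else if (!all(cd$group %in% c("A", "B"))) {
    msg <- c(msg, "sample groups must be 'A' or 'B'")
  }
  if (length(msg) == 0L && nrow(object) > 0L) {
    pos <- split(rd$position, rd$transcript_id)
    ok <- vapply(pos, function(p) identical(as.integer(p), seq_along(p)),
                 logical(1))
    if (!all(ok))
      msg <- c(msg, "positions must run 1..n within each transcript")
  }
  if (length(msg)) msg else TRUE
})

#' Subset plan for within/between-group variation
#'
#' The homogeneous (single-group) and heterogeneous (mixed-group) sample
#' subsets of size \code{m} over which per-nucleotide d scores are averaged.
#' Heterogeneous subsets retained all share the maximal heterogeneity
#' \eqn{g_A g_B / m^2}.
#'
#' @slot m integer subset size.
#' @slot homogeneous list of character vectors of sample ids, each drawn
#'   entirely from one group.
#' @slot heterogeneous list of character vectors of sample ids containing
#'   both groups.
#' @slot gA,gB integer counts of group-A and group-B samples in each retained
#'   heterogeneous subset.
#' @seealso [planSubsets()]
#' @export
setClass("SubsetPlan",
  representation(m = "integer", homogeneous = "list",
                 heterogeneous = "list", gA = "integer", gB = "integer"))

setValidity("SubsetPlan", function(object) {
  msg <- character()
  sizes <- lengths(c(object@homogeneous, object@heterogeneous))
  if (length(sizes) && any(sizes != object@m))
    msg <- c(msg, "all subsets must have exactly m members")
  if (length(object@homogeneous) < 1L)
    msg <- c(msg, "at least one homogeneous subset is required")
  if (length(object@heterogeneous) < 1L)
    msg <- c(msg, "at least one heterogeneous subset is required")
  if (object@gA + object@gB != object@m)
    msg <- c(msg, "gA + gB must equal m")
  if (length(msg)) msg else TRUE
})

#' Paired within/between d-score profiles for one transcript
#'
#' @slot transcript character transcript id.
#' @slot dWithin,dBetween numeric per-nucleotide averages of d scores over
#'   homogeneous / heterogeneous subsets, in [0, 1] or NA.
#' @seealso [withinBetween()], [dWithin()], [dBetween()], [deltaD()]
#' @export
setClass("DScoreProfiles",
  representation(transcript = "character", dWithin = "numeric",
                 dBetween = "numeric"))

setValidity("DScoreProfiles", function(object) {
  msg <- character()
  if (length(object@dWithin) != length(object@dBetween))
    msg <- c(msg, "dWithin and dBetween must have equal length")
  vals <- c(object@dWithin, object@dBetween)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (any(vals < -1e-12) || any(vals > 1 + 1e-12)))
    msg <- c(msg, "d scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ensemble of secondary-structure pairing states
#'
#' A set of unique per-nucleotide pairing-state vectors (TRUE = paired) for
#' one simulated region, with one structure designated as the MFE-like
#' reference whose ensemble weight can be raised identically in both groups
#' to increase between-group correlation.
#'
#' @slot pairing logical matrix, structures in rows, nucleotides in columns.
#' @slot mfeIndex integer row index of the MFE-like reference structure.
#' @seealso [sampleEnsemble()], [assignWeights()], [emitProfile()]
#' @export
setClass("StructureEnsemble",
  representation(pairing = "matrix", mfeIndex = "integer"))

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  if (!is.logical(object@pairing))
    msg <- c(msg, "pairing must be a logical matrix")
  if (anyDuplicated(apply(object@pairing, 1L, paste, collapse = "")))
    msg <- c(msg, "pairing-state vectors must be unique")
  if (object@mfeIndex < 1L || object@mfeIndex > nrow(object@pairing))
    msg <- c(msg, "mfeIndex out of range")
  if (length(msg)) msg else TRUE
})

#' Parameterized reactivity emission distributions
#'
#' Reactivity-generating distributions for paired and unpaired nucleotides
#' used by the simulator (positive support, unpaired mean well above paired
#' mean for SHAPE/DMS-type data).
#'
#' @slot pairedMeanlog,pairedSdlog,unpairedMeanlog,unpairedSdlog lognormal
#'   parameters of the two emission distributions.
#' @seealso [emissionModel()], [emitProfile()]
#' @export
setClass("EmissionModel",
  representation(pairedMeanlog = "numeric", pairedSdlog = "numeric",
                 unpairedMeanlog = "numeric", unpairedSdlog = "numeric"))

setValidity("EmissionModel", function(object) {
  if (object@pairedSdlog < 0 || object@unpairedSdlog < 0)
    "sdlog parameters must be non-negative" else TRUE
})
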