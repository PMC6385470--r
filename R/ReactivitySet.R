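#' Construct a ReactivitySet
#'
#' @param profiles either a named list of numeric matrices (one per
#'   transcript; nucleotides in rows, samples in columns, \code{NA} for
#'   missing) or a single matrix for a one-transcript set. All matrices must
#'   share the same sample (column) names.
#' @param groups character vector of \code{"A"}/\code{"B"} labels, one per
#'   sample, in column order. If \code{NULL}, groups are taken from the
#'   leading letter of the sample names (e.g. \code{"A1"}, \code{"B2"}).
#' @return a \linkS4class{ReactivitySet}.
#' @examples
#' m <- cbind(A1 = c(0.1, 1.2, 0.4), A2 = c(0.2, 1.1, 0.5),
#'            B1 = c(0.9, 0.1, 0.5))
#' rs <- ReactivitySet(list(tx1 = m))
#' transcripts(rs)
#' sampleGroups(rs)
#' @export
ReactivitySet <- function(profiles, groups = NULL) {
  if (is.matrix(profiles))
    profiles <- list(tx1 = profiles)
  if (is.null(names(profiles)) || anyNA(names(profiles)) ||
      any(names(profiles) == ""))
    stop("'profiles' must be a named list of matrices")
  samples <- colnames(profiles[[1L]])
  if (is.null(samples))
    stop("profile matrices must have sample column names")
  for (p in profiles)
    if (!identical(colnames(p), samples))
      stop("all transcripts must have identical sample columns")
  if (is.null(groups))
    groups <- substr(samples, 1L, 1L)
  if (length(groups) != length(samples))
    stop("'groups' must have one label per sample")
  assay <- do.call(rbind, lapply(profiles, unname))
  rowdat <- S4Vectors::DataFrame(
    transcript_id = rep(names(profiles),
                        vapply(profiles, nrow, integer(1))),
    position = unlist(lapply(profiles, function(p) seq_len(nrow(p))),
                      use.names = FALSE))
  coldat <- S4Vectors::DataFrame(sample_id = samples,
                                 group = as.character(groups),
                                 row.names = samples)
  dimnames(assay) <- list(NULL, samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reactivity = assay), rowData = rowdat, colData = coldat)
  methods::new("ReactivitySet", se)
}

#' @rdname ReactivitySet-class
#' @export
setMethod("transcripts", "ReactivitySet", function(x)
  unique(SummarizedExperiment::rowData(x)$transcript_id))

#' @rdname ReactivitySet-class
#' @export
setMethod("sampleGroups", "ReactivitySet", function(x)
  setNames(SummarizedExperiment::colData(x)$group,
           SummarizedExperiment::colData(x)$sample_id))

#' @rdname ReactivitySet-class
#' @export
setMethod("reactivityMatrix", "ReactivitySet", function(x, transcript) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- rd$transcript_id == transcript
  if (!any(keep))
    stop("unknown transcript: ", transcript)
  m <- SummarizedExperiment::assay(x, "reactivity")[keep, , drop = FALSE]
  rownames(m) <- NULL
  m
})

setMethod("show", "ReactivitySet", function(object) {
  grp <- sampleGroups(object)
  cat("ReactivitySet with", length(transcripts(object)), "transcript(s),",
      ncol(object), "sample(s) (", sum(grp == "A"), "A /",
      sum(grp == "B"), "B ),", nrow(object), "nucleotides\n")
})

#' @rdname SubsetPlan-class
#' @export
setMethod("subsetSize", "SubsetPlan", function(x) x@m)

#' @rdname SubsetPlan-class
#' @export
setMethod("homogeneousSubsets", "SubsetPlan", function(x) x@homogeneous)

#' @rdname SubsetPlan-class
#' @export
setMethod("heterogeneousSubsets", "SubsetPlan", function(x) x@heterogeneous)

setMethod("show", "SubsetPlan", function(object) {
  cat("SubsetPlan: m =", object@m, "|", length(object@homogeneous),
      "homogeneous,", length(object@heterogeneous),
      sprintf("heterogeneous (gA = %d, gB = %d)\n", object@gA, object@gB))
})

#' @rdname DScoreProfiles-class
#' @export
setMethod("dWithin", "DScoreProfiles", function(x) x@dWithin)

#' @rdname DScoreProfiles-class
#' @export
setMethod("dBetween", "DScoreProfiles", function(x) x@dBetween)

#' @rdname deltaD
#' @export
setMethod("deltaD", "DScoreProfiles", function(x) x@dBetween - x@dWithin)

setMethod("show", "DScoreProfiles", function(object) {
  n <- length(object@dWithin)
  cat("DScoreProfiles for", object@transcript, "(", n, "nt ):",
      sum(!is.na(object@dWithin) & !is.na(object@dBetween)),
      "nucleotides with paired d scores\n")
})
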