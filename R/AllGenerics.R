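#' @rdname DScoreProfiles-class
#' @param x a \linkS4class{DScoreProfiles} object.
#' @export
setGeneric("dWithin", function(x) standardGeneric("dWithin"))

#' @rdname DScoreProfiles-class
#' @export
setGeneric("dBetween", function(x) standardGeneric("dBetween"))

#' Per-nucleotide difference of between- and within-group variation
#'
#' \eqn{\Delta d_i = d_{between,i} - d_{within,i}}; missing when either side
#' is missing. Positive values are evidence of differential reactivity.
#'
#' @param x a \linkS4class{DScoreProfiles} object.
#' @return numeric vector of the same length as the profiles.
#' @examples
#' dsp <- new("DScoreProfiles", transcript = "tx",
#'            dWithin = c(0.2, NA), dBetween = c(0.6, 0.3))
#' deltaD(dsp)  # 0.4, NA
#' @export
setGeneric("deltaD", function(x) standardGeneric("deltaD"))

#' @rdname SubsetPlan-class
#' @param x a \linkS4class{SubsetPlan} object.
#' @export
setGeneric("subsetSize", function(x) standardGeneric("subsetSize"))

#' @rdname SubsetPlan-class
#' @export
setGeneric("homogeneousSubsets",
           function(x) standardGeneric("homogeneousSubsets"))

#' @rdname SubsetPlan-class
#' @export
setGeneric("heterogeneousSubsets",
           function(x) standardGeneric("heterogeneousSubsets"))

#' @rdname ReactivitySet-class
#' @param x a \linkS4class{ReactivitySet} object.
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname ReactivitySet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ReactivitySet-class
#' @param transcript a single transcript id.
#' @export
setGeneric("reactivityMatrix",
           function(x, transcript) standardGeneric("reactivityMatrix"))
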