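#' @include AllClasses.R
NULL

#' @export
setGeneric("rdValues", function(x) standardGeneric("rdValues"))
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @export
setGeneric("binIDs", function(x) standardGeneric("binIDs"))
#' @export
setGeneric("orderIndices", function(x) standardGeneric("orderIndices"))
#' @export
setGeneric("permutationMatrix", function(x) standardGeneric("permutationMatrix"))
#' @export
setGeneric("inverseOrdering", function(x) standardGeneric("inverseOrdering"))
#' @export
setGeneric("applyOrdering", function(x, target) standardGeneric("applyOrdering"))
#' @export
setGeneric("solverState", function(x) standardGeneric("solverState"))
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @export
setGeneric("recoveredMatrix", function(x) standardGeneric("recoveredMatrix"))
#' @export
setGeneric("solverTrace", function(x) standardGeneric("solverTrace"))
#' @export
setGeneric("sampleArrangement", function(x) standardGeneric("sampleArrangement"))
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @export
setGeneric("trueOrder", function(x) standardGeneric("trueOrder"))
#' @export
setGeneric("irrelevantMask", function(x) standardGeneric("irrelevantMask"))
#' @export
setGeneric("achievedSNR", function(x) standardGeneric("achievedSNR"))
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))
#' @export
setGeneric("keptIndices", function(x) standardGeneric("keptIndices"))
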