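#' @include AllClasses.R
NULL

#' @export
setGeneric("designValues", function(x) standardGeneric("designValues"))
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @export
setGeneric("storyBounds", function(x) standardGeneric("storyBounds"))
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @export
setGeneric("repeatStack", function(x) standardGeneric("repeatStack"))
#' @export
setGeneric("fitWeights", function(x) standardGeneric("fitWeights"))
#' @export
setGeneric("fitLambda", function(x) standardGeneric("fitLambda"))
#' @export
setGeneric("scoreR", function(x) standardGeneric("scoreR"))
#' @export
setGeneric("scoreR2", function(x) standardGeneric("scoreR2"))
#' @export
setGeneric("scoreP", function(x) standardGeneric("scoreP"))
#' @export
setGeneric("scoreQ", function(x) standardGeneric("scoreQ"))
#' @export
setGeneric("partitionValues", function(x) standardGeneric("partitionValues"))
#' @export
setGeneric("modelR2", function(x, corrected = TRUE) standardGeneric("modelR2"))
#' @export
setGeneric("biasTerms", function(x) standardGeneric("biasTerms"))
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @export
setGeneric("inertiaCurve", function(x) standardGeneric("inertiaCurve"))
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))
#' @export
setGeneric("ccValues", function(x) standardGeneric("ccValues"))
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
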