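#' @include AllGenerics.R
NULL

#' Accessors for voxenc S4 containers
#'
#' Small accessor layer over the package's S4 classes so downstream code never
#' touches slots directly.
#'
#' @param x a voxenc S4 object.
#' @param corrected for \code{modelR2}, return bias-corrected (default) or raw
#'   nested-model r2 values.
#' @return The requested component (matrix, vector or data.frame).
#' @name accessors
#' @aliases designValues columnMap storyBounds trSeconds responseValues
#'   regionLabels repeatStack fitWeights fitLambda scoreR scoreR2 scoreP scoreQ
#'   partitionValues modelR2 biasTerms clusterLabels clusterCentroids
#'   inertiaCurve chosenK eventTable nEvents featureDim ccValues nullDraws
#'   pValues
NULL

#' @rdname accessors
#' @export
setMethod("designValues", "DesignMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("columnMap", "DesignMatrix", function(x) x@columnMap)
#' @rdname accessors
#' @export
setMethod("columnMap", "RidgeFit", function(x) x@columnMap)
#' @rdname accessors
#' @export
setMethod("storyBounds", "DesignMatrix", function(x) x@storyBounds)
#' @rdname accessors
#' @export
setMethod("storyBounds", "ResponseSet", function(x) x@storyBounds)
#' @rdname accessors
#' @export
setMethod("trSeconds", "DesignMatrix", function(x) x@trS)
#' @rdname accessors
#' @export
setMethod("trSeconds", "ResponseSet", function(x) x@trS)
#' @rdname accessors
#' @export
setMethod("responseValues", "ResponseSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("regionLabels", "ResponseSet", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("repeatStack", "ResponseSet", function(x) x@repeats)
#' @rdname accessors
#' @export
setMethod("fitWeights", "RidgeFit", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("fitLambda", "RidgeFit", function(x) x@lambda)
#' @rdname accessors
#' @export
setMethod("scoreR", "VoxelScores", function(x) x@r)
#' @rdname accessors
#' @export
setMethod("scoreR2", "VoxelScores", function(x) x@r2Signed)
#' @rdname accessors
#' @export
setMethod("scoreP", "VoxelScores", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("scoreQ", "VoxelScores", function(x) x@q)
#' @rdname accessors
#' @export
setMethod("partitionValues", "PartitionTable", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("modelR2", "PartitionTable", function(x, corrected = TRUE) {
  if (corrected) x@r2 else x@r2Raw
})
#' @rdname accessors
#' @export
setMethod("biasTerms", "PartitionTable", function(x) x@bias)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("inertiaCurve", "ClusterModel", function(x) x@inertiaCurve)
#' @rdname accessors
#' @export
setMethod("chosenK", "ClusterModel", function(x) x@chosenK)
#' @rdname accessors
#' @export
setMethod("eventTable", "EventStream", function(x) {
  data.frame(
    onset_s = x@onsets, duration_s = x@durations, label = x@labels,
    stringsAsFactors = FALSE
  )
})
#' @rdname accessors
#' @export
setMethod("nEvents", "EventStream", function(x) length(x@onsets))
#' @rdname accessors
#' @export
setMethod("featureDim", "EventStream", function(x) ncol(x@vectors))
#' @rdname accessors
#' @export
setMethod("ccValues", "CeilingEstimates", function(x) {
  data.frame(
    ccAbs = x@ccAbs, ccHalf = x@ccHalf, ccMaxRaw = x@ccMaxRaw,
    ccMax = x@ccMax, ccNorm = x@ccNorm
  )
})
#' @rdname accessors
#' @export
setMethod("nullDraws", "PermutationResult", function(x) x@nullDraws)
#' @rdname accessors
#' @export
setMethod("pValues", "PermutationResult", function(x) x@p)

#' Feature vectors of an event stream
#'
#' @param x an \linkS4class{EventStream}.
#' @return numeric matrix, one row per event.
#' @export
eventVectors <- function(x) {
  stopIfNot(is(x, "EventStream"), "x must be an EventStream")
  x@vectors
}

setMethod("show", "EventStream", function(object) {
  cat(sprintf(
    "EventStream '%s': %d events, dim %d, span %.2f-%.2f s\n",
    object@spaceName, length(object@onsets), ncol(object@vectors),
    if (length(object@onsets)) min(object@onsets) else NA_real_,
    if (length(object@onsets)) max(object@onsets) else NA_real_
  ))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf(
    "DesignMatrix: %d TRs x %d columns (%d spaces, delays %s), %d stories, TR %.2f s\n",
    nrow(object@values), ncol(object@values),
    length(unique(object@columnMap$space)),
    paste(object@delaysTr, collapse = ","),
    nrow(object@storyBounds), object@trS
  ))
})

setMethod("show", "ResponseSet", function(object) {
  cat(sprintf(
    "ResponseSet: %d TRs x %d voxels (%d cerebellum, %d cortex), %d stories%s\n",
    nrow(object@values), ncol(object@values),
    sum(object@regionLabels == "cerebellum"),
    sum(object@regionLabels == "cortex"),
    nrow(object@storyBounds),
    if (is.null(object@repeats)) "" else
      sprintf(", %d test repeats of %d TRs", dim(object@repeats)[1],
              dim(object@repeats)[2])
  ))
})

setMethod("show", "RidgeFit", function(object) {
  cat(sprintf(
    "RidgeFit: %d columns x %d voxels, lambda = %.4g, spaces: %s\n",
    nrow(object@weights), ncol(object@weights), object@lambda,
    paste(unique(object@columnMap$space), collapse = ", ")
  ))
})

setMethod("show", "VoxelScores", function(object) {
  cat(sprintf(
    "VoxelScores: %d voxels, mean signed r2 = %.4f%s\n",
    length(object@r), mean(object@r2Signed),
    if (all(is.na(object@q))) "" else
      sprintf(", %d significant at q < 0.05", sum(object@q < 0.05, na.rm = TRUE))
  ))
})

setMethod("show", "CeilingEstimates", function(object) {
  cat(sprintf(
    "CeilingEstimates: %d voxels, median ccHalf = %.3f, median ccNorm = %.3f\n",
    length(object@ccHalf), stats::median(object@ccHalf),
    stats::median(object@ccNorm)
  ))
})

setMethod("show", "PartitionTable", function(object) {
  cat(sprintf(
    "PartitionTable (%s): %d voxels, partitions: %s\n",
    object@mode, nrow(object@partitions),
    paste(colnames(object@partitions), collapse = ", ")
  ))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: %d statistic(s), %d null draws, %s-sided, min p = %.4g\n",
    length(object@observed), nrow(object@nullDraws), object@sidedness,
    min(object@p)
  ))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: k = %d on %d components (%.1f%% variance), %d voxels\n",
    nrow(object@centroids), ncol(object@centroids),
    100 * max(object@explainedVar), length(object@labels)
  ))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d voxels, spaces: %s, target ccHalf = %.2f\n",
    ncol(object@weights[[1]]), paste(names(object@weights), collapse = ", "),
    object@targetCcHalf
  ))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d stories x %.0f s, TR %.2f s, %.2f events/s, dims: %s\n",
    object@nStories, object@storyLenS, object@trS, object@wordRateHz,
    paste(sprintf("%s=%d", names(object@dims), object@dims), collapse = ", ")
  ))
})
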