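#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Synthetic scenario description
#'
#' Parameters of a simulated natural-listening experiment: how many stories,
#' how long each is, the scanner TR, the word rate of the stimulus stream, the
#' vocabulary size and the dimensionality of each feature space. Defaults
#' mirror a natural-story listening study: TR = 2 s, 10-15 min stories, and
#' the five feature spaces (mel spectrogram 256, articulatory 22, part of
#' speech 17, word-level semantic 985, context-level semantic 768).
#'
#' @slot nStories number of training stories.
#' @slot storyLenS story duration in seconds.
#' @slot trS repetition time in seconds.
#' @slot wordRateHz mean stimulus event rate (events per second).
#' @slot vocabSize vocabulary size for the synthetic lexicon.
#' @slot dims named integer vector, feature-space name -> dimensionality.
#' @slot seed integer seed controlling all randomness in the scenario.
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(
    nStories = "integer", storyLenS = "numeric", trS = "numeric",
    wordRateHz = "numeric", vocabSize = "integer", dims = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@trS <= 0) msg <- c(msg, "trS must be > 0")
  if (any(object@dims < 1L)) msg <- c(msg, "all feature dims must be >= 1")
  if (is.null(names(object@dims)) || any(!nzchar(names(object@dims)))) {
    msg <- c(msg, "dims must be a named vector")
  }
  if (object@storyLenS < 10 * object@trS) {
    msg <- c(msg, "storyLenS must be at least 10 TRs long")
  }
  if (object@nStories < 1L) msg <- c(msg, "need at least one story")
  if (object@wordRateHz < 0) msg <- c(msg, "wordRateHz must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-stamped stimulus events carrying feature vectors
#'
#' One stream per story and feature space: word, phoneme or audio-frame
#' events, each with an onset (seconds from story start), a duration, a label
#' and a feature vector of fixed dimensionality.
#'
#' @slot spaceName feature-space identifier.
#' @slot onsets event onsets in seconds, strictly increasing.
#' @slot durations event durations in seconds, all >= 0.
#' @slot labels event token labels (word, phoneme or frame id).
#' @slot vectors numeric matrix, one row per event.
#' @exportClass EventStream
setClass("EventStream",
  representation(
    spaceName = "character", onsets = "numeric", durations = "numeric",
    labels = "character", vectors = "matrix"
  )
)

setValidity("EventStream", function(object) {
  msg <- character()
  n <- length(object@onsets)
  if (nrow(object@vectors) != n) msg <- c(msg, "vectors must have one row per event")
  if (length(object@durations) != n) msg <- c(msg, "durations length mismatch")
  if (length(object@labels) != n) msg <- c(msg, "labels length mismatch")
  if (n > 1L && any(diff(object@onsets) <= 0)) {
    msg <- c(msg, "onsets must be strictly increasing")
  }
  if (any(object@durations < 0)) msg <- c(msg, "durations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TR-rate FIR design matrix
#'
#' The stimulus matrix after Lanczos resampling to the TR grid, column
#' z-scoring on the training stories, and concatenation of delayed copies
#' (finite impulse response expansion). Column identity is carried in
#' \code{columnMap}; story boundaries are half-open TR intervals so that
#' delays never leak across stories.
#'
#' @slot values numeric matrix, nTR x nColumns.
#' @slot columnMap data.frame with columns \code{space}, \code{feature},
#'   \code{delay}, one row per design column.
#' @slot storyBounds integer matrix with columns (start, end), half-open,
#'   1-based, partitioning the TR axis.
#' @slot trS repetition time in seconds.
#' @slot delaysTr integer FIR delays in TR units.
#' @slot scaling per-space list of the training means/scales used for
#'   z-scoring (reused verbatim for held-out designs).
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(
    values = "matrix", columnMap = "data.frame", storyBounds = "matrix",
    trS = "numeric", delaysTr = "integer", scaling = "list"
  )
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (nrow(object@columnMap) != ncol(object@values)) {
    msg <- c(msg, "columnMap must have one row per design column")
  }
  if (!all(c("space", "feature", "delay") %in% names(object@columnMap))) {
    msg <- c(msg, "columnMap needs columns space, feature, delay")
  }
  bad <- checkStoryBounds(object@storyBounds, nrow(object@values))
  if (!is.null(bad)) msg <- c(msg, bad)
  if (object@trS <= 0) msg <- c(msg, "trS must be > 0")
  if (length(msg)) msg else TRUE
})

#' Voxel response container
#'
#' A TR x voxel BOLD matrix with per-voxel region labels (cerebellum or
#' cortex), story boundaries, and an optional repeat stack holding the
#' responses to the repeated held-out test story.
#'
#' @slot values numeric matrix, nTR x nVoxels.
#' @slot regionLabels character per voxel, "cerebellum" or "cortex".
#' @slot storyBounds half-open TR intervals partitioning the time axis.
#' @slot repeats optional array (nRepeats x nTRtest x nVoxels) or NULL.
#' @slot trS repetition time in seconds.
#' @exportClass ResponseSet
setClass("ResponseSet",
  representation(
    values = "matrix", regionLabels = "character", storyBounds = "matrix",
    repeats = "arrayOrNULL", trS = "numeric"
  )
)

setValidity("ResponseSet", function(object) {
  msg <- character()
  if (length(object@regionLabels) != ncol(object@values)) {
    msg <- c(msg, "one region label per voxel required")
  }
  if (!all(object@regionLabels %in% c("cerebellum", "cortex"))) {
    msg <- c(msg, "region labels must be 'cerebellum' or 'cortex'")
  }
  bad <- checkStoryBounds(object@storyBounds, nrow(object@values))
  if (!is.null(bad)) msg <- c(msg, bad)
  if (!is.null(object@repeats)) {
    if (length(dim(object@repeats)) != 3L) {
      msg <- c(msg, "repeats must be a 3-d array (repeat x TR x voxel)")
    } else if (dim(object@repeats)[3] != ncol(object@values)) {
      msg <- c(msg, "repeat stack voxel count mismatch")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated scenario
#'
#' Per-feature-space weight matrices on the delayed design columns, the
#' requested per-voxel variance fractions, and the noise level calibrated to
#' a target split-half reliability of the repeated test story.
#'
#' @slot weights named list, space -> (delayed feature dim x voxel) matrix.
#' @slot uniqueFractions matrix voxel x space of unique signal-variance
#'   fractions.
#' @slot sharedFraction per-voxel fraction carried by the latent component
#'   common to the designated spaces.
#' @slot noiseSd per-voxel noise standard deviation (response units).
#' @slot targetCcHalf intended split-half reliability of the repeats, in
#'   [0, 1].
#' @slot sharedSpaces names of the spaces carrying the shared latent.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    weights = "list", uniqueFractions = "matrix", sharedFraction = "numeric",
    noiseSd = "numeric", targetCcHalf = "numeric", sharedSpaces = "character"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  tot <- rowSums(object@uniqueFractions) + object@sharedFraction
  if (any(abs(tot - 1) > 1e-9)) {
    msg <- c(msg, "per voxel, unique fractions + shared fraction must sum to 1")
  }
  if (any(object@noiseSd < 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (object@targetCcHalf < 0 || object@targetCcHalf > 1) {
    msg <- c(msg, "targetCcHalf must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted ridge model
#'
#' @slot weights numeric matrix, nColumns x nVoxels.
#' @slot lambda the shared regularization value (>= 0).
#' @slot columnMap design column identity, as in \linkS4class{DesignMatrix}.
#' @slot trainingMeta list of provenance (story ids, seed, spaces).
#' @exportClass RidgeFit
setClass("RidgeFit",
  representation(
    weights = "matrix", lambda = "numeric", columnMap = "data.frame",
    trainingMeta = "list"
  )
)

setValidity("RidgeFit", function(object) {
  msg <- character()
  if (!all(is.finite(object@weights))) msg <- c(msg, "weights must be finite")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (nrow(object@columnMap) != nrow(object@weights)) {
    msg <- c(msg, "columnMap must match weight rows")
  }
  if (length(msg)) msg else TRUE
})

#' Per-voxel model scores
#'
#' @slot r per-voxel Pearson correlation between prediction and data.
#' @slot r2Signed signed squared correlation, r * |r|.
#' @slot p per-voxel permutation p value (NA before testing).
#' @slot q per-voxel BH-FDR adjusted value (NA before testing).
#' @slot degenerate flag for zero-variance predictions or data.
#' @exportClass VoxelScores
setClass("VoxelScores",
  representation(
    r = "numeric", r2Signed = "numeric", p = "numeric", q = "numeric",
    degenerate = "logical"
  )
)

setValidity("VoxelScores", function(object) {
  msg <- character()
  n <- length(object@r)
  if (any(lengths(list(object@r2Signed, object@p, object@q, object@degenerate)) != n)) {
    msg <- c(msg, "all score vectors must share one length")
  }
  if (any(abs(object@r) > 1 + 1e-12)) msg <- c(msg, "r must lie in [-1, 1]")
  if (any(object@r2Signed != signedSquare(object@r))) {
    msg <- c(msg, "r2Signed must equal r * |r| exactly")
  }
  ok <- is.na(object@p) | (object@p > 0 & object@p <= 1)
  if (!all(ok)) msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Noise-ceiling estimates
#'
#' Split-half repeat reliability and the derived prediction ceiling used to
#' normalize model-vs-data correlations, with the 0.3 floor applied to the
#' ceiling.
#'
#' @slot ccHalf per-voxel split-half reliability.
#' @slot ccMaxRaw per-voxel ceiling before flooring.
#' @slot ccMax per-voxel ceiling after flooring at 0.3.
#' @slot ccNorm per-voxel normalized correlation (ccAbs / ccMax).
#' @slot ccAbs the uncorrected model-vs-data correlation.
#' @exportClass CeilingEstimates
setClass("CeilingEstimates",
  representation(
    ccHalf = "numeric", ccMaxRaw = "numeric", ccMax = "numeric",
    ccNorm = "numeric", ccAbs = "numeric"
  )
)

setValidity("CeilingEstimates", function(object) {
  msg <- character()
  if (any(object@ccMax != pmax(object@ccMaxRaw, 0.3))) {
    msg <- c(msg, "ccMax must equal max(ccMaxRaw, 0.3) exactly")
  }
  if (length(msg)) msg else TRUE
})

#' Variance partition table
#'
#' Per-voxel partition values for the unique (five-way) or pairwise scheme,
#' together with the raw nested-model r2 values, the minimum-norm bias terms,
#' and any attached significance results.
#'
#' @slot mode "unique" or "pairwise".
#' @slot r2 matrix voxel x model (named columns), corrected values.
#' @slot r2Raw matrix voxel x model, the uncorrected inputs.
#' @slot partitions matrix voxel x partition (named columns).
#' @slot bias matrix voxel x bias-term.
#' @slot significance data.frame of permutation results (may be empty).
#' @exportClass PartitionTable
setClass("PartitionTable",
  representation(
    mode = "character", r2 = "matrix", r2Raw = "matrix",
    partitions = "matrix", bias = "matrix", significance = "data.frame"
  )
)

setValidity("PartitionTable", function(object) {
  msg <- character()
  if (!object@mode %in% c("unique", "pairwise")) {
    msg <- c(msg, "mode must be 'unique' or 'pairwise'")
  }
  if (nrow(object@partitions) != nrow(object@r2)) {
    msg <- c(msg, "partition and r2 tables must share voxels")
  }
  if (length(object@partitions) && min(object@partitions) < -1e-9) {
    msg <- c(msg, "corrected partitions must be >= -1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation test result
#'
#' @slot observed observed statistic value(s).
#' @slot nullDraws matrix, nPerm x nStatistics.
#' @slot p per-statistic p value in (0, 1].
#' @slot sidedness "one" or "two".
#' @slot seed integer seed used for the draws (NA for exact enumeration).
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    observed = "numeric", nullDraws = "matrix", p = "numeric",
    sidedness = "character", seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (any(object@p <= 0 | object@p > 1)) msg <- c(msg, "p must lie in (0, 1]")
  if (!object@sidedness %in% c("one", "two")) {
    msg <- c(msg, "sidedness must be 'one' or 'two'")
  }
  if (length(msg)) msg else TRUE
})

#' Semantic weight clustering model
#'
#' PCA basis retaining the requested explained variance, spherical k-means
#' centroids on the reduced space, per-voxel cluster labels, and the inertia
#' curve used for the elbow choice of k.
#'
#' @slot pcaBasis matrix, original dim x retained components.
#' @slot pcaCenter column means removed before projection.
#' @slot explainedVar cumulative explained-variance ratio of the retained
#'   components.
#' @slot centroids unit-norm matrix, k x retained components.
#' @slot labels per-voxel cluster index.
#' @slot inertia within-cluster sum of squares at the fitted k.
#' @slot inertiaCurve named numeric, k -> inertia (possibly empty).
#' @slot chosenK the k in use.
#' @slot seed integer seed.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    pcaBasis = "matrix", pcaCenter = "numeric", explainedVar = "numeric",
    centroids = "matrix", labels = "integer", inertia = "numeric",
    inertiaCurve = "numeric", chosenK = "integer", seed = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) > 0) {
    norms <- sqrt(rowSums(object@centroids^2))
    if (any(abs(norms - 1) > 1e-9)) {
      msg <- c(msg, "centroid rows must be unit norm")
    }
  }
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > nrow(object@centroids))) {
    msg <- c(msg, "labels must index centroid rows")
  }
  if (length(msg)) msg else TRUE
})
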