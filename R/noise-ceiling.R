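#' @include AllClasses.R utils.R
NULL

#' Split-half repeat reliability per voxel
#'
#' Splits the repeat stack into two halves by even/odd repeat index
#' (balanced across session order), averages each half across repeats, and
#' correlates the two half-averages over time for each voxel.
#'
#' @param repeats array nRepeats x nTR x nVoxels (at least two repeats).
#' @return numeric per-voxel split-half correlation in [-1, 1].
#' @export
ccHalf <- function(repeats) {
  stopIfNot(length(dim(repeats)) == 3L, "repeats must be a 3-d array")
  nRep <- dim(repeats)[1]
  stopIfNot(nRep >= 2, "need at least two repeats")
  odd <- seq(1L, nRep, by = 2L)
  even <- seq(2L, nRep, by = 2L)
  h1 <- apply(repeats[odd, , , drop = FALSE], c(2L, 3L), mean)
  h2 <- apply(repeats[even, , , drop = FALSE], c(2L, 3L), mean)
  as.numeric(colPearson(h1, h2))
}

#' Prediction ceiling implied by a split-half reliability
#'
#' The ceiling formula is isolated here so that an alternative algebraic
#' reading is a one-line change: ccMax = sqrt(2 / (1 + 1 / ccHalf^2)),
#' which satisfies the anchor ccHalf = 1 => ccMax = 1. Non-positive
#' reliabilities give an undefined raw ceiling and are mapped to 0 (the
#' subsequent 0.3 floor then applies, preventing corrected correlations
#' from exceeding 1).
#'
#' @param ccHalfValues per-voxel split-half reliabilities.
#' @return per-voxel raw ceiling values (before flooring).
#' @export
ccMaxFromHalf <- function(ccHalfValues) {
  out <- numeric(length(ccHalfValues))
  pos <- is.finite(ccHalfValues) & ccHalfValues > 0
  out[pos] <- sqrt(2 / (1 + 1 / ccHalfValues[pos]^2))
  out
}

#' Noise-ceiling-corrected model performance
#'
#' Normalizes the absolute model-vs-data correlation by the prediction
#' ceiling derived from repeat reliability, with the ceiling floored at 0.3
#' (a flooring that keeps corrected correlations from exploding for
#' unreliable voxels): ccNorm = ccAbs / max(ccMaxRaw, 0.3).
#'
#' @param ccAbs per-voxel model-vs-data correlation.
#' @param ccHalfValues per-voxel split-half reliability (same length).
#' @return a \linkS4class{CeilingEstimates}.
#' @export
ccNorm <- function(ccAbs, ccHalfValues) {
  stopIfNot(length(ccAbs) == length(ccHalfValues),
            "ccAbs and ccHalf must be aligned per voxel")
  raw <- ccMaxFromHalf(ccHalfValues)
  floored <- pmax(raw, 0.3)
  new("CeilingEstimates",
    ccHalf = as.numeric(ccHalfValues), ccMaxRaw = raw, ccMax = floored,
    ccNorm = as.numeric(ccAbs) / floored, ccAbs = as.numeric(ccAbs)
  )
}
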