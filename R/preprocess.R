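#' @include AllClasses.R utils.R
NULL

## Hat row for a local polynomial fit: prediction weights at offset 0 given
## window offsets `offs`.
polyHatRow <- function(offs, order) {
  V <- outer(offs, 0:order, "^")
  as.numeric(solve(crossprod(V), t(V))[1L, ])
}

#' Savitzky-Golay detrending of voxel time series
#'
#' Identifies low-frequency drift with a second-order Savitzky-Golay filter
#' over a 120 s window (61 TRs at TR = 2 s) and subtracts it. Interior
#' samples use the standard central smoothing coefficients; at the series
#' edges the trend is the least-squares polynomial fit on the truncated
#' window (edge samples are discarded by the subsequent trimming anyway).
#'
#' @param x numeric vector or matrix (TR x voxel), one scan.
#' @param order polynomial order (default 2).
#' @param windowS window length in seconds (default 120).
#' @param trS repetition time in seconds.
#' @return detrended series with the same shape as \code{x}.
#' @export
savgolDetrend <- function(x, order = 2, windowS = 120, trS = 2) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  win <- floor(windowS / trS)
  if (win %% 2L == 0L) win <- win + 1L
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  stopIfNot(win > order + 1L, "window must exceed order + 1 samples")
  h <- (win - 1L) %/% 2L
  central <- polyHatRow(seq.int(-h, h), order)
  trend <- matrix(0, n, ncol(x))
  interior <- (h + 1L):(n - h)
  filt <- stats::filter(x, central, sides = 2L)
  trend[interior, ] <- as.matrix(filt)[interior, , drop = FALSE]
  for (i in seq_len(h)) {
    offs <- seq.int(1L - i, h)          # truncated leading window
    trend[i, ] <- polyHatRow(offs, order) %*% x[i + offs, , drop = FALSE]
    j <- n - i + 1L                      # trailing mirror
    offs <- seq.int(-h, i - 1L)
    trend[j, ] <- polyHatRow(offs, order) %*% x[j + offs, , drop = FALSE]
  }
  out <- x - trend
  if (vec) out[, 1L] else out
}

#' Trim scan edges and standardize voxel time series
#'
#' Removes \code{nTrim} volumes (20 s at TR = 2 s for the default 10) at the
#' beginning and end of a scan, subtracts the per-voxel mean and scales to
#' unit variance. Voxels with zero variance after trimming are flagged in the
#' \code{"zeroVariance"} attribute and set to zero rather than raising, so
#' degenerate mask voxels can be excluded downstream.
#'
#' @param x numeric matrix (TR x voxel), one scan.
#' @param nTrim volumes to remove at each end (default 10).
#' @return standardized matrix with \code{2 * nTrim} fewer rows.
#' @export
trimStandardize <- function(x, nTrim = 10) {
  x <- as.matrix(x)
  stopIfNot(nrow(x) > 2 * nTrim, "scan too short for the requested trim")
  keep <- if (nTrim > 0) seq.int(nTrim + 1L, nrow(x) - nTrim) else seq_len(nrow(x))
  z <- zscoreColumns(x[keep, , drop = FALSE])
  ## population-variance scaling so var(out) = 1 exactly under stats::var
  out <- z$values
  attr(out, "zeroVariance") <- z$constant
  out
}

#' Condition a response set: detrend, trim, standardize per scan
#'
#' Applies the full voxel time-series conditioning pipeline story by story,
#' in the order detrend, trim, standardize, and rebuilds the story bounds to
#' account for the trimmed volumes.
#'
#' @param responses a \linkS4class{ResponseSet}.
#' @param order,windowS Savitzky-Golay parameters (defaults 2 and 120 s).
#' @param nTrim volumes trimmed at each scan edge (default 10).
#' @param detrend apply the Savitzky-Golay step (default TRUE).
#' @return a conditioned \linkS4class{ResponseSet}; voxels flagged
#'   zero-variance in any scan are recorded in the \code{"zeroVariance"}
#'   attribute of the value matrix.
#' @export
preprocessResponses <- function(responses, order = 2, windowS = 120,
                                nTrim = 10, detrend = TRUE) {
  stopIfNot(is(responses, "ResponseSet"), "responses must be a ResponseSet")
  b <- responses@storyBounds
  pieces <- vector("list", nrow(b))
  zv <- rep(FALSE, ncol(responses@values))
  for (i in seq_len(nrow(b))) {
    x <- responses@values[storyRows(b, i), , drop = FALSE]
    if (detrend) x <- savgolDetrend(x, order, windowS, responses@trS)
    x <- trimStandardize(x, nTrim)
    zv <- zv | attr(x, "zeroVariance")
    pieces[[i]] <- x
  }
  lens <- vapply(pieces, nrow, integer(1))
  ends <- cumsum(lens)
  vals <- do.call(rbind, pieces)
  attr(vals, "zeroVariance") <- zv
  new("ResponseSet",
    values = vals, regionLabels = responses@regionLabels,
    storyBounds = cbind(start = c(1L, head(ends, -1L) + 1L), end = ends + 1L),
    repeats = responses@repeats, trS = responses@trS
  )
}
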