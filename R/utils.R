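# Internal numeric helpers shared across modules.

#' @importFrom withr with_seed
#' @importFrom stats sd var cor rnorm runif quantile
NULL

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Column z-score returning the statistics used, so a held-out set can reuse
## the training means/scales. Zero-variance columns are mapped to 0 and
## reported in `constant`.
zscoreColumns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
  }
  constant <- !is.finite(scale) | scale < .Machine$double.eps^0.5
  eff <- ifelse(constant, 1, scale)
  out <- sweep(sweep(x, 2L, center, "-"), 2L, eff, "/")
  out[, constant] <- 0
  list(values = out, center = center, scale = scale, constant = constant)
}

## Pearson correlation per column between two equally shaped matrices
## (time x voxel). Zero-variance columns yield r = 0 with a flag.
colPearson <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  n <- nrow(x)
  cx <- sweep(x, 2L, colMeans(x), "-")
  cy <- sweep(y, 2L, colMeans(y), "-")
  sx <- sqrt(colSums(cx^2))
  sy <- sqrt(colSums(cy^2))
  degen <- sx < .Machine$double.eps^0.5 * sqrt(n) | sy < .Machine$double.eps^0.5 * sqrt(n)
  denom <- sx * sy
  denom[degen] <- 1
  r <- colSums(cx * cy) / denom
  r[degen] <- 0
  attr(r, "degenerate") <- degen
  r
}

signedSquare <- function(r) r * abs(r)

## Half-open story interval matrix validation: rows (start, end), 1-based
## start, end exclusive, contiguous partition of 1..nTR.
checkStoryBounds <- function(bounds, nTR) {
  if (is.null(bounds)) return("story bounds missing")
  b <- as.matrix(bounds)
  if (ncol(b) != 2L) return("story bounds need two columns (start, end)")
  if (b[1, 1] != 1L) return("story bounds must start at TR 1")
  if (any(b[, 2] <= b[, 1] - 1L)) return("empty story interval")
  if (nrow(b) > 1L && any(b[-1L, 1] != b[-nrow(b), 2])) {
    return("story bounds must be contiguous")
  }
  if (b[nrow(b), 2] != nTR + 1L) return("story bounds must end at nTR + 1")
  NULL
}

storyLengths <- function(bounds) as.integer(bounds[, 2] - bounds[, 1])

## Row indices of story `i` given a bounds matrix.
storyRows <- function(bounds, i) seq.int(bounds[i, 1], bounds[i, 2] - 1L)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
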