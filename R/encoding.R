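#' @include AllClasses.R features.R
NULL

## Ridge weights for a grid of penalties via one eigendecomposition of X'X.
## Zero eigenvalues are dropped when lambda = 0 (minimum-norm least squares).
ridgeWeightsGrid <- function(X, Y, lambdas) {
  eig <- eigen(crossprod(X), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  proj <- crossprod(eig$vectors, crossprod(X, Y))  # V' X'Y
  tol <- max(d) * 1e-12
  lapply(lambdas, function(lam) {
    dd <- d + lam
    inv <- ifelse(dd > tol, 1 / dd, 0)
    eig$vectors %*% (proj * inv)
  })
}

#' Fit voxelwise ridge regression
#'
#' Solves the penalized least-squares problem (X'X + lambda I) W = X'Y for
#' all voxels at once via an eigendecomposition of X'X (numerically stable
#' and reusable across a penalty grid). At lambda = 0 with a rank-deficient
#' design, the minimum-norm least-squares solution is returned.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param responses a \linkS4class{ResponseSet} or numeric matrix with
#'   matching rows.
#' @param lambda non-negative regularization value.
#' @param meta optional provenance list stored on the fit.
#' @return a \linkS4class{RidgeFit}.
#' @export
fitRidge <- function(design, responses, lambda, meta = list()) {
  stopIfNot(is(design, "DesignMatrix"), "design must be a DesignMatrix")
  Y <- if (is(responses, "ResponseSet")) responses@values else as.matrix(responses)
  stopIfNot(nrow(Y) == nrow(design@values),
            "design and responses must have the same number of TRs")
  stopIfNot(lambda >= 0, "lambda must be >= 0")
  W <- ridgeWeightsGrid(design@values, Y, lambda)[[1L]]
  new("RidgeFit",
    weights = W, lambda = as.numeric(lambda), columnMap = design@columnMap,
    trainingMeta = meta
  )
}

#' Select a single shared ridge penalty by bootstrap
#'
#' For each bootstrap sample, contiguous chunks of TRs are held out
#' (respecting temporal autocorrelation), models are fit on the remainder
#' for every penalty on the grid, and held-out prediction correlation is
#' recorded. Curves are averaged across bootstrap samples, then across
#' voxels, then across response sets when several are given (multiple
#' subjects), and the argmax penalty is returned -- one value shared by all
#' voxels, keeping the scale of the weights consistent across models.
#'
#' @param design a \linkS4class{DesignMatrix} (training stories).
#' @param responses a \linkS4class{ResponseSet}, matrix, or list of them.
#' @param lambdaGrid penalty grid (default 15 points log-spaced 1..1e7).
#' @param nBoot bootstrap samples (default 50).
#' @param chunkLenTr held-out chunk length in TRs (default 20).
#' @param holdoutFrac fraction of TRs held out per sample (default 0.2).
#' @param seed integer seed.
#' @return list with \code{lambda} (selected value), \code{curve} (mean
#'   held-out correlation per grid point) and \code{grid}.
#' @export
selectLambdaBootstrap <- function(design, responses,
                                  lambdaGrid = 10^seq(0, 7, length.out = 15),
                                  nBoot = 50, chunkLenTr = 20,
                                  holdoutFrac = 0.2, seed = 1L) {
  stopIfNot(length(lambdaGrid) >= 1, "lambda grid must be non-empty")
  stopIfNot(nBoot >= 1, "nBoot must be >= 1")
  if (!is.list(responses)) responses <- list(responses)
  X <- design@values
  n <- nrow(X)
  nChunks <- ceiling(n / chunkLenTr)
  nHold <- max(1L, round(holdoutFrac * nChunks))
  stopIfNot(nHold < nChunks, "holdout fraction too large")
  chunkOf <- ceiling(seq_len(n) / chunkLenTr)
  subjectCurves <- withSeed(seed, lapply(responses, function(rs) {
    Y <- if (is(rs, "ResponseSet")) rs@values else as.matrix(rs)
    curves <- matrix(0, nrow = nBoot, ncol = length(lambdaGrid))
    for (bIdx in seq_len(nBoot)) {
      hold <- chunkOf %in% sample.int(nChunks, nHold)
      Ws <- ridgeWeightsGrid(X[!hold, , drop = FALSE],
                             Y[!hold, , drop = FALSE], lambdaGrid)
      curves[bIdx, ] <- vapply(Ws, function(W) {
        mean(colPearson(X[hold, , drop = FALSE] %*% W,
                        Y[hold, , drop = FALSE]))
      }, numeric(1))
    }
    colMeans(curves)
  }))
  curve <- colMeans(do.call(rbind, subjectCurves))
  list(lambda = lambdaGrid[which.max(curve)], curve = curve,
       grid = lambdaGrid)
}

#' Predict held-out responses and score voxels
#'
#' Prediction is the dot product of the fitted weights with the held-out
#' stimulus matrix; performance is the Pearson correlation over time per
#' voxel and its signed square r * |r|. Voxels with zero-variance prediction
#' or data receive r = 0 and are flagged.
#'
#' @param fit a \linkS4class{RidgeFit}.
#' @param testDesign held-out \linkS4class{DesignMatrix}; its column map
#'   must be identical to the fit's.
#' @param testResponses a \linkS4class{ResponseSet} or matrix.
#' @return a \linkS4class{VoxelScores} (p and q are NA until permutation
#'   testing).
#' @export
predictAndScore <- function(fit, testDesign, testResponses) {
  stopIfNot(is(fit, "RidgeFit"), "fit must be a RidgeFit")
  stopIfNot(identical(fit@columnMap[c("space", "feature", "delay")],
                      testDesign@columnMap[c("space", "feature", "delay")]),
            "column maps of fit and test design must be identical")
  Y <- if (is(testResponses, "ResponseSet")) testResponses@values else
    as.matrix(testResponses)
  pred <- testDesign@values %*% fit@weights
  r <- colPearson(pred, Y)
  degen <- attr(r, "degenerate")
  n <- length(r)
  new("VoxelScores",
    r = as.numeric(r), r2Signed = signedSquare(as.numeric(r)),
    p = rep(NA_real_, n), q = rep(NA_real_, n), degenerate = degen
  )
}

#' Mean signed r-squared per region
#'
#' Arithmetic mean (not sum, so the differing voxel counts of cerebellum and
#' cortex do not bias the comparison) of per-voxel signed r2 within each
#' region.
#'
#' @param scores a \linkS4class{VoxelScores} or numeric vector of signed r2.
#' @param regionLabels per-voxel region labels covering all voxels.
#' @return named numeric, region -> mean signed r2; empty regions yield NA
#'   with a warning.
#' @export
meanRegionPerformance <- function(scores, regionLabels) {
  vals <- if (is(scores, "VoxelScores")) scores@r2Signed else as.numeric(scores)
  stopIfNot(length(regionLabels) == length(vals),
            "labels must cover all voxels")
  regions <- c("cerebellum", "cortex")
  out <- vapply(regions, function(rg) {
    sel <- regionLabels == rg
    if (!any(sel)) return(NA_real_)
    mean(vals[sel])
  }, numeric(1))
  if (anyNA(out)) warning("empty region: mean undefined")
  out
}

#' Attach block-permutation significance to voxel scores
#'
#' Runs the block permutation test of the data-vs-prediction correlation for
#' every voxel and stores one-sided p values and BH-FDR q values on the
#' score object.
#'
#' @param scores a \linkS4class{VoxelScores} from \code{predictAndScore}.
#' @param fit the \linkS4class{RidgeFit} that produced them.
#' @param testDesign held-out design.
#' @param testResponses held-out responses.
#' @param blockLenTr permutation block length in TRs (default 10).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return the \linkS4class{VoxelScores} with p and q filled in.
#' @export
scoreSignificance <- function(scores, fit, testDesign, testResponses,
                              blockLenTr = 10, nPerm = 10000, seed = 1L) {
  Y <- if (is(testResponses, "ResponseSet")) testResponses@values else
    as.matrix(testResponses)
  pred <- testDesign@values %*% fit@weights
  pr <- blockPermutationPvalues(Y, pred, blockLenTr = blockLenTr,
                                nPerm = nPerm, seed = seed,
                                keepNull = FALSE)
  scores@p <- pr@p
  scores@q <- bhFdr(pr@p)$q
  scores
}
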