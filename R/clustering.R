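#' @include AllClasses.R inference.R
NULL

#' Select the best-predicted voxels
#'
#' Returns the highest-scoring ceiling(fraction * n) voxels; ties are broken
#' by voxel index (lower index wins), so the selection is deterministic.
#'
#' @param scores a \linkS4class{VoxelScores} or numeric vector.
#' @param fraction fraction of voxels to keep, in (0, 1].
#' @return integer vector of selected voxel indices, in score order.
#' @export
selectTopVoxels <- function(scores, fraction = 0.25) {
  vals <- if (is(scores, "VoxelScores")) scores@r2Signed else as.numeric(scores)
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  k <- ceiling(fraction * length(vals))
  order(-vals, seq_along(vals))[seq_len(k)]
}

#' Normalize voxel weight vectors and reduce dimensionality by PCA
#'
#' Each voxel's weight vector is scaled to unit Euclidean norm (consistent
#' with the subsequent cosine-based clustering), then principal components
#' analysis retains the smallest number of components whose cumulative
#' explained-variance ratio reaches the target (default 80\%).
#'
#' @param weights matrix, voxels x original dimension (e.g. 985).
#' @param varianceTarget cumulative explained-variance target in (0, 1]
#'   (default 0.80).
#' @return list with \code{reduced} (voxels x k), \code{basis} (dim x k),
#'   \code{center}, \code{explainedVar} (cumulative ratios of the retained
#'   components) and \code{k}.
#' @export
reduceDimensions <- function(weights, varianceTarget = 0.80) {
  weights <- as.matrix(weights)
  stopIfNot(nrow(weights) >= 2, "need at least two voxels")
  stopIfNot(varianceTarget > 0 && varianceTarget <= 1,
            "varianceTarget must lie in (0, 1]")
  norms <- sqrt(rowSums(weights^2))
  stopIfNot(all(norms > 0), "zero weight vectors cannot be normalized")
  x <- weights / norms
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  stopIfNot(sum(ev) > 0, "degenerate rank-0 input")
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= varianceTarget - 1e-12)[1L]
  list(
    reduced = pc$x[, seq_len(k), drop = FALSE],
    basis = pc$rotation[, seq_len(k), drop = FALSE],
    center = pc$center,
    explainedVar = cum[seq_len(k)],
    k = k
  )
}

## One spherical k-means run from given initial centroids.
skmeansRun <- function(x, centroids, maxIter = 100L) {
  k <- nrow(centroids)
  labels <- integer(nrow(x))
  for (it in seq_len(maxIter)) {
    sims <- x %*% t(centroids)
    newLabels <- max.col(sims, ties.method = "first")
    ## re-seed empty clusters with the worst-fit point
    empty <- which(tabulate(newLabels, k) == 0L)
    if (length(empty)) {
      cosAssigned <- sims[cbind(seq_len(nrow(x)), newLabels)]
      for (cl in empty) {
        worst <- which.min(cosAssigned)
        newLabels[worst] <- cl
        cosAssigned[worst] <- Inf
      }
    }
    if (identical(newLabels, labels)) break
    labels <- newLabels
    for (cl in seq_len(k)) {
      m <- colMeans(x[labels == cl, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm > 0) centroids[cl, ] <- m / nm
    }
  }
  sims <- x %*% t(centroids)
  cos <- sims[cbind(seq_len(nrow(x)), labels)]
  ## squared Euclidean distance on the unit sphere: ||x - c||^2 = 2 - 2 cos
  list(labels = labels, centroids = centroids, inertia = sum(2 - 2 * cos))
}

#' Spherical k-means clustering of unit-normalized weight vectors
#'
#' Rows are normalized to unit length and clustered by cosine similarity;
#' centroids are the unit-normalized means of their members. The best of
#' \code{nInit} random restarts (by within-cluster sum of squares, inertia)
#' is kept. Within a run the inertia never increases across iterations.
#'
#' @param x matrix, voxels x dimensions (reduced weights).
#' @param k number of clusters (1 <= k <= number of points).
#' @param nInit random restarts (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{ClusterModel} with labels, centroids and inertia
#'   at this k (the PCA slots are empty unless filled by
#'   \code{\link{clusterSemanticWeights}}).
#' @export
sphericalKmeans <- function(x, k, nInit = 10, seed = 1L) {
  x <- as.matrix(x)
  stopIfNot(k >= 1, "k must be >= 1")
  stopIfNot(k <= nrow(x), "k cannot exceed the number of points")
  norms <- sqrt(rowSums(x^2))
  stopIfNot(all(norms > 0), "zero rows cannot be normalized")
  xn <- x / norms
  best <- NULL
  withSeed(seed, {
    for (i in seq_len(nInit)) {
      init <- xn[sample.int(nrow(xn), k), , drop = FALSE]
      run <- skmeansRun(xn, init)
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })
  new("ClusterModel",
    pcaBasis = matrix(numeric(0), 0L, 0L), pcaCenter = numeric(0),
    explainedVar = numeric(0), centroids = best$centroids,
    labels = as.integer(best$labels), inertia = best$inertia,
    inertiaCurve = stats::setNames(best$inertia, as.character(k)),
    chosenK = as.integer(k), seed = as.integer(seed)
  )
}

#' Inertia curve over a range of k
#'
#' @param x matrix of points (rows normalized internally).
#' @param kMax largest k (default 20).
#' @param nInit restarts per k (default 10).
#' @param seed integer seed.
#' @return named numeric, k = 1..kMax -> inertia.
#' @export
inertiaOverK <- function(x, kMax = 20, nInit = 10, seed = 1L) {
  kMax <- min(kMax, nrow(x))
  vapply(seq_len(kMax), function(k) {
    sphericalKmeans(x, k, nInit = nInit, seed = seed + k)@inertia
  }, numeric(1)) -> vals
  stats::setNames(vals, as.character(seq_len(kMax)))
}

#' Elbow choice of the number of clusters
#'
#' Picks the k whose inertia lies farthest (perpendicular distance) from the
#' chord connecting the inertia at k = 1 to the inertia at k = kMax -- the
#' point where the inertia drop changes from steep to linear. Candidates are
#' the interior points 2..(kMax - 1); ties take the smallest k, so an
#' exactly linear curve (all distances zero) degenerates to k = 2.
#'
#' @param inertia named or plain numeric vector over consecutive k starting
#'   at 1 (at least 3 points).
#' @return the chosen k (integer).
#' @export
elbowK <- function(inertia) {
  n <- length(inertia)
  stopIfNot(n >= 3, "need at least 3 inertia values")
  ks <- seq_len(n)
  x1 <- 1; y1 <- inertia[1L]; x2 <- n; y2 <- inertia[n]
  ## perpendicular distance from (k, inertia_k) to the chord
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * ks - (x2 - x1) * inertia + x2 * y1 - y2 * x1) / denom
  interior <- 2:(n - 1L)
  interior[which.max(dist[interior])]
}

#' Words most aligned with a weight vector or cluster centroid
#'
#' Ranks vocabulary words by the dot product of the (back-projected) vector
#' with each word's embedding row; the top of the list reads out what the
#' voxel or cluster is most responsive to.
#'
#' @param vector weight vector in the original embedding space, or a
#'   centroid in the reduced space together with \code{model} for
#'   back-projection.
#' @param table embedding matrix, words x dim, with word row names.
#' @param model optional \linkS4class{ClusterModel}; when supplied,
#'   \code{vector} is interpreted in the reduced space and back-projected
#'   through the PCA basis.
#' @param n number of words to return (default 10; Inf for all).
#' @return data.frame with columns word and score, sorted by descending
#'   score.
#' @export
topWords <- function(vector, table, model = NULL, n = 10) {
  if (!is.null(model)) {
    stopIfNot(length(vector) == ncol(model@pcaBasis),
              "centroid length must match the PCA basis")
    vector <- as.numeric(model@pcaBasis %*% vector)
  }
  stopIfNot(length(vector) == ncol(table),
            "vector length must match the embedding dimension")
  score <- as.numeric(table %*% vector)
  ord <- order(-score, seq_along(score))
  keep <- seq_len(min(n, length(score)))
  data.frame(word = rownames(table)[ord][keep], score = score[ord][keep],
             stringsAsFactors = FALSE)
}

#' Full semantic-weight clustering pipeline
#'
#' Normalizes voxel weight vectors, reduces them by PCA to the requested
#' explained variance, computes the inertia curve, chooses k by the elbow
#' rule (unless fixed), and runs spherical k-means.
#'
#' @param weights matrix, voxels x original dimension.
#' @param varianceTarget PCA explained-variance target (default 0.80).
#' @param k fixed number of clusters, or NULL to use the elbow choice.
#' @param kMax largest k scanned for the inertia curve (default 20).
#' @param nInit restarts per fit (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{ClusterModel} with the PCA slots filled.
#' @export
clusterSemanticWeights <- function(weights, varianceTarget = 0.80, k = NULL,
                                   kMax = 20, nInit = 10, seed = 1L) {
  red <- reduceDimensions(weights, varianceTarget)
  curve <- inertiaOverK(red$reduced, kMax = kMax, nInit = nInit, seed = seed)
  if (is.null(k)) k <- elbowK(curve)
  model <- sphericalKmeans(red$reduced, k, nInit = nInit, seed = seed)
  model@pcaBasis <- red$basis
  model@pcaCenter <- red$center
  model@explainedVar <- red$explainedVar
  model@inertiaCurve <- curve
  model@chosenK <- as.integer(k)
  model
}

#' Region-composition permutation test per cluster
#'
#' For each cluster, the statistic is the fraction of cerebellar voxels in
#' that cluster minus the fraction of cortical voxels in it. The null is
#' built by shuffling region labels over voxels; two-tailed p values use the
#' summed-tails rule and are BH-FDR adjusted across clusters. A cluster
#' absent from both regions has statistic 0.
#'
#' @param labels per-voxel cluster indices.
#' @param regionLabels per-voxel region labels (both non-empty).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param exact enumerate all label assignments (small n only).
#' @return data.frame with columns cluster, observed, p, q.
#' @export
clusterProportionTest <- function(labels, regionLabels, nPerm = 10000,
                                  seed = 1L, exact = FALSE) {
  labels <- as.integer(labels)
  stopIfNot(length(labels) == length(regionLabels),
            "labels and region labels must be aligned")
  regions <- sort(unique(regionLabels))
  stopIfNot(length(regions) == 2L, "both regions must be non-empty")
  k <- max(labels)
  propDiff <- function(rl) {
    in1 <- rl == regions[1L]
    tabulate(labels[in1], k) / sum(in1) -
      tabulate(labels[!in1], k) / sum(!in1)
  }
  obs <- propDiff(regionLabels)
  n <- length(labels); n1 <- sum(regionLabels == regions[1L])
  if (exact) {
    combos <- utils::combn(n, n1)
    nulls <- apply(combos, 2L, function(ix) {
      rl <- rep(regions[2L], n); rl[ix] <- regions[1L]
      propDiff(rl)
    })
    nulls <- matrix(nulls, nrow = k)
    p <- vapply(seq_len(k), function(cl) {
      min(1, mean(nulls[cl, ] >= abs(obs[cl])) +
            mean(nulls[cl, ] <= -abs(obs[cl])))
    }, numeric(1))
  } else {
    hi <- integer(k); lo <- integer(k)
    withSeed(seed, {
      for (i in seq_len(nPerm)) {
        nullStat <- propDiff(sample(regionLabels))
        hi <- hi + (nullStat >= abs(obs))
        lo <- lo + (nullStat <= -abs(obs))
      }
    })
    p <- pmin(1, (1 + hi + lo) / (nPerm + 1))
  }
  out <- data.frame(cluster = seq_len(k), observed = obs, p = p)
  out$q <- bhFdr(out$p)$q
  out
}
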