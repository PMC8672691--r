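#' @include AllClasses.R utils.R
NULL

## Row indices after permuting the order of contiguous blocks. A series
## length not divisible by blockLen keeps its final partial block as a
## shorter block.
blockShuffleIndices <- function(n, blockLen, perm = NULL) {
  blockOf <- ceiling(seq_len(n) / blockLen)
  nBlocks <- max(blockOf)
  if (is.null(perm)) perm <- sample.int(nBlocks)
  unlist(split(seq_len(n), blockOf)[perm], use.names = FALSE)
}

#' Block permutation test of prediction-data correlation
#'
#' Shuffles each voxel's data series in contiguous blocks (preserving local
#' autocorrelation), recorrelates with the fixed model prediction, and
#' returns one-sided p values for the observed correlations using the
#' add-one convention p = (1 + #\{null >= observed\}) / (nPerm + 1), which can
#' never be zero. The same block order is applied to all voxels in a given
#' permutation; voxels remain exchangeable because their data are
#' conditionally independent given the permutation.
#'
#' @param data numeric matrix (TR x voxel) of held-out responses.
#' @param predictions numeric matrix (TR x voxel) of model predictions.
#' @param blockLenTr block length in TRs (default 10).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param keepNull store the full null draw matrix (default TRUE; disable
#'   for large voxel counts).
#' @return a \linkS4class{PermutationResult}; observed statistics are the
#'   per-voxel correlations.
#' @export
blockPermutationPvalues <- function(data, predictions, blockLenTr = 10,
                                    nPerm = 10000, seed = 1L,
                                    keepNull = TRUE) {
  data <- as.matrix(data); predictions <- as.matrix(predictions)
  stopIfNot(all(dim(data) == dim(predictions)),
            "data and predictions must be equally shaped")
  n <- nrow(data)
  stopIfNot(blockLenTr >= 1 && blockLenTr <= n,
            "block length must lie in [1, series length]")
  stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  obs <- as.numeric(colPearson(predictions, data))
  nV <- ncol(data)
  counts <- integer(nV)
  draws <- if (keepNull) matrix(0, nrow = nPerm, ncol = nV) else
    matrix(numeric(0), 0L, 0L)
  withSeed(seed, {
    for (p in seq_len(nPerm)) {
      idx <- blockShuffleIndices(n, blockLenTr)
      rNull <- as.numeric(colPearson(predictions, data[idx, , drop = FALSE]))
      counts <- counts + (rNull >= obs)
      if (keepNull) draws[p, ] <- rNull
    }
  })
  new("PermutationResult",
    observed = obs, nullDraws = draws,
    p = (1 + counts) / (nPerm + 1), sidedness = "one",
    seed = as.integer(seed)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values via \code{stats::p.adjust(method = "BH")} and
#' the rejection mask at the given level.
#'
#' @param p vector of p values in (0, 1].
#' @param alpha rejection threshold (default 0.05).
#' @return list with \code{q} (adjusted values) and \code{reject} (logical
#'   mask, q < alpha). Empty input gives empty output.
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), reject = logical(0)))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q < alpha)
}

#' Label-shuffle permutation test for a two-group mean difference
#'
#' The statistic is the difference of group means (first group minus
#' second, groups in sorted label order). The null is built by shuffling the
#' group labels over observations. Two-sided p values follow the summed-tails
#' rule: the fraction of permuted differences at or above |observed| plus the
#' fraction at or below -|observed| (with the add-one convention for random
#' permutations). With \code{exact = TRUE} all label assignments are
#' enumerated instead of sampled.
#'
#' @param values numeric vector of per-voxel values.
#' @param labels group labels (exactly two groups, both non-empty).
#' @param nPerm number of random permutations (default 10000).
#' @param sidedness "two" (default) or "one" (upper tail).
#' @param seed integer seed.
#' @param exact enumerate all assignments (feasible for small n).
#' @return a \linkS4class{PermutationResult} with the observed difference.
#' @export
labelShuffleTest <- function(values, labels, nPerm = 10000,
                             sidedness = c("two", "one"), seed = 1L,
                             exact = FALSE) {
  sidedness <- match.arg(sidedness)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  stopIfNot(length(groups) == 2L, "exactly two groups required")
  g1 <- labels == groups[1L]
  stopIfNot(any(g1) && any(!g1), "both groups must be non-empty")
  obs <- mean(values[g1]) - mean(values[!g1])
  n <- length(values); n1 <- sum(g1)
  if (exact) {
    combos <- utils::combn(n, n1)
    nullStat <- apply(combos, 2L, function(ix) {
      mean(values[ix]) - mean(values[-ix])
    })
    p <- if (sidedness == "two") {
      mean(nullStat >= abs(obs)) + mean(nullStat <= -abs(obs))
    } else {
      mean(nullStat >= obs)
    }
    p <- min(p, 1)
    return(new("PermutationResult",
      observed = obs, nullDraws = matrix(nullStat, ncol = 1L), p = p,
      sidedness = sidedness, seed = NA_integer_
    ))
  }
  nullStat <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    ix <- sample.int(n, n1)
    mean(values[ix]) - mean(values[-ix])
  }, numeric(1)))
  p <- if (sidedness == "two") {
    (1 + sum(nullStat >= abs(obs)) + sum(nullStat <= -abs(obs))) / (nPerm + 1)
  } else {
    (1 + sum(nullStat >= obs)) / (nPerm + 1)
  }
  p <- min(p, 1)
  new("PermutationResult",
    observed = obs, nullDraws = matrix(nullStat, ncol = 1L), p = p,
    sidedness = sidedness, seed = as.integer(seed)
  )
}
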