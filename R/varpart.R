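#' @include AllClasses.R inference.R encoding.R
NULL

#' Minimum-norm projection onto a polyhedron of bias terms
#'
#' Solves min ||b||^2 subject to A b >= c, the constrained correction
#' applied per voxel to nested-model r2 estimates so that no derived
#' variance partition is negative. Solved by a dual active-set iteration
#' (the optimum satisfies b = A_S' lambda with lambda >= 0 on the active
#' constraints); a full enumeration over active sets backs the iteration up
#' for degenerate systems. For these low-dimensional systems (at most six
#' constraints) the exact minimum-norm feasible point is returned to 1e-9.
#'
#' @param A constraint matrix (one row per inequality).
#' @param cvec right-hand side.
#' @param tol numerical tolerance (default 1e-10).
#' @return the minimum-norm feasible b.
#' @export
minNormProject <- function(A, cvec, tol = 1e-10) {
  A <- as.matrix(A)
  m <- nrow(A); d <- ncol(A)
  scale <- max(1, max(abs(cvec)))
  if (all(cvec <= tol * scale)) return(numeric(d))
  active <- integer(0)
  b <- numeric(d)
  for (iter in seq_len(50L + 10L * m)) {
    if (length(active)) {
      M <- A[active, , drop = FALSE]
      lam <- as.numeric(MASS::ginv(tcrossprod(M)) %*% cvec[active])
      if (any(lam < -tol)) {
        active <- active[-which.min(lam)]
        next
      }
      b <- as.numeric(crossprod(M, lam))
    } else {
      b <- numeric(d)
    }
    viol <- cvec - as.numeric(A %*% b)
    if (max(viol) <= tol * scale) return(b)
    active <- union(active, which.max(viol))
  }
  ## enumeration fallback: every active set, keep the feasible minimum norm
  best <- NULL; bestNorm <- Inf
  for (mask in seq_len(2^m) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    cand <- if (length(S)) {
      M <- A[S, , drop = FALSE]
      as.numeric(crossprod(M, MASS::ginv(tcrossprod(M)) %*% cvec[S]))
    } else numeric(d)
    if (max(cvec - as.numeric(A %*% cand)) <= 1e-8 * scale) {
      nrm <- sum(cand^2)
      if (nrm < bestNorm) { best <- cand; bestNorm <- nrm }
    }
  }
  stopIfNot(!is.null(best), "bias-correction constraint system infeasible")
  best
}

## Constraint system of the unique (leave-one-out) correction: bias terms
## (b0 for the full union, b_s for each drop-one model).
uniqueConstraints <- function(u, d) {
  S <- length(d)
  A <- rbind(
    cbind(1, -diag(S)),                  # unique_s >= 0
    c(-(S - 1), rep(1, S))               # nonunique >= 0
  )
  cvec <- c(d - u, (S - 1) * u - sum(d))
  list(A = A, c = cvec)
}

## Constraint system of the pairwise correction: bias terms
## (b1 union, b2 first space, b3 second space).
pairwiseConstraints <- function(uax, a, x) {
  A <- rbind(
    c(-1, 1, 1),                         # intersection >= 0
    c(1, 0, -1),                         # first space unique >= 0
    c(1, -1, 0)                          # second space unique >= 0
  )
  cvec <- c(uax - a - x, x - uax, a - uax)
  list(A = A, c = cvec)
}

#' Minimum-norm bias correction of nested-model r2 estimates
#'
#' Sampling noise makes larger joint models prone to underestimating r2,
#' which can turn derived partitions negative. The correction adds a bias
#' term to each model's estimate, choosing the smallest-norm set of bias
#' terms under the constraint that every derived partition is non-negative;
#' it is applied independently per voxel. Voxels whose raw partitions are
#' already non-negative are untouched (b = 0).
#'
#' @param r2 matrix voxel x model of raw signed r2 values. For
#'   \code{mode = "unique"} the first column is the full union and the
#'   remaining columns the leave-one-out models; for
#'   \code{mode = "pairwise"} the columns are (union, first space, second
#'   space).
#' @param mode "unique" or "pairwise".
#' @return list with \code{r2} (corrected matrix) and \code{bias} (voxel x
#'   model matrix of bias terms).
#' @export
biasCorrect <- function(r2, mode = c("unique", "pairwise")) {
  mode <- match.arg(mode)
  r2 <- as.matrix(r2)
  nV <- nrow(r2)
  bias <- matrix(0, nrow = nV, ncol = ncol(r2),
                 dimnames = dimnames(r2))
  for (v in seq_len(nV)) {
    sys <- if (mode == "unique") {
      uniqueConstraints(r2[v, 1L], r2[v, -1L])
    } else {
      pairwiseConstraints(r2[v, 1L], r2[v, 2L], r2[v, 3L])
    }
    if (all(sys$c <= 0)) next
    bias[v, ] <- minNormProject(sys$A, sys$c)
  }
  list(r2 = r2 + bias, bias = bias)
}

#' Unique (five-way) variance partitions
#'
#' The variance uniquely explained by each feature space is the relative
#' complement r2(full union) - r2(union without that space); the nonunique
#' partition is the full-union r2 minus the sum of the unique partitions.
#' With \code{correct = TRUE} (default) the minimum-norm bias correction is
#' applied first, so all partitions are non-negative and sum exactly to the
#' corrected union r2.
#'
#' @param r2Union per-voxel signed r2 of the full union model.
#' @param r2Drop matrix voxel x space of leave-one-out model r2, with the
#'   dropped space as column name.
#' @param correct apply the bias correction (default TRUE).
#' @return a \linkS4class{PartitionTable} (mode "unique") with partitions
#'   \code{unique_<space>} and \code{nonunique}.
#' @export
uniquePartitions <- function(r2Union, r2Drop, correct = TRUE) {
  r2Drop <- as.matrix(r2Drop)
  stopIfNot(length(r2Union) == nrow(r2Drop),
            "union and leave-one-out scores must share voxels")
  spaces <- colnames(r2Drop)
  stopIfNot(!is.null(spaces), "r2Drop needs the dropped space as column names")
  raw <- cbind(union = r2Union, r2Drop)
  cor <- if (correct) biasCorrect(raw, "unique") else
    list(r2 = raw, bias = matrix(0, nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  u <- cor$r2[, 1L]
  uniq <- u - cor$r2[, -1L, drop = FALSE]
  nonunique <- u - rowSums(uniq)
  parts <- cbind(uniq, nonunique)
  colnames(parts) <- c(paste0("unique_", spaces), "nonunique")
  new("PartitionTable",
    mode = "unique", r2 = cor$r2, r2Raw = raw, partitions = parts,
    bias = cor$bias, significance = data.frame()
  )
}

#' Pairwise variance partitions against a reference space
#'
#' For a pair of feature spaces (the context-level space A and one other
#' space X), the intersection is r2(A) + r2(X) - r2(A union X) and the
#' unique contributions are the relative complements r2(A union X) - r2(X)
#' and r2(A union X) - r2(A).
#'
#' @param r2Pair per-voxel signed r2 of the concatenated pair model.
#' @param r2First per-voxel r2 of the first (reference) space alone.
#' @param r2Second per-voxel r2 of the second space alone.
#' @param names length-2 character naming the two spaces (default
#'   \code{c("contextual", "other")}).
#' @param correct apply the bias correction (default TRUE).
#' @return a \linkS4class{PartitionTable} (mode "pairwise") with partitions
#'   \code{unique_<first>}, \code{unique_<second>} and \code{intersection}.
#' @export
pairwisePartitions <- function(r2Pair, r2First, r2Second,
                               names = c("contextual", "other"),
                               correct = TRUE) {
  stopIfNot(length(r2Pair) == length(r2First) &&
              length(r2Pair) == length(r2Second),
            "all three model scores must share voxels")
  raw <- cbind(pair = r2Pair, first = r2First, second = r2Second)
  cor <- if (correct) biasCorrect(raw, "pairwise") else
    list(r2 = raw, bias = matrix(0, nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  uax <- cor$r2[, 1L]; a <- cor$r2[, 2L]; x <- cor$r2[, 3L]
  parts <- cbind(uax - x, uax - a, a + x - uax)
  colnames(parts) <- c(paste0("unique_", names[1L]),
                       paste0("unique_", names[2L]), "intersection")
  new("PartitionTable",
    mode = "pairwise", r2 = cor$r2, r2Raw = raw, partitions = parts,
    bias = cor$bias, significance = data.frame()
  )
}

## Align a held-out design's columns to a fit's column map and predict.
predictFromFit <- function(fit, testDesign) {
  keyFit <- paste(fit@columnMap$space, fit@columnMap$feature,
                  fit@columnMap$delay)
  keyTest <- paste(testDesign@columnMap$space, testDesign@columnMap$feature,
                   testDesign@columnMap$delay)
  idx <- match(keyFit, keyTest)
  stopIfNot(!anyNA(idx), "test design lacks columns required by the fit")
  testDesign@values[, idx, drop = FALSE] %*% fit@weights
}

## Partition matrix (voxel x partition) from per-model prediction matrices.
partitionsFromPreds <- function(preds, Y, mode, spaces, pairNames) {
  r2 <- vapply(preds, function(p) {
    signedSquare(as.numeric(colPearson(p, Y)))
  }, numeric(ncol(Y)))
  if (is.null(dim(r2))) r2 <- matrix(r2, nrow = 1L, dimnames = list(NULL, names(preds)))
  if (mode == "unique") {
    pt <- uniquePartitions(r2[, "union"], r2[, spaces, drop = FALSE])
  } else {
    pt <- pairwisePartitions(r2[, "pair"], r2[, "first"], r2[, "second"],
                             names = pairNames)
  }
  pt@partitions
}

#' Permutation significance of variance partitions
#'
#' Builds a null distribution of mean partition sizes per region by
#' block-shuffling the model predictions (not the data), recomputing every
#' model's r2, re-deriving the partitions including the bias correction,
#' and averaging partition sizes over voxels within each region -- the same
#' correct-then-average ordering used for the observed values. One-sided p
#' values use the add-one convention; q values are BH-FDR adjusted across
#' all partition-by-region cells.
#'
#' @param fits named list of \linkS4class{RidgeFit}. For
#'   \code{mode = "unique"}: element "union" plus one \code{drop_<space>}
#'   element per feature space. For \code{mode = "pairwise"}: elements
#'   "pair", "first", "second".
#' @param testDesign held-out \linkS4class{DesignMatrix} (full, all spaces).
#' @param testResponses held-out \linkS4class{ResponseSet} or matrix; a
#'   matrix requires \code{regionLabels}.
#' @param mode "unique" or "pairwise".
#' @param nPerm number of permutations (default 1000).
#' @param blockLenTr block length in TRs (default 10).
#' @param seed integer seed.
#' @param pairNames names of the two spaces in pairwise mode.
#' @param regionLabels per-voxel labels (taken from the ResponseSet when
#'   available).
#' @return data.frame with columns partition, region, observed, p, q.
#' @export
partitionSignificance <- function(fits, testDesign, testResponses,
                                  mode = c("unique", "pairwise"),
                                  nPerm = 1000, blockLenTr = 10, seed = 1L,
                                  pairNames = c("contextual", "other"),
                                  regionLabels = NULL) {
  mode <- match.arg(mode)
  Y <- if (is(testResponses, "ResponseSet")) testResponses@values else
    as.matrix(testResponses)
  if (is.null(regionLabels) && is(testResponses, "ResponseSet")) {
    regionLabels <- testResponses@regionLabels
  }
  stopIfNot(!is.null(regionLabels), "region labels required")
  n <- nrow(Y)
  stopIfNot(blockLenTr <= n, "block length exceeds series length")
  spaces <- if (mode == "unique") {
    sub("^drop_", "", grep("^drop_", names(fits), value = TRUE))
  } else character(0)
  if (mode == "unique") {
    stopIfNot("union" %in% names(fits) && length(spaces) >= 2L,
              "unique mode needs a union fit and drop_<space> fits")
  } else {
    stopIfNot(all(c("pair", "first", "second") %in% names(fits)),
              "pairwise mode needs fits named pair, first, second")
  }
  preds <- lapply(fits, predictFromFit, testDesign = testDesign)
  if (mode == "unique") {
    names(preds) <- ifelse(names(preds) == "union", "union",
                           sub("^drop_", "", names(preds)))
  }
  regions <- sort(unique(regionLabels))
  regionMeans <- function(parts) {
    out <- sapply(regions, function(rg) {
      colMeans(parts[regionLabels == rg, , drop = FALSE])
    })
    ## rows: partitions, cols: regions
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                         dimnames = list(colnames(parts), regions))
    out
  }
  obsParts <- partitionsFromPreds(preds, Y, mode, spaces, pairNames)
  obs <- regionMeans(obsParts)
  counts <- matrix(0L, nrow = nrow(obs), ncol = ncol(obs),
                   dimnames = dimnames(obs))
  withSeed(seed, {
    for (it in seq_len(nPerm)) {
      idx <- blockShuffleIndices(n, blockLenTr)
      permPreds <- lapply(preds, function(p) p[idx, , drop = FALSE])
      nullMeans <- regionMeans(
        partitionsFromPreds(permPreds, Y, mode, spaces, pairNames))
      counts <- counts + (nullMeans >= obs)
    }
  })
  p <- (1 + counts) / (nPerm + 1)
  out <- data.frame(
    partition = rep(rownames(obs), times = ncol(obs)),
    region = rep(colnames(obs), each = nrow(obs)),
    observed = as.numeric(obs), p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  out$q <- bhFdr(out$p)$q
  out
}

#' Region-difference permutation test for partition sizes
#'
#' Tests, for each partition, whether the mean partition value differs
#' between cerebellum and cortex by shuffling the region label assigned to
#' each voxel (two-sided, difference of region means, cerebellum minus
#' cortex).
#'
#' @param partitions a \linkS4class{PartitionTable} or a voxel x partition
#'   matrix.
#' @param regionLabels per-voxel region labels (both regions non-empty).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with columns partition, observed, p, q.
#' @export
regionDifferenceTest <- function(partitions, regionLabels, nPerm = 10000,
                                 seed = 1L) {
  parts <- if (is(partitions, "PartitionTable")) partitions@partitions else
    as.matrix(partitions)
  stopIfNot(length(regionLabels) == nrow(parts),
            "one region label per voxel required")
  stopIfNot(length(unique(regionLabels)) == 2L,
            "both regions must be non-empty")
  res <- lapply(seq_len(ncol(parts)), function(j) {
    pr <- labelShuffleTest(parts[, j], regionLabels, nPerm = nPerm,
                           sidedness = "two", seed = seed + j)
    c(observed = pr@observed, p = pr@p)
  })
  out <- data.frame(
    partition = colnames(parts),
    observed = vapply(res, `[[`, numeric(1), "observed"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$q <- bhFdr(out$p)$q
  out
}

#' Fit the nested model family for variance partitioning
#'
#' Convenience wrapper fitting, with one shared penalty, the models required
#' by the unique scheme (full union plus each leave-one-out union) or by the
#' pairwise scheme (pair concatenation plus each space alone).
#'
#' @param design training \linkS4class{DesignMatrix} containing all spaces.
#' @param responses training responses.
#' @param lambda shared ridge penalty.
#' @param mode "unique" or "pairwise".
#' @param pair for pairwise mode, length-2 character of space names
#'   (reference space first).
#' @return named list of \linkS4class{RidgeFit} suitable for
#'   \code{\link{partitionSignificance}}.
#' @export
fitNestedModels <- function(design, responses, lambda,
                            mode = c("unique", "pairwise"), pair = NULL) {
  mode <- match.arg(mode)
  spaces <- unique(design@columnMap$space)
  if (mode == "unique") {
    sets <- c(list(union = spaces),
              stats::setNames(lapply(spaces, function(sp) setdiff(spaces, sp)),
                              paste0("drop_", spaces)))
  } else {
    stopIfNot(length(pair) == 2L, "pairwise mode needs two space names")
    sets <- list(pair = pair, first = pair[1L], second = pair[2L])
  }
  lapply(sets, function(sp) {
    fitRidge(subsetDesign(design, sp), responses, lambda,
             meta = list(spaces = sp))
  })
}
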