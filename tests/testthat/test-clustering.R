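test_that("top-voxel selection sorts by score with index tie-breaks", {
  scores <- c(0.2, 0.9, 0.5, 0.9, 0.1, 0.3, 0.8, 0.4)
  expect_equal(selectTopVoxels(scores, 0.25), c(2L, 4L))  # top-2 of 8
  expect_equal(selectTopVoxels(scores, 1.0), order(-scores, 1:8))
  ## all-equal scores: first ceil(frac*n) indices
  expect_equal(selectTopVoxels(rep(1, 10), 0.3), 1:3)
  expect_error(selectTopVoxels(scores, 0), "fraction")
})

test_that("PCA reduction retains the smallest k reaching the variance
           target", {
  ## data in an exact 3-dim subspace: k = 3 at target 0.8, ratio 1
  withr::with_seed(61, {
    basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
    x <- matrix(rnorm(100 * 3), 100, 3) %*% t(basis)
  })
  red <- reduceDimensions(x, 0.8)
  expect_equal(red$k, 3L)
  expect_gt(max(red$explainedVar), 1 - 1e-9)

  ## random full-rank data: k matches the eigendecomposition rule
  y <- withr::with_seed(62, matrix(rnorm(60 * 10), 60, 10))
  red2 <- reduceDimensions(y, 0.8)
  yn <- y / sqrt(rowSums(y^2))
  ev <- eigen(cov(yn))$values
  oracle <- which(cumsum(ev) / sum(ev) >= 0.8)[1]
  expect_equal(red2$k, as.integer(oracle))

  ## full retention
  red3 <- reduceDimensions(y, 1.0)
  expect_equal(red3$k, as.integer(min(nrow(y) - 1, ncol(y))))
  expect_error(reduceDimensions(matrix(0, 5, 3)), "normalized|rank")
})

test_that("spherical k-means recovers planted direction bundles", {
  ## two well-separated bundles: perfect recovery (ARI = 1)
  withr::with_seed(63, {
    c1 <- c(1, rep(0, 9)); c2 <- c(0, 1, rep(0, 8))
    x <- rbind(
      matrix(rep(c1, 40), 40, byrow = TRUE) + matrix(rnorm(400, sd = 0.05), 40),
      matrix(rep(c2, 40), 40, byrow = TRUE) + matrix(rnorm(400, sd = 0.05), 40)
    )
  })
  truth <- rep(1:2, each = 40)
  cm <- sphericalKmeans(x, 2, nInit = 5, seed = 3)
  expect_equal(ari(clusterLabels(cm), truth), 1)
  ## centroids unit norm
  expect_lt(max(abs(sqrt(rowSums(clusterCentroids(cm)^2)) - 1)), 1e-9)

  ## k = n: inertia 0, each point its own centroid
  small <- x[1:5, ]
  cmN <- sphericalKmeans(small, 5, nInit = 2, seed = 1)
  expect_lt(cmN@inertia, 1e-12)
  expect_error(sphericalKmeans(small, 6), "exceed")
})

test_that("6-point inertia equals the exhaustive minimum over 2-partitions", {
  x <- withr::with_seed(64, matrix(rnorm(6 * 4), 6, 4))
  xn <- x / sqrt(rowSums(x^2))
  cm <- sphericalKmeans(x, 2, nInit = 25, seed = 5)
  ## brute force: all 2^6 assignments with both clusters non-empty
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(mask))[1:6] + 1L
    if (length(unique(lab)) < 2) next
    inertia <- 0
    for (cl in 1:2) {
      pts <- xn[lab == cl, , drop = FALSE]
      m <- colMeans(pts)
      nm <- sqrt(sum(m^2))
      if (nm > 0) m <- m / nm
      inertia <- inertia + sum(2 - 2 * (pts %*% m))
    }
    best <- min(best, inertia)
  }
  expect_equal(cm@inertia, best, tolerance = 1e-9)
})

test_that("inertia never increases with k and clustering ignores voxel
           order", {
  x <- withr::with_seed(65, matrix(rnorm(60 * 5), 60, 5))
  curve <- inertiaOverK(x, kMax = 6, nInit = 8, seed = 2)
  expect_true(all(diff(curve) <= 1e-6))

  ## voxel-order invariance (up to label names) on separable data
  withr::with_seed(67, {
    protos <- diag(5)[1:3, ]
    xs <- do.call(rbind, lapply(1:3, function(i) {
      matrix(rep(protos[i, ], 20), 20, byrow = TRUE) +
        matrix(rnorm(100, sd = 0.05), 20)
    }))
  })
  perm <- withr::with_seed(66, sample(60))
  a <- sphericalKmeans(xs, 3, nInit = 10, seed = 4)
  b <- sphericalKmeans(xs[perm, ], 3, nInit = 10, seed = 4)
  expect_equal(ari(clusterLabels(a)[perm], clusterLabels(b)), 1)
})

test_that("elbow selection finds constructed breakpoints", {
  ## piecewise-linear curve with a single breakpoint at k* = 5
  k <- 1:20
  curve <- ifelse(k <= 5, 100 - 15 * (k - 1), 40 - 1 * (k - 5))
  expect_equal(elbowK(curve), 5L)
  ## breakpoint location is recovered for other k*
  for (kstar in c(3, 4, 7)) {
    cv <- ifelse(k <= kstar, 100 - 20 * (k - 1),
                 100 - 20 * (kstar - 1) - 0.5 * (k - kstar))
    expect_equal(elbowK(cv), as.integer(kstar))
  }
  ## exactly linear: all distances zero, smallest interior k wins
  expect_equal(elbowK(seq(100, 5, length.out = 20)), 2L)
  expect_error(elbowK(c(3, 1)), "at least 3")
})

test_that("elbow choice recovers the planted bundle count from data", {
  for (c0 in c(3, 4, 5)) {
    withr::with_seed(70 + c0, {
      protos <- qr.Q(qr(matrix(rnorm(12 * c0), 12, c0)))
      x <- do.call(rbind, lapply(seq_len(c0), function(i) {
        matrix(rep(protos[, i], 40), 40, byrow = TRUE) +
          matrix(rnorm(12 * 40, sd = 0.08), 40)
      }))
    })
    curve <- inertiaOverK(x, kMax = 10, nInit = 5, seed = c0)
    expect_equal(elbowK(curve), as.integer(c0))
  }
})

test_that("top-word readout is a dot-product sort with antisymmetry", {
  ## orthonormal toy table: the weight equal to one word's row wins with
  ## score 1
  tab <- diag(8)
  rownames(tab) <- paste0("w", 1:8)
  out <- topWords(tab[3, ], tab, n = 3)
  expect_equal(out$word[1], "w3")
  expect_equal(out$score[1], 1)

  tab2 <- genEmbeddingTable(50, 7, seed = 9)
  v <- withr::with_seed(10, rnorm(7))
  got <- topWords(v, tab2, n = Inf)
  oracle <- rownames(tab2)[order(-as.numeric(tab2 %*% v), 1:50)]
  expect_equal(got$word, oracle)
  ## negated vector reverses the ranking exactly (ties absent a.s.)
  rev <- topWords(-v, tab2, n = Inf)
  expect_equal(rev$word, rev(got$word))
  expect_error(topWords(rnorm(3), tab2), "dimension")
})

test_that("cluster proportion test: enumeration oracle, null identity, and
           planted enrichment power", {
  ## 3-vs-3 toy case matches exhaustive enumeration
  labels <- c(1L, 1L, 2L, 2L, 1L, 2L)
  regions <- rep(c("cerebellum", "cortex"), each = 3)
  got <- clusterProportionTest(labels, regions, exact = TRUE)
  combos <- combn(6, 3)
  for (cl in 1:2) {
    obs <- mean(labels[1:3] == cl) - mean(labels[4:6] == cl)
    nulls <- apply(combos, 2, function(ix) {
      mean(labels[ix] == cl) - mean(labels[-ix] == cl)
    })
    oracle <- min(1, mean(nulls >= abs(obs)) + mean(nulls <= -abs(obs)))
    expect_equal(got$p[cl], oracle)
  }

  ## identical composition: all statistics 0
  even <- rep(1:2, 50)
  evenReg <- rep(c("cerebellum", "cortex"), each = 50)
  sameComp <- clusterProportionTest(even, evenReg, nPerm = 199, seed = 1)
  expect_true(all(sameComp$observed == 0))
  expect_true(all(sameComp$q > 0.5))

  ## planted 2x enrichment of cluster 1 in cerebellum, 500 voxels/region
  withr::with_seed(77, {
    cereb <- sample(1:5, 500, replace = TRUE, prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
    cort <- sample(1:5, 500, replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
  })
  labs <- c(cereb, cort)
  regs <- rep(c("cerebellum", "cortex"), each = 500)
  enr <- clusterProportionTest(labs, regs, nPerm = 499, seed = 2)
  expect_lt(enr$q[1], 0.05)
})
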