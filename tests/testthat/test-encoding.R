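test_that("ridge solutions match the independent SVD oracle", {
  withr::with_seed(42, {
    X <- matrix(rnorm(200 * 50), 200, 50)
    Y <- matrix(rnorm(200 * 20), 200, 20)
  })
  d <- new("DesignMatrix",
    values = X,
    columnMap = data.frame(space = "s", feature = 1:50, delay = 1L),
    storyBounds = cbind(1L, 201L), trS = 2, delaysTr = 1L,
    scaling = list(s = list())
  )
  for (lam in c(0, 1, 100, 1e5)) {
    fit <- fitRidge(d, Y, lam)
    oracle <- svdRidge(X, Y, lam)
    expect_lt(max(abs(fitWeights(fit) - oracle)) / max(abs(oracle)), 1e-8)
  }
  ## lambda = 0 on a full-rank tall design equals OLS
  fit0 <- fitRidge(d, Y, 0)
  ols <- qr.solve(X, Y)
  expect_equal(fitWeights(fit0), ols, tolerance = 1e-8, ignore_attr = TRUE)
  ## infinite-penalty limit: weights shrink to zero
  fitBig <- fitRidge(d, Y, 1e12)
  expect_lt(max(abs(fitWeights(fitBig))), 1e-6)

  expect_error(fitRidge(d, Y[1:100, ], 1), "same number of TRs")
  expect_error(fitRidge(d, Y, -1), "lambda")
})

test_that("ridge solution is invariant to voxel and column ordering", {
  sim <- tinySim(seed = 14, nVoxels = 6)
  fit <- fitRidge(sim$design, sim$responses, 50)
  ## voxel permutation
  perm <- c(3, 1, 6, 2, 5, 4)
  permResp <- sim$responses
  permResp@values <- permResp@values[, perm]
  permResp@regionLabels <- permResp@regionLabels[perm]
  fitP <- fitRidge(sim$design, permResp, 50)
  expect_equal(fitWeights(fitP), fitWeights(fit)[, perm], tolerance = 1e-10)

  ## consistent column permutation leaves predictions unchanged
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  s1 <- predictAndScore(fit, sim$testDesign, testY)
  cols <- sample(seq_len(ncol(designValues(sim$design))))
  dPerm <- new("DesignMatrix",
    values = designValues(sim$design)[, cols],
    columnMap = columnMap(sim$design)[cols, ],
    storyBounds = storyBounds(sim$design), trS = 2,
    delaysTr = sim$design@delaysTr, scaling = sim$design@scaling
  )
  tPerm <- new("DesignMatrix",
    values = designValues(sim$testDesign)[, cols],
    columnMap = columnMap(sim$testDesign)[cols, ],
    storyBounds = storyBounds(sim$testDesign), trS = 2,
    delaysTr = sim$testDesign@delaysTr, scaling = sim$testDesign@scaling
  )
  fit2 <- fitRidge(dPerm, sim$responses, 50)
  s2 <- predictAndScore(fit2, tPerm, testY)
  expect_equal(scoreR(s2), scoreR(s1), tolerance = 1e-8)
})

test_that("bootstrap lambda selection tracks true held-out performance", {
  grid <- 10^seq(0, 7, length.out = 15)
  sim <- tinySim(seed = 16, nVoxels = 10, nStories = 4, storyLenS = 300)
  ## singleton grid returns that value
  one <- selectLambdaBootstrap(sim$design, sim$responses, lambdaGrid = 42,
                               nBoot = 2, seed = 1)
  expect_equal(one$lambda, 42)

  sel <- selectLambdaBootstrap(sim$design, sim$responses, lambdaGrid = grid,
                               nBoot = 10, seed = 2)
  ## exhaustive oracle: fit each grid value on the training set, score on
  ## the (noisy) held-out story against the true evaluation story
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  oracle <- vapply(grid, function(lam) {
    f <- fitRidge(sim$design, sim$responses, lam)
    mean(scoreR(predictAndScore(f, sim$testDesign, testY)))
  }, numeric(1))
  bestIdx <- which.max(oracle)
  selIdx <- which(grid == sel$lambda)
  expect_lte(abs(selIdx - bestIdx), 2)
  expect_error(
    selectLambdaBootstrap(sim$design, sim$responses, grid, nBoot = 1,
                          holdoutFrac = 1.5), "holdout")
})

test_that("held-out scoring computes signed r2 and flags degenerate voxels", {
  withr::with_seed(5, {
    pred <- matrix(rnorm(300), 100, 3)
  })
  ## perfect prediction: r = 1, signed r2 = 1
  d <- new("DesignMatrix",
    values = pred, columnMap = data.frame(space = "s", feature = 1:3,
                                          delay = 1L),
    storyBounds = cbind(1L, 101L), trS = 2, delaysTr = 1L, scaling = list()
  )
  fit <- new("RidgeFit", weights = diag(3), lambda = 0,
             columnMap = d@columnMap, trainingMeta = list())
  s <- predictAndScore(fit, d, pred)
  expect_equal(scoreR(s), rep(1, 3), tolerance = 1e-12)
  expect_equal(scoreR2(s), rep(1, 3), tolerance = 1e-12)

  ## sign-preserving square and brute-force correlation formula
  y <- -0.5 * pred + matrix(rnorm(300, sd = 0.5), 100, 3)
  s2 <- predictAndScore(fit, d, y)
  brute <- vapply(1:3, function(j) {
    cv <- mean((pred[, j] - mean(pred[, j])) * (y[, j] - mean(y[, j])))
    cv / sqrt(mean((pred[, j] - mean(pred[, j]))^2) *
                mean((y[, j] - mean(y[, j]))^2))
  }, numeric(1))
  expect_equal(scoreR(s2), brute, tolerance = 1e-12)
  expect_equal(scoreR2(s2), brute * abs(brute), tolerance = 1e-12)

  ## zero-variance data: r defined as 0 with a flag
  y[, 2] <- 7
  s3 <- predictAndScore(fit, d, y)
  expect_equal(scoreR(s3)[2], 0)
  expect_true(s3@degenerate[2])
})

test_that("noiseless data at the grid floor is recovered almost perfectly", {
  sim <- tinySim(seed = 18, nVoxels = 8, ccHalf = 1)
  fit <- fitRidge(sim$design, sim$responses, 1e-8)
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  s <- predictAndScore(fit, sim$testDesign, testY)
  expect_true(all(scoreR(s) >= 0.999))
})

test_that("mean region performance is an arithmetic mean per region", {
  vals <- c(0.1, 0.3, -0.2, 0.6)
  labs <- c("cerebellum", "cerebellum", "cortex", "cortex")
  out <- meanRegionPerformance(vals, labs)
  expect_equal(unname(out), c(mean(c(0.1, 0.3)), mean(c(-0.2, 0.6))))
  ## singleton region equals that voxel's value
  out2 <- meanRegionPerformance(c(0.5, 0.2, 0.1),
                                c("cerebellum", "cortex", "cortex"))
  expect_equal(unname(out2["cerebellum"]), 0.5)
  ## null field
  expect_equal(unname(meanRegionPerformance(c(0, 0), c("cerebellum", "cortex"))),
               c(0, 0))
  expect_warning(meanRegionPerformance(c(1, 2), c("cortex", "cortex")),
                 "empty region")
})
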