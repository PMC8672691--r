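test_that("partition arithmetic follows the set-theoretic definitions", {
  ## hand-computed one-voxel unique case
  r2u <- 0.5
  r2d <- matrix(c(0.3, 0.5, 0.5, 0.5, 0.5), 1,
                dimnames = list(NULL, letters[1:5]))
  pt <- uniquePartitions(r2u, r2d, correct = FALSE)
  parts <- partitionValues(pt)
  expect_equal(parts[1, "unique_a"], 0.2, ignore_attr = TRUE)
  expect_equal(parts[1, "unique_b"], 0, ignore_attr = TRUE)
  expect_equal(parts[1, "nonunique"],
               0.5 - 0.2, ignore_attr = TRUE)

  ## fully redundant spaces: all uniques 0, nonunique = union
  r2same <- matrix(0.4, 1, 5, dimnames = list(NULL, letters[1:5]))
  pt2 <- uniquePartitions(0.4, r2same, correct = FALSE)
  expect_equal(unname(partitionValues(pt2)[1, ]), c(rep(0, 5), 0.4))

  ## hand-computed pairwise case
  pw <- pairwisePartitions(0.6, 0.5, 0.3, correct = FALSE)
  expect_equal(unname(partitionValues(pw)[1, ]),
               c(0.6 - 0.3, 0.6 - 0.5, 0.5 + 0.3 - 0.6))
})

test_that("bias correction is a minimum-norm projection (grid oracle)", {
  ## feasible input (all partitions already >= 0): untouched
  ok <- biasCorrect(cbind(0.5, 0.45, 0.45, 0.45, 0.48, 0.47), "unique")
  expect_equal(ok$bias, matrix(0, 1, 6), ignore_attr = TRUE)

  ## the spec's worked pairwise voxel: negative unique partition
  res <- biasCorrect(cbind(pair = 0.4, first = 0.5, second = 0.0),
                     "pairwise")
  sys <- voxenc:::pairwiseConstraints(0.4, 0.5, 0.0)
  oracle <- gridMinNorm(sys$A, sys$c)
  expect_lt(max(abs(as.numeric(res$bias) - as.numeric(oracle))), 1e-3)

  ## random infeasible pairwise systems vs the grid oracle
  withr::with_seed(31, {
    for (i in 1:15) {
      uax <- runif(1, 0, 0.5); a <- runif(1, 0, 0.6); x <- runif(1, 0, 0.6)
      sys <- voxenc:::pairwiseConstraints(uax, a, x)
      got <- minNormProject(sys$A, sys$c)
      oracle <- gridMinNorm(sys$A, sys$c)
      expect_lt(max(abs(got - as.numeric(oracle))), 1e-3)
      ## feasibility and optimality basics
      expect_true(all(sys$A %*% got >= sys$c - 1e-9))
    }
  })

  ## unique-mode systems vs constrOptim from a feasible interior start
  withr::with_seed(37, {
    for (i in 1:10) {
      u <- runif(1, 0, 0.4)
      d <- runif(5, 0, 0.5)
      sys <- voxenc:::uniqueConstraints(u, d)
      got <- minNormProject(sys$A, sys$c)
      expect_true(all(sys$A %*% got >= sys$c - 1e-9))
      if (max(sys$c) > 1e-9) {
        start <- MASS::ginv(sys$A) %*% (sys$c + 1)  # strictly feasible
        co <- constrOptim(as.numeric(start), function(b) sum(b^2),
                          grad = function(b) 2 * b,
                          ui = sys$A, ci = sys$c, mu = 1e-6,
                          outer.iterations = 200)
        ## the active-set solution must be feasible and at least as good as
        ## the (approximate) barrier solver's optimum
        expect_lt(sum(got^2), sum(co$par^2) + 1e-4)
      }
    }
  })

  ## homogeneity bound: scaling inputs scales the optimal norm at most
  ## proportionally
  sys <- voxenc:::pairwiseConstraints(0.4, 0.5, 0.0)
  b1 <- minNormProject(sys$A, sys$c)
  sys2 <- voxenc:::pairwiseConstraints(0.2, 0.25, 0.0)
  b2 <- minNormProject(sys2$A, sys2$c)
  expect_lt(sqrt(sum(b2^2)), 0.5 * sqrt(sum(b1^2)) + 1e-9)
})

test_that("corrected partitions are non-negative and sum to the union r2", {
  sim <- tinySim(seed = 41, nVoxels = 20, ccHalf = 0.5, nStories = 3,
                 storyLenS = 300)
  fits <- fitNestedModels(sim$design, sim$responses, 100, mode = "unique")
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  spaces <- unique(columnMap(sim$design)$space)
  r2 <- sapply(names(fits), function(nm) {
    sp <- fits[[nm]]@trainingMeta$spaces
    scoreR2(predictAndScore(fits[[nm]], subsetDesign(sim$testDesign, sp),
                            testY))
  })
  drop <- r2[, paste0("drop_", spaces)]
  colnames(drop) <- spaces
  pt <- uniquePartitions(r2[, "union"], drop)
  parts <- partitionValues(pt)
  expect_true(all(parts >= -1e-9))
  expect_lt(max(abs(rowSums(parts) - modelR2(pt)[, "union"])), 1e-9)

  ## pairwise algebra closes the same way
  pf <- fitNestedModels(sim$design, sim$responses, 100, mode = "pairwise",
                        pair = c("contextual", "alpha"))
  r2p <- sapply(names(pf), function(nm) {
    sp <- pf[[nm]]@trainingMeta$spaces
    scoreR2(predictAndScore(pf[[nm]], subsetDesign(sim$testDesign, sp),
                            testY))
  })
  pw <- pairwisePartitions(r2p[, "pair"], r2p[, "first"], r2p[, "second"])
  expect_true(all(partitionValues(pw) >= -1e-9))
  expect_lt(max(abs(rowSums(partitionValues(pw)) - modelR2(pw)[, "pair"])),
            1e-9)
})

test_that("planted unique fractions are recovered and shared variance lands
           in the intersection", {
  sim <- tinySim(seed = 43, fractions = c(0.4, 0.3, 0.2, 0.1, 0),
                 nVoxels = 16, ccHalf = 0.7, nStories = 5, storyLenS = 600,
                 nRepeats = 10)
  fits <- fitNestedModels(sim$design, sim$responses, 50, mode = "unique")
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  spaces <- unique(columnMap(sim$design)$space)
  r2 <- sapply(names(fits), function(nm) {
    sp <- fits[[nm]]@trainingMeta$spaces
    scoreR2(predictAndScore(fits[[nm]], subsetDesign(sim$testDesign, sp),
                            testY))
  })
  drop <- r2[, paste0("drop_", spaces)]
  colnames(drop) <- spaces
  pt <- uniquePartitions(r2[, "union"], drop)
  shares <- colMeans(partitionValues(pt)[, paste0("unique_", spaces)] /
                       modelR2(pt)[, "union"])
  expect_lt(max(abs(shares - c(0.4, 0.3, 0.2, 0.1, 0))), 0.1)

  ## orthogonal planted spaces: pairwise intersection near zero
  pf <- fitNestedModels(sim$design, sim$responses, 50, mode = "pairwise",
                        pair = c("contextual", "alpha"))
  r2p <- sapply(names(pf), function(nm) {
    sp <- pf[[nm]]@trainingMeta$spaces
    scoreR2(predictAndScore(pf[[nm]], subsetDesign(sim$testDesign, sp),
                            testY))
  })
  pw <- pairwisePartitions(r2p[, "pair"], r2p[, "first"], r2p[, "second"])
  expect_lt(mean(partitionValues(pw)[, "intersection"]), 0.06)

  ## planting shared variance grows the intersection monotonically
  simSh <- tinySim(seed = 43, fractions = c(0.2, 0.15, 0.1, 0.05, 0),
                   shared = 0.5, nVoxels = 16, ccHalf = 0.7, nStories = 5,
                   storyLenS = 600, nRepeats = 10)
  fitsSh <- fitNestedModels(simSh$design, simSh$responses, 50,
                            mode = "pairwise", pair = c("contextual", "alpha"))
  testYSh <- apply(repeatStack(simSh$responses), c(2, 3), mean)
  r2sh <- sapply(names(fitsSh), function(nm) {
    sp <- fitsSh[[nm]]@trainingMeta$spaces
    scoreR2(predictAndScore(fitsSh[[nm]], subsetDesign(simSh$testDesign, sp),
                            testYSh))
  })
  pwSh <- pairwisePartitions(r2sh[, "pair"], r2sh[, "first"],
                             r2sh[, "second"])
  expect_gt(mean(partitionValues(pwSh)[, "intersection"]),
            mean(partitionValues(pw)[, "intersection"]) + 0.1)
})

test_that("partition permutation test is seeded, anchored, and identity-safe", {
  sim <- tinySim(seed = 47, nVoxels = 10, ccHalf = 0.7)
  fits <- fitNestedModels(sim$design, sim$responses, 50, mode = "unique")
  testY <- apply(repeatStack(sim$responses), c(2, 3), mean)
  sig <- partitionSignificance(fits, sim$testDesign, testY, mode = "unique",
                               nPerm = 49, blockLenTr = 10, seed = 3,
                               regionLabels = regionLabels(sim$responses))
  expect_true(all(sig$p > 0 & sig$p <= 1))
  expect_true(all(sig$q >= sig$p - 1e-12))
  ## strong planted signal: the union-dominant partitions hit the add-one
  ## floor p = 1/(nPerm+1)
  expect_true(any(abs(sig$p - 1 / 50) < 1e-12))
  sig2 <- partitionSignificance(fits, sim$testDesign, testY, mode = "unique",
                                nPerm = 49, blockLenTr = 10, seed = 3,
                                regionLabels = regionLabels(sim$responses))
  expect_identical(sig, sig2)
})

test_that("region difference test finds planted shifts and respects symmetry", {
  withr::with_seed(51, {
    vals <- cbind(p1 = c(rnorm(60), rnorm(60) + 1),
                  p2 = rnorm(120))
  })
  labs <- rep(c("cerebellum", "cortex"), each = 60)
  out <- regionDifferenceTest(vals, labs, nPerm = 999, seed = 2)
  expect_lt(out$p[out$partition == "p1"], 0.01)
  expect_gt(out$p[out$partition == "p2"], 0.05)
  ## statistic is cerebellum minus cortex
  expect_equal(out$observed[1], mean(vals[1:60, 1]) - mean(vals[61:120, 1]))
  expect_error(regionDifferenceTest(vals, rep("cortex", 120), 99),
               "both regions")
})
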