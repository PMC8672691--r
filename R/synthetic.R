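#' @include features.R
NULL

#' Describe a synthetic natural-listening scenario
#'
#' Defaults mirror the experimental conditions the package's analyses are
#' designed for: 26 stories of 10-15 minutes sampled at TR = 2 s, a stimulus
#' stream at roughly conversational word rate, and the five feature spaces
#' with their standard dimensionalities (spectral 256, articulatory 22, part
#' of speech 17, word-level semantic 985, context-level semantic 768).
#' Smaller values can be passed for scaled-down simulations.
#'
#' @param nStories number of training stories.
#' @param storyLenS story duration in seconds (default 750 s, i.e. 12.5 min).
#' @param trS repetition time in seconds (default 2).
#' @param wordRateHz mean event rate of the stimulus stream (default 2).
#' @param vocabSize synthetic vocabulary size (default 1000).
#' @param dims named integer vector of feature-space dimensionalities.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
SyntheticScenario <- function(nStories = 26, storyLenS = 750, trS = 2,
                              wordRateHz = 2, vocabSize = 1000,
                              dims = c(spectral = 256L, articulatory = 22L,
                                       pos = 17L, semantic = 985L,
                                       contextual = 768L),
                              seed = 1L) {
  new("SyntheticScenario",
    nStories = as.integer(nStories), storyLenS = as.numeric(storyLenS),
    trS = as.numeric(trS), wordRateHz = as.numeric(wordRateHz),
    vocabSize = as.integer(vocabSize),
    dims = stats::setNames(as.integer(dims), names(dims)),
    seed = as.integer(seed)
  )
}

#' Generate a synthetic embedding table
#'
#' Rows are independent standard Gaussian vectors, giving approximately
#' isotropic covariance; an emulation of a word co-occurrence embedding
#' space, not a reproduction of one.
#'
#' @param vocabSize number of words (rows).
#' @param dim embedding dimensionality.
#' @param seed integer seed; the table is bit-reproducible under a fixed
#'   seed.
#' @return numeric matrix vocabSize x dim with word row names.
#' @export
genEmbeddingTable <- function(vocabSize, dim, seed) {
  stopIfNot(vocabSize >= 1, "vocabSize must be >= 1")
  stopIfNot(dim >= 1, "dim must be >= 1")
  withSeed(seed, {
    m <- matrix(rnorm(vocabSize * dim), nrow = vocabSize, ncol = dim)
    rownames(m) <- sprintf("word%05d", seq_len(vocabSize))
    m
  })
}

#' Generate per-story stimulus event streams
#'
#' Event onsets are drawn from a homogeneous Poisson process at the
#' scenario's word rate (the simplest stream with irregular spacing, which is
#' exactly the resampling problem the Lanczos stage must solve); each event
#' carries a word drawn uniformly from the vocabulary together with its
#' embedding vector.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param table embedding table from \code{\link{genEmbeddingTable}}.
#' @param nStories optionally override the scenario's story count.
#' @param spaceName stream name (default "semantic").
#' @return list of \linkS4class{EventStream}, one per story.
#' @export
genEventStream <- function(scenario, table, nStories = scenario@nStories,
                           spaceName = "semantic") {
  stopIfNot(is(scenario, "SyntheticScenario"), "scenario must be a SyntheticScenario")
  withSeed(scenario@seed, {
    lapply(seq_len(nStories), function(i) {
      onsets <- poissonOnsets(scenario@wordRateHz, scenario@storyLenS)
      ids <- if (length(onsets)) {
        sample.int(nrow(table), length(onsets), replace = TRUE)
      } else integer(0)
      EventStream(spaceName, onsets,
                  table[ids, , drop = FALSE],
                  labels = rownames(table)[ids])
    })
  })
}

## Homogeneous Poisson onsets on (0, lenS): exponential gaps.
poissonOnsets <- function(rateHz, lenS) {
  if (rateHz <= 0) return(numeric(0))
  n <- stats::rpois(1L, rateHz * lenS * 1.5) + 50L
  on <- cumsum(stats::rexp(n, rateHz))
  while (length(on) && on[length(on)] < lenS) {
    on <- c(on, on[length(on)] + cumsum(stats::rexp(n, rateHz)))
  }
  on[on < lenS]
}

#' Plant ground-truth voxel weights with controlled variance structure
#'
#' Draws random weights per feature space and scales them, per voxel, so
#' that on the supplied training design the noiseless contribution of each
#' space realizes the requested unique signal-variance fraction. Shared
#' variance is carried by a latent TR time course that the scenario builder
#' plants as a dedicated feature of every designated space (so the latent is
#' exactly in each designated space's column span); its weights live on the
#' first designated space's latent columns. The noise standard deviation is
#' solved analytically from the test-story signal variance so that the
#' split-half reliability of \code{nRepeats} repeats hits
#' \code{targetCcHalf}.
#'
#' @param design training \linkS4class{DesignMatrix}.
#' @param uniqueFractions numeric vector (one per space, recycled across
#'   voxels) or matrix (voxel x space) of unique variance fractions.
#' @param sharedFraction scalar or per-voxel fraction for the shared latent
#'   component; unique + shared must sum to 1 per voxel.
#' @param nVoxels number of voxels.
#' @param targetCcHalf intended split-half reliability in [0, 1].
#' @param nRepeats number of test-story repeats the reliability refers to.
#' @param seed integer seed.
#' @param testDesign held-out-story \linkS4class{DesignMatrix} used to
#'   compute the signal variance entering the noise calibration; defaults to
#'   the training design.
#' @param latentFeature index of the feature column carrying the latent in
#'   each designated space (default 1).
#' @param sharedSpaces names of the spaces sharing the latent (default all).
#' @return a \linkS4class{GroundTruth}.
#' @export
genGroundTruthVoxels <- function(design, uniqueFractions, sharedFraction = 0,
                                 nVoxels, targetCcHalf = 0.6, nRepeats = 10,
                                 seed = 1L, testDesign = design,
                                 latentFeature = 1L,
                                 sharedSpaces = NULL) {
  stopIfNot(is(design, "DesignMatrix"), "design must be a DesignMatrix")
  spaces <- unique(design@columnMap$space)
  if (is.null(sharedSpaces)) sharedSpaces <- spaces
  uf <- if (is.matrix(uniqueFractions)) uniqueFractions else {
    matrix(uniqueFractions, nrow = nVoxels, ncol = length(uniqueFractions),
           byrow = TRUE)
  }
  colnames(uf) <- spaces
  sf <- rep_len(sharedFraction, nVoxels)
  tot <- rowSums(uf) + sf
  stopIfNot(all(abs(tot - 1) < 1e-9),
            "unique fractions + shared fraction must sum to 1 per voxel")
  X <- design@values
  cm <- design@columnMap
  withSeed(seed, {
    weights <- list()
    for (sp in spaces) {
      cols <- which(cm$space == sp)
      isLatent <- (sp %in% sharedSpaces) & cm$feature[cols] == latentFeature
      ## unique weights avoid the latent feature so shared and unique
      ## contributions stay separable
      w <- matrix(rnorm(length(cols) * nVoxels), nrow = length(cols))
      if (any(sf > 0)) w[isLatent, ] <- 0
      contrib <- X[, cols, drop = FALSE] %*% w
      csd <- apply(contrib, 2L, stats::sd)
      csd[csd < .Machine$double.eps] <- 1
      w <- sweep(w, 2L, sqrt(uf[, sp]) / csd, "*")
      weights[[sp]] <- w
    }
    ## shared component rides on the first designated space's latent columns
    if (any(sf > 0)) {
      sp1 <- sharedSpaces[1]
      cols <- which(cm$space == sp1)
      lat <- cm$feature[cols] == latentFeature
      wsh <- matrix(0, nrow = length(cols), ncol = nVoxels)
      wsh[lat, ] <- matrix(rnorm(sum(lat) * nVoxels), nrow = sum(lat))
      contrib <- X[, cols, drop = FALSE] %*% wsh
      csd <- apply(contrib, 2L, stats::sd)
      csd[csd < .Machine$double.eps] <- 1
      wsh <- sweep(wsh, 2L, sqrt(sf) / csd, "*")
      weights[[sp1]] <- weights[[sp1]] + wsh
    }
    ## analytic noise calibration against the test-story signal variance
    Wall <- do.call(rbind, weights[spaces])
    sigTest <- testDesign@values %*% Wall
    sVar <- apply(sigTest, 2L, stats::var)
    noiseSd <- if (targetCcHalf <= 0) {
      sqrt(1e4 * pmax(sVar, 1e-12))
    } else if (targetCcHalf >= 1) {
      rep(0, nVoxels)
    } else {
      sqrt(nRepeats * sVar * (1 - targetCcHalf) / (2 * targetCcHalf))
    }
    new("GroundTruth",
      weights = weights[spaces], uniqueFractions = uf, sharedFraction = sf,
      noiseSd = noiseSd, targetCcHalf = as.numeric(targetCcHalf),
      sharedSpaces = as.character(sharedSpaces)
    )
  })
}

## Concatenate ground-truth weights in design column order.
truthWeightMatrix <- function(design, truth) {
  cm <- design@columnMap
  spaces <- unique(cm$space)
  stopIfNot(all(spaces %in% names(truth@weights)),
            "design contains spaces absent from the ground truth")
  blocks <- lapply(spaces, function(sp) truth@weights[[sp]])
  W <- do.call(rbind, blocks)
  stopIfNot(nrow(W) == ncol(design@values),
            "design column count must match concatenated delayed weights")
  W
}

#' Simulate BOLD responses from a design and ground truth
#'
#' Response = design x weights + Gaussian noise with the ground truth's
#' per-voxel standard deviation (white by default; AR(1) optionally, for
#' block-permutation calibration work). Deterministic under a fixed seed: two
#' seeds share the identical signal component and differ only in noise.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param seed integer seed for the noise.
#' @param regionLabels per-voxel labels; default splits voxels half
#'   cerebellum, half cortex.
#' @param arCoef AR(1) coefficient for temporally correlated noise
#'   (default 0 = white).
#' @return a \linkS4class{ResponseSet} (no repeat stack).
#' @export
simulateBold <- function(design, truth, seed, regionLabels = NULL,
                         arCoef = 0) {
  W <- truthWeightMatrix(design, truth)
  signal <- design@values %*% W
  nTR <- nrow(signal); nV <- ncol(signal)
  noise <- withSeed(seed, arNoise(nTR, nV, arCoef))
  y <- signal + sweep(noise, 2L, truth@noiseSd, "*")
  if (is.null(regionLabels)) {
    regionLabels <- rep(c("cerebellum", "cortex"), c(floor(nV / 2), ceiling(nV / 2)))
  }
  new("ResponseSet",
    values = y, regionLabels = regionLabels,
    storyBounds = design@storyBounds, repeats = NULL, trS = design@trS
  )
}

## Unit-variance AR(1) noise matrix (white when phi = 0).
arNoise <- function(nTR, nV, phi = 0) {
  eps <- matrix(rnorm(nTR * nV), nrow = nTR)
  if (phi == 0) return(eps)
  out <- eps * sqrt(1 - phi^2)
  out[1, ] <- eps[1, ]
  for (t in 2:nTR) out[t, ] <- phi * out[t - 1, ] + out[t, ]
  out
}

#' Generate the repeated test-story response stack
#'
#' All repeats share the identical noiseless signal; each repeat receives
#' independent noise at the ground truth's per-voxel standard deviation,
#' which was calibrated analytically so the split-half reliability across
#' repeats approximates the ground truth's target.
#'
#' @param testDesign held-out-story \linkS4class{DesignMatrix}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param nRepeats number of repeats (>= 2).
#' @param seed integer seed.
#' @param arCoef AR(1) coefficient for the noise (default 0).
#' @return array nRepeats x nTR x nVoxels.
#' @export
genRepeatSet <- function(testDesign, truth, nRepeats, seed, arCoef = 0) {
  stopIfNot(nRepeats >= 2, "need at least two repeats")
  W <- truthWeightMatrix(testDesign, truth)
  signal <- testDesign@values %*% W
  nTR <- nrow(signal); nV <- ncol(signal)
  out <- array(0, dim = c(nRepeats, nTR, nV))
  withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      noise <- arNoise(nTR, nV, arCoef)
      out[r, , ] <- signal + sweep(noise, 2L, truth@noiseSd, "*")
    }
  })
  out
}

#' Simulate a complete scenario with known ground truth
#'
#' Orchestrates the generators into the input set every downstream stage
#' needs: per-space event streams (with a latent TR time course planted as a
#' dedicated feature of designated spaces when shared variance is
#' requested), Lanczos-resampled and FIR-delayed training and test designs,
#' ground-truth weights realizing the requested variance fractions, noisy
#' training responses, and a repeat stack for the test story.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param uniqueFractions per-space unique variance fractions (vector over
#'   the scenario's spaces).
#' @param sharedFraction fraction for the shared latent component.
#' @param nVoxels number of voxels to simulate.
#' @param targetCcHalf target split-half reliability of the repeats.
#' @param nRepeats number of test-story repeats (default 10).
#' @param delaysTr FIR delays (default 1:4).
#' @param testStoryLenS test story length in seconds (defaults to one
#'   training story).
#' @param arCoef AR(1) noise coefficient (default 0, white).
#' @return list with elements \code{design}, \code{testDesign},
#'   \code{responses} (with repeat stack attached), \code{truth},
#'   \code{scenario}.
#' @export
simulateScenario <- function(scenario, uniqueFractions, sharedFraction = 0,
                             nVoxels = 50, targetCcHalf = 0.6, nRepeats = 10,
                             delaysTr = 1:4,
                             testStoryLenS = scenario@storyLenS,
                             arCoef = 0) {
  spaces <- names(scenario@dims)
  stopIfNot(length(uniqueFractions) == length(spaces),
            "need one unique fraction per feature space")
  nTRstory <- floor(scenario@storyLenS / scenario@trS)
  nTRtest <- floor(testStoryLenS / scenario@trS)

  trMats <- withSeed(scenario@seed, {
    tabs <- lapply(seq_along(spaces), function(i) {
      genEmbeddingTable(scenario@vocabSize, scenario@dims[[i]],
                        seed = scenario@seed + 1000L + i)
    })
    names(tabs) <- spaces
    allStories <- lapply(seq_len(scenario@nStories + 1L), function(st) {
      isTest <- st > scenario@nStories
      nTR <- if (isTest) nTRtest else nTRstory
      lenS <- if (isTest) testStoryLenS else scenario@storyLenS
      mats <- lapply(spaces, function(sp) {
        onsets <- poissonOnsets(scenario@wordRateHz, lenS)
        ids <- if (length(onsets)) {
          sample.int(scenario@vocabSize, length(onsets), replace = TRUE)
        } else integer(0)
        es <- EventStream(sp, onsets, tabs[[sp]][ids, , drop = FALSE],
                          labels = rownames(tabs[[sp]])[ids])
        lanczosResample(es, scenario@trS, nTR)
      })
      names(mats) <- spaces
      if (sharedFraction > 0) {
        g <- rnorm(nTR)
        for (sp in spaces) mats[[sp]][, 1L] <- g
      }
      mats
    })
    allStories
  })

  trainStories <- trMats[seq_len(scenario@nStories)]
  testStory <- trMats[[scenario@nStories + 1L]]
  design <- buildDesignMatrix(trainStories, scenario@trS, delaysTr)
  testDesign <- buildDesignMatrix(list(testStory), scenario@trS, delaysTr,
                                  scaling = design@scaling)
  truth <- genGroundTruthVoxels(
    design, uniqueFractions, sharedFraction, nVoxels,
    targetCcHalf = targetCcHalf, nRepeats = nRepeats,
    seed = scenario@seed + 17L, testDesign = testDesign
  )
  responses <- simulateBold(design, truth, seed = scenario@seed + 29L,
                            arCoef = arCoef)
  repeats <- genRepeatSet(testDesign, truth, nRepeats,
                          seed = scenario@seed + 43L, arCoef = arCoef)
  responses@repeats <- repeats
  list(design = design, testDesign = testDesign, responses = responses,
       truth = truth, scenario = scenario)
}
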