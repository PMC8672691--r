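#' @include synthetic.R preprocess.R encoding.R noise-ceiling.R varpart.R clustering.R io.R
NULL

pipelineDefaults <- function() {
  list(
    ## scenario
    nStories = 6L, storyLenS = 300, trS = 2, wordRateHz = 2,
    vocabSize = 200L,
    dims = c(spectral = 8L, articulatory = 8L, pos = 6L, semantic = 12L,
             contextual = 10L),
    nVoxels = 40L,
    uniqueFractions = c(0.05, 0.05, 0.10, 0.20, 0.30),
    sharedFraction = 0.30,
    targetCcHalf = 0.6, nRepeats = 10L,
    ## preprocessing
    detrend = TRUE, detrendWindowS = 120, nTrim = 10L,
    ## encoding
    delays = 1:4,
    lambdaGrid = 10^seq(0, 7, length.out = 15),
    nBoot = 15L, chunkLenTr = 20L, holdoutFrac = 0.2,
    ## inference
    blockLen = 10L, nPermScores = 500L, nPermPartition = 200L,
    nPermRegion = 2000L, fdrAlpha = 0.05,
    ## clustering
    topFrac = 0.25, varianceTarget = 0.80, k = NULL, kMax = 10L,
    nInit = 5L,
    seed = 1L
  )
}

#' Build and validate a pipeline configuration
#'
#' Returns the demo configuration (a scaled-down synthetic scenario that
#' exercises every stage) with any overrides applied. Unknown keys are
#' rejected by name; the configuration round-trips losslessly through JSON.
#'
#' @param ... named overrides of the default configuration.
#' @return validated configuration list (class "voxencConfig").
#' @export
pipelineConfig <- function(...) {
  cfg <- pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stopIfNot(length(unknown) == 0L,
            paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  stopIfNot(cfg$trS > 0, "trS must be > 0")
  stopIfNot(length(cfg$uniqueFractions) == length(cfg$dims),
            "one unique fraction per feature space required")
  stopIfNot(abs(sum(cfg$uniqueFractions) + cfg$sharedFraction - 1) < 1e-9,
            "unique fractions + shared fraction must sum to 1")
  stopIfNot(cfg$fdrAlpha > 0 && cfg$fdrAlpha < 1, "fdrAlpha must be in (0,1)")
  stopIfNot(cfg$topFrac > 0 && cfg$topFrac <= 1, "topFrac must be in (0,1]")
  class(cfg) <- c("voxencConfig", "list")
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path path to a .json or .yaml/.yml file of overrides.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- if (ext %in% c("yaml", "yml")) {
    stopIfNot(requireNamespace("yaml", quietly = TRUE),
              "the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(over$dims)) over$dims <- unlist(over$dims)
  do.call(pipelineConfig, over)
}

## Drop the first/last nTrim rows of each story of a design so that it stays
## aligned with trimmed responses.
trimDesignRows <- function(design, nTrim) {
  if (nTrim == 0L) return(design)
  b <- design@storyBounds
  keep <- unlist(lapply(seq_len(nrow(b)), function(i) {
    r <- storyRows(b, i)
    r[seq.int(nTrim + 1L, length(r) - nTrim)]
  }))
  lens <- storyLengths(b) - 2L * nTrim
  ends <- cumsum(lens)
  new("DesignMatrix",
    values = design@values[keep, , drop = FALSE],
    columnMap = design@columnMap,
    storyBounds = cbind(start = c(1L, head(ends, -1L) + 1L), end = ends + 1L),
    trS = design@trS, delaysTr = design@delaysTr, scaling = design@scaling
  )
}

## Per-voxel semantic weight matrix: average the fitted weights over FIR
## delays, giving one vector per voxel in the embedding dimensionality.
semanticWeightMatrix <- function(fit, space) {
  sel <- fit@columnMap$space == space
  cm <- fit@columnMap[sel, , drop = FALSE]
  w <- fit@weights[sel, , drop = FALSE]
  feats <- sort(unique(cm$feature))
  out <- matrix(0, nrow = ncol(w), ncol = length(feats))
  for (i in seq_along(feats)) {
    out[, i] <- colMeans(w[cm$feature == feats[i], , drop = FALSE])
  }
  out
}

#' Run the full encoding-model pipeline on a synthetic scenario
#'
#' Executes, in order: synthetic data generation, voxel time-series
#' conditioning (detrend, trim, standardize), ridge penalty selection and
#' model fitting per feature space and for the nested model families,
#' held-out scoring with block-permutation significance, noise-ceiling
#' correction against the repeat stack, unique and pairwise variance
#' partitioning with bias correction and permutation tests, the
#' cerebellum-vs-cortex region comparisons, and spherical k-means clustering
#' of the word-level semantic weights with the cluster-composition test.
#' Every stage derives its seed from the configuration seed, so a rerun with
#' the same configuration is bit-identical.
#'
#' @param config configuration from \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, results and a text report
#'   are written there.
#' @param verbose log stage progress (default TRUE).
#' @return list with all stage outputs (see Details in the vignette).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
  stopIfNot(inherits(config, "voxencConfig"),
            "config must come from pipelineConfig()")
  log <- function(...) if (verbose) message("[voxenc] ", sprintf(...))
  seed <- as.integer(config$seed)

  log("simulate: %d stories x %.0f s, %d voxels, seed %d",
      config$nStories, config$storyLenS, config$nVoxels, seed)
  scen <- SyntheticScenario(
    nStories = config$nStories, storyLenS = config$storyLenS,
    trS = config$trS, wordRateHz = config$wordRateHz,
    vocabSize = config$vocabSize, dims = config$dims, seed = seed
  )
  sim <- simulateScenario(
    scen, config$uniqueFractions, config$sharedFraction,
    nVoxels = config$nVoxels, targetCcHalf = config$targetCcHalf,
    nRepeats = config$nRepeats, delaysTr = config$delays
  )
  spaces <- names(config$dims)
  ctx <- spaces[length(spaces)]

  log("preprocess: detrend=%s, trim %d volumes", config$detrend, config$nTrim)
  resp <- preprocessResponses(sim$responses, windowS = config$detrendWindowS,
                              nTrim = config$nTrim, detrend = config$detrend)
  design <- trimDesignRows(sim$design, config$nTrim)
  testDesign <- trimDesignRows(sim$testDesign, config$nTrim)
  rep3 <- sim$responses@repeats
  nTrim <- config$nTrim
  keepT <- seq.int(nTrim + 1L, dim(rep3)[2] - nTrim)
  repTrim <- rep3[, keepT, , drop = FALSE]
  testY <- apply(repTrim, c(2L, 3L), mean)

  log("encoding: selecting lambda (%d bootstraps, %d grid points)",
      config$nBoot, length(config$lambdaGrid))
  sel <- selectLambdaBootstrap(design, resp, lambdaGrid = config$lambdaGrid,
                               nBoot = config$nBoot,
                               chunkLenTr = config$chunkLenTr,
                               holdoutFrac = config$holdoutFrac,
                               seed = seed + 101L)
  lambda <- sel$lambda
  log("encoding: lambda = %.4g", lambda)

  singleFits <- lapply(spaces, function(sp) {
    fitRidge(subsetDesign(design, sp), resp, lambda, meta = list(spaces = sp))
  })
  names(singleFits) <- spaces
  unionFit <- fitRidge(design, resp, lambda, meta = list(spaces = spaces))

  log("scoring: %d permutations, block %d", config$nPermScores,
      config$blockLen)
  scores <- lapply(spaces, function(sp) {
    s <- predictAndScore(singleFits[[sp]], subsetDesign(testDesign, sp), testY)
    scoreSignificance(s, singleFits[[sp]], subsetDesign(testDesign, sp), testY,
                      blockLenTr = config$blockLen,
                      nPerm = config$nPermScores, seed = seed + 211L)
  })
  names(scores) <- spaces
  unionScores <- predictAndScore(unionFit, testDesign, testY)
  unionScores <- scoreSignificance(unionScores, unionFit, testDesign, testY,
                                   blockLenTr = config$blockLen,
                                   nPerm = config$nPermScores,
                                   seed = seed + 223L)

  regionPerf <- t(vapply(c(scores, list(union = unionScores)),
                         meanRegionPerformance,
                         numeric(2), regionLabels = resp@regionLabels))

  log("noise ceiling: %d repeats", dim(repTrim)[1])
  rel <- ccHalf(repTrim)
  ceilings <- lapply(scores, function(s) ccNorm(s@r, rel))

  log("variance partitioning: unique + pairwise")
  nested <- fitNestedModels(design, resp, lambda, mode = "unique")
  r2Models <- vapply(names(nested), function(nm) {
    sp <- nested[[nm]]@trainingMeta$spaces
    predictAndScore(nested[[nm]], subsetDesign(testDesign, sp), testY)@r2Signed
  }, numeric(ncol(testY)))
  uniquePT <- uniquePartitions(
    r2Models[, "union"],
    `colnames<-`(r2Models[, paste0("drop_", spaces), drop = FALSE], spaces)
  )
  uniqueSig <- partitionSignificance(
    nested, testDesign, testY, mode = "unique",
    nPerm = config$nPermPartition, blockLenTr = config$blockLen,
    seed = seed + 307L, regionLabels = resp@regionLabels
  )
  sigMask <- unionScores@q < config$fdrAlpha
  regionTest <- if (sum(sigMask) >= 4L &&
                      length(unique(resp@regionLabels[sigMask])) == 2L) {
    regionDifferenceTest(uniquePT@partitions[sigMask, , drop = FALSE],
                         resp@regionLabels[sigMask],
                         nPerm = config$nPermRegion, seed = seed + 401L)
  } else NULL

  pairwisePT <- list()
  for (sp in setdiff(spaces, ctx)) {
    pf <- fitNestedModels(design, resp, lambda, mode = "pairwise",
                          pair = c(ctx, sp))
    r2p <- vapply(pf, function(f) {
      s <- f@trainingMeta$spaces
      predictAndScore(f, subsetDesign(testDesign, s), testY)@r2Signed
    }, numeric(ncol(testY)))
    pairwisePT[[sp]] <- pairwisePartitions(r2p[, "pair"], r2p[, "first"],
                                           r2p[, "second"],
                                           names = c(ctx, sp))
  }

  log("clustering: word-level semantic weights, top %.0f%%",
      100 * config$topFrac)
  semSpace <- if ("semantic" %in% spaces) "semantic" else spaces[max(1L, length(spaces) - 1L)]
  top <- selectTopVoxels(scores[[semSpace]], config$topFrac)
  semW <- semanticWeightMatrix(singleFits[[semSpace]], semSpace)[top, , drop = FALSE]
  cluster <- clusterSemanticWeights(
    semW, varianceTarget = config$varianceTarget, k = config$k,
    kMax = min(config$kMax, nrow(semW) - 1L), nInit = config$nInit,
    seed = seed + 503L
  )
  clusterTest <- clusterProportionTest(cluster@labels,
                                       resp@regionLabels[top],
                                       nPerm = config$nPermRegion,
                                       seed = seed + 601L)

  out <- list(
    config = config, sim = sim, responses = resp, testResponses = testY,
    lambda = lambda, lambdaCurve = sel, singleFits = singleFits,
    unionFit = unionFit, scores = scores, unionScores = unionScores,
    regionPerformance = regionPerf, ccHalf = rel, ceilings = ceilings,
    uniquePartitions = uniquePT, uniqueSignificance = uniqueSig,
    regionTest = regionTest, pairwisePartitions = pairwisePT,
    cluster = cluster, clusterTest = clusterTest, topVoxels = top
  )
  out$report <- pipelineReport(out)
  if (!is.null(outDir)) writePipelineResults(out, outDir)
  log("done")
  out
}

pipelineReport <- function(res) {
  cfg <- res$config
  spaces <- names(cfg$dims)
  fmt <- function(x) sprintf("%.6f", x)
  lines <- c(
    "voxenc pipeline report",
    sprintf("seed: %d", cfg$seed),
    sprintf("lambda: %.6g", res$lambda),
    "",
    "mean signed r2 per region:",
    sprintf("  %-12s cerebellum=%s cortex=%s",
            rownames(res$regionPerformance),
            fmt(res$regionPerformance[, "cerebellum"]),
            fmt(res$regionPerformance[, "cortex"])),
    "",
    sprintf("median ccHalf: %s", fmt(stats::median(res$ccHalf))),
    "",
    "unique partitions (mean per voxel):",
    sprintf("  %-20s %s", colnames(res$uniquePartitions@partitions),
            fmt(colMeans(res$uniquePartitions@partitions))),
    "",
    "partition significance (region means, p):",
    sprintf("  %-20s %-11s obs=%s p=%s q=%s",
            res$uniqueSignificance$partition, res$uniqueSignificance$region,
            fmt(res$uniqueSignificance$observed),
            fmt(res$uniqueSignificance$p), fmt(res$uniqueSignificance$q)),
    "",
    sprintf("clusters: k = %d (inertia elbow over 1..%d)",
            res$cluster@chosenK, length(res$cluster@inertiaCurve)),
    sprintf("  cluster %d: diff=%s p=%s q=%s", res$clusterTest$cluster,
            fmt(res$clusterTest$observed), fmt(res$clusterTest$p),
            fmt(res$clusterTest$q))
  )
  if (!is.null(res$regionTest)) {
    lines <- c(lines, "",
               "region differences (cerebellum - cortex):",
               sprintf("  %-20s diff=%s p=%s q=%s", res$regionTest$partition,
                       fmt(res$regionTest$observed), fmt(res$regionTest$p),
                       fmt(res$regionTest$q)))
  }
  lines
}

#' Write pipeline results to a plain-text container
#'
#' @param res result list from \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writePipelineResults <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeLines(res$report, p("report.txt"))
  cfg <- res$config
  cfg$dims <- as.list(cfg$dims)
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  scoreTab <- data.frame(
    voxel = seq_along(res$unionScores@r),
    region = res$responses@regionLabels,
    union_r = res$unionScores@r, union_q = res$unionScores@q
  )
  for (sp in names(res$scores)) {
    scoreTab[[paste0(sp, "_r")]] <- res$scores[[sp]]@r
    scoreTab[[paste0(sp, "_ccnorm")]] <- res$ceilings[[sp]]@ccNorm
  }
  data.table::fwrite(scoreTab, p("scores.tsv"), sep = "\t")
  writeMatrixTsv(res$uniquePartitions@partitions, p("partitions_unique.tsv"))
  data.table::fwrite(res$uniqueSignificance, p("partition_significance.tsv"),
                     sep = "\t")
  for (sp in names(res$pairwisePartitions)) {
    writeMatrixTsv(res$pairwisePartitions[[sp]]@partitions,
                   p(sprintf("partitions_pairwise_%s.tsv", sp)))
  }
  data.table::fwrite(res$clusterTest, p("cluster_test.tsv"), sep = "\t")
  writeMatrixTsv(cbind(k = as.integer(names(res$cluster@inertiaCurve)),
                       inertia = res$cluster@inertiaCurve),
                 p("inertia_curve.tsv"))
  writeMatrixTsv(cbind(voxel = res$topVoxels, cluster = res$cluster@labels),
                 p("cluster_labels.tsv"))
  if (!is.null(res$regionTest)) {
    data.table::fwrite(res$regionTest, p("region_test.tsv"), sep = "\t")
  }
  invisible(dir)
}
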