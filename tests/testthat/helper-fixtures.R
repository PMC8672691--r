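# Shared fixture builders; everything generated in code under fixed seeds.

tinyScenario <- function(seed = 5, nStories = 3, storyLenS = 120,
                         dims = c(alpha = 4L, beta = 4L, gamma = 3L,
                                  semantic = 6L, contextual = 5L)) {
  SyntheticScenario(nStories = nStories, storyLenS = storyLenS, trS = 2,
                    wordRateHz = 2, vocabSize = 50, dims = dims, seed = seed)
}

tinySim <- function(seed = 5, fractions = c(0.3, 0.2, 0.2, 0.2, 0.1),
                    shared = 0, nVoxels = 10, ccHalf = 0.6, nRepeats = 6,
                    ...) {
  simulateScenario(tinyScenario(seed = seed, ...), fractions, shared,
                   nVoxels = nVoxels, targetCcHalf = ccHalf,
                   nRepeats = nRepeats)
}

randomEventStream <- function(n = 50, dim = 3, lenS = 100, seed = 1) {
  withr::with_seed(seed, {
    onsets <- sort(runif(n, 0, lenS))
    while (any(diff(onsets) <= 0)) onsets <- sort(runif(n, 0, lenS))
    EventStream("test", onsets, matrix(rnorm(n * dim), n, dim))
  })
}

## independent SVD ridge oracle
svdRidge <- function(X, Y, lambda) {
  sv <- svd(X)
  d <- sv$d
  shrink <- d / (d^2 + lambda)
  sv$v %*% (shrink * crossprod(sv$u, Y))
}

## brute-force windowed-sinc sum, scalar arithmetic per (TR, event) pair
bruteLanczos <- function(stream, trS, nTR, nLobes = 3,
                         cutoff = 1 / (2 * trS)) {
  vec <- eventVectors(stream)
  on <- stream@onsets
  out <- matrix(0, nTR, ncol(vec))
  for (k in seq_len(nTR)) {
    tk <- (k - 0.5) * trS
    for (e in seq_along(on)) {
      x <- cutoff * (tk - on[e])
      w <- if (x == 0) 1 else if (abs(x) >= nLobes) 0 else
        nLobes * sin(pi * x) * sin(pi * x / nLobes) / (pi^2 * x^2)
      out[k, ] <- out[k, ] + w * vec[e, ]
    }
  }
  out
}

## brute-force BH step-up from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q)[order(o)]
}

## adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}

## coarse-to-fine grid search for the minimum-norm feasible bias vector
gridMinNorm <- function(A, cvec, span = NULL, levels = 5, nGrid = 21) {
  d <- ncol(A)
  if (is.null(span)) span <- max(1, 2 * max(abs(cvec)))
  center <- rep(0, d)
  best <- NULL; bestNorm <- Inf
  for (lv in seq_len(levels)) {
    grids <- lapply(seq_len(d), function(j) {
      seq(center[j] - span, center[j] + span, length.out = nGrid)
    })
    pts <- as.matrix(expand.grid(grids))
    feas <- pts %*% t(A)
    ok <- apply(feas, 1L, function(r) all(r >= cvec - 1e-9))
    if (any(ok)) {
      nrm <- rowSums(pts^2)
      nrm[!ok] <- Inf
      j <- which.min(nrm)
      if (nrm[j] < bestNorm) { best <- pts[j, ]; bestNorm <- nrm[j] }
      center <- pts[j, ]
    }
    span <- 2 * span / (nGrid - 1)
  }
  best
}
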