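test_that("Lanczos resampling matches the brute-force windowed-sinc sum", {
  stream <- randomEventStream(n = 60, dim = 3, lenS = 80, seed = 2)
  got <- lanczosResample(stream, trS = 2, nTR = 40)
  expect_equal(got, bruteLanczos(stream, 2, 40), tolerance = 1e-12)

  ## linearity: scaling events scales output
  scaled <- EventStream("test", stream@onsets, eventVectors(stream) * 3)
  expect_equal(lanczosResample(scaled, 2, 40), 3 * got, tolerance = 1e-12)

  ## dense constant stream: interior samples constant
  dense <- EventStream("c", seq(0.05, 60, by = 0.1),
                       matrix(1, nrow = 600, ncol = 1))
  out <- lanczosResample(dense, 2, 30)
  interior <- out[5:25, 1]
  ## a 3-lobe windowed sinc reproduces constants only to ~1% ripple
  expect_lt(diff(range(interior)), 0.02 * abs(mean(interior)))

  expect_error(lanczosResample(stream, 2, 0), "nTR")
})

test_that("resampling commutes with integer-TR time shifts in the interior", {
  stream <- randomEventStream(n = 80, dim = 2, lenS = 100, seed = 4)
  base <- lanczosResample(stream, trS = 2, nTR = 60)
  shifted <- EventStream("test", stream@onsets + 2 * 3, eventVectors(stream))
  out <- lanczosResample(shifted, trS = 2, nTR = 60)
  ## shifting events 3 TRs later shifts the samples 3 TRs later
  expect_equal(out[10:55, ], base[7:52, ], tolerance = 1e-10)
})

test_that("design matrix standardizes before delaying and respects stories", {
  sim <- tinySim(seed = 3)
  X <- designValues(sim$design)
  cm <- columnMap(sim$design)
  b <- storyBounds(sim$design)
  dims <- table(cm$space) / length(unique(cm$delay))

  ## column count = sum dims x 4 delays
  expect_equal(ncol(X), as.integer(sum(dims) * 4))

  ## reconstruct each undelayed standardized column from the delay-1 copy:
  ## it must have mean 0, var 1 (population) on the training set
  for (sp in unique(cm$space)) {
    sc <- sim$design@scaling[[sp]]
    expect_false(any(sc$constant))
  }
  ## check via an undelayed rebuild: delay-1 column shifted back by 1
  col <- which(cm$space == "alpha" & cm$feature == 1 & cm$delay == 1)
  und <- numeric(0)
  for (i in seq_len(nrow(b))) {
    rows <- seq.int(b[i, 1], b[i, 2] - 1L)
    und <- c(und, X[rows[-1], col])  # drop the zero-padded first row
  }
  ## nearly the full standardized column: mean ~ 0, var ~ 1
  expect_lt(abs(mean(und)), 0.05)
  expect_lt(abs(var(und) - 1), 0.05)

  ## impulse response: the whole design equals a hand-built oracle
  ## (z-score the concatenated column, then shift within stories with
  ## zero padding), and the impulse lands at t+1..t+4 only
  raw <- c(rep(0, 30), rep(0, 9), 1, rep(0, 20))
  perStory <- list(list(a = matrix(raw[1:30], 30, 1)),
                   list(a = matrix(raw[31:60], 30, 1)))
  d <- buildDesignMatrix(perStory, trS = 2)
  vals <- designValues(d)
  z <- (raw - mean(raw)) / sd(raw)
  expected <- sapply(1:4, function(dd) {
    c(c(rep(0, dd), z[1:(30 - dd)]), c(rep(0, dd), z[31:(60 - dd)]))
  })
  expect_equal(vals, expected, ignore_attr = TRUE, tolerance = 1e-12)
  ## the impulse value appears only at rows 30 + 10 + delay
  for (dd in 1:4) {
    expect_equal(which(vals[, dd] == max(z)), 40L + dd)
  }
})

test_that("delays never leak across story boundaries", {
  ## impulse at the END of story 1 must not bleed into story 2
  raw <- c(rep(0, 19), 1, rep(0, 20))
  perStory <- list(list(a = matrix(raw[1:20], 20, 1)),
                   list(a = matrix(raw[21:40], 20, 1)))
  d <- buildDesignMatrix(perStory, trS = 2, delaysTr = 1:4)
  vals <- designValues(d)
  z0 <- (0 - mean(raw)) / sd(raw)  # baseline of a z-scored zero
  ## story 2 contains only padding zeros and baseline values -- no impulse
  expect_true(all(vals[21:40, ] %in% c(0, z0)))
  expect_equal(max(vals[21:40, ]), 0)  # impulse (positive) never appears
})

test_that("held-out designs reuse training scaling without leakage", {
  sim <- tinySim(seed = 6)
  tr <- sim$design
  te <- sim$testDesign
  for (sp in names(tr@scaling)) {
    expect_identical(tr@scaling[[sp]]$center, te@scaling[[sp]]$center)
    expect_identical(tr@scaling[[sp]]$scale, te@scaling[[sp]]$scale)
  }
  ## design construction is independent of story processing order:
  ## a permutation of stories yields the same per-story blocks
  perStory <- withr::with_seed(9, lapply(1:3, function(i) {
    list(a = matrix(rnorm(40), 20, 2), b = matrix(rnorm(20), 20, 1))
  }))
  d1 <- buildDesignMatrix(perStory, trS = 2)
  d2 <- buildDesignMatrix(perStory[c(2, 3, 1)], trS = 2)
  ## story 2's block in d1 equals story 2's block (now first) in d2
  expect_equal(designValues(d1)[21:40, ], designValues(d2)[1:20, ],
               tolerance = 1e-12)
})

test_that("articulatory encoding is a binary table lookup with zero OOV", {
  tab <- articulatoryTable()
  expect_equal(dim(tab), c(39L, 22L))
  expect_true(all(tab %in% c(0, 1)))

  stream <- EventStream("phonemes", c(0.1, 0.5, 0.9),
                        matrix(numeric(0), 3, 0),
                        labels = c("AA", "ZZZ", "sh"))
  expect_message(enc <- encodeArticulations(stream), "zero-coded")
  v <- eventVectors(enc)
  expect_equal(ncol(v), 22L)
  expect_true(all(v %in% c(0, 1)))
  expect_equal(v[1, ], tab["AA", ], ignore_attr = TRUE)
  expect_equal(v[2, ], rep(0, 22), ignore_attr = TRUE)  # unknown phoneme
  expect_equal(v[3, ], tab["SH", ], ignore_attr = TRUE) # case-folded
})

test_that("POS encoding is strict one-hot over the 17-tag inventory", {
  inv <- posInventory()
  expect_length(inv, 17L)
  stream <- EventStream("words", c(0.2, 0.7, 1.4), matrix(numeric(0), 3, 0),
                        labels = c("NOUN", "VERB", "DET"))
  enc <- encodePos(stream)
  v <- eventVectors(enc)
  expect_equal(rowSums(v), rep(1, 3))
  expect_equal(inv[apply(v, 1, which.max)], c("NOUN", "VERB", "DET"))
  bad <- EventStream("words", 0.5, matrix(numeric(0), 1, 0), labels = "BLORP")
  expect_error(encodePos(bad), "BLORP")
})

test_that("embedding lookup returns table rows and zero for OOV words", {
  tab <- genEmbeddingTable(20, 6, seed = 3)
  stream <- EventStream("words", c(0.1, 0.4), matrix(numeric(0), 2, 0),
                        labels = c(rownames(tab)[5], "nonesuch"))
  enc <- lookupEmbeddings(stream, tab)
  expect_equal(eventVectors(enc)[1, ], tab[5, ], ignore_attr = TRUE)
  expect_equal(eventVectors(enc)[2, ], rep(0, 6), ignore_attr = TRUE)
  empty <- lookupEmbeddings(EventStream("w", numeric(0),
                                        matrix(numeric(0), 0, 0)), tab)
  expect_equal(nEvents(empty), 0L)
  expect_equal(featureDim(empty), 6L)
})

test_that("mel spectrogram localizes pure tones and floors silence", {
  sr <- 16000
  ## digital silence: all bands at the floor
  sil <- melSpectrogram(numeric(sr), sr, nBands = 32)
  expect_true(all(eventVectors(sil) == 1e-12))

  ## 1 kHz tone: peak band's center frequency contains 1 kHz
  t <- seq(0, 1, length.out = sr)
  tone <- sin(2 * pi * 1000 * t)
  ms <- melSpectrogram(tone, sr, nBands = 32)
  centers <- attr(eventVectors(ms), "centersHz")
  meanSpec <- colMeans(eventVectors(ms))
  peak <- which.max(meanSpec)
  ## the band containing 1 kHz (by nearest center) must be the peak +- 1
  expect_lt(abs(peak - which.min(abs(centers - 1000))), 2)

  ## default config yields 256 bands
  def <- melSpectrogram(tone[1:8000], sr)
  expect_equal(featureDim(def), 256L)

  expect_error(melSpectrogram(tone, 4000), "Nyquist")
})
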