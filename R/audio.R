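#' @include features.R
NULL

hz2mel <- function(f) 2595 * log10(1 + f / 700)
mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

## Triangular mel filterbank on FFT bin frequencies (HTK-style mel scale).
melFilterbank <- function(nBands, fLoHz, fHiHz, binFreqs) {
  pts <- mel2hz(seq(hz2mel(fLoHz), hz2mel(fHiHz), length.out = nBands + 2L))
  fb <- matrix(0, nrow = nBands, ncol = length(binFreqs))
  for (b in seq_len(nBands)) {
    lo <- pts[b]; ctr <- pts[b + 1L]; hi <- pts[b + 2L]
    up <- binFreqs >= lo & binFreqs <= ctr
    dn <- binFreqs > ctr & binFreqs <= hi
    if (ctr > lo) fb[b, up] <- (binFreqs[up] - lo) / (ctr - lo)
    if (hi > ctr) fb[b, dn] <- (hi - binFreqs[dn]) / (hi - ctr)
  }
  attr(fb, "centers") <- pts[2:(nBands + 1L)]
  fb
}

#' Mel-band spectrogram of an audio waveform
#'
#' Short-time Fourier transform (Hamming window) followed by a triangular
#' mel filterbank spanning roughly 0 Hz to 8 kHz with 256 bands, matching the
#' spectral feature space of the encoding models. Frames are dense relative
#' to the TR (10 ms hop, 25 ms window by default) because band identity, not
#' frame timing, is what the downstream Lanczos resampling consumes. Band
#' energies are floored at \code{floorValue} so digital silence yields a
#' constant floor-level frame.
#'
#' @param waveform numeric vector of audio samples.
#' @param sampleRate sampling rate in Hz; must be at least 2 * fHiHz.
#' @param nBands number of mel bands (default 256).
#' @param fLoHz,fHiHz filterbank frequency range (defaults 0 and 8000 Hz).
#' @param frameHopS hop between frames in seconds (default 0.010).
#' @param frameLenS analysis window length in seconds (default 0.025).
#' @param floorValue energy floor (default 1e-12).
#' @return an \linkS4class{EventStream} named "spectral", one event per
#'   frame; vector columns are non-negative mel band energies. The filterbank
#'   center frequencies are attached as the stream's column names attribute
#'   via \code{attr(eventVectors(x), "centersHz")}.
#' @export
melSpectrogram <- function(waveform, sampleRate, nBands = 256,
                           fLoHz = 0, fHiHz = 8000,
                           frameHopS = 0.010, frameLenS = 0.025,
                           floorValue = 1e-12) {
  stopIfNot(sampleRate >= 2 * fHiHz,
            "sampleRate must be at least twice fHiHz (Nyquist)")
  stopIfNot(nBands >= 1, "nBands must be >= 1")
  win <- max(4L, round(frameLenS * sampleRate))
  hop <- max(1L, round(frameHopS * sampleRate))
  stopIfNot(length(waveform) >= win, "waveform shorter than one frame")
  nfft <- 2^ceiling(log2(win))
  starts <- seq.int(1L, length(waveform) - win + 1L, by = hop)
  frameIdx <- outer(seq_len(win) - 1L, starts, "+")
  frames <- matrix(waveform[frameIdx], nrow = win)
  frames <- frames * as.numeric(signal::hamming(win))
  padded <- rbind(frames, matrix(0, nrow = nfft - win, ncol = ncol(frames)))
  spec <- stats::mvfft(padded)
  nBins <- nfft %/% 2L + 1L
  power <- Mod(spec[seq_len(nBins), , drop = FALSE])^2
  binFreqs <- (seq_len(nBins) - 1L) * sampleRate / nfft
  fb <- melFilterbank(nBands, fLoHz, fHiHz, binFreqs)
  energies <- t(fb %*% power)
  energies <- pmax(energies, floorValue)
  onsets <- (starts - 1L + win / 2) / sampleRate
  out <- EventStream("spectral", onsets, energies,
                     durations = rep(win / sampleRate, length(onsets)))
  attr(out@vectors, "centersHz") <- attr(fb, "centers")
  out
}

#' Read a PCM WAV file
#'
#' Minimal reader for uncompressed 8- or 16-bit PCM RIFF/WAVE files. Channels
#' are averaged to mono and samples scaled to [-1, 1].
#'
#' @param path path to a .wav file.
#' @return list with \code{samples} (numeric vector) and \code{sampleRate}.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  stopIfNot(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  stopIfNot(identical(wave, "WAVE"), "not a WAVE file")
  fmt <- NULL; dataRaw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  stopIfNot(!is.null(fmt) && !is.null(dataRaw), "missing fmt or data chunk")
  u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
  audioFormat <- u16(fmt, 1L)
  nChannels <- u16(fmt, 3L)
  sampleRate <- u16(fmt, 5L) + 65536L * u16(fmt, 7L)
  bits <- u16(fmt, 15L)
  stopIfNot(audioFormat == 1L, "only uncompressed PCM WAV is supported")
  stopIfNot(bits %in% c(8L, 16L), "only 8- or 16-bit PCM is supported")
  if (bits == 16L) {
    vals <- readBin(dataRaw, "integer", n = length(dataRaw) %/% 2L,
                    size = 2L, signed = TRUE, endian = "little") / 32768
  } else {
    vals <- (as.integer(dataRaw) - 128L) / 128
  }
  if (nChannels > 1L) {
    n <- length(vals) %/% nChannels
    vals <- rowMeans(matrix(vals[seq_len(n * nChannels)],
                            ncol = nChannels, byrow = TRUE))
  }
  list(samples = vals, sampleRate = sampleRate)
}
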