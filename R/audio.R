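#' Synthesize audio from a stimulus descriptor
#'
#' Renders each frequency track as a linear chirp at its relative amplitude
#' and sums them. Used for round-trip validation of band limits and for
#' exporting listenable stimuli; the neural simulator works from the tracks
#' directly, not from audio.
#'
#' @param stim A [stimulus_descriptor()].
#' @param fs Sample rate in Hz (default 500 kHz, sufficient for content up
#'   to 100 kHz with headroom).
#' @return Numeric waveform vector, peak-normalized to 0.9.
#' @export
synthesize_stimulus <- function(stim, fs = 500e3) {
  n <- max(1L, round(stim$duration / 1000 * fs))
  wave <- numeric(n)
  # a linear chirp's PSD scales as amp^2 / sweep rate, so track amplitudes
  # are rate-compensated to make each track's spectral density sit at its
  # nominal level_rel_peak relative to the others
  rates <- vapply(stim$tracks, function(tr) {
    max(1e4, abs(tr$f_end - tr$f_start) * 1000 /
          ((tr$t_end - tr$t_start) / 1000))
  }, 0)
  rate_comp <- sqrt(rates / max(rates))
  for (k in seq_along(stim$tracks)) {
    tr <- stim$tracks[[k]]
    i0 <- floor(tr$t_start / 1000 * fs) + 1L
    i1 <- min(n, ceiling(tr$t_end / 1000 * fs))
    if (i1 < i0) next
    t <- (seq.int(i0, i1) - i0) / fs                       # s from track start
    dur_s <- (tr$t_end - tr$t_start) / 1000
    f0 <- tr$f_start * 1000
    f1 <- tr$f_end * 1000
    sweep_rate <- (f1 - f0) / dur_s                        # Hz/s
    phase <- 2 * pi * (f0 * t + 0.5 * sweep_rate * t^2)
    amp <- 10^(tr$level_rel_peak / 20) * rate_comp[k]
    wave[i0:i1] <- wave[i0:i1] + amp * sin(phase)
  }
  if (max(abs(wave)) > 0) wave <- 0.9 * wave / max(abs(wave))
  wave
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the waveform is split into
#' Hann-windowed segments with 50% overlap and the squared FFT magnitudes
#' are averaged. Only relative levels are used downstream, so the PSD is
#' returned unnormalized.
#'
#' @param wave Numeric waveform.
#' @param fs Sample rate (Hz).
#' @param nfft Segment length in samples.
#' @return Tibble with columns `freq_khz` and `power`.
#' @export
welch_psd <- function(wave, fs, nfft = 1024L) {
  n <- length(wave)
  if (n < nfft) nfft <- 2^floor(log2(n))
  if (nfft < 8) stop("waveform too short for spectral analysis")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  step <- nfft %/% 2L
  starts <- seq.int(1L, n - nfft + 1L, by = step)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- wave[s:(s + nfft - 1L)] * win
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(nfft %/% 2L + 1L)]
  }
  tibble::tibble(
    freq_khz = (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft / 1000,
    power = acc / length(starts)
  )
}

#' Measure spectral band limits of a waveform
#'
#' Finds the lowest and highest frequency at which the Welch power spectrum
#' lies within `|rel_db|` dB of its peak -- the measurement behind the
#' tabulated -20 / -30 dB bandwidths of the vocal stimuli.
#'
#' @param wave Numeric waveform (or a [stimulus_descriptor()], which is
#'   synthesized first).
#' @param fs Sample rate (Hz); must be at least twice the highest analysis
#'   frequency of interest.
#' @param rel_db Threshold relative to the spectral peak, in dB; must be
#'   negative (e.g. -30).
#' @param nfft Welch segment length.
#' @return Named numeric `c(lo, hi)` in kHz.
#' @export
measure_band_limits <- function(wave, fs = 500e3, rel_db = -30,
                                nfft = 1024L) {
  if (inherits(wave, "stimulus_descriptor")) {
    wave <- synthesize_stimulus(wave, fs = fs)
  }
  if (!is.numeric(rel_db) || rel_db >= 0) {
    stop("rel_db must be negative (dB below spectral peak)")
  }
  if (length(wave) == 0L || all(wave == 0)) stop("no signal")
  psd <- welch_psd(wave, fs, nfft)
  pmax_ <- max(psd$power)
  if (pmax_ <= 0) stop("no signal")
  keep <- 10 * log10(psd$power / pmax_) >= rel_db
  f <- psd$freq_khz[keep]
  c(lo = min(f), hi = max(f))
}

#' Read a RIFF WAV file
#'
#' Minimal reader for uncompressed PCM (8/16/32-bit integer) and IEEE
#' float (32/64-bit) mono or multichannel WAV, up to 500 kHz sample rates.
#' Samples are returned as floats in \[-1, 1\]; multichannel files are
#' averaged to mono unless `channels = "all"`.
#'
#' @param path File path.
#' @param channels `"mono"` (average) or `"all"` (matrix, one column per
#'   channel).
#' @return List with `wave` and `fs` (Hz).
#' @export
read_wav <- function(path, channels = c("mono", "all")) {
  channels <- match.arg(channels)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path)
  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    (readBin(data_raw, "integer", n, 1, signed = FALSE,
             endian = "little") - 128) / 128
  } else {
    readBin(data_raw, "integer", n, bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$n_channels > 1L) {
    m <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
    x <- if (channels == "mono") rowMeans(m) else m
  }
  list(wave = x, fs = fmt$fs)
}

#' Write a RIFF WAV file
#'
#' Writes mono 16-bit PCM or 32-bit IEEE float WAV.
#'
#' @param wave Numeric samples in \[-1, 1\] (clipped otherwise).
#' @param path Output path.
#' @param fs Sample rate (Hz).
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  wave <- pmin(1, pmax(-1, wave))
  bytes <- bits %/% 8L
  data_sz <- length(wave) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_int(36L + data_sz, 4)
  writeChar("WAVEfmt ", con, eos = NULL)
  w_int(16L, 4)
  w_int(if (bits == 32L) 3L else 1L, 2)        # format: float or PCM
  w_int(1L, 2)                                 # mono
  w_int(fs, 4)
  w_int(fs * bytes, 4)                         # byte rate
  w_int(bytes, 2)                              # block align
  w_int(bits, 2)
  writeChar("data", con, eos = NULL)
  w_int(data_sz, 4)
  if (bits == 32L) {
    writeBin(wave, con, size = 4, endian = "little")
  } else {
    w_int(round(wave * 32767), 2)
  }
  invisible(path)
}
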