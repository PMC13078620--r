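#' Uniformly sampled series
#'
#' @param values Nonempty numeric vector.
#' @param rate Sampling rate, samples per second (positive). Video-derived
#'   flash counts run at 29.97 frames/s; audio at the file's rate.
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(values, rate) {
  if (length(values) == 0L) stop("series must be nonempty")
  if (!(is.numeric(rate) && length(rate) == 1L && rate > 0)) {
    stop("rate must be a positive scalar")
  }
  structure(list(values = as.numeric(values), rate = rate),
            class = "sampled_series")
}

#' Preprocess a flash-count series
#'
#' Savitzky-Golay smoothing (polynomial order 2, frame length 9) followed
#' by mean subtraction; the sampling rate is unchanged. This is the chain
#' applied to per-frame summed flash counts before the tempo spectrogram.
#'
#' @param series A [sampled_series()] of at least 9 samples.
#' @param order Polynomial order (default 2).
#' @param frame Filter frame length, odd (default 9).
#' @return Preprocessed [sampled_series()].
#' @export
preprocess_flash_counts <- function(series, order = 2, frame = 9) {
  stopifnot(inherits(series, "sampled_series"))
  if (length(series$values) < frame) {
    stop("series shorter than the filter frame")
  }
  sm <- signal::sgolayfilt(series$values, p = order, n = frame)
  sampled_series(sm - mean(sm), series$rate)
}

# Analytic signal by the standard FFT construction: double the positive-
# frequency half, zero the negative half, inverse transform.
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase Butterworth highpass
#'
#' 4th-order Butterworth highpass applied forward-backward
#' (`signal::filtfilt`), so the filter is zero-phase.
#'
#' @param series A [sampled_series()]; rate must exceed `2 * cutoff`.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order (default 4).
#' @return Filtered [sampled_series()].
#' @export
highpass_series <- function(series, cutoff = 5000, order = 4) {
  stopifnot(inherits(series, "sampled_series"))
  if (series$rate <= 2 * cutoff) {
    stop("sampling rate too low for the highpass cutoff")
  }
  bf <- signal::butter(order, cutoff / (series$rate / 2), type = "high")
  sampled_series(signal::filtfilt(bf, series$values), series$rate)
}

#' Preprocess chirp-like audio to a tempo-carrying envelope
#'
#' Zero-phase 4th-order Butterworth highpass (cutoff 5 kHz), magnitude of
#' the analytic (Hilbert) signal, sliding-window peak envelope over
#' `env_window` samples (3,000 samples = 68 ms at 44.1 kHz), then mean
#' subtraction. The sampling rate is unchanged; downsample afterwards with
#' [downsample_series()] before the tempo spectrogram.
#'
#' @param series A [sampled_series()]; the rate must exceed twice the
#'   cutoff and the length must exceed the envelope window.
#' @param cutoff Highpass cutoff, Hz (default 5000).
#' @param env_window Peak-envelope window, samples (default 3000).
#' @return Preprocessed [sampled_series()] at the original rate.
#' @export
preprocess_audio <- function(series, cutoff = 5000, env_window = 3000) {
  stopifnot(inherits(series, "sampled_series"))
  if (series$rate <= 2 * cutoff) {
    stop("sampling rate too low for the highpass cutoff")
  }
  if (length(series$values) <= env_window) {
    stop("series not longer than the envelope window")
  }
  hp <- highpass_series(series, cutoff)$values
  env <- Mod(.analytic_signal(hp))
  peak <- .running_max(env, as.integer(env_window))
  sampled_series(peak - mean(peak), series$rate)
}

#' Downsample a series by block averaging
#'
#' Reduces the rate to at most `target_rate` by averaging consecutive
#' blocks of samples (adequate anti-aliasing for the slowly varying
#' envelopes this package extracts; the tempo band of interest sits far
#' below the reduced Nyquist frequency).
#'
#' @param series A [sampled_series()].
#' @param target_rate Desired maximum output rate, samples/s (default 200).
#' @return A [sampled_series()] at `rate / ceiling(rate / target_rate)`.
#' @export
downsample_series <- function(series, target_rate = 200) {
  stopifnot(inherits(series, "sampled_series"))
  q <- ceiling(series$rate / target_rate)
  if (q <= 1) return(series)
  n <- floor(length(series$values) / q) * q
  blocks <- matrix(series$values[seq_len(n)], nrow = q)
  sampled_series(colMeans(blocks), series$rate / q)
}

#' Short-time Fourier spectrogram
#'
#' One-sided short-time Fourier transform with Hann windows and 50%
#' overlap; power is reported in dB. The frequency resolution is
#' `rate / window_samples`.
#'
#' @param series A [sampled_series()] at least one window long.
#' @param window_samples Window length in samples (default 100, i.e.
#'   3.33 s at the 29.97 frames/s video rate).
#' @return An object of class `spectrogram` with fields `times` (s,
#'   window centres), `freqs` (Hz, ascending, `window/2 + 1` bins), and
#'   `power` (time x freq, dB).
#' @export
spectrogram <- function(series, window_samples = 100) {
  stopifnot(inherits(series, "sampled_series"))
  x <- series$values
  n <- length(x)
  w <- as.integer(window_samples)
  if (w > n) stop("window longer than the series")
  if (w < 4) stop("window too short")
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, n - w + 1L, by = hop)
  win <- signal::hanning(w)
  n_freq <- w %/% 2L + 1L
  power <- matrix(0, nrow = length(starts), ncol = n_freq)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + w - 1L)] * win
    X <- stats::fft(seg)[seq_len(n_freq)]
    power[k, ] <- Mod(X)^2
  }
  freqs <- (seq_len(n_freq) - 1L) * series$rate / w
  times <- (starts - 1L + (w - 1) / 2) / series$rate
  structure(list(times = times, freqs = freqs,
                 power = 10 * log10(pmax(power, .Machine$double.xmin))),
            class = "spectrogram")
}

#' Dominant tempo of a spectrogram
#'
#' Frequency of the maximal time-averaged power inside a band. Averaging
#' is done on the linear power scale.
#'
#' @param spec A [spectrogram()].
#' @param band Two-element frequency band in Hz (default `c(0.25, 10)`,
#'   bracketing the communication-tempo range).
#' @return Dominant frequency, Hz.
#' @export
dominant_tempo <- function(spec, band = c(0.25, 10)) {
  stopifnot(inherits(spec, "spectrogram"), length(band) == 2L)
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(sel) == 0L) stop("band does not intersect the frequency axis")
  avg <- colMeans(10^(spec$power[, sel, drop = FALSE] / 10))
  spec$freqs[sel[which.max(avg)]]
}

#' Dominant tempo of a flash-count series
#'
#' Full chain: Savitzky-Golay smoothing + mean removal, spectrogram,
#' band-limited dominant frequency.
#'
#' @param series A [sampled_series()] of per-frame flash counts.
#' @param window_samples Spectrogram window (default 100 samples).
#' @param band Search band, Hz.
#' @return Dominant tempo, Hz.
#' @export
tempo_from_counts <- function(series, window_samples = 100,
                              band = c(0.25, 10)) {
  dominant_tempo(spectrogram(preprocess_flash_counts(series),
                             window_samples), band)
}

#' Dominant tempo of chirp-like audio
#'
#' Full chain: highpass + Hilbert peak envelope + mean removal,
#' block-average downsampling to about 200 samples/s, spectrogram,
#' band-limited dominant frequency.
#'
#' @param series Audio as a [sampled_series()].
#' @param window_s Spectrogram window length in seconds at the downsampled
#'   rate (default 5).
#' @param band Search band, Hz.
#' @param target_rate Downsampled rate ceiling, samples/s.
#' @inheritParams preprocess_audio
#' @return Dominant tempo, Hz.
#' @export
tempo_from_audio <- function(series, cutoff = 5000, env_window = 3000,
                             window_s = 5, band = c(0.25, 10),
                             target_rate = 200) {
  env <- downsample_series(preprocess_audio(series, cutoff, env_window),
                           target_rate)
  dominant_tempo(spectrogram(env, round(window_s * env$rate)), band)
}

#' Export a spectrogram
#'
#' Writes the power grid as CSV and the axes as JSON next to it.
#'
#' @param spec A [spectrogram()].
#' @param path Base path; `.csv` and `.json` files are written.
#' @export
write_spectrogram <- function(spec, path) {
  stopifnot(inherits(spec, "spectrogram"))
  utils::write.csv(spec$power, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(times = spec$times, freqs = spec$freqs),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("<sampled_series> %d samples at %.4g Hz (%.3g s)\n",
              length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, df = %.4g Hz\n",
              nrow(x$power), ncol(x$power), x$freqs[2] - x$freqs[1]))
  invisible(x)
}
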