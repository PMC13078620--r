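# Seeded generators for every input the analysis modules consume:
# isochronous event trains, log-normal tempo samples, firefly-like
# flash-count series, and cricket-like amplitude-modulated audio.

#' Generate an isochronous event train with controllable jitter
#'
#' Inter-onset intervals are drawn i.i.d.
#' `Normal(1/tempo, (jitter_cv/tempo)^2)`, truncated to positive values;
#' onsets start at 0. `jitter_cv = 0` gives an exact metronome.
#'
#' @param tempo Event rate, Hz (positive).
#' @param n_events Number of onsets (>= 2).
#' @param jitter_cv Coefficient of variation of the intervals, in
#'   `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Strictly increasing vector of onset times, seconds.
#' @export
generate_event_train <- function(tempo, n_events, jitter_cv = 0,
                                 seed = NULL) {
  if (tempo <= 0) stop("tempo must be positive")
  if (n_events < 2) stop("need at least two events")
  if (jitter_cv < 0 || jitter_cv >= 1) stop("jitter_cv must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  mu <- 1 / tempo
  iois <- stats::rnorm(n_events - 1, mu, jitter_cv * mu)
  while (any(iois <= 0)) {
    bad <- iois <= 0
    iois[bad] <- stats::rnorm(sum(bad), mu, jitter_cv * mu)
  }
  c(0, cumsum(iois))
}

#' Sample tempos from the fitted log-normal distribution
#'
#' Draws `exp(Normal(mu_ln, sigma_ln^2))`; the defaults are the fitted
#' parameters of the cross-species tempo distribution (median
#' `exp(1.1) = 3.0 Hz`).
#'
#' @param n Number of draws (>= 1).
#' @param mu_ln Log-scale mean (default 1.1).
#' @param sigma_ln Log-scale standard deviation (default 0.90).
#' @param seed Optional integer seed.
#' @return Vector of positive tempos, Hz.
#' @export
sample_tempos <- function(n, mu_ln = 1.1, sigma_ln = 0.90, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  exp(stats::rnorm(n, mu_ln, sigma_ln))
}

#' Synthesise a group flash-count series
#'
#' Emulates per-frame summed flash counts of a group of periodically
#' flashing individuals sharing one tempo: each individual gets a random
#' phase offset, each flash lights up `flash_frames` consecutive frames,
#' counts are summed across individuals, Gaussian noise is added and the
#' result clipped at zero.
#'
#' @param tempo Group flash tempo, Hz.
#' @param fps Frame rate (default 29.97, the video standard).
#' @param duration Length in seconds; must cover at least two flash
#'   periods.
#' @param n_individuals Number of flashers (default 21).
#' @param noise_sd Per-frame Gaussian noise standard deviation.
#' @param flash_frames Frames lit per flash (default 2, about 67 ms).
#' @param seed Optional integer seed.
#' @return A [sampled_series()] of counts at `fps`.
#' @export
synth_flash_series <- function(tempo, fps = 29.97, duration = 60,
                               n_individuals = 21, noise_sd = 0.2,
                               flash_frames = 2, seed = NULL) {
  if (duration * fps < 2 * fps / tempo) {
    stop("duration must cover at least two flash periods")
  }
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(duration * fps)
  counts <- numeric(n_frames)
  if (n_individuals > 0) {
    offsets <- stats::runif(n_individuals, 0, 1 / tempo)
    for (ind in seq_len(n_individuals)) {
      t_flash <- seq(offsets[ind], duration, by = 1 / tempo)
      frames <- floor(t_flash * fps) + 1L
      for (d in seq_len(flash_frames) - 1L) {
        f <- frames + d
        f <- f[f >= 1L & f <= n_frames]
        counts[f] <- counts[f] + 1
      }
    }
  }
  if (noise_sd > 0) counts <- counts + stats::rnorm(n_frames, 0, noise_sd)
  sampled_series(pmax(counts, 0), fps)
}

#' Synthesise cricket-like chirp audio
#'
#' A high-frequency carrier gated by a periodic on/off envelope at the
#' chirp tempo with the given duty cycle, plus low-level broadband noise.
#'
#' @param tempo Chirp repetition rate, Hz.
#' @param carrier Carrier tone frequency, Hz (default 8000; must be below
#'   the Nyquist frequency).
#' @param rate Sampling rate, samples/s (default 44100).
#' @param duration Length in seconds.
#' @param duty On fraction of each chirp period, in `(0, 1]`
#'   (default 0.3); `duty = 1` gives an unmodulated tone.
#' @param noise_sd Additive Gaussian noise standard deviation
#'   (default 0.01).
#' @param seed Optional integer seed.
#' @return A [sampled_series()] at `rate`.
#' @export
synth_chirp_audio <- function(tempo, carrier = 8000, rate = 44100,
                              duration = 60, duty = 0.3, noise_sd = 0.01,
                              seed = NULL) {
  if (rate <= 2 * carrier) stop("carrier must be below the Nyquist frequency")
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  if (tempo <= 0) stop("tempo must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  gate <- as.numeric((t * tempo) %% 1 < duty)
  x <- gate * sin(2 * pi * carrier * t)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  sampled_series(x, rate)
}

#' Materialise a demo dataset
#'
#' Writes one of each synthetic input to a directory: an event-onset CSV,
#' a tempo-table CSV, a flash-count CSV and a chirp WAV, all seeded.
#'
#' @param dir Output directory (created if missing).
#' @param seed Base seed.
#' @return Invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"),
             tempos = file.path(dir, "tempos.csv"),
             counts = file.path(dir, "flash_counts.csv"),
             audio = file.path(dir, "chirps.wav"))
  onsets <- generate_event_train(2.4, 30, jitter_cv = 0.1, seed = seed)
  utils::write.csv(data.frame(onset_s = onsets), paths["events"],
                   row.names = FALSE)
  tempos <- sample_tempos(50, seed = seed + 1)
  utils::write.csv(data.frame(species = sprintf("synthetic_sp%02d", 1:50),
                              group = rep(c("bird", "bat", "frog",
                                            "grasshopper", "land-mammal"),
                                          each = 10),
                              tempo_hz = round(tempos, 3)),
                   paths["tempos"], row.names = FALSE)
  fl <- synth_flash_series(2.4, duration = 60, seed = seed + 2)
  utils::write.csv(data.frame(frame = seq_along(fl$values) - 1L,
                              count = fl$values),
                   paths["counts"], row.names = FALSE)
  au <- synth_chirp_audio(2.4, duration = 30, seed = seed + 3)
  write_wav(au, paths["audio"])
  invisible(paths)
}
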