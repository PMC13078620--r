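#' Inter-onset intervals of an event train
#'
#' @param onsets Strictly increasing vector of onset times, seconds, with
#'   at least two elements.
#' @return Vector of successive differences (length `n - 1`), seconds.
#' @export
inter_onset_intervals <- function(onsets) {
  if (length(onsets) < 2L) stop("need at least two onsets")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing")
  }
  diff(onsets)
}

#' Summary statistics of inter-onset intervals
#'
#' Mean and sample standard deviation (n-1 denominator; 0 for a single
#' interval), coefficient of variation, and the implied tempo
#' `1 / mean(IOI)` in Hz.
#'
#' @param iois Nonempty vector of positive intervals, seconds.
#' @return An object of class `ioi_stats` with fields `n_intervals`,
#'   `mean_ioi`, `sd_ioi`, `cv`, `tempo`.
#' @export
ioi_stats <- function(iois) {
  if (length(iois) == 0L) stop("no intervals supplied")
  if (any(iois <= 0)) stop("intervals must be positive")
  m <- mean(iois)
  s <- if (length(iois) == 1L) 0 else stats::sd(iois)
  structure(list(n_intervals = length(iois), mean_ioi = m, sd_ioi = s,
                 cv = s / m, tempo = 1 / m),
            class = "ioi_stats")
}

#' Isochrony criterion
#'
#' A signal counts as isochronous when it has at least `min_intervals`
#' inter-onset intervals and their standard deviation is at most
#' `max_cv` of the mean (coefficient of variation). Both boundaries are
#' inclusive.
#'
#' @param stats An [ioi_stats()] object.
#' @param min_intervals Minimum number of intervals (default 5).
#' @param max_cv Maximum coefficient of variation (default 0.25).
#' @return Logical flag.
#' @export
is_isochronous <- function(stats, min_intervals = 5, max_cv = 0.25) {
  stopifnot(inherits(stats, "ioi_stats"))
  stats$n_intervals >= min_intervals && stats$cv <= max_cv
}

#' Maximum-likelihood log-normal fit of a tempo sample
#'
#' Fits `ln f ~ Normal(mu_ln, sigma_ln^2)` by maximum likelihood
#' (`mu_ln = mean(ln f)`, `sigma_ln` with the 1/n denominator), derives the
#' implied mode `exp(mu_ln - sigma_ln^2)` and median `exp(mu_ln)`, and runs
#' a Kolmogorov-Smirnov goodness-of-fit test of the log data against the
#' fitted normal. The KS test uses the fitted parameters directly; set
#' `lilliefors = TRUE` for the estimated-parameter correction
#' (requires the nortest package).
#'
#' @param tempos At least two positive tempos, Hz.
#' @param lilliefors Use the Lilliefors variant of the normality test.
#' @return An object of class `lognormal_fit` with fields `mu_ln`,
#'   `sigma_ln`, `mode`, `median`, `ks_stat`, `ks_p`, `n`.
#' @export
fit_lognormal <- function(tempos, lilliefors = FALSE) {
  if (any(tempos <= 0)) stop("tempos must be positive")
  if (length(tempos) < 2L) stop("need at least two tempos")
  lx <- log(tempos)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  mm <- lognormal_mode_median(mu, sigma)
  if (sigma == 0) {
    ks_stat <- NA_real_; ks_p <- NA_real_
  } else if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors option requires the nortest package")
    }
    lt <- nortest::lillie.test(lx)
    ks_stat <- unname(lt$statistic); ks_p <- lt$p.value
  } else {
    kt <- suppressWarnings(stats::ks.test(lx, "pnorm", mean = mu, sd = sigma))
    ks_stat <- unname(kt$statistic); ks_p <- kt$p.value
  }
  structure(list(mu_ln = mu, sigma_ln = sigma, mode = mm[["mode"]],
                 median = mm[["median"]], ks_stat = ks_stat, ks_p = ks_p,
                 n = length(tempos)),
            class = "lognormal_fit")
}

#' Mode and median implied by log-normal parameters
#'
#' `mode = exp(mu_ln - sigma_ln^2)`, `median = exp(mu_ln)`; the mode never
#' exceeds the median (equality iff `sigma_ln = 0`).
#'
#' @param mu_ln Log-scale mean.
#' @param sigma_ln Log-scale standard deviation (nonnegative).
#' @return Named vector `c(mode = , median = )`, Hz.
#' @export
lognormal_mode_median <- function(mu_ln, sigma_ln) {
  if (sigma_ln < 0) stop("sigma_ln must be nonnegative")
  c(mode = exp(mu_ln - sigma_ln^2), median = exp(mu_ln))
}

#' Summarise a tempo table
#'
#' Sample size, sample median (midpoint convention for even n), per-group
#' tallies, and log-spaced histogram counts of the tempo column.
#'
#' @param records Nonempty data frame with columns `tempo_hz` and
#'   optionally `group`.
#' @param n_bins Number of log-spaced histogram bins (default 12).
#' @return A list with `n`, `median`, `group_counts`, `breaks`, `counts`.
#' @export
summarize_sample <- function(records, n_bins = 12) {
  if (nrow(records) == 0L) stop("no records supplied")
  tempos <- records$tempo_hz
  if (any(tempos <= 0)) stop("tempos must be positive")
  rng <- range(tempos)
  breaks <- if (rng[1] == rng[2]) {
    c(rng[1] * 0.99, rng[2] * 1.01)
  } else {
    exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  }
  counts <- as.integer(table(cut(tempos, breaks, include.lowest = TRUE)))
  group_counts <- if ("group" %in% names(records)) {
    table(records$group)
  } else NULL
  list(n = nrow(records), median = stats::median(tempos),
       group_counts = group_counts, breaks = breaks, counts = counts)
}

#' Read a tempo table
#'
#' CSV with columns `species`, `group`, `tempo_hz` and optional
#' `weight_g`, `modality`, `medium`. The packaged example table
#' (`system.file("extdata", "xeno_tempos_synthetic.csv", package =
#' "isochron")`) is a synthetic stand-in for a 50-species wildlife-database
#' sample: 10 tempos per animal group drawn from the fitted log-normal
#' tempo distribution (see the package vignette).
#'
#' @param path CSV file path.
#' @return Data frame of tempo records.
#' @export
read_tempo_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "group", "tempo_hz") %in% names(df))) {
    stop("tempo table needs columns species, group, tempo_hz")
  }
  if (any(df$tempo_hz <= 0)) stop("tempos must be positive")
  df
}

#' Read an event-onset table
#'
#' CSV with a column `onset_s` (and optionally `label`).
#'
#' @param path CSV file path.
#' @return Numeric vector of onset times (seconds), sorted check applied
#'   downstream.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"onset_s" %in% names(df)) stop("event table needs a column onset_s")
  df$onset_s
}

#' @export
print.ioi_stats <- function(x, ...) {
  cat(sprintf("<ioi_stats> n = %d, mean IOI = %.4g s, cv = %.3f, tempo = %.4g Hz\n",
              x$n_intervals, x$mean_ioi, x$cv, x$tempo))
  invisible(x)
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> mu_ln = %.3f, sigma_ln = %.3f, mode = %.3g Hz, median = %.3g Hz\n",
    x$mu_ln, x$sigma_ln, x$mode, x$median))
  if (!is.na(x$ks_stat)) {
    cat(sprintf("  KS D = %.4f, p = %.4f (n = %d)\n", x$ks_stat, x$ks_p, x$n))
  }
  invisible(x)
}
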