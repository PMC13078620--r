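#' Natural-frequency specification for a receiver circuit
#'
#' Oscillator natural frequencies are drawn from a Gaussian with mean
#' `mean_tempo` and standard deviation `spread`, both in Hz. Internally all
#' frequencies are angular (rad/s, factor `2*pi`); user-facing tempos stay
#' in Hz.
#'
#' @param mean_tempo Mean natural tempo in Hz (default 2, a representative
#'   mid-delta-band value).
#' @param spread Standard deviation of the natural tempos in Hz (must be
#'   nonnegative).
#' @return An object of class `freq_spec`.
#' @export
freq_spec <- function(mean_tempo = 2, spread = 0.5) {
  stopifnot(is.numeric(mean_tempo), length(mean_tempo) == 1L,
            is.numeric(spread), length(spread) == 1L)
  if (mean_tempo <= 0) stop("mean_tempo must be positive")
  if (spread < 0) stop("spread must be nonnegative")
  structure(list(mean_tempo = mean_tempo, spread = spread),
            class = "freq_spec")
}

#' Critical coupling of the Kuramoto model
#'
#' Large-N critical coupling `K_c = 2 / (pi * g(0))` for a zero-centred
#' Gaussian frequency density `g` with standard deviation `spread_angular`
#' (rad/s). For the Gaussian this reduces to the closed form
#' `K_c = 2 * sigma * sqrt(2/pi)`; the degenerate `spread_angular = 0`
#' returns 0.
#'
#' @param spread_angular Standard deviation of the natural (angular)
#'   frequencies, rad/s.
#' @return Critical coupling in rad/s.
#' @export
critical_coupling <- function(spread_angular) {
  stopifnot(is.numeric(spread_angular), length(spread_angular) == 1L)
  if (spread_angular < 0) stop("spread_angular must be nonnegative")
  if (spread_angular == 0) return(0)
  g0 <- stats::dnorm(0, mean = 0, sd = spread_angular)
  2 / (pi * g0)
}

#' Subcritical coupling
#'
#' Sets the circuit coupling just below the critical point:
#' `K = (1 - epsilon) * K_c`. The unforced circuit then stays incoherent;
#' only external forcing can order it.
#'
#' @param critical Critical coupling, rad/s.
#' @param epsilon Fractional distance below criticality, in `[0, 1]`
#'   (default 0.1).
#' @return Coupling in rad/s.
#' @export
subcritical_coupling <- function(critical, epsilon = 0.1) {
  stopifnot(is.numeric(critical), length(critical) == 1L)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single value in [0, 1]")
  }
  (1 - epsilon) * critical
}

#' Build a receiver circuit
#'
#' Assembles a circuit from a binary adjacency matrix and a frequency
#' specification. Natural frequencies are drawn i.i.d.
#' `Normal(2*pi*mean_tempo, (2*pi*spread)^2)` rad/s; the coupling is set
#' subcritically from the angular spread, `K = (1-epsilon) * K_c(2*pi*spread)`.
#'
#' @param adjacency Square binary matrix with zero diagonal; entry
#'   `A[i, j] = 1` means oscillator `j` is an input of oscillator `i`.
#' @param spec A [freq_spec()].
#' @param epsilon Subcriticality fraction, see [subcritical_coupling()].
#' @param seed Optional integer seed making the frequency draw reproducible.
#' @param coupling Optional explicit coupling (rad/s) overriding the
#'   subcritical rule.
#' @return An object of class `circuit` with fields `n`, `adjacency`,
#'   `omega` (rad/s) and `coupling` (rad/s).
#' @export
build_circuit <- function(adjacency, spec = freq_spec(), epsilon = 0.1,
                          seed = NULL, coupling = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal (no self-loops)")
  stopifnot(inherits(spec, "freq_spec"))
  n <- nrow(adjacency)
  if (!is.null(seed)) set.seed(seed)
  omega <- stats::rnorm(n, mean = 2 * pi * spec$mean_tempo,
                        sd = 2 * pi * spec$spread)
  if (is.null(coupling)) {
    coupling <- subcritical_coupling(critical_coupling(2 * pi * spec$spread),
                                     epsilon)
  }
  if (coupling < 0) stop("coupling must be nonnegative")
  structure(list(n = n, adjacency = adjacency, omega = omega,
                 coupling = coupling),
            class = "circuit")
}

#' External periodic forcing
#'
#' The forcing enters the phase equation as
#' `(K/N) * K_ext * sin(theta_ext - theta_i)`, i.e. `relative_strength`
#' (`K_ext`) is expressed in units of the internal coupling `K` and is still
#' subject to the `1/N` normalisation. The forcing phase rotates uniformly:
#' `theta_ext(t) = initial_phase + 2*pi*tempo*t`. A zero tempo gives a
#' static attractor phase.
#'
#' @param tempo Forcing tempo in Hz (nonnegative).
#' @param relative_strength Dimensionless multiplier `K_ext` (nonnegative).
#' @param initial_phase Forcing phase at `t = 0`, radians.
#' @return An object of class `forcing`.
#' @export
forcing <- function(tempo, relative_strength = 1, initial_phase = 0) {
  stopifnot(is.numeric(tempo), length(tempo) == 1L)
  if (tempo < 0) stop("tempo must be nonnegative")
  if (relative_strength < 0) stop("relative_strength must be nonnegative")
  structure(list(tempo = tempo, relative_strength = relative_strength,
                 initial_phase = initial_phase),
            class = "forcing")
}

#' Forcing phase at a given time
#'
#' @param t Time in seconds (nonnegative).
#' @param fc A [forcing()].
#' @return Phase in radians, wrapped to `[0, 2*pi)`.
#' @export
forcing_phase <- function(t, fc) {
  stopifnot(inherits(fc, "forcing"), all(t >= 0))
  (fc$initial_phase + 2 * pi * fc$tempo * t) %% (2 * pi)
}

#' Integration settings
#'
#' @param dt Fixed RK4 step size in seconds (default 1e-3).
#' @param duration Total simulated time in seconds (default 30).
#' @param transient Initial span discarded from time averages, seconds
#'   (default 10).
#' @param seed Optional integer seed for the initial-phase draw.
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(dt = 1e-3, duration = 30, transient = 10,
                               seed = NULL) {
  if (!(dt > 0 && dt < duration)) stop("need 0 < dt < duration")
  if (!(transient >= 0 && transient < duration)) {
    stop("need 0 <= transient < duration")
  }
  structure(list(dt = dt, duration = duration, transient = transient,
                 seed = seed),
            class = "integration_config")
}

#' Instantaneous phase velocities of the forced circuit
#'
#' Evaluates, for each oscillator,
#' `omega_i + (K/N) * (sum_j A_ij sin(theta_j - theta_i) +
#' K_ext sin(theta_ext(t) - theta_i))`.
#'
#' @param phases Length-N phase vector, radians.
#' @param t Time in seconds (sets the forcing phase).
#' @param circuit A [build_circuit()] object.
#' @param fc A [forcing()].
#' @return Length-N vector of phase velocities, rad/s.
#' @export
phase_velocity <- function(phases, t, circuit, fc) {
  stopifnot(inherits(circuit, "circuit"), inherits(fc, "forcing"))
  if (length(phases) != circuit$n) {
    stop("phase vector length does not match circuit size")
  }
  n <- circuit$n
  text <- fc$initial_phase + 2 * pi * fc$tempo * t
  coup <- vapply(seq_len(n), function(i) {
    sum(circuit$adjacency[i, ] * sin(phases - phases[i])) +
      fc$relative_strength * sin(text - phases[i])
  }, numeric(1))
  circuit$omega + circuit$coupling / n * coup
}

#' Integrate a forced receiver circuit
#'
#' Classical fixed-step 4th-order Runge-Kutta integration of the forced
#' Kuramoto circuit. Phases are stored wrapped to `[0, 2*pi)`; the order
#' parameter is evaluated at every step, by default with the forcing phase
#' included as an extra node (divisor `N + 1`), so that high order means
#' the circuit is both internally synchronised and entrained to the
#' forcing.
#'
#' @param circuit A [build_circuit()] object.
#' @param fc A [forcing()].
#' @param config An [integration_config()].
#' @param init_phases Optional length-N initial phases (radians); when
#'   `NULL` they are drawn uniformly on `[0, 2*pi)` using `config$seed`.
#' @param include_forcing_in_order Include the forcing node in the order
#'   parameter (default `TRUE`).
#' @return An object of class `trajectory` with fields `times`, `phases`
#'   (time x N, wrapped), `forcing_phase` and `order_series`.
#' @export
integrate_circuit <- function(circuit, fc, config = integration_config(),
                              init_phases = NULL,
                              include_forcing_in_order = TRUE) {
  stopifnot(inherits(circuit, "circuit"), inherits(fc, "forcing"),
            inherits(config, "integration_config"))
  if (is.null(init_phases)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    init_phases <- stats::runif(circuit$n, 0, 2 * pi)
  }
  if (length(init_phases) != circuit$n) {
    stop("init_phases length does not match circuit size")
  }
  n_steps <- round(config$duration / config$dt)
  out <- .rk4_kuramoto(circuit$adjacency, circuit$omega, circuit$coupling,
                       fc$relative_strength, 2 * pi * fc$tempo,
                       fc$initial_phase, init_phases, config$dt, n_steps,
                       include_forcing_in_order)
  structure(c(out, list(transient = config$transient)), class = "trajectory")
}

#' Kuramoto order parameter
#'
#' Modulus of the mean unit phasor, `R = |mean(exp(1i * theta))|`, in
#' `[0, 1]`: 0 for balanced/incoherent phases, 1 for perfect synchrony.
#' With `include_forcing = TRUE` the forcing phasor is appended before
#' averaging (divisor `N + 1`).
#'
#' @param phases Nonempty numeric vector of phases, radians.
#' @param include_forcing Append the external forcing phase as an extra
#'   node?
#' @param ext_phase Forcing phase, radians (required when
#'   `include_forcing = TRUE`).
#' @return Scalar `R` in `[0, 1]`.
#' @export
order_parameter <- function(phases, include_forcing = FALSE,
                            ext_phase = NULL) {
  if (length(phases) < 1L) stop("need at least one phase")
  if (include_forcing) {
    if (is.null(ext_phase)) stop("ext_phase required when include_forcing")
    phases <- c(phases, ext_phase)
  }
  Mod(mean(exp(1i * phases)))
}

#' Time-averaged order parameter
#'
#' Arithmetic mean of the stored order-parameter series restricted to
#' `t >= transient`.
#'
#' @param trajectory A [integrate_circuit()] result.
#' @param transient Span (seconds) discarded from the start; defaults to
#'   the value carried by the trajectory.
#' @return Mean order parameter in `[0, 1]`.
#' @export
mean_order <- function(trajectory, transient = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (is.null(transient)) transient <- trajectory$transient
  tmax <- trajectory$times[length(trajectory$times)]
  if (transient >= tmax) stop("transient must be smaller than the final time")
  keep <- trajectory$times >= transient
  mean(trajectory$order_series[keep])
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> N = %d, %d edges, K = %.4g rad/s\n",
              x$n, sum(x$adjacency), x$coupling))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps, N = %d, final R = %.3f\n",
              length(x$times) - 1L, ncol(x$phases),
              x$order_series[length(x$order_series)]))
  invisible(x)
}
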