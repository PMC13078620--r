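# The three computational experiments: topology sweep, resonance curves,
# Arnold-tongue map. Each averages the time-averaged order parameter over
# seeded realizations (fresh random phases and natural frequencies per
# realization), i.e. a mean of per-realization curves, not a pooled series.

.realization_mean_order <- function(adjacency, spec, fc, config, epsilon,
                                    seed) {
  set.seed(seed)
  n <- nrow(adjacency)
  omega <- stats::rnorm(n, 2 * pi * spec$mean_tempo, 2 * pi * spec$spread)
  phases <- stats::runif(n, 0, 2 * pi)
  circ <- structure(
    list(n = n, adjacency = adjacency, omega = omega,
         coupling = subcritical_coupling(
           critical_coupling(2 * pi * spec$spread), epsilon)),
    class = "circuit")
  traj <- integrate_circuit(circ, fc, config, init_phases = phases)
  mean_order(traj)
}

#' Topology sweep: entrainability of every circuit wiring
#'
#' For each digraph, integrates `n_realizations` independent realizations
#' (fresh uniform phases and Gaussian frequencies each time) under a fixed
#' external forcing and averages the post-transient mean order parameter.
#' Per-graph realization seeds are derived from the base seed and the
#' graph's canonical code, so results are invariant to the order in which
#' graphs are supplied.
#'
#' @param graphs Nonempty list of [digraph()] objects (same vertex count).
#' @param spec A [freq_spec()]; the mean tempo is held at its value while
#'   topologies vary.
#' @param fc A [forcing()]; the reference stimulus is 2 Hz.
#' @param config An [integration_config()].
#' @param n_realizations Realizations per graph (default 100).
#' @param epsilon Subcriticality fraction.
#' @param base_seed Base RNG seed; sub-seeds are derived deterministically.
#' @return An object of class `topology_sweep` with per-graph mean orders
#'   (`r_mean`), the sorted curve (`sorted`), and the parameter record.
#' @export
topology_sweep <- function(graphs, spec = freq_spec(mean_tempo = 2, spread = 0.5),
                           fc = forcing(2, 1), config = integration_config(),
                           n_realizations = 100, epsilon = 0.1,
                           base_seed = 1) {
  if (length(graphs) == 0L) stop("graph list must be nonempty")
  stopifnot(n_realizations >= 1)
  n <- graphs[[1]]$n_vertices
  maps <- .perm_arc_maps(n)
  r_mean <- vapply(graphs, function(g) {
    code <- .canonical_code(g, maps)
    gseed <- (base_seed + (code %% 99991) * 1009) %% .Machine$integer.max
    mean(vapply(seq_len(n_realizations), function(r) {
      .realization_mean_order(to_adjacency(g), spec, fc, config, epsilon,
                              seed = gseed + r)
    }, numeric(1)))
  }, numeric(1))
  structure(list(r_mean = r_mean, sorted = sort(r_mean),
                 n_realizations = n_realizations,
                 params = list(spec = spec, forcing = fc, config = config,
                               epsilon = epsilon, base_seed = base_seed)),
            class = "topology_sweep")
}

#' Neural resonance curve
#'
#' Mean order parameter of an all-to-all circuit as a function of the
#' forcing tempo. Each realization draws fresh phases and frequencies;
#' the same realization draws are reused across the tempo grid so each
#' realization contributes one full curve, and curves are averaged.
#'
#' @param f_grid Strictly increasing grid of forcing tempos, Hz
#'   (nonnegative).
#' @param K_ext Forcing strength in units of the internal coupling.
#' @param spec A [freq_spec()] (mean tempo and heterogeneity sigma).
#' @param config An [integration_config()].
#' @param n_realizations Curves averaged (default 10).
#' @param n_oscillators Circuit size (default 5).
#' @param epsilon Subcriticality fraction.
#' @param base_seed Base seed; realization `r` uses `base_seed + r`.
#' @return Object of class `resonance_curve` with fields `f_grid`,
#'   `r_mean`, and the parameter record.
#' @export
resonance_curve <- function(f_grid, K_ext = 1,
                            spec = freq_spec(mean_tempo = 2, spread = 0.3),
                            config = integration_config(),
                            n_realizations = 10, n_oscillators = 5,
                            epsilon = 0.1, base_seed = 1) {
  if (any(f_grid < 0)) stop("forcing tempos must be nonnegative")
  if (is.unsorted(f_grid, strictly = TRUE)) {
    stop("f_grid must be strictly increasing")
  }
  stopifnot(n_realizations >= 1)
  A <- to_adjacency(complete_digraph(n_oscillators))
  per_real <- vapply(seq_len(n_realizations), function(r) {
    vapply(f_grid, function(f) {
      .realization_mean_order(A, spec, forcing(f, K_ext), config, epsilon,
                              seed = base_seed + r)
    }, numeric(1))
  }, numeric(length(f_grid)))
  structure(list(f_grid = f_grid,
                 r_mean = rowMeans(matrix(per_real, nrow = length(f_grid))),
                 K_ext = K_ext, spread = spec$spread,
                 n_realizations = n_realizations,
                 params = list(spec = spec, config = config,
                               epsilon = epsilon, base_seed = base_seed)),
            class = "resonance_curve")
}

#' Arnold-tongue map
#'
#' Mean order parameter over the product grid of forcing strength and
#' forcing tempo, for the all-to-all circuit. The locked region around the
#' circuit's intrinsic tempo forms a tongue that widens with `K_ext`.
#'
#' @param K_ext_grid Nonempty grid of forcing strengths.
#' @param f_grid Strictly increasing, nonnegative grid of forcing tempos,
#'   Hz.
#' @inheritParams resonance_curve
#' @return Object of class `arnold_map` with `K_ext_grid`, `f_grid`, and
#'   `r_matrix` (`length(K_ext_grid) x length(f_grid)`).
#' @export
arnold_tongue_map <- function(K_ext_grid, f_grid,
                              spec = freq_spec(mean_tempo = 2, spread = 0.3),
                              config = integration_config(),
                              n_realizations = 10, n_oscillators = 5,
                              epsilon = 0.1, base_seed = 1) {
  if (length(K_ext_grid) == 0L || length(f_grid) == 0L) {
    stop("grids must be nonempty")
  }
  rows <- lapply(K_ext_grid, function(K_ext) {
    resonance_curve(f_grid, K_ext, spec, config, n_realizations,
                    n_oscillators, epsilon, base_seed)$r_mean
  })
  structure(list(K_ext_grid = K_ext_grid, f_grid = f_grid,
                 r_matrix = do.call(rbind, rows),
                 n_realizations = n_realizations,
                 params = list(spec = spec, config = config,
                               epsilon = epsilon, base_seed = base_seed)),
            class = "arnold_map")
}

#' Width of the Arnold tongue at a given forcing strength
#'
#' Length (Hz) of the maximal contiguous run of tempo grid points, around
#' the row's global maximum, whose mean order is at or above `threshold`.
#' Returns 0 when no point qualifies (a single qualifying point also has
#' zero extent).
#'
#' @param map An [arnold_tongue_map()] result.
#' @param K_ext A forcing strength present in the map's grid.
#' @param threshold Order-parameter threshold in `(0, 1)` (default 0.6,
#'   between the incoherent baseline ~ `1/sqrt(N+1)` and full locking).
#' @return Width in Hz.
#' @export
tongue_width <- function(map, K_ext, threshold = 0.6) {
  stopifnot(inherits(map, "arnold_map"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  row <- match(K_ext, map$K_ext_grid)
  if (is.na(row)) stop("K_ext not present in the map's grid")
  r <- map$r_matrix[row, ]
  if (max(r) < threshold) return(0)
  peak <- which.max(r)
  lo <- peak
  while (lo > 1 && r[lo - 1] >= threshold) lo <- lo - 1
  hi <- peak
  while (hi < length(r) && r[hi + 1] >= threshold) hi <- hi + 1
  map$f_grid[hi] - map$f_grid[lo]
}

#' Export a trajectory as a CSV table
#'
#' Columns: `time_s`, `phase_0 .. phase_{N-1}`, `forcing_phase`, `R`.
#'
#' @param trajectory A [integrate_circuit()] result.
#' @param path Output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(time_s = trajectory$times, trajectory$phases,
                   forcing_phase = trajectory$forcing_phase,
                   R = trajectory$order_series)
  names(df)[2:(1 + ncol(trajectory$phases))] <-
    paste0("phase_", seq_len(ncol(trajectory$phases)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
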