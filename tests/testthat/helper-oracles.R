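# Independent oracles used across test files. These deliberately avoid the
# package's canonicalization / integration code paths.

# Brute-force digraph isomorphism test: try every vertex permutation and
# compare edge sets directly.
iso_brute <- function(g1, g2) {
  n <- g1$n_vertices
  if (n != g2$n_vertices || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  key <- function(e) as.numeric(sort(e[, 1] * n + e[, 2]))
  k2 <- key(g2$edges)
  perms <- pracma::perms(seq_len(n))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ] - 1L
    mapped <- cbind(p[g1$edges[, 1] + 1L], p[g1$edges[, 2] + 1L])
    if (identical(key(mapped), k2)) return(TRUE)
  }
  FALSE
}

# Partition a list of digraphs into isomorphism classes by pairwise
# brute-force comparison; returns the number of classes.
count_classes_brute <- function(graphs) {
  reps <- list()
  for (g in graphs) {
    found <- FALSE
    for (r in reps) {
      if (iso_brute(g, r)) { found <- TRUE; break }
    }
    if (!found) reps[[length(reps) + 1L]] <- g
  }
  length(reps)
}

# All digraphs (all labelled edge subsets) on n vertices with m edges.
all_edge_subsets <- function(n, m) {
  arcs <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)),
                arr.ind = TRUE)
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE] - 1L
  if (m == 0) return(list(digraph(n)))
  sets <- utils::combn(nrow(arcs), m)
  lapply(seq_len(ncol(sets)), function(j) {
    digraph(n, arcs[sets[, j], , drop = FALSE])
  })
}

# A small fixed 5-node circuit with deterministic frequencies, used by the
# integrator-accuracy tests.
fixed_test_circuit <- function() {
  g <- digraph(5, rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 0),
                        c(0, 2), c(1, 3), c(2, 4), c(3, 0), c(4, 1)))
  circ <- build_circuit(to_adjacency(g), freq_spec(2, 0.3), seed = 1)
  circ$omega <- 2 * pi * c(1.8, 1.9, 2.0, 2.1, 2.2)  # fixed, not drawn
  circ
}

fixed_test_phases <- function() c(0.3, 1.1, 2.9, 4.2, 5.5)

# Reference integration with deSolve's adaptive dopri-class method at
# tight tolerances; returns final phases (unwrapped).
desolve_final_phases <- function(circ, fc, t_end, dt_out = 0.01) {
  deriv <- function(t, y, parms) list(phase_velocity(y, t, circ, fc))
  out <- deSolve::ode(fixed_test_phases(), seq(0, t_end, dt_out), deriv,
                      NULL, method = "ode45", atol = 1e-10, rtol = 1e-10)
  out[nrow(out), -1]
}

# Smallest absolute angular difference, elementwise.
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# All ordered pairs (i, j), i != j, 0-based, independent of package internals.
all_arcs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)),
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE] - 1L
  colnames(idx) <- c("tail", "head")
  idx
}
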