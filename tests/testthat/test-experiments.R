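# Scaled-down experiment settings keep these tests fast: 5-point grids,
# few realizations, short integrations. The full-scale protocols live in
# the vignette and acceptance checks.
fast_cfg <- integration_config(dt = 2e-3, duration = 8, transient = 3)

test_that("topology sweep keeps shape, order and reproducibility", {
  gs <- enumerate_digraphs(4, 5)[1:6]
  sw1 <- topology_sweep(gs, freq_spec(2, 0.5), forcing(2, 1), fast_cfg,
                        n_realizations = 2, base_seed = 3)
  expect_length(sw1$r_mean, 6)
  expect_true(all(sw1$r_mean >= 0 & sw1$r_mean <= 1))
  # sorted curve is a nondecreasing permutation of the per-graph values
  expect_equal(sort(sw1$r_mean), sw1$sorted)
  expect_true(!is.unsorted(sw1$sorted))
  # bitwise reproducibility under the same base seed
  sw2 <- topology_sweep(gs, freq_spec(2, 0.5), forcing(2, 1), fast_cfg,
                        n_realizations = 2, base_seed = 3)
  expect_identical(sw1$r_mean, sw2$r_mean)
  # per-graph values do not depend on graph input order
  sw3 <- topology_sweep(rev(gs), freq_spec(2, 0.5), forcing(2, 1), fast_cfg,
                        n_realizations = 2, base_seed = 3)
  expect_equal(rev(sw3$r_mean), sw1$r_mean)
  expect_error(topology_sweep(list(), freq_spec()), "nonempty")
})

test_that("resonance curve is flat without forcing and validates grids", {
  fg <- seq(0, 4, 1)
  rc0 <- resonance_curve(fg, K_ext = 0, spec = freq_spec(2, 0.3),
                         config = fast_cfg, n_realizations = 4,
                         base_seed = 2)
  expect_length(rc0$r_mean, length(fg))
  expect_true(all(rc0$r_mean >= 0 & rc0$r_mean <= 1))
  # with K_ext = 0 the forcing tempo cannot matter beyond realization
  # noise in the forcing-node phasor; the spread must be small
  expect_lt(diff(range(rc0$r_mean)), 0.06)
  expect_error(resonance_curve(c(-1, 0, 1)), "nonnegative")
  expect_error(resonance_curve(c(0, 0, 1)), "strictly increasing")
})

test_that("resonance peak sits at the intrinsic tempo across seeds", {
  fg <- seq(1, 3, 0.5)
  for (s in 1:2) {
    rc <- resonance_curve(fg, K_ext = 2, spec = freq_spec(2, 0.3),
                          config = fast_cfg, n_realizations = 5,
                          base_seed = s)
    expect_lte(abs(fg[which.max(rc$r_mean)] - 2), 0.5)
  }
})

test_that("heterogeneity widens and strengthens the resonance peak", {
  fg <- seq(1, 3, 0.25)
  rc_lo <- resonance_curve(fg, K_ext = 1, spec = freq_spec(2, 0.1),
                           config = fast_cfg, n_realizations = 6,
                           base_seed = 4)
  rc_hi <- resonance_curve(fg, K_ext = 1, spec = freq_spec(2, 1.0),
                           config = fast_cfg, n_realizations = 6,
                           base_seed = 4)
  expect_gte(max(rc_hi$r_mean), max(rc_lo$r_mean) - 0.05)
  half_width <- function(rc) {
    thr <- min(rc$r_mean) + 0.5 * (max(rc$r_mean) - min(rc$r_mean))
    diff(range(rc$f_grid[rc$r_mean >= thr]))
  }
  expect_gte(half_width(rc_hi), half_width(rc_lo))
})

test_that("harmonic driving is far less effective than resonant driving", {
  fg <- c(2, 4)
  # strong forcing makes the contrast unambiguous against the
  # finite-size synchrony baseline of the subcritical 5-node circuit
  rc <- resonance_curve(fg, K_ext = 4, spec = freq_spec(2, 0.3),
                        config = integration_config(), n_realizations = 5,
                        base_seed = 1)
  expect_lt(rc$r_mean[2] / rc$r_mean[1], 0.8)
})

test_that("arnold map has the right shape and its tongue widens", {
  fg <- seq(1, 3, 0.25)
  Ks <- c(1, 2, 4)
  m <- arnold_tongue_map(Ks, fg, spec = freq_spec(2, 0.3),
                         config = integration_config(), n_realizations = 5,
                         base_seed = 1)
  expect_equal(dim(m$r_matrix), c(3, length(fg)))
  expect_true(all(m$r_matrix >= 0 & m$r_matrix <= 1))
  w <- vapply(Ks, function(K) tongue_width(m, K, threshold = 0.6),
              numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_gt(w[3], 0)
  expect_error(arnold_tongue_map(numeric(0), fg), "nonempty")
})

test_that("tongue width is exact on a constructed plateau", {
  m <- structure(list(K_ext_grid = c(1, 2),
                      f_grid = seq(0, 4, 0.5),
                      r_matrix = rbind(rep(0.2, 9),
                                       c(0.2, 0.2, 0.7, 0.8, 0.9, 0.7,
                                         0.2, 0.2, 0.2))),
                 class = "arnold_map")
  expect_equal(tongue_width(m, 1, 0.6), 0)       # all below threshold
  expect_equal(tongue_width(m, 2, 0.6), 1.5)     # plateau 1.0 .. 2.5 Hz
  expect_equal(tongue_width(m, 2, 0.85), 0)      # single point => no extent
  expect_error(tongue_width(m, 3, 0.6), "not present")
  expect_error(tongue_width(m, 2, 1.2), "threshold")
})

test_that("trajectory export writes the documented columns", {
  circ <- fixed_test_circuit()
  tr <- integrate_circuit(circ, forcing(2, 1),
                          integration_config(dt = 0.01, duration = 1,
                                             transient = 0, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_s", paste0("phase_", 0:4), "forcing_phase", "R"))
  expect_equal(df$R, tr$order_series)
})
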