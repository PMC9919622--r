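# Activity counts, muscle counts, ratios, dwell grids and windowed ratios.

test_that("activity counts average the acceleration norm per quant", {
  rate <- 80; T <- 0.25
  n <- rate * 10 + 1
  const <- matrix(0, n, 3); const[, 1] <- 0.5
  expect_equal(activity_counts(const, rate, T), rep(0.5, 40))
  expect_equal(activity_counts(matrix(0, n, 3), rate, T), rep(0, 40))
  expect_error(activity_counts(const, rate, 0), "parameter error")
  expect_error(activity_counts(const, rate, 0.24), "not an integer")
})

test_that("activity counts match a fine-grid quadrature oracle within 1e-6", {
  rate <- 4000; T <- 0.25
  t <- (0:(rate * 2)) / rate
  nrm <- abs(sin(2 * pi * t))
  ac <- activity_counts(nrm, rate, T)
  oracle <- vapply(seq_along(ac), function(i) {
    stats::integrate(function(x) abs(sin(2 * pi * x)),
                     (i - 1) * T, i * T, rel.tol = 1e-12)$value / T
  }, numeric(1))
  expect_equal(ac, oracle, tolerance = 1e-6)
})

test_that("count_ratio follows the offset log form and is antisymmetric", {
  expect_equal(count_ratio(2, 2), list(sum = 4, ratio = 0))
  expect_equal(count_ratio(exp(1) - 1, 0)$ratio, 1)
  expect_equal(count_ratio(0, 0), list(sum = 0, ratio = 0))
  expect_error(count_ratio(-1, 0), "domain error")

  set.seed(3)
  a <- rexp(200); b <- rexp(200)
  expect_equal(count_ratio(a, b)$ratio, -count_ratio(b, a)$ratio,
               tolerance = 1e-12)
})

test_that("muscle counts integrate summed squared EMG per electrode group", {
  rate <- 200; T <- 0.25
  n <- rate * 2 + 1
  zero <- matrix(0, 8, n)
  expect_equal(muscle_counts(zero, rate, T), rep(0, 8))

  c0 <- 0.3
  emg <- matrix(0, 8, n); emg[2:5, ] <- c0
  expect_equal(muscle_counts(emg, rate, T, electrodes = 2:5),
               rep(4 * c0^2, 8))

  set.seed(4)
  emg <- matrix(runif(8 * n, -1, 1), 8, n)
  full <- muscle_counts(emg, rate, T, 1:8)
  flex <- muscle_counts(emg, rate, T, 1:4)
  ext <- muscle_counts(emg, rate, T, 5:8)
  expect_equal(full, flex + ext, tolerance = 1e-12)
  expect_error(muscle_counts(emg, rate, T, integer(0)), "parameter error")
})

test_that("gravity subtraction lowers activity counts when the gravity
           direction wanders inside the passband", {
  rate <- 80; T <- 0.25
  n <- rate * 30 + 1
  t <- (0:(n - 1)) / rate
  # trunk slowly tilting: gravity direction in the trunk frame rotates at
  # 0.5 Hz (inside the 0.25-2.5 Hz band)
  g <- 9.81 * cbind(sin(0.15 * sin(2 * pi * 0.5 * t)), 0,
                    -cos(0.15 * sin(2 * pi * 0.5 * t)))
  dyn <- cbind(0.3 * sin(2 * pi * 1.2 * t), 0, 0)
  ah <- dyn + g
  cfg <- analysis_config()
  ac_raw <- activity_counts(bandpass(corrected_accel(ah, mode = "raw"),
                                     rate, cfg$band_lo, cfg$band_hi),
                            rate, T)
  ac_g <- activity_counts(bandpass(corrected_accel(ah, gravity = g,
                                                   mode = "minus_gravity"),
                                   rate, cfg$band_lo, cfg$band_hi),
                          rate, T)
  interior <- 20:100
  expect_true(all(ac_g[interior] <= ac_raw[interior] + 1e-9))
  expect_gt(mean(ac_raw[interior]), mean(ac_g[interior]))
})

test_that("quant boundaries are contiguous and the grid conserves dwell", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 4,
                                        seed = 6))
  ts <- time_segments(gen$session, mode = "minus_trunk")
  expect_equal(ts$t_start[-1], ts$t_end[-nrow(ts)])
  expect_true(all(ts$ac_uaf >= 0 & ts$ac_af >= 0))
  expect_true(all(ts$mc_uaf >= 0 & ts$mc_af >= 0))

  g <- activity_grid(ts$ac_sum, ts$rac, 0.25)
  expect_identical(sum(g$dwell), nrow(ts) * 0.25)

  g1 <- activity_grid(1.5, 0.2, 0.25)
  expect_identical(sum(g1$dwell), 0.25)

  # values far outside the range are clipped to edge bins, never dropped
  g2 <- activity_grid(c(1, 1), c(-50, 50), 0.25,
                      ratio_edges = seq(-6, 6, length.out = 61))
  expect_identical(sum(g2$dwell), 0.5)
  expect_equal(sum(g2$dwell[1, ]) + sum(g2$dwell[60, ]), 0.5)
  expect_error(activity_grid(1, 1, 0.25, ratio_edges = c(1, 0)),
               "parameter error")
})

test_that("uniform ratios spanning two bins split dwell evenly", {
  n <- 40
  ratios <- rep(c(-0.5, 0.5), n / 2)
  g <- activity_grid(rep(1, n), ratios, 0.25,
                     ratio_edges = c(-1, 0, 1),
                     intensity_edges = c(0, 2))
  expect_equal(as.vector(g$dwell), c(n / 2 * 0.25, n / 2 * 0.25))
})

test_that("windowed length ratios recover scale and flag dead windows", {
  rate <- 80
  n <- rate * 10 + 1
  t <- (0:(n - 1)) / rate
  pu <- cbind(0.2 * t, 0, 0)
  pa <- cbind(0.1 * t, 0, 0)

  same <- windowed_length_ratio(pu, pu, rate, 1)
  expect_equal(same$ratio, rep(0, 10), tolerance = 1e-9)

  twice <- windowed_length_ratio(pu, pa, rate, 1)
  interior <- 3:8
  expect_equal(twice$ratio[interior], rep(log(2), length(interior)),
               tolerance = 1e-3)

  dead <- windowed_length_ratio(pu, matrix(0, n, 3), rate, 1)
  expect_true(all(!dead$valid))
  expect_true(all(is.na(dead$ratio)))
  expect_error(windowed_length_ratio(pu, pa, rate, -1), "parameter error")
})
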