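# Per-movement metrics, the BMP and classification.

test_that("path length matches simple geometry", {
  rate <- 80
  pos <- stroke_with_rest(c(0, 0, 0), c(0.1, 0, 0), 1, rate)
  seg <- segment_movements(pos, rate)
  expect_equal(path_length(pos, seg[1, ], rate), 0.1, tolerance = 0.01)

  hex <- hexagon_trace(0.05, 1, 1)
  whole <- list(n_onset = 1, n_termination = nrow(hex$position))
  expect_equal(path_length(hex$position, whole, hex$rate), 0.30,
               tolerance = 0.01)

  still <- list(n_onset = 10, n_termination = 60)
  expect_equal(path_length(matrix(0.2, 200, 3), still, rate), 0)
  expect_error(path_length(pos, list(n_onset = 0, n_termination = 5), rate),
               "bounds error")
})

test_that("length ratio is the log ratio with antisymmetry and saturation", {
  expect_equal(length_ratio(0.15, 0.15)$value, 0)
  expect_equal(length_ratio(0.2, 0.1)$value, log(2), tolerance = 1e-12)
  expect_equal(length_ratio(0.1, 0.2)$value, -log(2), tolerance = 1e-12)
  expect_false(length_ratio(0.2, 0.1)$flagged)

  sat <- length_ratio(0.2, 1e-5)
  expect_true(sat$flagged)
  expect_equal(sat$value, 6)
  expect_equal(length_ratio(1e-5, 0.2)$value, -6)
  expect_equal(length_ratio(1e-5, 1e-6)$value, 0)
  expect_error(length_ratio(-0.1, 0.1), "domain error")
})

test_that("speed PCC matches the covariance definition and handles
           degenerate profiles", {
  a <- c(0.1, 0.4, 0.9, 0.4, 0.1)
  b <- c(0.2, 0.3, 0.8, 0.5, 0.0)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(speed_pcc(a, b)$value, oracle, tolerance = 1e-12)

  expect_equal(speed_pcc(a, a)$value, 1)
  expect_equal(speed_pcc(a, 2.5 * a + 0.3)$value, 1, tolerance = 1e-12)
  flat <- speed_pcc(a, rep(0.2, 5))
  expect_true(flat$flagged)
  expect_equal(flat$value, 0)
  expect_error(speed_pcc(a, b[1:3]), "alignment error")
})

test_that("discrete Fréchet equals the exhaustive coupling minimum", {
  expect_equal(frechet_distance(1:5, 1:5), 0)
  expect_equal(frechet_distance(3, 7), 4)
  expect_equal(frechet_distance(c(0, 1), c(0, 2)), 1)
  expect_error(frechet_distance(numeric(0), 1), "length error")

  set.seed(17)
  for (rep in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- round(rnorm(n), 2); b <- round(rnorm(m), 2)
    expect_identical(frechet_distance(a, b), brute_frechet(a, b))
  }
})

test_that("speed variance matches the sample-variance oracle and scales
           quadratically", {
  x <- c(0.12, 0.55, 0.31, 0.44)
  sv <- speed_variance(x)
  expect_equal(sv[["mean"]], sum(x) / 4, tolerance = 1e-12)
  expect_equal(sv[["variance"]], sum((x - mean(x))^2) / 3, tolerance = 1e-12)

  expect_equal(speed_variance(rep(0.4, 10))[["variance"]], 0)
  expect_equal(variance_ratio(speed_variance(2 * x)[["variance"]],
                              speed_variance(x)[["variance"]])$value,
               log(4), tolerance = 1e-12)
  expect_error(speed_variance(0.3), "length error")
})

test_that("variance ratio mirrors the length-ratio contract", {
  expect_equal(variance_ratio(0.3, 0.3)$value, 0)
  expect_equal(variance_ratio(4, 1)$value, log(4), tolerance = 1e-12)
  expect_equal(variance_ratio(1, 4)$value, -variance_ratio(4, 1)$value)
  expect_true(variance_ratio(0.3, 0)$flagged)
})

test_that("the BMP formula reproduces worked values and clamps", {
  expect_identical(bmp(1, 0, 0, 0), 1)
  expect_equal(bmp(0.8, 0.55, 0.13, 0.25), 0.9, tolerance = 1e-12)
  expect_identical(bmp(-1, 5.5, 1.3, 2.5), 0)
  expect_identical(bmp(-1, 20, 5, 9), 0)    # clamped below zero
  expect_error(bmp(NA, 0, 0, 0), "domain error")
})

test_that("BMP is monotone in each criterion", {
  pccs <- seq(-1, 1, by = 0.25)
  mags <- seq(0, 6, by = 0.75)
  for (p in pccs) {
    expect_true(all(diff(bmp(p, mags, 0.2, 0.2)) <= 1e-12))
    expect_true(all(diff(bmp(p, 0.2, mags, 0.2)) <= 1e-12))
    expect_true(all(diff(bmp(p, 0.2, 0.2, mags)) <= 1e-12))
  }
  expect_true(all(diff(bmp(pccs, 0.2, 0.2, 0.2)) >= -1e-12))
})

test_that("classification respects the 0.4 / 0.7 thresholds", {
  expect_equal(classify_bmp(0.95), "bimanual")
  expect_equal(classify_bmp(0.60), "unclassified")
  expect_equal(classify_bmp(0.25), "unimanual")
  # boundary values fall in the unclassified band
  expect_equal(classify_bmp(c(0.4, 0.7)), rep("unclassified", 2))
  expect_error(classify_bmp(1.2), "domain error")
})

test_that("movement EMG averages summed squares and RW scales", {
  rate <- 200
  seg <- list(t_onset = 0.5, t_termination = 1.5)
  zero <- matrix(0, 8, 400)
  expect_equal(movement_emg(zero, seg, rate), 0)

  c0 <- 0.25
  const <- matrix(c0, 8, 400)
  expect_equal(movement_emg(const, seg, rate), 8 * c0^2, tolerance = 1e-12)
  half <- matrix(c0 / 2, 8, 400)
  w1 <- movement_emg(const, seg, rate)
  w2 <- movement_emg(half, seg, rate)
  expect_equal(log(w1 / w2), log(4), tolerance = 1e-12)
})

test_that("swapping limb roles negates the ratios and preserves the rest", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 5,
                                        inter_limb_noise = 0.05, seed = 23))
  s <- gen$session
  swapped <- bilateral_session(s$af, s$uaf, s$trunk_accel, s$gravity)
  segs <- segment_bilateral(s)
  m1 <- movement_metrics(s, segs)
  m2 <- movement_metrics(swapped, segment_bilateral(swapped))
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(m2$rl, -m1$rl, tolerance = 1e-12)
  expect_equal(m2$rv, -m1$rv, tolerance = 1e-12)
  expect_equal(m2$rw, -m1$rw, tolerance = 1e-12)
  expect_equal(m2$pcc, m1$pcc, tolerance = 1e-12)
  expect_equal(m2$f, m1$f, tolerance = 1e-12)
  expect_equal(m2$bmp, m1$bmp, tolerance = 1e-12)
})

test_that("identical limb recordings give BMP exactly 1, class bimanual", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 4,
                                        inter_limb_noise = 0,
                                        sensor_noise_sd = 0,
                                        emg_noise_sd = 0, seed = 1))
  m <- movement_metrics(gen$session, segment_bilateral(gen$session))
  expect_equal(nrow(m), 4)
  expect_identical(m$bmp, rep(1, 4))
  expect_equal(m$movement_class, rep("bimanual", 4))
  expect_equal(m$rw, rep(0, 4))
})
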