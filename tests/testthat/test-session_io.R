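# Session containers, validation and CSV round-trips.

make_tiny_session <- function(n = 3, emg = FALSE, rate = 80) {
  pos <- matrix(0, n, 3)
  acc <- matrix(rep(c(0, 0, -9.81), each = n), n, 3)
  e <- if (emg) matrix(0.1, 8, ceiling(n * 200 / rate)) else NULL
  limb <- limb_recording(pos, acc, emg = e, kin_rate = rate)
  bilateral_session(limb, limb, trunk_accel = acc)
}

test_that("a zero-motion fixture builds a session with the expected duration", {
  s <- make_tiny_session(3)
  expect_s3_class(s, "bilateral_session")
  expect_equal(s$duration, 2 / 80)
  expect_equal(s$uaf$position, matrix(0, 3, 3))
})

test_that("container invariants are enforced with named errors", {
  pos <- matrix(0, 4, 3); acc <- matrix(0, 4, 3)
  l4 <- limb_recording(pos, acc)
  l5 <- limb_recording(matrix(0, 5, 3), matrix(0, 5, 3))
  expect_error(bilateral_session(l4, l5, trunk_accel = acc),
               "alignment error")
  expect_error(limb_recording(pos, matrix(0, 5, 3)), "alignment error")
  expect_error(limb_recording(matrix(NA_real_, 4, 3), acc), "non-finite")
  expect_error(limb_recording(pos, acc, emg = matrix(0, 7, 10)),
               "8 channels")
  expect_error(limb_recording(pos, acc, emg = matrix(2, 8, 10)),
               "\\[-1, 1\\]")
  expect_error(bilateral_session(l4, l4, trunk_accel = acc,
                                 gravity = c(0, 0, -5)),
               "gravity magnitude")
})

test_that("session CSV round-trip preserves every numeric field to 1e-9", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 3,
                                        rest_gap = 0.5, seed = 11))
  kin <- withr::local_tempfile(fileext = ".csv")
  emg <- withr::local_tempfile(fileext = ".csv")
  write_session(gen$session, kin, emg)
  back <- read_session(kin, emg)
  expect_equal(back$uaf$position, gen$session$uaf$position, tolerance = 1e-9)
  expect_equal(back$af$hand_accel, gen$session$af$hand_accel,
               tolerance = 1e-9)
  expect_equal(back$trunk_accel, gen$session$trunk_accel, tolerance = 1e-9)
  expect_equal(back$uaf$emg, gen$session$uaf$emg, tolerance = 1e-9)
  expect_equal(back$kin_rate, gen$session$kin_rate)
  expect_equal(back$uaf$emg_rate, gen$session$uaf$emg_rate)
})

test_that("schema and format violations are reported by name", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 2,
                                        seed = 2))
  kin <- withr::local_tempfile(fileext = ".csv")
  emg <- withr::local_tempfile(fileext = ".csv")
  write_session(gen$session, kin, emg)
  d <- utils::read.csv(kin)
  d$uaf_px <- NULL
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, bad, row.names = FALSE)
  expect_error(read_session(bad), "uaf_px")

  d2 <- utils::read.csv(kin)
  d2$time_s[2] <- d2$time_s[1]          # non-monotone time
  utils::write.csv(d2, bad, row.names = FALSE)
  expect_error(read_session(bad), "strictly increasing")
})

test_that("movement CSV writer handles empty tables and round-trips values", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- movement_metrics(make_tiny_session(250),
                            data.frame(index = integer(0),
                                       n_onset = integer(0),
                                       n_termination = integer(0),
                                       t_onset = numeric(0),
                                       t_termination = numeric(0)))
  write_movements(empty, path)
  expect_length(readLines(path), 1)      # header only

  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 1,
                                        inter_limb_noise = 0,
                                        sensor_noise_sd = 0, seed = 1))
  m <- movement_metrics(gen$session, segment_bilateral(gen$session))
  expect_equal(nrow(m), 1)
  write_movements(m, path)
  expect_length(readLines(path), 2)
  back <- read_movements(path)
  for (col in c("l_uaf", "l_af", "rl", "pcc", "rv", "f", "bmp", "w_uaf",
                "w_af", "rw")) {
    expect_equal(back[[col]], m[[col]], tolerance = 1e-9, label = col)
  }
  expect_equal(back$movement_class, m$movement_class)
})
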