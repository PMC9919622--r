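# Arc-length resampling and path-based movement segmentation.

test_that("arc-length resampling counts points and measures length", {
  straight <- cbind(seq(0, 0.10, length.out = 101), 0, 0)
  ap <- arclength_resample(straight, 0.01)
  expect_equal(nrow(ap$points), 11)
  expect_equal(ap$s, seq(0, 0.10, by = 0.01))
  expect_true(all(abs(diff(ap$s) - 0.01) < 1e-9))

  still <- matrix(1, 50, 3)
  ap0 <- arclength_resample(still, 0.01)
  expect_equal(nrow(ap0$points), 1)
  expect_equal(max(ap0$cumulative_s), 0)

  th <- seq(0, pi, length.out = 2000)
  r <- 0.2
  semi <- cbind(r * cos(th), r * sin(th), 0)
  aps <- arclength_resample(semi, 0.001)
  expect_equal(max(aps$cumulative_s), pi * r, tolerance = 0.01)
  expect_error(arclength_resample(straight, 0), "parameter error")
  expect_error(arclength_resample(straight[1, , drop = FALSE], 0.01),
               "length error")
})

test_that("a single rest-bounded stroke yields exactly one movement", {
  pos <- stroke_with_rest(c(0, 0, 0), c(0.2, 0, 0), 1, 80)
  segs <- segment_movements(pos, 80)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$path_length, 0.2, tolerance = 0.01)
  # the movement covers the stroke; bounds sit at the surrounding stillness
  expect_lte(segs$t_onset, 1.05)
  expect_gte(segs$t_termination, 1.95)
})

test_that("a stroke below the minimum movement length is not reported", {
  pos <- stroke_with_rest(c(0, 0, 0), c(0.03, 0, 0), 1, 80)
  expect_equal(nrow(segment_movements(pos, 80)), 0)
})

test_that("an empty or trivial trajectory gives an empty movement table", {
  expect_equal(nrow(segment_movements(matrix(0, 2, 3), 80)), 0)
  expect_equal(nrow(segment_movements(matrix(0, 500, 3), 80)), 0)
})

test_that("hexagon circuits are split at every vertex without pauses", {
  # constant tracing speed: only direction changes can split
  hex <- hexagon_trace(0.05, 1, 0.5, profile = "constant")
  segs <- segment_movements(hex$position, hex$rate)
  expect_equal(nrow(segs), 6)
  expect_equal(segs$path_length, rep(0.05, 6), tolerance = 0.02)
})

test_that("hexagon recovery is exact across sides and circuit counts", {
  for (case in list(c(side = 0.05, circuits = 2),
                    c(side = 0.08, circuits = 3),
                    c(side = 0.10, circuits = 1))) {
    hex <- hexagon_trace(case[["side"]], case[["circuits"]], 1)
    segs <- segment_movements(hex$position, hex$rate)
    expect_equal(nrow(segs), hex$n_strokes,
                 label = sprintf("side %.2f x %d circuits", case[["side"]],
                                 case[["circuits"]]))
  }
})

test_that("segmentation is invariant under rigid transforms", {
  hex <- hexagon_trace(0.05, 2, 1)
  R <- rotation_matrix(c(0.3, -1, 2), 0.8)
  shift <- matrix(rep(c(0.5, -0.2, 1.0), each = nrow(hex$position)),
                  ncol = 3)
  s1 <- segment_movements(hex$position, hex$rate)
  s2 <- segment_movements(hex$position %*% t(R) + shift, hex$rate)
  expect_identical(s1$n_onset, s2$n_onset)
  expect_identical(s1$n_termination, s2$n_termination)
})

test_that("direction-change boundaries survive time re-scaling", {
  fast <- hexagon_trace(0.05, 1, 0.4, profile = "constant")
  slow <- hexagon_trace(0.05, 1, 0.8, profile = "constant")
  sf <- segment_movements(fast$position, fast$rate)
  ss <- segment_movements(slow$position, slow$rate)
  expect_equal(nrow(sf), nrow(ss))
  # boundary arc positions agree within one arc step
  arc_at <- function(hex, idx) {
    d <- sqrt(rowSums(diff(hex$position)^2))
    cum <- c(0, cumsum(d))
    cum[idx]
  }
  expect_equal(arc_at(fast, sf$n_onset), arc_at(slow, ss$n_onset),
               tolerance = 0.011)
})

test_that("per-movement path lengths never exceed the total arc length", {
  gen <- bimanual_session(scenario_spec("bimanual_symmetric", n_strokes = 8,
                                        seed = 13))
  segs <- segment_bilateral(gen$session)
  total <- max(
    sum(sqrt(rowSums(diff(gen$session$uaf$position)^2))),
    sum(sqrt(rowSums(diff(gen$session$af$position)^2))))
  expect_lte(sum(segs$path_length), total)
})

test_that("shared bilateral segmentation captures unimanual strokes", {
  us <- unimanual_session(scenario_spec("unimanual", n_strokes = 6,
                                        seed = 21), active_limb = "af")
  segs <- segment_bilateral(us$session)
  expect_equal(nrow(segs), 6)
})
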