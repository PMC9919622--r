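# Synthetic session generators with ground truth: minimum-jerk strokes,
# hexagon tracing, coordinated bimanual sessions and unimanual sessions.
# These emulate the study conditions used for validation: simultaneous
# bell-shaped speed profiles for bimanual movement, independent strokes for
# unimanual movement, and speed-coupled EMG bursts.

# run expr with an isolated RNG stream so generators are reproducible from
# their own seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Scenario specification for synthetic sessions
#'
#' @param kind scenario kind: `"bimanual_symmetric"`, `"unimanual"`,
#'   `"hexagon"` or `"mixed"`.
#' @param n_strokes number of strokes.
#' @param stroke_amplitude stroke displacement (m).
#' @param stroke_duration stroke duration (s).
#' @param rest_gap rest between strokes (s).
#' @param inter_limb_noise relative inter-limb asymmetry: timing jitter is
#'   uniform within that fraction of the stroke duration and amplitude
#'   jitter Gaussian with that relative SD.
#' @param sensor_noise_sd additive position noise SD per axis (m).
#' @param emg_gain peak EMG envelope amplitude (normalized units).
#' @param emg_noise_sd EMG additive noise SD (normalized units).
#' @param seed integer seed; a fixed seed makes the generated session
#'   bitwise reproducible.
#' @param kin_rate,emg_rate sampling rates (Hz).
#' @param lead_in,lead_out stationary padding (s) at the session ends.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("bimanual_symmetric", "unimanual",
                                   "hexagon", "mixed"),
                          n_strokes = 100, stroke_amplitude = 0.3,
                          stroke_duration = 1, rest_gap = 0.5,
                          inter_limb_noise = 0.02, sensor_noise_sd = 0.002,
                          emg_gain = 0.6, emg_noise_sd = 0.02, seed = 1,
                          kin_rate = 80, emg_rate = 200,
                          lead_in = 1, lead_out = 1) {
  kind <- match.arg(kind)
  if (n_strokes < 1) stop("parameter error: n_strokes must be >= 1")
  if (stroke_amplitude <= 0 || stroke_duration <= 0)
    stop("parameter error: amplitudes and durations must be > 0")
  if (rest_gap < 0 || inter_limb_noise < 0 || sensor_noise_sd < 0 ||
      emg_noise_sd < 0)
    stop("parameter error: noise levels and gaps must be >= 0")
  structure(list(kind = kind, n_strokes = as.integer(n_strokes),
                 stroke_amplitude = stroke_amplitude,
                 stroke_duration = stroke_duration, rest_gap = rest_gap,
                 inter_limb_noise = inter_limb_noise,
                 sensor_noise_sd = sensor_noise_sd,
                 emg_gain = emg_gain, emg_noise_sd = emg_noise_sd,
                 seed = as.integer(seed), kin_rate = kin_rate,
                 emg_rate = emg_rate, lead_in = lead_in,
                 lead_out = lead_out),
            class = "scenario_spec")
}

# position / velocity / acceleration of one minimum-jerk stroke, analytic
.minjerk_profiles <- function(start, end, duration, rate) {
  n <- as.integer(round(duration * rate))
  if (n < 4) stop("parameter error: duration * rate must be >= 4")
  tau <- (0:n) / n
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sv <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  sa <- (60 * tau - 180 * tau^2 + 120 * tau^3) / duration^2
  disp <- rbind(end - start)
  list(pos = rep(1, n + 1) %*% rbind(start) + s %*% disp,
       vel = sv %*% disp, acc = sa %*% disp, n = n)
}

#' Minimum-jerk point-to-point stroke
#'
#' Fifth-order polynomial reach along a straight line with zero velocity
#' and acceleration at both ends; the standard synthetic model of a
#' point-to-point arm movement. Peak speed is 1.875 D / duration for a
#' displacement D.
#'
#' @param start,end 3-vectors (m).
#' @param duration stroke duration (s); `duration * rate` must be >= 4.
#' @param rate sampling rate (Hz).
#' @return (n + 1) x 3 position matrix including both endpoints.
#' @export
minimum_jerk_stroke <- function(start, end, duration, rate) {
  if (!(duration > 0)) stop("parameter error: duration must be > 0")
  .minjerk_profiles(as.numeric(start), as.numeric(end), duration, rate)$pos
}

# assemble one limb's position/velocity/acceleration from a stroke table
# (onset_s, duration_s, target columns tx/ty/tz); holds position between
# strokes
.assemble_limb <- function(n_samples, rate, start_pos, strokes) {
  pos <- matrix(rep(start_pos, each = n_samples), n_samples, 3)
  vel <- matrix(0, n_samples, 3)
  acc <- matrix(0, n_samples, 3)
  current <- as.numeric(start_pos)
  if (nrow(strokes) > 0) {
    ord <- order(strokes$onset_s)
    strokes <- strokes[ord, ]
    truth_on <- truth_off <- numeric(nrow(strokes))
    for (k in seq_len(nrow(strokes))) {
      i0 <- as.integer(round(strokes$onset_s[k] * rate)) + 1L
      prof <- .minjerk_profiles(current,
                                c(strokes$tx[k], strokes$ty[k], strokes$tz[k]),
                                strokes$duration_s[k], rate)
      i1 <- i0 + prof$n
      if (i0 < 1 || i1 > n_samples)
        stop("parameter error: stroke schedule exceeds the session")
      pos[i0:i1, ] <- prof$pos
      vel[i0:i1, ] <- prof$vel
      acc[i0:i1, ] <- prof$acc
      if (i1 < n_samples) {
        pos[(i1 + 1):n_samples, ] <-
          matrix(rep(prof$pos[prof$n + 1, ], each = n_samples - i1),
                 n_samples - i1, 3)
      }
      current <- prof$pos[prof$n + 1, ]
      truth_on[k] <- (i0 - 1) / rate
      truth_off[k] <- (i1 - 1) / rate
    }
    strokes$onset_s <- truth_on
    strokes$termination_s <- truth_off
  }
  list(pos = pos, vel = vel, acc = acc, strokes = strokes)
}

# speed-coupled 8-channel EMG envelope: flexor channels weighted on the
# acceleration phase of each stroke and extensor channels on the
# deceleration phase, plus clipped Gaussian noise
.emg_from_speed <- function(vel, kin_rate, emg_rate, n_emg, gain, noise_sd) {
  speed <- sqrt(rowSums(vel^2))
  t_kin <- (seq_along(speed) - 1) / kin_rate
  t_emg <- (seq_len(n_emg) - 1) / emg_rate
  sp <- stats::approx(t_kin, speed, xout = pmin(t_emg, max(t_kin)),
                      rule = 2)$y
  peak <- max(sp)
  env <- if (peak > 0) sp / peak else sp
  dsp <- c(0, diff(sp)) * emg_rate
  dmax <- max(abs(dsp))
  phase <- if (dmax > 0) pmin(1, pmax(-1, dsp / dmax)) else rep(0, n_emg)
  env_flex <- env * (1 + phase) / 2
  env_ext <- env * (1 - phase) / 2
  emg <- matrix(0, 8, n_emg)
  for (ch in 1:8) {
    base <- if (ch <= 4) env_flex else env_ext
    emg[ch, ] <- pmin(1, pmax(-1, gain * base +
                                stats::rnorm(n_emg, 0, noise_sd)))
  }
  emg
}

# random stroke targets: unit directions scaled by the (possibly jittered)
# amplitude, rejected until the target stays inside the reachable box
.random_targets <- function(n, start, amplitude, half_width = 0.35) {
  targets <- matrix(0, n, 3)
  cur <- start
  for (k in seq_len(n)) {
    for (try in 1:100) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- cur + amplitude * dir
      if (all(abs(cand) <= half_width)) break
      if (try == 100) cand <- cur + amplitude * (-cur / sqrt(sum(cur^2)))
    }
    targets[k, ] <- cand
    cur <- cand
  }
  targets
}

.session_from_limbs <- function(uaf_parts, af_parts, spec, n_samples,
                                gravity = c(0, 0, -9.81)) {
  noise <- function(m) {
    if (spec$sensor_noise_sd > 0)
      m + matrix(stats::rnorm(length(m), 0, spec$sensor_noise_sd),
                 nrow(m), ncol(m))
    else m
  }
  n_emg <- as.integer(round((n_samples - 1) / spec$kin_rate *
                              spec$emg_rate)) + 1L
  emg_u <- .emg_from_speed(uaf_parts$vel, spec$kin_rate, spec$emg_rate,
                           n_emg, spec$emg_gain, spec$emg_noise_sd)
  emg_a_gain <- if (identical(attr(af_parts, "passive"), TRUE)) 0 else
    spec$emg_gain
  emg_a <- .emg_from_speed(af_parts$vel, spec$kin_rate, spec$emg_rate,
                           n_emg, emg_a_gain, spec$emg_noise_sd)
  grav_row <- rbind(gravity)
  uaf <- limb_recording(noise(uaf_parts$pos),
                        uaf_parts$acc + grav_row[rep(1, n_samples), ],
                        emg = emg_u, kin_rate = spec$kin_rate,
                        emg_rate = spec$emg_rate)
  af <- limb_recording(noise(af_parts$pos),
                       af_parts$acc + grav_row[rep(1, n_samples), ],
                       emg = emg_a, kin_rate = spec$kin_rate,
                       emg_rate = spec$emg_rate)
  bilateral_session(uaf, af, grav_row[rep(1, n_samples), ],
                    gravity = gravity)
}

#' Coordinated symmetric bimanual session
#'
#' Both limbs execute the same minimum-jerk stroke schedule. The
#' affected-limb copy is perturbed by inter-limb timing jitter (uniform
#' within `inter_limb_noise` of the stroke duration) and amplitude jitter
#' (Gaussian, relative SD `inter_limb_noise`); both limbs receive additive
#' position sensor noise. Hand accelerometers carry the analytic stroke
#' acceleration plus constant gravity in the trunk frame; the trunk
#' accelerometer measures gravity only. EMG is a speed-coupled envelope per
#' limb.
#'
#' @param spec a `scenario_spec`.
#' @return list with `session` (a `bilateral_session`), `truth` (data frame
#'   with stroke index, limb, onset_s, termination_s, class) and `spec`.
#' @export
bimanual_session <- function(spec = scenario_spec("bimanual_symmetric")) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_strokes
    td <- spec$stroke_duration
    total <- spec$lead_in + n * td + (n - 1) * spec$rest_gap + spec$lead_out
    n_samples <- as.integer(round(total * spec$kin_rate)) + 1L
    onsets <- spec$lead_in + (seq_len(n) - 1) * (td + spec$rest_gap)
    start <- c(0, 0, 0)
    targets <- .random_targets(n, start, spec$stroke_amplitude)
    uaf_strokes <- data.frame(onset_s = onsets, duration_s = td,
                              tx = targets[, 1], ty = targets[, 2],
                              tz = targets[, 3])
    eta <- spec$inter_limb_noise
    dt_max <- min(eta * td, 0.4 * max(spec$rest_gap, 1e-6))
    dts <- if (eta > 0) stats::runif(n, -dt_max, dt_max) else rep(0, n)
    amps <- if (eta > 0) 1 + stats::rnorm(n, 0, eta) else rep(1, n)
    af_targets <- matrix(0, n, 3)
    cur <- start
    prev <- start
    for (k in seq_len(n)) {
      disp <- targets[k, ] - prev
      cur <- cur + amps[k] * disp
      af_targets[k, ] <- cur
      prev <- targets[k, ]
    }
    af_strokes <- data.frame(onset_s = onsets + dts, duration_s = td,
                             tx = af_targets[, 1], ty = af_targets[, 2],
                             tz = af_targets[, 3])
    u <- .assemble_limb(n_samples, spec$kin_rate, start, uaf_strokes)
    a <- .assemble_limb(n_samples, spec$kin_rate, start, af_strokes)
    session <- .session_from_limbs(u, a, spec, n_samples)
    truth <- rbind(
      data.frame(stroke = seq_len(n), limb = "uaf",
                 onset_s = u$strokes$onset_s,
                 termination_s = u$strokes$termination_s,
                 class = "bimanual"),
      data.frame(stroke = seq_len(n), limb = "af",
                 onset_s = a$strokes$onset_s,
                 termination_s = a$strokes$termination_s,
                 class = "bimanual"))
    list(session = session, truth = truth, spec = spec)
  })
}

#' Strictly unimanual session
#'
#' The active limb executes the stroke schedule; the passive limb holds its
#' position (plus sensor noise) and its EMG is baseline noise only.
#'
#' @param spec a `scenario_spec`.
#' @param active_limb `"uaf"` or `"af"`.
#' @return list with `session`, `truth` and `spec` as in
#'   [bimanual_session()].
#' @export
unimanual_session <- function(spec = scenario_spec("unimanual"),
                              active_limb = c("uaf", "af")) {
  stopifnot(inherits(spec, "scenario_spec"))
  active_limb <- match.arg(active_limb)
  .with_seed(spec$seed, {
    n <- spec$n_strokes
    td <- spec$stroke_duration
    total <- spec$lead_in + n * td + (n - 1) * spec$rest_gap + spec$lead_out
    n_samples <- as.integer(round(total * spec$kin_rate)) + 1L
    onsets <- spec$lead_in + (seq_len(n) - 1) * (td + spec$rest_gap)
    start <- c(0, 0, 0)
    targets <- .random_targets(n, start, spec$stroke_amplitude)
    strokes <- data.frame(onset_s = onsets, duration_s = td,
                          tx = targets[, 1], ty = targets[, 2],
                          tz = targets[, 3])
    active <- .assemble_limb(n_samples, spec$kin_rate, start, strokes)
    passive <- .assemble_limb(n_samples, spec$kin_rate, c(0, 0.4, 0),
                              strokes[0, ])
    attr(passive, "passive") <- TRUE
    parts <- if (active_limb == "uaf") list(u = active, a = passive) else
      list(u = passive, a = active)
    session <- .session_from_limbs(parts$u, parts$a, spec, n_samples)
    truth <- data.frame(stroke = seq_len(n), limb = active_limb,
                        onset_s = active$strokes$onset_s,
                        termination_s = active$strokes$termination_s,
                        class = paste0("unimanual_", active_limb))
    list(session = session, truth = truth, spec = spec)
  })
}

#' Hexagon-tracing trajectory with ground truth
#'
#' Traces the sides of a regular hexagon (circumradius equal to the side
#' length) in the horizontal plane, one stroke per side, for a given number
#' of circuits; the heading changes by 60 degrees at every vertex (interior
#' angle 120 degrees). The speed profile along each side is either a
#' minimum-jerk bell (stopping momentarily at vertices) or constant speed
#' through the vertices.
#'
#' @param side hexagon side length (m).
#' @param n_circuits number of full circuits (6 strokes each).
#' @param stroke_duration duration per side (s).
#' @param rate sampling rate (Hz).
#' @param profile `"minjerk"` or `"constant"`.
#' @param pause_at_vertices add a stationary pause at each vertex
#'   (minimum-jerk profile only).
#' @param pause_s pause duration (s).
#' @param lead_in,lead_out stationary padding (s).
#' @param noise_sd additive position noise SD per axis (m).
#' @param seed seed used when `noise_sd > 0`.
#' @return list with `position` (matrix), `velocity`, `accel` (dynamic,
#'   minimum-jerk profile only; NULL for constant speed), `rate`,
#'   `n_strokes` (ground truth, 6 per circuit) and `truth` (per-stroke
#'   onset/termination times).
#' @export
hexagon_trace <- function(side, n_circuits = 1, stroke_duration = 1,
                          rate = 80, profile = c("minjerk", "constant"),
                          pause_at_vertices = FALSE, pause_s = 0.3,
                          lead_in = 1, lead_out = 1, noise_sd = 0,
                          seed = 1) {
  profile <- match.arg(profile)
  if (!(side > 0)) stop("parameter error: side must be > 0")
  if (n_circuits < 1) stop("parameter error: n_circuits must be >= 1")
  n_strokes <- 6L * as.integer(n_circuits)
  verts <- cbind(side * cos((0:5) * pi / 3), side * sin((0:5) * pi / 3), 0)
  vseq <- verts[(0:n_strokes) %% 6 + 1, , drop = FALSE]
  if (profile == "minjerk") {
    pause <- if (pause_at_vertices) pause_s else 0
    total <- lead_in + n_strokes * stroke_duration +
      (n_strokes - 1) * pause + lead_out
    n_samples <- as.integer(round(total * rate)) + 1L
    onsets <- lead_in + (seq_len(n_strokes) - 1) * (stroke_duration + pause)
    strokes <- data.frame(onset_s = onsets, duration_s = stroke_duration,
                          tx = vseq[-1, 1], ty = vseq[-1, 2],
                          tz = vseq[-1, 3])
    parts <- .assemble_limb(n_samples, rate, vseq[1, ], strokes)
    pos <- parts$pos
    vel <- parts$vel
    acc <- parts$acc
    truth <- data.frame(stroke = seq_len(n_strokes),
                        onset_s = parts$strokes$onset_s,
                        termination_s = parts$strokes$termination_s)
  } else {
    v <- side / stroke_duration
    d <- sqrt(rowSums((vseq[-1, , drop = FALSE] -
                       vseq[-nrow(vseq), , drop = FALSE])^2))
    cum <- c(0, cumsum(d))
    total <- lead_in + n_strokes * stroke_duration + lead_out
    n_samples <- as.integer(round(total * rate)) + 1L
    t <- (seq_len(n_samples) - 1) / rate
    s_of_t <- pmin(pmax((t - lead_in) * v, 0), cum[length(cum)])
    pos <- vapply(1:3, function(k) {
      stats::approx(cum, vseq[, k], xout = s_of_t, ties = "ordered")$y
    }, numeric(n_samples))
    vel <- acc <- NULL
    truth <- data.frame(stroke = seq_len(n_strokes),
                        onset_s = lead_in + (seq_len(n_strokes) - 1) *
                          stroke_duration,
                        termination_s = lead_in + seq_len(n_strokes) *
                          stroke_duration)
  }
  if (noise_sd > 0) {
    pos <- .with_seed(seed, pos + matrix(stats::rnorm(length(pos), 0,
                                                      noise_sd),
                                         nrow(pos), ncol(pos)))
  }
  list(position = pos, velocity = vel, accel = acc, rate = rate,
       n_strokes = n_strokes, truth = truth)
}
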