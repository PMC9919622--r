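# Data model and CSV I/O for bilateral sensor sessions.
#
# A session pairs two limb recordings (unaffected/dominant "uaf" vs
# affected/non-dominant "af") sampled on a shared kinematic clock, plus the
# trunk accelerometer and the gravity vector, all expressed in the trunk
# reference frame. EMG, when present, stays on its own (faster) clock.

.as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("format error: ", what, " must have 3 columns")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("format error: non-finite values in ", what)
  unname(x)
}

#' Single-limb recording
#'
#' Container for one limb's hand position, hand acceleration and (optional)
#' 8-channel forearm EMG.
#'
#' @param position n x 3 matrix of hand positions (m, trunk frame).
#' @param hand_accel n x 3 matrix of hand accelerations (m/s^2, trunk frame).
#' @param emg optional 8 x m matrix of normalized EMG amplitudes in [-1, 1].
#' @param kin_rate kinematic sampling rate (Hz).
#' @param emg_rate EMG sampling rate (Hz); required when `emg` is given.
#' @return an object of class `limb_recording`.
#' @export
limb_recording <- function(position, hand_accel, emg = NULL,
                           kin_rate = 80, emg_rate = 200) {
  position <- .as_mat3(position, "position")
  hand_accel <- .as_mat3(hand_accel, "hand_accel")
  if (nrow(position) != nrow(hand_accel))
    stop("alignment error: position and hand_accel sample counts differ")
  if (!(kin_rate > 0)) stop("format error: kin_rate must be > 0")
  if (!is.null(emg)) {
    emg <- as.matrix(emg)
    if (nrow(emg) != 8)
      stop("format error: emg must have exactly 8 channels (rows)")
    if (!all(is.finite(emg))) stop("format error: non-finite values in emg")
    if (max(abs(emg)) > 1 + 1e-9)
      stop("format error: emg amplitudes must lie in [-1, 1] after scaling")
    if (!(emg_rate > 0)) stop("format error: emg_rate must be > 0")
    storage.mode(emg) <- "double"
    emg <- unname(emg)
  }
  structure(list(position = position, hand_accel = hand_accel, emg = emg,
                 kin_rate = kin_rate, emg_rate = emg_rate),
            class = "limb_recording")
}

#' Bilateral session
#'
#' Pairs the unaffected/dominant and affected/non-dominant limb recordings
#' with trunk acceleration and gravity, and validates the shared clock.
#'
#' @param limb_uaf,limb_af `limb_recording` objects for the
#'   unaffected/dominant and the affected/non-dominant limb.
#' @param trunk_accel n x 3 matrix of trunk accelerations (m/s^2, trunk
#'   frame), aligned to the kinematic samples.
#' @param gravity either a single 3-vector (constant gravity in the trunk
#'   frame, default c(0, 0, -9.81)) or an n x 3 matrix of per-sample gravity.
#' @return an object of class `bilateral_session` with fields `uaf`, `af`,
#'   `trunk_accel`, `gravity`, `kin_rate`, `n_samples` and `duration` (s).
#' @export
bilateral_session <- function(limb_uaf, limb_af, trunk_accel,
                              gravity = c(0, 0, -9.81)) {
  stopifnot(inherits(limb_uaf, "limb_recording"),
            inherits(limb_af, "limb_recording"))
  n <- nrow(limb_uaf$position)
  if (nrow(limb_af$position) != n)
    stop("alignment error: limbs have different sample counts")
  if (limb_uaf$kin_rate != limb_af$kin_rate)
    stop("alignment error: limbs have different kinematic rates")
  trunk_accel <- .as_mat3(trunk_accel, "trunk_accel")
  if (nrow(trunk_accel) != n)
    stop("alignment error: trunk_accel not aligned to kinematic samples")
  if (is.matrix(gravity) || (is.numeric(gravity) && length(gravity) != 3)) {
    gravity <- .as_mat3(gravity, "gravity")
    if (nrow(gravity) != n)
      stop("alignment error: per-sample gravity not aligned to kinematic samples")
  } else {
    gravity <- as.numeric(gravity)
    gmag <- sqrt(sum(gravity^2))
    if (gmag < 9.5 || gmag > 10.1)
      stop("format error: constant gravity magnitude ", signif(gmag, 4),
           " outside [9.5, 10.1] m/s^2")
  }
  rate <- limb_uaf$kin_rate
  structure(list(uaf = limb_uaf, af = limb_af, trunk_accel = trunk_accel,
                 gravity = gravity, kin_rate = rate, n_samples = n,
                 duration = (n - 1) / rate),
            class = "bilateral_session")
}

#' Validate a bilateral session
#'
#' Re-checks every container invariant (finite values, aligned clocks,
#' 8 EMG channels, gravity magnitude). Errors name the violated field;
#' nothing is silently coerced.
#'
#' @param session a `bilateral_session`.
#' @return the session, invisibly.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "bilateral_session"))
  s <- bilateral_session(session$uaf, session$af, session$trunk_accel,
                         session$gravity)
  invisible(s)
}

.kin_columns <- function() {
  c("time_s",
    paste0("uaf_", c("px", "py", "pz")), paste0("uaf_", c("ax", "ay", "az")),
    paste0("af_", c("px", "py", "pz")), paste0("af_", c("ax", "ay", "az")),
    paste0("trunk_", c("ax", "ay", "az")))
}

.check_time <- function(t, path) {
  if (any(!is.finite(t))) stop("format error: non-finite time in ", path)
  if (any(diff(t) <= 0))
    stop("format error: time_s not strictly increasing in ", path)
  invisible(t)
}

.infer_rate <- function(t) {
  dt <- stats::median(diff(t))
  r <- 1 / dt
  # snap to an integer rate when the grid is regular to machine precision
  if (abs(r - round(r)) < 1e-6) r <- round(r)
  r
}

#' Read a bilateral session from CSV
#'
#' The kinematics file carries columns `time_s`,
#' `uaf_{px,py,pz}`, `uaf_{ax,ay,az}`, `af_{px,py,pz}`, `af_{ax,ay,az}`,
#' `trunk_{ax,ay,az}` and optionally `gx,gy,gz` (per-sample gravity).
#' The EMG file (separate because the rates differ) carries `time_s` and
#' `uaf_emg1..8`, `af_emg1..8`. The time column is for human readability;
#' sample index and rate are authoritative, and rates are inferred from the
#' median time step.
#'
#' @param kin_path path to the kinematics CSV.
#' @param emg_path optional path to the EMG CSV.
#' @param gravity constant gravity used when the file has no gravity columns.
#' @param emg_scale full-scale divisor applied to EMG samples (1 for
#'   normalized data, 128 for raw 8-bit armband exports).
#' @return a validated `bilateral_session`.
#' @export
read_session <- function(kin_path, emg_path = NULL,
                         gravity = c(0, 0, -9.81), emg_scale = 1) {
  if (!file.exists(kin_path)) stop("I/O error: file not found: ", kin_path)
  kin <- utils::read.csv(kin_path, check.names = FALSE)
  missing_cols <- setdiff(.kin_columns(), names(kin))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) in ", kin_path, ": ",
         paste(missing_cols, collapse = ", "))
  .check_time(kin$time_s, kin_path)
  rate <- .infer_rate(kin$time_s)
  grav <- if (all(c("gx", "gy", "gz") %in% names(kin))) {
    as.matrix(kin[, c("gx", "gy", "gz")])
  } else gravity

  emg_uaf <- emg_af <- NULL
  emg_rate <- 200
  if (!is.null(emg_path)) {
    if (!file.exists(emg_path)) stop("I/O error: file not found: ", emg_path)
    emg <- utils::read.csv(emg_path, check.names = FALSE)
    need <- c("time_s", paste0("uaf_emg", 1:8), paste0("af_emg", 1:8))
    missing_cols <- setdiff(need, names(emg))
    if (length(missing_cols) > 0)
      stop("schema error: missing column(s) in ", emg_path, ": ",
           paste(missing_cols, collapse = ", "))
    .check_time(emg$time_s, emg_path)
    emg_rate <- .infer_rate(emg$time_s)
    emg_uaf <- t(as.matrix(emg[, paste0("uaf_emg", 1:8)])) / emg_scale
    emg_af <- t(as.matrix(emg[, paste0("af_emg", 1:8)])) / emg_scale
  }

  uaf <- limb_recording(kin[, paste0("uaf_", c("px", "py", "pz"))],
                        kin[, paste0("uaf_", c("ax", "ay", "az"))],
                        emg = emg_uaf, kin_rate = rate, emg_rate = emg_rate)
  af <- limb_recording(kin[, paste0("af_", c("px", "py", "pz"))],
                       kin[, paste0("af_", c("ax", "ay", "az"))],
                       emg = emg_af, kin_rate = rate, emg_rate = emg_rate)
  bilateral_session(uaf, af, kin[, paste0("trunk_", c("ax", "ay", "az"))],
                    gravity = grav)
}

#' Write a bilateral session to CSV
#'
#' Inverse of [read_session()]: numeric fields round-trip within 1e-9.
#'
#' @param session a `bilateral_session`.
#' @param kin_path output path for the kinematics CSV.
#' @param emg_path optional output path for the EMG CSV (required when the
#'   session carries EMG).
#' @param emg_scale full-scale multiplier applied to EMG samples on write
#'   (matching the `emg_scale` used at read time).
#' @return invisibly, the paths written.
#' @export
write_session <- function(session, kin_path, emg_path = NULL, emg_scale = 1) {
  validate_session(session)
  n <- session$n_samples
  t <- (seq_len(n) - 1) / session$kin_rate
  kin <- data.frame(time_s = t,
                    session$uaf$position, session$uaf$hand_accel,
                    session$af$position, session$af$hand_accel,
                    session$trunk_accel)
  names(kin) <- .kin_columns()
  if (is.matrix(session$gravity)) {
    kin$gx <- session$gravity[, 1]
    kin$gy <- session$gravity[, 2]
    kin$gz <- session$gravity[, 3]
  }
  utils::write.csv(kin, kin_path, row.names = FALSE)
  paths <- kin_path
  if (!is.null(session$uaf$emg)) {
    if (is.null(emg_path))
      stop("I/O error: session carries EMG but no emg_path given")
    m <- ncol(session$uaf$emg)
    te <- (seq_len(m) - 1) / session$uaf$emg_rate
    emg <- data.frame(time_s = te,
                      t(session$uaf$emg) * emg_scale,
                      t(session$af$emg) * emg_scale)
    names(emg) <- c("time_s", paste0("uaf_emg", 1:8), paste0("af_emg", 1:8))
    utils::write.csv(emg, emg_path, row.names = FALSE)
    paths <- c(paths, emg_path)
  }
  invisible(paths)
}

.movement_columns <- function() {
  c("onset_s", "termination_s", "L_uaf", "L_af", "RL", "PCC", "RV", "F",
    "BMP", "class", "W_uaf", "W_af", "RW", "flags")
}

#' Write per-movement metrics to CSV
#'
#' One row per completed movement; an empty metrics table produces a
#' header-only file.
#'
#' @param movements a `movement_metrics` data frame (see
#'   [movement_metrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_movements <- function(movements, path) {
  cols <- .movement_columns()
  if (is.null(movements) || nrow(movements) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
  } else {
    map <- c(onset_s = "t_onset", termination_s = "t_termination",
             L_uaf = "l_uaf", L_af = "l_af", RL = "rl", PCC = "pcc",
             RV = "rv", F = "f", BMP = "bmp", class = "movement_class",
             W_uaf = "w_uaf", W_af = "w_af", RW = "rw", flags = "flags")
    missing_cols <- setdiff(unname(map), names(movements))
    if (length(missing_cols) > 0)
      stop("schema error: movements lack column(s): ",
           paste(missing_cols, collapse = ", "))
    out <- movements[, unname(map)]
    names(out) <- cols
  }
  ok <- tryCatch({utils::write.csv(out, path, row.names = FALSE); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read per-movement metrics written by [write_movements()]
#'
#' @param path CSV path.
#' @return a data frame with the [movement_metrics()] column names.
#' @export
read_movements <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  x <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(class = "character", flags = "character"))
  missing_cols <- setdiff(.movement_columns(), names(x))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  names(x) <- c("t_onset", "t_termination", "l_uaf", "l_af", "rl", "pcc",
                "rv", "f", "bmp", "movement_class", "w_uaf", "w_af", "rw",
                "flags")
  x
}

#' @export
print.bilateral_session <- function(x, ...) {
  cat("bilateral_session:", x$n_samples, "kinematic samples @", x$kin_rate,
      "Hz (", round(x$duration, 2), "s )\n")
  cat("  EMG:", if (is.null(x$uaf$emg)) "absent" else
    paste0(ncol(x$uaf$emg), " samples @ ", x$uaf$emg_rate, " Hz"), "\n")
  cat("  gravity:", if (is.matrix(x$gravity)) "per-sample" else
    paste0("constant (", paste(signif(x$gravity, 3), collapse = ", "), ")"),
    "\n")
  invisible(x)
}
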