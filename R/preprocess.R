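# Filtering, numerical differentiation and acceleration corrections feeding
# both analysis tracks.

# zero-phase Butterworth; `pad` > 0 extends both ends by odd reflection
# before filtering so records with non-zero edge values have no zero-state
# transient
.butter_filtfilt <- function(x, rate, w, type, pad = 0L) {
  bf <- signal::butter(2, w, type = type)
  one <- function(col) {
    n <- length(col)
    p <- min(as.integer(pad), n - 1L)
    if (p > 0) {
      head_ref <- 2 * col[1] - col[(p + 1):2]
      tail_ref <- 2 * col[n] - col[(n - 1):(n - p)]
      out <- signal::filtfilt(bf, c(head_ref, col, tail_ref))
      out[(p + 1):(p + n)]
    } else {
      signal::filtfilt(bf, col)
    }
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass (two poles per band edge) applied
#' forward and backward, so the output has no group delay and quant
#' boundaries stay aligned with the input samples. The filter is applied
#' per column for matrix input. Warm-up: the zero-state transient decays on
#' the scale of a few periods of the lower cut-off (roughly `3 / lo`
#' seconds at each end of the record).
#'
#' @param x numeric vector or n x k matrix (filtered column-wise).
#' @param rate sampling rate (Hz).
#' @param lo,hi cut-off frequencies (Hz); must satisfy 0 < lo < hi < rate/2.
#' @return an object of class `filtered_signal`: list with `values` (same
#'   shape as `x`), `rate` and `band`.
#' @examples
#' x <- sin(2 * pi * 1 * (0:799) / 80)
#' f <- bandpass(x, 80, 0.25, 2.5)
#' range(f$values[300:500]) # ~ [-1, 1]: 1 Hz is in the passband
#' @export
bandpass <- function(x, rate, lo, hi) {
  if (!(lo > 0 && lo < hi && hi < rate / 2))
    stop("parameter error: need 0 < lo < hi < rate/2")
  vals <- if (inherits(x, "filtered_signal")) x$values else x
  out <- .butter_filtfilt(vals, rate, c(lo, hi) / (rate / 2), "pass")
  if (!all(is.finite(out))) stop("filter error: non-finite filter output")
  structure(list(values = out, rate = rate, band = c(lo, hi)),
            class = "filtered_signal")
}

#' Smoothed hand speed from positions
#'
#' Differentiates each position component with central differences
#' (one-sided at the endpoints), low-passes the velocity components with a
#' zero-phase Butterworth filter, and returns the Euclidean norm. The
#' smoothing makes rest periods read approximately zero in the presence of
#' sensor noise; it commutes with rigid rotations of the trajectory, so the
#' speed estimate is rotation-invariant.
#'
#' @param position n x 3 matrix of hand positions (m); n >= 3.
#' @param rate sampling rate (Hz).
#' @param cutoff low-pass cut-off (Hz) for the velocity components; set to
#'   `Inf` to skip smoothing. Very short records (under ~3 filter time
#'   constants) are returned unsmoothed.
#' @return numeric vector of speeds (m/s), same length as the input.
#' @export
hand_speed <- function(position, rate, cutoff = 5) {
  position <- .as_mat3(position, "position")
  n <- nrow(position)
  if (n < 3) stop("length error: need at least 3 samples")
  vel <- matrix(0, n, 3)
  vel[2:(n - 1), ] <- (position[3:n, ] - position[1:(n - 2), ]) * rate / 2
  vel[1, ] <- (position[2, ] - position[1, ]) * rate
  vel[n, ] <- (position[n, ] - position[n - 1, ]) * rate
  if (is.finite(cutoff) && cutoff > 0 && cutoff < rate / 2 && n >= 24) {
    vel <- .butter_filtfilt(vel, rate, cutoff / (rate / 2), "low",
                            pad = ceiling(3 * rate / cutoff))
  }
  sqrt(rowSums(vel^2))
}

#' Acceleration correction modes
#'
#' Applies the correction chosen for activity-count computation: `raw`
#' leaves the hand acceleration unchanged, `minus_gravity` subtracts the
#' gravity vector, and `minus_trunk` subtracts the trunk acceleration
#' (which, when the trunk accelerometer measures gravity, also removes
#' gravity). All vectors must be expressed in the trunk frame.
#'
#' @param hand_accel n x 3 matrix of hand accelerations (m/s^2).
#' @param gravity 3-vector or n x 3 matrix (required for `minus_gravity`).
#' @param trunk_accel n x 3 matrix (required for `minus_trunk`).
#' @param mode one of `"raw"`, `"minus_gravity"`, `"minus_trunk"`.
#' @return n x 3 matrix of corrected accelerations.
#' @export
corrected_accel <- function(hand_accel, gravity = NULL, trunk_accel = NULL,
                            mode = c("raw", "minus_gravity", "minus_trunk")) {
  mode <- match.arg(mode)
  hand_accel <- .as_mat3(hand_accel, "hand_accel")
  n <- nrow(hand_accel)
  if (mode == "raw") return(hand_accel)
  if (mode == "minus_gravity") {
    if (is.null(gravity)) stop("parameter error: gravity required")
    if (is.matrix(gravity)) {
      gravity <- .as_mat3(gravity, "gravity")
      if (nrow(gravity) != n)
        stop("alignment error: gravity not aligned to hand_accel")
      return(hand_accel - gravity)
    }
    return(sweep(hand_accel, 2, as.numeric(gravity)))
  }
  if (is.null(trunk_accel)) stop("parameter error: trunk_accel required")
  trunk_accel <- .as_mat3(trunk_accel, "trunk_accel")
  if (nrow(trunk_accel) != n)
    stop("alignment error: trunk_accel not aligned to hand_accel")
  hand_accel - trunk_accel
}
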