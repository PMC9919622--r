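# Per-movement kinematic and EMG metrics, and the bimanual movement
# parameter (BMP) with unimanual/bimanual classification.

# Saturated log-ratio: log(a / b) capped at +/- cap; degenerate inputs
# (either value at or below the floor) saturate with a flag instead of
# evaluating to an infinity.
.log_ratio_capped <- function(a, b, floor, cap) {
  if (a <= floor && b <= floor) return(list(value = 0, flagged = TRUE))
  if (b <= floor) return(list(value = cap, flagged = TRUE))
  if (a <= floor) return(list(value = -cap, flagged = TRUE))
  r <- log(a / b)
  if (r > cap) return(list(value = cap, flagged = TRUE))
  if (r < -cap) return(list(value = -cap, flagged = TRUE))
  list(value = r, flagged = FALSE)
}

#' Path length of a movement
#'
#' Integral of the smoothed speed over the movement (trapezoidal rule),
#' equivalent to the traversed polyline length for clean data but robust to
#' sensor noise on a near-stationary limb.
#'
#' @param position n x 3 matrix of positions for the whole record.
#' @param seg one-row movement (list/row with `n_onset`, `n_termination`),
#'   or explicit `n_onset`/`n_termination` indices.
#' @param rate sampling rate (Hz).
#' @param speed optional precomputed speed for the whole record.
#' @param cutoff speed-smoothing cut-off (Hz).
#' @return path length (m).
#' @export
path_length <- function(position, seg, rate, speed = NULL, cutoff = 5) {
  i0 <- as.integer(seg$n_onset); i1 <- as.integer(seg$n_termination)
  if (is.null(speed)) {
    position <- .as_mat3(position, "position")
    if (i0 < 1 || i1 > nrow(position) || i0 >= i1)
      stop("bounds error: segment outside the record")
    speed <- hand_speed(position, rate, cutoff)
  }
  if (i0 < 1 || i1 > length(speed) || i0 >= i1)
    stop("bounds error: segment outside the record")
  pracma::trapz(speed[i0:i1]) / rate
}

#' Log path-length ratio of a movement
#'
#' `ln(l_uaf / l_af)`; close to zero for bimanual movements. Either length
#' at or below `floor` saturates the ratio at the cap with a flag.
#'
#' @param l_uaf,l_af per-limb path lengths (m).
#' @param floor length floor (m).
#' @param cap saturation cap.
#' @return list with `value` and `flagged`.
#' @export
length_ratio <- function(l_uaf, l_af, floor = 0.001, cap = 6) {
  if (l_uaf < 0 || l_af < 0) stop("domain error: lengths must be nonnegative")
  .log_ratio_capped(l_uaf, l_af, floor, cap)
}

#' Pearson correlation of paired speed profiles
#'
#' Close to one when both limbs accelerate and decelerate together. A
#' degenerate profile (zero variance) gives the flagged neutral value 0 so
#' batch processing stays total.
#'
#' @param speed_uaf,speed_af equal-length speed profiles over the shared
#'   movement window.
#' @return list with `value` (in [-1, 1]) and `flagged`.
#' @export
speed_pcc <- function(speed_uaf, speed_af) {
  if (length(speed_uaf) != length(speed_af))
    stop("alignment error: speed profiles differ in length")
  if (length(speed_uaf) < 2)
    stop("length error: need at least 2 samples")
  if (stats::sd(speed_uaf) == 0 || stats::sd(speed_af) == 0)
    return(list(value = 0, flagged = TRUE))
  list(value = stats::cor(speed_uaf, speed_af), flagged = FALSE)
}

#' Discrete Fréchet distance between scalar sequences
#'
#' Minimum over all monotone couplings of the maximum pointwise distance
#' `|a - b|`, computed by dynamic programming. Applied here to speed
#' profiles, so the value carries speed units; it is zero for identical
#' profiles and grows with shape dissimilarity.
#'
#' @param a,b nonempty numeric sequences.
#' @return the discrete Fréchet distance (same units as the inputs).
#' @examples
#' frechet_distance(c(0, 1), c(0, 2)) # 1
#' @export
frechet_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("length error: sequences must be nonempty")
  prev <- numeric(m)
  prev[1] <- abs(a[1] - b[1])
  if (m > 1) for (j in 2:m) prev[j] <- max(prev[j - 1], abs(a[1] - b[j]))
  if (n > 1) {
    cur <- numeric(m)
    for (i in 2:n) {
      di <- abs(a[i] - b)
      cur[1] <- max(prev[1], di[1])
      if (m > 1) for (j in 2:m) {
        cur[j] <- max(min(prev[j], prev[j - 1], cur[j - 1]), di[j])
      }
      prev <- cur
    }
  }
  prev[m]
}

#' Mean and variance of a speed profile
#'
#' Sample mean and unbiased (n - 1 divisor) sample variance of the speed
#' magnitudes over a movement.
#'
#' @param speed speed profile with at least 2 samples.
#' @return named numeric vector `c(mean, variance)`.
#' @export
speed_variance <- function(speed) {
  if (length(speed) < 2) stop("length error: need at least 2 samples")
  c(mean = mean(speed), variance = stats::var(speed))
}

#' Log speed-variance ratio
#'
#' `ln(v_uaf / v_af)`; close to zero for bimanual movements, saturated with
#' a flag when either variance is degenerate.
#'
#' @param v_uaf,v_af per-limb speed variances.
#' @param floor variance floor.
#' @param cap saturation cap.
#' @return list with `value` and `flagged`.
#' @export
variance_ratio <- function(v_uaf, v_af, floor = 1e-12, cap = 6) {
  if (v_uaf < 0 || v_af < 0) stop("domain error: variances must be nonnegative")
  .log_ratio_capped(v_uaf, v_af, floor, cap)
}

#' Bimanual movement parameter
#'
#' Combines the four coordination criteria into one index:
#' `BMP = 1 - ((1 - pcc)/w_pcc + |rv|/w_rv + f/w_f + |rl|/w_rl) / 4`,
#' clamped to [0, 1]. The default weights (2, 5.5, 1.3, 2.5) scale each
#' criterion by its 95th-percentile magnitude, so a movement at all four
#' caps scores exactly 0 and identical limb profiles score exactly 1.
#'
#' @param pcc speed-profile Pearson correlation.
#' @param rv log speed-variance ratio.
#' @param f discrete Fréchet distance between the speed profiles (m/s).
#' @param rl log path-length ratio.
#' @param weights named weights (`pcc`, `rv`, `f`, `rl`).
#' @return BMP in [0, 1]. Vectorized over movements.
#' @examples
#' bmp(1, 0, 0, 0)                 # 1: perfect bimanual
#' bmp(0.8, 0.55, 0.13, 0.25)      # 0.9
#' bmp(-1, 5.5, 1.3, 2.5)          # 0: every criterion at its cap
#' @export
bmp <- function(pcc, rv, f, rl, weights = c(pcc = 2, rv = 5.5, f = 1.3, rl = 2.5)) {
  if (any(!is.finite(c(pcc, rv, f, rl))))
    stop("domain error: criteria must be finite (saturated values permitted)")
  raw <- 1 - ((1 - pcc) / weights[["pcc"]] + abs(rv) / weights[["rv"]] +
                f / weights[["f"]] + abs(rl) / weights[["rl"]]) / 4
  pmin(1, pmax(0, raw))
}

#' Classify a movement from its BMP
#'
#' Below `low` is unimanual, above `high` bimanual; the closed middle band
#' (boundaries included) is unclassified.
#'
#' @param bmp_value BMP value(s) in [0, 1].
#' @param low,high classification thresholds.
#' @return character vector: `"unimanual"`, `"unclassified"` or
#'   `"bimanual"`.
#' @export
classify_bmp <- function(bmp_value, low = 0.4, high = 0.7) {
  if (any(!is.finite(bmp_value)) || any(bmp_value < 0 | bmp_value > 1))
    stop("domain error: BMP must lie in [0, 1]")
  ifelse(bmp_value < low, "unimanual",
         ifelse(bmp_value > high, "bimanual", "unclassified"))
}

#' Average forearm muscle activity over a movement
#'
#' Time-average over the movement of the summed squared EMG amplitudes of
#' all eight electrodes, on the EMG clock (the kinematic segment bounds are
#' mapped to EMG samples by time).
#'
#' @param emg 8 x m EMG matrix for one limb.
#' @param seg one-row movement with `t_onset`, `t_termination` (s).
#' @param emg_rate EMG sampling rate (Hz).
#' @return scalar W (normalized units squared).
#' @export
movement_emg <- function(emg, seg, emg_rate) {
  emg <- as.matrix(emg)
  if (nrow(emg) != 8) stop("format error: emg must have 8 channels (rows)")
  m <- ncol(emg)
  i0 <- max(1L, as.integer(floor(seg$t_onset * emg_rate)) + 1L)
  i1 <- min(m, as.integer(round(seg$t_termination * emg_rate)) + 1L)
  if (i1 <= i0) stop("bounds error: movement maps to fewer than 2 EMG samples")
  sq <- colSums(emg[, i0:i1, drop = FALSE]^2)
  pracma::trapz(sq) / (i1 - i0)
}

#' Per-movement metric table
#'
#' Computes, for every movement of a shared segmentation, the per-limb path
#' lengths and their log-ratio, the speed-profile correlation, log
#' variance-ratio and discrete Fréchet distance, the BMP with its
#' classification, and (when EMG is present) the per-limb average muscle
#' activity with its log-ratio. Saturated or degenerate criteria are
#' recorded in a `flags` column.
#'
#' @param session a `bilateral_session`.
#' @param segments movement table from [segment_bilateral()] (or
#'   [segment_movements()] run on a shared trajectory).
#' @param config an `analysis_config`.
#' @return data frame of class `movement_metrics`, one row per movement.
#' @export
movement_metrics <- function(session, segments, config = analysis_config()) {
  cfg <- validate_config(config)
  validate_session(session)
  rate <- session$kin_rate
  su <- hand_speed(session$uaf$position, rate, cfg$speed_cutoff)
  sa <- hand_speed(session$af$position, rate, cfg$speed_cutoff)
  has_emg <- !is.null(session$uaf$emg)
  nseg <- nrow(segments)
  rows <- vector("list", nseg)
  for (k in seq_len(nseg)) {
    seg <- segments[k, ]
    i0 <- seg$n_onset; i1 <- seg$n_termination
    spu <- su[i0:i1]; spa <- sa[i0:i1]
    lu <- pracma::trapz(spu) / rate
    la <- pracma::trapz(spa) / rate
    rl <- length_ratio(lu, la, cfg$length_floor, cfg$rl_cap)
    pcc <- speed_pcc(spu, spa)
    vu <- speed_variance(spu)[["variance"]]
    va <- speed_variance(spa)[["variance"]]
    rv <- variance_ratio(vu, va, cap = cfg$rl_cap)
    f <- frechet_distance(spu, spa)
    b <- bmp(pcc$value, rv$value, f, rl$value, cfg$weights)
    cls <- classify_bmp(b, cfg$bmp_low, cfg$bmp_high)
    wu <- wa <- NA_real_
    rw <- list(value = NA_real_, flagged = FALSE)
    if (has_emg) {
      wu <- movement_emg(session$uaf$emg, seg, session$uaf$emg_rate)
      wa <- movement_emg(session$af$emg, seg, session$af$emg_rate)
      rw <- .log_ratio_capped(wu, wa, 0, cfg$rw_cap)
    }
    flags <- c(if (rl$flagged) "rl_saturated",
               if (pcc$flagged) "pcc_degenerate",
               if (rv$flagged) "rv_saturated",
               if (rw$flagged) "rw_saturated")
    rows[[k]] <- data.frame(
      index = seg$index, n_onset = i0, n_termination = i1,
      t_onset = seg$t_onset, t_termination = seg$t_termination,
      l_uaf = lu, l_af = la, rl = rl$value, pcc = pcc$value,
      rv = rv$value, f = f, bmp = b, movement_class = cls,
      w_uaf = wu, w_af = wa, rw = rw$value,
      flags = paste(flags, collapse = ";"))
  }
  out <- if (nseg == 0) {
    data.frame(index = integer(0), n_onset = integer(0),
               n_termination = integer(0), t_onset = numeric(0),
               t_termination = numeric(0), l_uaf = numeric(0),
               l_af = numeric(0), rl = numeric(0), pcc = numeric(0),
               rv = numeric(0), f = numeric(0), bmp = numeric(0),
               movement_class = character(0), w_uaf = numeric(0),
               w_af = numeric(0), rw = numeric(0), flags = character(0))
  } else do.call(rbind, rows)
  class(out) <- c("movement_metrics", "data.frame")
  out
}
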