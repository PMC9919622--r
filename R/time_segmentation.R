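# Time-based segmentation: fixed-duration quants with activity counts,
# muscle activity counts, their log-ratios, dwell-time grids and windowed
# path-length ratios.

# Samples per quant; T*rate must land on the sample grid so quant edges are
# exact (0.25 s x 80 Hz = 20 samples; 0.25 s x 200 Hz = 50 samples).
.quant_samples <- function(rate, T) {
  if (!(T > 0)) stop("parameter error: T must be > 0")
  np <- T * rate
  if (abs(np - round(np)) > 1e-9)
    stop("parameter error: T * rate = ", np,
         " is not an integer; quant edges must snap to samples")
  as.integer(round(np))
}

# Mean of y over successive quants of np intervals, by the trapezoidal rule
# on the native grid. Boundary samples are shared between adjacent quants.
.quant_means <- function(y, rate, np) {
  n <- length(y)
  q <- (n - 1) %/% np
  if (q < 1) stop("length error: record shorter than one quant")
  ct <- c(0, cumsum((y[-1] + y[-n]) / 2)) / rate
  edges <- seq(1L, by = np, length.out = q + 1L)
  diff(ct[edges]) / (np / rate)
}

#' Accelerometer activity counts per time quant
#'
#' The activity count of quant i is the time-average of the corrected,
#' band-passed hand-acceleration norm over that quant (trapezoidal
#' integration on the native sample grid). A trailing partial quant is
#' discarded.
#'
#' @param accel the corrected and band-passed acceleration: a
#'   `filtered_signal`, an n x 3 matrix (norm taken per sample), or a
#'   numeric vector of precomputed norms.
#' @param rate sampling rate (Hz).
#' @param T quant duration (s); `T * rate` must be an integer.
#' @return numeric vector of activity counts (m/s^2), one per full quant.
#' @export
activity_counts <- function(accel, rate, T) {
  if (inherits(accel, "filtered_signal")) {
    rate <- accel$rate
    accel <- accel$values
  }
  nrm <- if (is.matrix(accel)) sqrt(rowSums(accel^2)) else abs(as.numeric(accel))
  np <- .quant_samples(rate, T)
  .quant_means(nrm, rate, np)
}

#' Sum and log-ratio of paired activity counts
#'
#' Combines the two limbs' counts for a quant into their sum (total
#' intensity) and the offset log-ratio `ln((uaf + 1) / (af + 1))`. The +1
#' offset keeps the ratio defined for idle quants and tames the positive
#' skew of untransformed ratios. Vectorized over quants.
#'
#' @param count_uaf,count_af nonnegative counts for the unaffected/dominant
#'   and affected/non-dominant limb.
#' @return list with numeric vectors `sum` and `ratio`.
#' @examples
#' count_ratio(2, 2)           # ratio 0
#' count_ratio(exp(1) - 1, 0)  # ratio 1
#' @export
count_ratio <- function(count_uaf, count_af) {
  if (any(count_uaf < 0) || any(count_af < 0))
    stop("domain error: counts must be nonnegative")
  list(sum = count_uaf + count_af,
       ratio = log((count_uaf + 1) / (count_af + 1)))
}

#' Muscle activity counts per time quant
#'
#' The muscle activity count of quant i is the time-average over the quant
#' of the sum of squared EMG amplitudes across the selected electrodes,
#' integrated on the EMG clock (no resampling to the kinematic clock).
#'
#' @param emg 8 x m matrix of normalized EMG amplitudes.
#' @param rate EMG sampling rate (Hz).
#' @param T quant duration (s); `T * rate` must be an integer.
#' @param electrodes nonempty subset of 1..8 (all eight for total forearm
#'   activity; 4-element groups for flexors/extensors).
#' @return numeric vector (normalized units squared), one per full quant.
#' @export
muscle_counts <- function(emg, rate, T, electrodes = 1:8) {
  emg <- as.matrix(emg)
  if (nrow(emg) != 8) stop("format error: emg must have 8 channels (rows)")
  electrodes <- as.integer(electrodes)
  if (length(electrodes) == 0 || !all(electrodes %in% 1:8))
    stop("parameter error: electrodes must be a nonempty subset of 1..8")
  sq <- colSums(emg[electrodes, , drop = FALSE]^2)
  np <- .quant_samples(rate, T)
  .quant_means(sq, rate, np)
}

#' Per-quant table for a session
#'
#' Runs the full time-based track on a session: per-limb activity counts in
#' the chosen correction mode (subtract, then band-pass, then norm), their
#' sum and log-ratio, and — when EMG is present — muscle activity counts for
#' the chosen electrode set with their sum and log-ratio. The number of
#' quants is limited by the shorter of the kinematic and EMG records.
#'
#' @param session a `bilateral_session`.
#' @param config an `analysis_config`.
#' @param mode acceleration correction mode (see [corrected_accel()]).
#' @param electrodes electrode set for muscle counts (default all eight).
#' @return data frame with one row per quant: `index`, `t_start`, `t_end`,
#'   `ac_uaf`, `ac_af`, `ac_sum`, `rac`, and `mc_uaf`, `mc_af`, `mc_sum`,
#'   `rmc` (NA without EMG).
#' @export
time_segments <- function(session, config = analysis_config(),
                          mode = c("raw", "minus_gravity", "minus_trunk"),
                          electrodes = 1:8) {
  mode <- match.arg(mode)
  validate_session(session)
  cfg <- validate_config(config)
  rate <- session$kin_rate
  ac <- lapply(list(session$uaf, session$af), function(limb) {
    corr <- corrected_accel(limb$hand_accel, gravity = session$gravity,
                            trunk_accel = session$trunk_accel, mode = mode)
    filt <- bandpass(corr, rate, cfg$band_lo, cfg$band_hi)
    activity_counts(filt, rate, cfg$T)
  })
  q <- length(ac[[1]])
  mc_uaf <- mc_af <- rep(NA_real_, q)
  if (!is.null(session$uaf$emg)) {
    mu <- muscle_counts(session$uaf$emg, session$uaf$emg_rate, cfg$T, electrodes)
    ma <- muscle_counts(session$af$emg, session$af$emg_rate, cfg$T, electrodes)
    q <- min(q, length(mu), length(ma))
    mc_uaf <- mu[seq_len(q)]
    mc_af <- ma[seq_len(q)]
  }
  acr <- count_ratio(ac[[1]][seq_len(q)], ac[[2]][seq_len(q)])
  out <- data.frame(index = seq_len(q),
                    t_start = (seq_len(q) - 1) * cfg$T,
                    t_end = seq_len(q) * cfg$T,
                    ac_uaf = ac[[1]][seq_len(q)], ac_af = ac[[2]][seq_len(q)],
                    ac_sum = acr$sum, rac = acr$ratio,
                    mc_uaf = mc_uaf[seq_len(q)], mc_af = mc_af[seq_len(q)],
                    mc_sum = NA_real_, rmc = NA_real_)
  if (!is.null(session$uaf$emg)) {
    mcr <- count_ratio(out$mc_uaf, out$mc_af)
    out$mc_sum <- mcr$sum
    out$rmc <- mcr$ratio
  }
  out
}

#' Dwell-time grid of intensity versus log-ratio
#'
#' Each quant contributes `T` seconds of dwell to exactly one 2-D bin
#' (log-ratio x intensity); quants outside the binning range are clipped to
#' the edge bins, so total dwell is conserved exactly.
#'
#' @param sums per-quant intensity values (activity-count or muscle-count
#'   sums).
#' @param ratios per-quant log-ratios, same length as `sums`.
#' @param T quant duration (s).
#' @param ratio_edges,intensity_edges strictly increasing bin boundaries.
#' @return an `activity_grid`: list with `ratio_edges`, `intensity_edges`
#'   and a dwell matrix (seconds; ratio bins in rows).
#' @export
activity_grid <- function(sums, ratios, T,
                          ratio_edges = seq(-6, 6, length.out = 61),
                          intensity_edges = NULL) {
  if (length(sums) != length(ratios))
    stop("alignment error: sums and ratios differ in length")
  if (is.null(intensity_edges)) {
    hi <- stats::quantile(sums, 0.99, names = FALSE)
    if (!(hi > 0)) hi <- max(sums, 1e-12)
    intensity_edges <- seq(0, hi, length.out = 61)
  }
  if (any(diff(ratio_edges) <= 0) || any(diff(intensity_edges) <= 0))
    stop("parameter error: bin edges must be strictly increasing")
  ri <- findInterval(ratios, ratio_edges, all.inside = TRUE)
  ii <- findInterval(sums, intensity_edges, all.inside = TRUE)
  dwell <- matrix(0, length(ratio_edges) - 1, length(intensity_edges) - 1)
  for (k in seq_along(ri)) dwell[ri[k], ii[k]] <- dwell[ri[k], ii[k]] + T
  structure(list(ratio_edges = ratio_edges,
                 intensity_edges = intensity_edges, dwell = dwell),
            class = "activity_grid")
}

#' Long-format export of an activity grid
#'
#' @param grid an `activity_grid`.
#' @return data frame with `ratio_bin`, `intensity_bin` (left edges and bin
#'   index) and `dwell_s`.
#' @export
grid_to_df <- function(grid) {
  stopifnot(inherits(grid, "activity_grid"))
  nr <- nrow(grid$dwell); ni <- ncol(grid$dwell)
  data.frame(ratio_bin = rep(seq_len(nr), times = ni),
             ratio_left = rep(grid$ratio_edges[seq_len(nr)], times = ni),
             intensity_bin = rep(seq_len(ni), each = nr),
             intensity_left = rep(grid$intensity_edges[seq_len(ni)], each = nr),
             dwell_s = as.vector(grid$dwell))
}

#' Windowed path-length log-ratios
#'
#' Splits the session into fixed windows (default 1, 3 or 5 s), computes
#' each limb's traversed path length inside the window as the integral of
#' the smoothed speed, and returns `ln(L_uaf / L_af)` per window. Windows in
#' which either limb moved less than `eps` are marked invalid (ratio NA)
#' rather than evaluated to an infinite ratio; a trailing partial window is
#' discarded.
#'
#' @param pos_uaf,pos_af n x 3 position matrices on a shared clock.
#' @param rate sampling rate (Hz).
#' @param period window length (s).
#' @param eps validity floor on the window path length (m).
#' @param cutoff speed-smoothing cut-off (Hz), see [hand_speed()].
#' @return data frame with `window`, `t_start`, `t_end`, `l_uaf`, `l_af`,
#'   `ratio`, `valid`.
#' @export
windowed_length_ratio <- function(pos_uaf, pos_af, rate, period,
                                  eps = 0.001, cutoff = 5) {
  if (!(period > 0)) stop("parameter error: period must be > 0")
  pos_uaf <- .as_mat3(pos_uaf, "pos_uaf")
  pos_af <- .as_mat3(pos_af, "pos_af")
  if (nrow(pos_uaf) != nrow(pos_af))
    stop("alignment error: limb position lengths differ")
  np <- .quant_samples(rate, period)
  n <- nrow(pos_uaf)
  q <- (n - 1) %/% np
  if (q < 1) stop("length error: record shorter than one window")
  lens <- lapply(list(pos_uaf, pos_af), function(p) {
    s <- hand_speed(p, rate, cutoff)
    ct <- c(0, cumsum((s[-1] + s[-n]) / 2)) / rate
    edges <- seq(1L, by = np, length.out = q + 1L)
    diff(ct[edges])
  })
  valid <- lens[[1]] >= eps & lens[[2]] >= eps
  ratio <- ifelse(valid, log(lens[[1]] / lens[[2]]), NA_real_)
  data.frame(window = seq_len(q),
             t_start = (seq_len(q) - 1) * period,
             t_end = seq_len(q) * period,
             l_uaf = lens[[1]], l_af = lens[[2]],
             ratio = ratio, valid = valid)
}
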