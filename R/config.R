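#' Analysis configuration
#'
#' Builds the configuration object shared by both analysis tracks. All
#' defaults follow the methodology the package implements: 0.25 s time
#' quants, a 0.25--2.5 Hz band-pass for activity counts, a 50 mm minimum
#' movement length, and the BMP criterion weights 2 / 5.5 / 1.3 / 2.5 with
#' classification thresholds 0.4 and 0.7.
#'
#' @param T time-quant duration in seconds.
#' @param band_lo,band_hi band-pass cut-off frequencies (Hz) applied to hand
#'   acceleration before activity counts.
#' @param min_movement_length minimum path length (m) for a candidate segment
#'   to count as a completed movement.
#' @param arc_step arc-length resampling step (m) used by the direction-change
#'   detector.
#' @param heading_window arc-length window (m) over which tangent directions
#'   are averaged on each side of a candidate direction-change point.
#' @param heading_threshold heading rotation (degrees) between adjacent
#'   tangent windows that splits a trajectory. Must be below 60 degrees so
#'   that the 120-degree interior angle of a regular hexagon (a 60-degree
#'   heading change) is detected.
#' @param rest_speed speed threshold (m/s) below which the hand is considered
#'   at rest. The default sits above the speed-noise floor produced by
#'   differentiating millimetre-level position noise at 80 Hz.
#' @param rest_min_duration minimum duration (s) of a sub-threshold span for
#'   it to count as rest.
#' @param speed_cutoff low-pass cut-off (Hz) for the smoothed speed estimate.
#' @param heading_smooth_cutoff low-pass cut-off (Hz) applied to positions
#'   before direction-change analysis; kept above `speed_cutoff` so corners
#'   are not rounded away while arc-scale sensor noise is suppressed.
#' @param weights named numeric vector of BMP criterion weights
#'   (`pcc`, `rv`, `f`, `rl`).
#' @param bmp_low,bmp_high classification thresholds: BMP below `bmp_low` is
#'   unimanual, above `bmp_high` bimanual, in between unclassified.
#' @param flexor_electrodes,extensor_electrodes disjoint 4-element subsets of
#'   1..8 assigning armband electrodes to forearm muscle groups.
#' @param windowed_periods window lengths (s) for windowed path-length ratios.
#' @param length_floor path length (m) below which a log length ratio is
#'   saturated rather than evaluated.
#' @param rl_cap,rw_cap saturation caps for log-ratios with degenerate
#'   denominators (dimensionless).
#' @param grid_ratio_range range of the ratio axis of activity grids.
#' @param grid_bins number of bins per axis of activity grids.
#' @param emg_scale full-scale divisor applied to EMG samples at read time
#'   (1 for already-normalized data; 128 for raw 8-bit armband exports).
#'
#' @return an object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$T
#' @export
analysis_config <- function(T = 0.25,
                            band_lo = 0.25, band_hi = 2.5,
                            min_movement_length = 0.05,
                            arc_step = 0.01,
                            heading_window = 0.02,
                            heading_threshold = 45,
                            rest_speed = 0.05,
                            rest_min_duration = 0.2,
                            speed_cutoff = 5,
                            heading_smooth_cutoff = 10,
                            weights = c(pcc = 2, rv = 5.5, f = 1.3, rl = 2.5),
                            bmp_low = 0.4, bmp_high = 0.7,
                            flexor_electrodes = 1:4,
                            extensor_electrodes = 5:8,
                            windowed_periods = c(1, 3, 5),
                            length_floor = 0.001,
                            rl_cap = 6, rw_cap = 6,
                            grid_ratio_range = c(-6, 6),
                            grid_bins = 60,
                            emg_scale = 1) {
  cfg <- list(T = T, band_lo = band_lo, band_hi = band_hi,
              min_movement_length = min_movement_length,
              arc_step = arc_step,
              heading_window = heading_window,
              heading_threshold = heading_threshold,
              rest_speed = rest_speed,
              rest_min_duration = rest_min_duration,
              speed_cutoff = speed_cutoff,
              heading_smooth_cutoff = heading_smooth_cutoff,
              weights = weights,
              bmp_low = bmp_low, bmp_high = bmp_high,
              flexor_electrodes = as.integer(flexor_electrodes),
              extensor_electrodes = as.integer(extensor_electrodes),
              windowed_periods = windowed_periods,
              length_floor = length_floor,
              rl_cap = rl_cap, rw_cap = rw_cap,
              grid_ratio_range = grid_ratio_range,
              grid_bins = as.integer(grid_bins),
              emg_scale = emg_scale)
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

#' Validate an analysis configuration
#'
#' @param cfg an `analysis_config` object (or plain list with the same fields).
#' @return the validated object, invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!(is.numeric(cfg$T) && length(cfg$T) == 1 && cfg$T > 0))
    stop("config error: T must be a positive scalar (seconds)")
  if (!(cfg$band_lo > 0 && cfg$band_lo < cfg$band_hi))
    stop("config error: need 0 < band_lo < band_hi")
  if (cfg$min_movement_length <= 0)
    stop("config error: min_movement_length must be > 0")
  if (cfg$arc_step <= 0) stop("config error: arc_step must be > 0")
  if (cfg$heading_threshold <= 0 || cfg$heading_threshold >= 180)
    stop("config error: heading_threshold must be in (0, 180) degrees")
  if (cfg$rest_speed <= 0) stop("config error: rest_speed must be > 0")
  if (cfg$rest_min_duration <= 0)
    stop("config error: rest_min_duration must be > 0")
  if (cfg$heading_smooth_cutoff <= 0)
    stop("config error: heading_smooth_cutoff must be > 0")
  w <- cfg$weights
  if (!all(c("pcc", "rv", "f", "rl") %in% names(w)) || any(w <= 0))
    stop("config error: weights must be positive and named pcc, rv, f, rl")
  if (!(cfg$bmp_low >= 0 && cfg$bmp_low < cfg$bmp_high && cfg$bmp_high <= 1))
    stop("config error: need 0 <= bmp_low < bmp_high <= 1")
  fe <- cfg$flexor_electrodes; ee <- cfg$extensor_electrodes
  if (length(fe) != 4 || length(ee) != 4 ||
      !all(c(fe, ee) %in% 1:8) || length(intersect(fe, ee)) > 0)
    stop("config error: electrode groups must be disjoint 4-element subsets of 1..8")
  if (any(cfg$windowed_periods <= 0))
    stop("config error: windowed_periods must be positive")
  if (cfg$length_floor <= 0) stop("config error: length_floor must be > 0")
  if (cfg$rl_cap <= 0 || cfg$rw_cap <= 0)
    stop("config error: saturation caps must be > 0")
  if (diff(cfg$grid_ratio_range) <= 0)
    stop("config error: grid_ratio_range must be increasing")
  if (cfg$grid_bins < 1) stop("config error: grid_bins must be >= 1")
  if (cfg$emg_scale <= 0) stop("config error: emg_scale must be > 0")
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unstated fields fall back to the package defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- analysis_config()
  known <- names(base)
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$weights)) vals$weights <- unlist(vals$weights)
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML or JSON
#'
#' @param cfg an `analysis_config`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  out$weights <- as.list(out$weights)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
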