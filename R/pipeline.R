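# Batch pipeline entry points shared by the command-line front end:
# time-based analysis, path-based analysis, hexagon validation and
# session simulation. Every run writes a machine-readable manifest.

.pkg_version <- function() {
  as.character(utils::packageVersion("limbuse"))
}

.write_manifest <- function(outdir, entries) {
  manifest <- c(list(tool = "limbuse", version = .pkg_version(),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                entries)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.config_for_manifest <- function(cfg) {
  out <- unclass(cfg)
  out$weights <- as.list(out$weights)
  out
}

.resolve_session <- function(session, kin_path, emg_path, emg_scale) {
  if (!is.null(session)) return(validate_session(session))
  read_session(kin_path, emg_path, emg_scale = emg_scale)
}

#' Run the time-based analysis track
#'
#' Quantizes the session and writes per-quant tables for every acceleration
#' correction mode, dwell-time grids for activity counts (three modes) and
#' muscle counts (total / flexor / extensor electrode sets), and windowed
#' path-length ratio tables, plus a JSON run manifest.
#'
#' @param kin_path,emg_path input CSVs (see [read_session()]); alternatively
#'   pass a ready `session`.
#' @param outdir output directory (created if needed).
#' @param config an `analysis_config`.
#' @param session optional `bilateral_session` overriding the file inputs.
#' @return invisibly, a list with `status`, `outdir`, `files` and counts.
#' @export
run_time_analysis <- function(kin_path = NULL, emg_path = NULL, outdir,
                              config = analysis_config(), session = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- validate_config(config)
  res <- tryCatch({
    session <- .resolve_session(session, kin_path, emg_path, cfg$emg_scale)
    files <- character(0)
    n_quants <- NA_integer_
    for (mode in c("raw", "minus_gravity", "minus_trunk")) {
      ts <- time_segments(session, cfg, mode = mode)
      n_quants <- nrow(ts)
      f <- file.path(outdir, paste0("quants_", mode, ".csv"))
      utils::write.csv(ts, f, row.names = FALSE)
      g <- activity_grid(ts$ac_sum, ts$rac, cfg$T,
                         ratio_edges = seq(cfg$grid_ratio_range[1],
                                           cfg$grid_ratio_range[2],
                                           length.out = cfg$grid_bins + 1))
      fg <- file.path(outdir, paste0("grid_ac_", mode, ".csv"))
      utils::write.csv(grid_to_df(g), fg, row.names = FALSE)
      files <- c(files, f, fg)
    }
    if (!is.null(session$uaf$emg)) {
      sets <- list(total = 1:8, flexor = cfg$flexor_electrodes,
                   extensor = cfg$extensor_electrodes)
      for (nm in names(sets)) {
        ts <- time_segments(session, cfg, mode = "minus_trunk",
                            electrodes = sets[[nm]])
        g <- activity_grid(ts$mc_sum, ts$rmc, cfg$T,
                           ratio_edges = seq(cfg$grid_ratio_range[1],
                                             cfg$grid_ratio_range[2],
                                             length.out = cfg$grid_bins + 1))
        f <- file.path(outdir, paste0("grid_mc_", nm, ".csv"))
        utils::write.csv(grid_to_df(g), f, row.names = FALSE)
        files <- c(files, f)
      }
    }
    for (p in cfg$windowed_periods) {
      wl <- windowed_length_ratio(session$uaf$position,
                                  session$af$position,
                                  session$kin_rate, p,
                                  cutoff = cfg$speed_cutoff)
      f <- file.path(outdir, sprintf("windowed_ratio_%gs.csv", p))
      utils::write.csv(wl, f, row.names = FALSE)
      files <- c(files, f)
    }
    .write_manifest(outdir, list(
      stage = "time_analysis", status = "ok",
      inputs = list(kin = kin_path, emg = emg_path),
      config = .config_for_manifest(cfg),
      counts = list(n_samples = session$n_samples, n_quants = n_quants),
      outputs = as.list(basename(files))))
    list(status = 0L, outdir = outdir, files = files, n_quants = n_quants)
  }, error = function(e) {
    .write_manifest(outdir, list(stage = "time_analysis", status = "error",
                                 inputs = list(kin = kin_path,
                                               emg = emg_path),
                                 error = conditionMessage(e)))
    stop(e)
  })
  invisible(res)
}

#' Run the path-based analysis track
#'
#' Segments the session into completed movements (shared bilateral
#' segmentation on the composite speed), computes per-movement metrics and
#' the BMP classification, and writes the movement-interval table, the
#' per-movement metric table, log-ratio distribution summaries, the
#' bimanual/unimanual proportion table and a manifest. A session with no
#' detected movements exits successfully with a warning recorded in the
#' manifest.
#'
#' @inheritParams run_time_analysis
#' @return invisibly, a list with `status`, `outdir`, `files`, `metrics`.
#' @export
run_path_analysis <- function(kin_path = NULL, emg_path = NULL, outdir,
                              config = analysis_config(), session = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- validate_config(config)
  res <- tryCatch({
    session <- .resolve_session(session, kin_path, emg_path, cfg$emg_scale)
    segs <- segment_bilateral(session, cfg)
    metrics <- movement_metrics(session, segs, cfg)
    files <- file.path(outdir, "movement_intervals.csv")
    utils::write.csv(segs, files[1], row.names = FALSE)
    f_mov <- file.path(outdir, "movements.csv")
    write_movements(metrics, f_mov)
    files <- c(files, f_mov)
    warn <- NULL
    if (nrow(metrics) > 0) {
      summarize <- function(v, fl) {
        tryCatch(dist_summary(v, fl), error = function(e) NULL)
      }
      flg <- function(tag) grepl(tag, metrics$flags)
      sums <- list(RL = summarize(metrics$rl, flg("rl_saturated")),
                   RV = summarize(metrics$rv, flg("rv_saturated")),
                   RW = summarize(metrics$rw, flg("rw_saturated")),
                   BMP = summarize(metrics$bmp, rep(FALSE, nrow(metrics))))
      rows <- lapply(names(sums), function(nm) {
        s <- sums[[nm]]
        if (is.null(s)) return(NULL)
        data.frame(parameter = nm, kurtosis = s$kurtosis, mean = s$mean,
                   sd = s$sd, n = s$n, n_flagged_excluded = s$n_flagged_excluded)
      })
      f_sum <- file.path(outdir, "distribution_summaries.csv")
      utils::write.csv(do.call(rbind, rows), f_sum, row.names = FALSE)
      f_tab <- file.path(outdir, "bimanual_table.csv")
      utils::write.csv(bimanual_table(metrics), f_tab, row.names = FALSE)
      f_hist <- file.path(outdir, "rl_histogram.csv")
      utils::write.csv(ratio_histogram(metrics$rl), f_hist,
                       row.names = FALSE)
      files <- c(files, f_sum, f_tab, f_hist)
    } else {
      warn <- "no movements detected"
    }
    .write_manifest(outdir, list(
      stage = "path_analysis", status = "ok", warning = warn,
      inputs = list(kin = kin_path, emg = emg_path),
      config = .config_for_manifest(cfg),
      counts = list(n_samples = session$n_samples,
                    n_movements = nrow(metrics)),
      outputs = as.list(basename(files))))
    list(status = 0L, outdir = outdir, files = files, metrics = metrics)
  }, error = function(e) {
    .write_manifest(outdir, list(stage = "path_analysis", status = "error",
                                 inputs = list(kin = kin_path,
                                               emg = emg_path),
                                 error = conditionMessage(e)))
    stop(e)
  })
  invisible(res)
}

#' Validate path-based segmentation on a hexagon-tracing task
#'
#' Generates a hexagon-tracing trajectory with a known stroke count, runs
#' path-based segmentation and reports the detected movement count and the
#' percent error against ground truth.
#'
#' @param side hexagon side length (m).
#' @param n_circuits number of circuits (6 strokes each).
#' @param stroke_duration seconds per side.
#' @param noise_sd position noise SD (m).
#' @param seed generator seed (used when `noise_sd > 0`).
#' @param config an `analysis_config`.
#' @param outdir optional output directory for the report and manifest.
#' @param profile speed profile along the sides (see [hexagon_trace()]).
#' @return list with `generated`, `detected`, `percent_error` and the
#'   movement table.
#' @export
run_validation <- function(side = 0.05, n_circuits = 20,
                           stroke_duration = 1, noise_sd = 0, seed = 1,
                           config = analysis_config(), outdir = NULL,
                           profile = "minjerk") {
  cfg <- validate_config(config)
  hex <- hexagon_trace(side, n_circuits, stroke_duration,
                       profile = profile, noise_sd = noise_sd, seed = seed)
  segs <- segment_movements(hex$position, hex$rate, cfg)
  detected <- nrow(segs)
  pct <- 100 * abs(detected - hex$n_strokes) / hex$n_strokes
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    report <- data.frame(side_m = side, generated = hex$n_strokes,
                         detected = detected, percent_error = pct)
    utils::write.csv(report, file.path(outdir, "validation.csv"),
                     row.names = FALSE)
    utils::write.csv(segs, file.path(outdir, "movement_intervals.csv"),
                     row.names = FALSE)
    .write_manifest(outdir, list(
      stage = "validation", status = "ok",
      config = .config_for_manifest(cfg),
      seed = seed,
      counts = list(generated = hex$n_strokes, detected = detected),
      outputs = list("validation.csv", "movement_intervals.csv")))
  }
  list(generated = hex$n_strokes, detected = detected,
       percent_error = pct, segments = segs)
}

#' Simulate a session and write it in the session CSV schema
#'
#' @param spec a `scenario_spec`.
#' @param outdir output directory.
#' @param active_limb active limb for unimanual scenarios.
#' @return invisibly, the generated session bundle with file paths.
#' @export
run_simulation <- function(spec, outdir, active_limb = "uaf") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(inherits(spec, "scenario_spec"))
  gen <- switch(spec$kind,
                bimanual_symmetric = bimanual_session(spec),
                mixed = bimanual_session(spec),
                unimanual = unimanual_session(spec, active_limb),
                hexagon = stop("parameter error: use run_validation() for hexagon scenarios"))
  kin <- file.path(outdir, "kinematics.csv")
  emg <- file.path(outdir, "emg.csv")
  write_session(gen$session, kin, emg)
  gt <- file.path(outdir, "ground_truth.csv")
  utils::write.csv(gen$truth, gt, row.names = FALSE)
  .write_manifest(outdir, list(
    stage = "simulation", status = "ok",
    seed = spec$seed,
    scenario = unclass(spec),
    counts = list(n_samples = gen$session$n_samples,
                  n_strokes = spec$n_strokes),
    outputs = list(basename(kin), basename(emg), basename(gt))))
  invisible(c(gen, list(files = c(kin, emg, gt))))
}
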