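# Path-based segmentation: split a continuous hand trajectory into completed
# movements using rest detection on the smoothed speed, direction-change
# detection on the arc-length-resampled path, and a minimum-length floor.

#' Arc-length parametrization of a trajectory
#'
#' Separates form from speed: the trajectory is re-expressed as a function
#' of traversed path length and resampled piecewise-linearly at uniform arc
#' increments. Zero-length steps (rest) are collapsed before interpolation.
#'
#' @param position n x 3 matrix of positions (m); at least 2 samples.
#' @param arc_step resampling step (m).
#' @return an `arc_path`: list with `cumulative_s` (per original sample),
#'   `points` (resampled positions), `s` (arc position of each resampled
#'   point), `sample_of_point` (nearest original sample index per resampled
#'   point) and `arc_step`.
#' @export
arclength_resample <- function(position, arc_step) {
  if (!(arc_step > 0)) stop("parameter error: arc_step must be > 0")
  position <- .as_mat3(position, "position")
  n <- nrow(position)
  if (n < 2) stop("length error: need at least 2 samples")
  d <- sqrt(rowSums((position[-1, , drop = FALSE] -
                     position[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(d))
  total <- cum[n]
  if (total <= arc_step * 1e-9) {
    return(structure(list(cumulative_s = cum,
                          points = position[1, , drop = FALSE],
                          s = 0, sample_of_point = 1L, arc_step = arc_step),
                     class = "arc_path"))
  }
  keep <- c(TRUE, d > 0)           # strictly increasing support for interp
  cs <- cum[keep]
  ps <- position[keep, , drop = FALSE]
  idx <- which(keep)
  s_grid <- seq(0, by = arc_step,
                length.out = floor(total / arc_step + 1e-9) + 1)
  pts <- vapply(1:3, function(k) {
    stats::approx(cs, ps[, k], xout = s_grid, ties = "ordered")$y
  }, numeric(length(s_grid)))
  if (!is.matrix(pts)) pts <- matrix(pts, nrow = 1)
  lo <- findInterval(s_grid, cs, all.inside = TRUE)
  nearer_hi <- (s_grid - cs[lo]) > (cs[lo + 1] - s_grid)
  samp <- idx[ifelse(nearer_hi, lo + 1L, lo)]
  structure(list(cumulative_s = cum, points = pts, s = s_grid,
                 sample_of_point = as.integer(samp), arc_step = arc_step),
            class = "arc_path")
}

# Heading-change boundaries inside one active interval of one trajectory.
# Tangents of the arc-resampled path are averaged over `heading_window`
# metres on each side of a candidate point; local maxima of the angle
# between the two mean tangents that exceed the threshold are boundaries.
# Returns global sample indices.
.heading_boundaries <- function(position, i0, i1, cfg) {
  if (i1 - i0 < 2) return(integer(0))
  ap <- arclength_resample(position[i0:i1, , drop = FALSE], cfg$arc_step)
  npts <- nrow(ap$points)
  w <- max(1L, as.integer(round(cfg$heading_window / cfg$arc_step)))
  ntan <- npts - 1
  if (ntan < 2 * w + 1) return(integer(0))
  g <- 1L                               # one-step gap absorbs corner rounding
  if (ntan < 2 * (w + g) + 1) return(integer(0))
  tang <- ap$points[-1, , drop = FALSE] - ap$points[-npts, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  jj <- (w + g + 1):(ntan - w - g + 1)  # candidate resampled-point indices
  ang <- vapply(jj, function(j) {
    before <- colMeans(tang[(j - w - g):(j - 1 - g), , drop = FALSE])
    after <- colMeans(tang[(j + g):(j + w - 1 + g), , drop = FALSE])
    cosang <- sum(before * after) /
      sqrt(sum(before^2) * sum(after^2))
    acos(min(1, max(-1, cosang)))
  }, numeric(1))
  thr <- cfg$heading_threshold * pi / 180
  k <- length(ang)
  if (k == 0) return(integer(0))
  is_peak <- ang > thr &
    ang >= c(-Inf, ang[-k]) & ang >= c(ang[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))
  # greedy non-maximum suppression: keep strongest peaks at least two
  # heading windows apart in arc length
  ord <- cand[order(ang[cand], decreasing = TRUE)]
  min_sep <- 2 * cfg$heading_window - 1e-9
  kept <- numeric(0)
  kept_s <- numeric(0)
  for (c0 in ord) {
    s0 <- ap$s[jj[c0]]
    if (all(abs(s0 - kept_s) >= min_sep)) {
      kept <- c(kept, c0)
      kept_s <- c(kept_s, s0)
    }
  }
  raw <- i0 - 1L + ap$sample_of_point[jj[kept]]
  # refine each boundary to the true corner: the arc resampling quantizes
  # peak location to the arc step, which can misplace the boundary by
  # several samples; within +/- 1.5 arc steps pick the sample maximizing
  # the angle between the incoming and outgoing chords of one heading
  # window
  cum <- ap$cumulative_s
  refined <- vapply(raw, function(m) {
    sm <- cum[m - i0 + 1L]
    wnd <- which(abs(cum - sm) <= 1.5 * cfg$arc_step)
    if (length(wnd) < 2) return(m)
    best <- m; best_ang <- -Inf
    for (i in wnd) {
      a <- findInterval(cum[i] - cfg$heading_window, cum) + 1L
      b <- findInterval(cum[i] + cfg$heading_window, cum)
      a <- max(1L, min(a, i - 1L)); b <- min(length(cum), max(b, i + 1L))
      u <- position[i0 - 1L + i, ] - position[i0 - 1L + a, ]
      v <- position[i0 - 1L + b, ] - position[i0 - 1L + i, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) next
      ang_i <- acos(min(1, max(-1, sum(u * v) / (nu * nv))))
      if (ang_i > best_ang) { best_ang <- ang_i; best <- i0 - 1L + i }
    }
    best
  }, numeric(1))
  sort(as.integer(refined))
}

# Rest spans on a speed trace: maximal runs below `rest_speed` lasting at
# least `rest_min_duration`. For each span the stop point is the first
# sample near the span's minimum speed and the go point the last such
# sample; on noise-free data these coincide with the true zero-speed
# samples, and on noisy data they bracket the deep part of the rest.
.rest_spans <- function(speed, rate, cfg) {
  below <- speed < cfg$rest_speed
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- as.integer(round(cfg$rest_min_duration * rate))
  sel <- which(r$values & r$lengths >= need)
  if (length(sel) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      stop_at = integer(0), go_at = integer(0)))
  out <- lapply(sel, function(k) {
    a <- starts[k]; b <- ends[k]
    sseg <- speed[a:b]
    smin <- min(sseg)
    # on noise-free data only the true zero-speed samples qualify (exact
    # vertex/stop boundaries); on noisy data the threshold opens up to half
    # the rest threshold so the stop/go points bracket nearly the full span
    thr <- max(smin + 1e-9, min(0.5 * cfg$rest_speed, 3 * smin))
    near <- which(sseg <= thr)
    c(a, b, a - 1L + near[1], a - 1L + near[length(near)])
  })
  out <- do.call(rbind, out)
  data.frame(start = out[, 1], end = out[, 2],
             stop_at = out[, 3], go_at = out[, 4])
}

# Low-pass the position components for direction-change analysis; tangent
# directions at the arc-step scale are otherwise dominated by sensor noise.
# The cut-off stays well above the stroke bandwidth so path geometry
# (including hexagon corners) is preserved.
.smooth_position <- function(position, rate, cutoff) {
  n <- nrow(position)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2 || n < 24)
    return(position)
  .butter_filtfilt(position, rate, cutoff / (rate / 2), "low",
                   pad = ceiling(3 * rate / cutoff))
}

.polyline_length <- function(position, i0, i1) {
  if (i1 <= i0) return(0)
  seg <- position[i0:i1, , drop = FALSE]
  sum(sqrt(rowSums((seg[-1, , drop = FALSE] -
                    seg[-nrow(seg), , drop = FALSE])^2)))
}

# Shared segmentation core. `positions` is a list of one or two n x 3
# matrices (heading detection runs on each); `speed` drives rest detection
# (the composite max-speed for bilateral mode). Returns the movement table.
.segment_core <- function(positions, speed, rate, cfg) {
  n <- length(speed)
  positions_smooth <- lapply(positions, .smooth_position, rate = rate,
                             cutoff = cfg$heading_smooth_cutoff)
  spans <- .rest_spans(speed, rate, cfg)
  # active intervals between consecutive dead (deep-rest) zones
  a_start <- 1L
  intervals <- list()
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) {
      if (spans$stop_at[k] > a_start)
        intervals[[length(intervals) + 1]] <- c(a_start, spans$stop_at[k])
      a_start <- spans$go_at[k]
    }
  }
  if (a_start < n) intervals[[length(intervals) + 1]] <- c(a_start, n)
  # drop intervals fully inside a rest span (leading/trailing stillness)
  if (nrow(spans) > 0 && length(intervals) > 0) {
    inside <- vapply(intervals, function(iv) {
      any(iv[1] >= spans$start & iv[2] <= spans$end)
    }, logical(1))
    intervals <- intervals[!inside]
  }

  merge_gap <- max(2L, as.integer(round(0.15 * rate)))
  segs <- list()
  for (iv in intervals) {
    bnds <- sort(unique(unlist(lapply(positions_smooth, function(p) {
      .heading_boundaries(p, iv[1], iv[2], cfg)
    }))))
    bnds <- bnds[bnds > iv[1] & bnds < iv[2]]
    if (length(bnds) > 1) {
      # cluster near-coincident boundaries from the two limbs; keep the
      # member at the lowest speed (closest to an actual stop)
      cl <- cumsum(c(1, diff(bnds) > merge_gap))
      bnds <- vapply(split(bnds, cl), function(g) {
        g[which.min(speed[g])]
      }, numeric(1))
    }
    cuts <- c(iv[1], bnds, iv[2])
    for (k in seq_len(length(cuts) - 1)) {
      segs[[length(segs) + 1]] <- c(cuts[k], cuts[k + 1])
    }
  }
  if (length(segs) == 0) {
    return(data.frame(index = integer(0), n_onset = integer(0),
                      n_termination = integer(0), t_onset = numeric(0),
                      t_termination = numeric(0), path_length = numeric(0)))
  }
  segs <- do.call(rbind, segs)
  # Minimum-length floor (max across limbs), measured two ways and the
  # larger taken: the endpoint displacement of the raw trajectory (exact
  # and noise-immune for straight strokes, including a side exactly at the
  # floor) and the polyline length of the noise-suppressed trajectory
  # (catches curved movements; raw polylines are not used because sensor
  # noise inflates them by ~0.3 m per second of dwell). Sub-threshold
  # candidates are dropped, not merged into a neighbour.
  gate_len <- function(iv) {
    disp <- vapply(positions, function(p) {
      sqrt(sum((p[iv[2], ] - p[iv[1], ])^2))
    }, numeric(1))
    smooth <- vapply(positions_smooth, .polyline_length, numeric(1),
                     i0 = iv[1], i1 = iv[2])
    max(disp, smooth)
  }
  gate <- apply(segs, 1, gate_len)
  keep <- gate >= cfg$min_movement_length - 1e-9
  segs <- segs[keep, , drop = FALSE]
  # reported length: noise-suppressed polyline of the busier limb
  plen <- apply(segs, 1, function(iv) {
    max(vapply(positions_smooth, .polyline_length, numeric(1),
               i0 = iv[1], i1 = iv[2]))
  })
  data.frame(index = seq_len(nrow(segs)),
             n_onset = as.integer(segs[, 1]),
             n_termination = as.integer(segs[, 2]),
             t_onset = (segs[, 1] - 1) / rate,
             t_termination = (segs[, 2] - 1) / rate,
             path_length = plen)
}

#' Split a trajectory into completed movements
#'
#' Boundaries are placed (a) where the smoothed speed stays below
#' `rest_speed` for at least `rest_min_duration` (the movement terminates at
#' the first near-minimum-speed sample of the rest span and the next one
#' starts at the last), and (b) where the heading of the arc-length-
#' resampled path rotates by more than `heading_threshold` degrees between
#' adjacent tangent windows. Candidate segments shorter than
#' `min_movement_length` are discarded. Boundaries are inclusive at both
#' ends; consecutive movements may share a boundary sample. Segmentation is
#' invariant under rigid transforms of the trajectory and, for
#' direction-change boundaries, under time re-scaling.
#'
#' @param position n x 3 matrix of hand positions (m).
#' @param rate sampling rate (Hz).
#' @param config an `analysis_config`.
#' @param speed optional precomputed speed (defaults to
#'   `hand_speed(position, rate, config$speed_cutoff)`).
#' @return data frame with one row per movement: `index`, `n_onset`,
#'   `n_termination` (sample indices), `t_onset`, `t_termination` (s) and
#'   `path_length` (m, polyline length of the segment). An empty trajectory
#'   gives zero rows, not an error.
#' @export
segment_movements <- function(position, rate, config = analysis_config(),
                              speed = NULL) {
  cfg <- validate_config(config)
  position <- .as_mat3(position, "position")
  if (nrow(position) < 3) {
    return(data.frame(index = integer(0), n_onset = integer(0),
                      n_termination = integer(0), t_onset = numeric(0),
                      t_termination = numeric(0), path_length = numeric(0)))
  }
  if (is.null(speed)) speed <- hand_speed(position, rate, cfg$speed_cutoff)
  .segment_core(list(position), speed, rate, cfg)
}

#' Shared bilateral segmentation
#'
#' Produces one set of movement intervals for both limbs: rest detection
#' runs on the composite speed `max(speed_uaf, speed_af)` so unimanual
#' movements of either limb are captured, and direction-change detection
#' runs on each limb's trajectory with near-coincident boundaries merged.
#' Per-limb segmentation (for single-limb validation tasks) is available by
#' passing that limb's trajectory to [segment_movements()].
#'
#' @param session a `bilateral_session`.
#' @param config an `analysis_config`.
#' @return a movement table as in [segment_movements()].
#' @export
segment_bilateral <- function(session, config = analysis_config()) {
  cfg <- validate_config(config)
  validate_session(session)
  rate <- session$kin_rate
  su <- hand_speed(session$uaf$position, rate, cfg$speed_cutoff)
  sa <- hand_speed(session$af$position, rate, cfg$speed_cutoff)
  .segment_core(list(session$uaf$position, session$af$position),
                pmax(su, sa), rate, cfg)
}
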