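# Distribution statistics and session-level tables.

#' Distribution summary: mean, SD, Pearson kurtosis
#'
#' Mean, sample standard deviation (n - 1 divisor) and Pearson (non-excess)
#' kurtosis `m4 / m2^2` — a normal sample gives kurtosis near 3. Non-finite
#' values and flagged (saturated) entries are excluded from the moments but
#' counted in `n_flagged_excluded`, since saturation caps are artifacts of
#' the capping rule rather than data. A zero-variance sample yields an
#' undefined kurtosis, reported as NA with a flag.
#'
#' @param values numeric vector.
#' @param flagged optional logical vector marking entries to exclude.
#' @return object of class `dist_summary`: list with `mean`, `sd`,
#'   `kurtosis`, `kurtosis_flagged`, `n`, `n_flagged_excluded`.
#' @export
dist_summary <- function(values, flagged = NULL) {
  if (is.null(flagged)) flagged <- rep(FALSE, length(values))
  if (length(flagged) != length(values))
    stop("alignment error: flagged and values differ in length")
  drop <- flagged | !is.finite(values)
  x <- values[!drop]
  n <- length(x)
  if (n < 2) stop("summary error: fewer than 2 usable values")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m4 <- mean((x - mu)^4)
  kurt_flag <- m2 == 0
  structure(list(mean = mu, sd = stats::sd(x),
                 kurtosis = if (kurt_flag) NA_real_ else m4 / m2^2,
                 kurtosis_flagged = kurt_flag,
                 n = n, n_flagged_excluded = sum(drop)),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("dist_summary: mean %.4g, sd %.4g, kurtosis %s (n = %d, excluded = %d)\n",
              x$mean, x$sd,
              if (x$kurtosis_flagged) "undefined" else sprintf("%.4g", x$kurtosis),
              x$n, x$n_flagged_excluded))
  invisible(x)
}

#' Bimanual/unimanual movement table
#'
#' Per movement class (unimanual / unclassified / bimanual): the proportion
#' of movements (percent of all movements; the proportions sum to 100
#' before rounding) and the median per-limb path length within the class.
#'
#' @param metrics a `movement_metrics` data frame with at least one row.
#' @return data frame of class `bimanual_table`: `movement_class`,
#'   `proportion_pct`, `n`, `med_l_uaf`, `med_l_af`.
#' @export
bimanual_table <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0)
    stop("summary error: no movements")
  classes <- c("unimanual", "unclassified", "bimanual")
  cls <- factor(metrics$movement_class, levels = classes)
  n_by <- as.integer(table(cls))
  med <- function(v, which_cls) {
    sel <- cls == which_cls
    if (!any(sel)) NA_real_ else stats::median(v[sel])
  }
  out <- data.frame(
    movement_class = classes,
    proportion_pct = 100 * n_by / nrow(metrics),
    n = n_by,
    med_l_uaf = vapply(classes, med, numeric(1), v = metrics$l_uaf),
    med_l_af = vapply(classes, med, numeric(1), v = metrics$l_af))
  rownames(out) <- NULL
  class(out) <- c("bimanual_table", "data.frame")
  out
}

#' Histogram export for log-ratio panels
#'
#' Fixed-width probability histogram over a symmetric range (50 bins over
#' [-6, 6] by default), with out-of-range values clipped to the edge bins.
#'
#' @param values numeric vector (NA dropped).
#' @param range histogram range.
#' @param bins number of bins.
#' @return data frame with `bin_left`, `bin_right`, `probability`.
#' @export
ratio_histogram <- function(values, range = c(-6, 6), bins = 50) {
  x <- values[is.finite(values)]
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- findInterval(x, edges, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  data.frame(bin_left = edges[-(bins + 1)], bin_right = edges[-1],
             probability = if (length(x) > 0) counts / length(x) else
               rep(0, bins))
}
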