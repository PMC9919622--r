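# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive discrete Fréchet: minimum over all monotone couplings of the
# maximum pointwise |a - b|, by plain recursion (feasible up to length ~6).
brute_frechet <- function(a, b) {
  rec <- function(i, j) {
    d <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(d)
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    max(d, prev)
  }
  rec(length(a), length(b))
}

# Cumulative Simpson integration on a uniform grid: exact for cubic
# integrands, so it integrates minimum-jerk accelerations without the
# trapezoid's O(h^2) bias. Even indices follow the composite-Simpson chain;
# odd indices add a single-interval three-point Newton-Cotes step.
cum_simpson <- function(y, h) {
  n <- length(y)
  out <- numeric(n)
  if (n >= 3) {
    for (k in seq(3, n, by = 2)) {
      out[k] <- out[k - 2] + h / 3 * (y[k - 2] + 4 * y[k - 1] + y[k])
    }
    for (k in seq(2, n, by = 2)) {
      out[k] <- out[k - 1] + h / 12 * (5 * y[k - 1] + 8 * y[k] -
                                         y[min(k + 1, n)])
      if (k + 1 > n)  # trailing odd point: fall back to trapezoid
        out[k] <- out[k - 1] + h / 2 * (y[k - 1] + y[k])
    }
  } else if (n == 2) {
    out[2] <- h / 2 * (y[1] + y[2])
  }
  out
}

# column-wise cumulative Simpson for vector-valued signals
cum_simpson_mat <- function(m, h) apply(m, 2, cum_simpson, h = h)

# rotation matrix about an arbitrary axis (Rodrigues)
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# a resting trajectory padded around a single minimum-jerk stroke
stroke_with_rest <- function(from, to, duration = 1, rate = 80,
                             pad_s = 1) {
  pad <- as.integer(round(pad_s * rate))
  p <- limbuse::minimum_jerk_stroke(from, to, duration, rate)
  rbind(matrix(rep(from, each = pad), pad, 3), p,
        matrix(rep(to, each = pad), pad, 3))
}
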