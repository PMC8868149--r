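# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: integration is numeric where the package is
# closed-form, and interpolation is re-derived from first principles.

# Fine-grid numeric integration of the piecewise interpolant (linear on
# rising/flat/zero-touching segments, exponential on strictly declining
# positive segments). Composite Simpson within each inter-knot piece.
oracle_auc <- function(time, conc, t0, t1, n_sub = 2001) {
  knots <- sort(unique(c(t0, t1, time[time > t0 & time < t1])))
  total <- 0
  for (j in seq_len(length(knots) - 1)) {
    a <- knots[j]; b <- knots[j + 1]
    i <- findInterval((a + b) / 2, time, rightmost.closed = TRUE)
    ta <- time[i]; tb <- time[i + 1]; ca <- conc[i]; cb <- conc[i + 1]
    xs <- seq(a, b, length.out = n_sub)  # odd count for Simpson
    u <- (xs - ta) / (tb - ta)
    ys <- if (cb >= ca || ca <= 0 || cb <= 0) ca + (cb - ca) * u
          else ca * (cb / ca)^u
    hh <- (b - a) / (n_sub - 1)
    w <- rep(c(4, 2), length.out = n_sub - 2)
    total <- total + hh / 3 * (ys[1] + sum(w * ys[2:(n_sub - 1)]) + ys[n_sub])
  }
  total
}

# Time above threshold from a dense evaluation of the piecewise-linear
# interpolant at `step`-min resolution, with linear crossing location
# between adjacent grid samples.
oracle_time_above <- function(time, conc, mic, t0, t1, step = 1e-3) {
  ts <- seq(t0, t1, by = step)
  if (ts[length(ts)] < t1) ts <- c(ts, t1)
  cs <- approx(time, conc, xout = ts)$y
  ca <- cs[-length(cs)]; cb <- cs[-1]; dt <- diff(ts)
  both <- ca > mic & cb > mic
  one <- xor(ca > mic, cb > mic)
  fr <- numeric(length(dt))
  fr[one] <- {
    u <- (mic - ca[one]) / (cb[one] - ca[one])
    ifelse(ca[one] > mic, u, 1 - u)
  }
  sum(dt[both]) + sum(dt[one] * fr[one])
}

# Closed-form OLS slope of log(conc) on time.
oracle_ols_slope <- function(t, c) {
  x <- t - mean(t); y <- log(c) - mean(log(c))
  sum(x * y) / sum(x * x)
}

# Random piecewise-linear profile on knots rounded to 0.01 min (so the
# 1e-3-min oracle grid passes exactly through every knot).
random_profile <- function(n_points = sample(4:10, 1), span = 60) {
  t <- sort(sample(seq(0, span, by = 0.01), n_points))
  conc_profile(t, round(runif(n_points, 0, 12), 3))
}
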