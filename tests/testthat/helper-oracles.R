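# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force rather than calling the implementation paths
# they check.

# Intensity-weighted centroid over all pixels above a threshold, by direct
# summation (x = column, y = row).
oracle_centroid <- function(frame, thr) {
  sel <- which(frame > thr, arr.ind = TRUE)
  w <- frame[sel] - median(frame)
  c(x = sum(sel[, 2] * w) / sum(w), y = sum(sel[, 1] * w) / sum(w))
}

# Median pairwise center-to-neighbor distance of a seven-dot layout.
oracle_spacing <- function(xy) {
  ctr <- which.min((xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2)
  median(sqrt((xy[-ctr, 1] - xy[ctr, 1])^2 + (xy[-ctr, 2] - xy[ctr, 2])^2))
}

# Loop-based event-triggered mean for one channel.
oracle_triggered_mean <- function(time_s, ch, events, window) {
  rate <- 1 / median(diff(time_s))
  lags <- seq(round(window[1] * rate), round(window[2] * rate))
  snips <- list()
  for (e in events) {
    c0 <- which.min(abs(time_s - e))
    if (c0 + lags[1] >= 1 && c0 + lags[length(lags)] <= length(ch))
      snips[[length(snips) + 1]] <- ch[c0 + lags]
  }
  Reduce(`+`, snips) / length(snips)
}

# Closed-form log-log regression for the main sequence.
oracle_power_fit <- function(amp, vpeak) {
  x <- log(amp); y <- log(vpeak)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  k <- exp(mean(y) - b * mean(x))
  list(k = k, b = b)
}

# One-sample two-sided t-test p-value from the t CDF directly.
oracle_t_pvalue <- function(x) {
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}

# A smooth 2-D test trajectory staying well inside the default frame.
make_test_traj <- function(duration = 2, rate = 100, ax = 3, ay = 1.5) {
  tt <- seq(0, duration - 1 / rate, by = 1 / rate)
  trajectory_gt(tt, ax * sin(2 * pi * 0.5 * tt), ay * cos(2 * pi * 0.7 * tt))
}
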