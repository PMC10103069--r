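# Eye-trace kinematics: smoothed differentiation, saccade detection and
# cataloguing, main-sequence fits, optokinetic gain and optomotor index.

#' Saccade-detection configuration
#'
#' Saccades are detected on the 2-D speed trace with a velocity threshold
#' and hysteresis: an event starts where speed exceeds `threshold_deg_s` and
#' extends outward until speed falls below `hysteresis_frac * threshold`.
#' Events separated by less than `refractory_s` are merged. Amplitudes are
#' median positions in a `amp_window_s` window after offset minus before
#' onset, optionally corrected for the local smooth drift estimated from a
#' longer pre-onset window.
#'
#' @param threshold_deg_s speed threshold, deg/s.
#' @param hysteresis_frac lower bound as a fraction of the threshold.
#' @param refractory_s minimum separation between events, s.
#' @param amp_window_s amplitude estimation window, s.
#' @param drift_correct subtract the pre-onset drift from amplitudes.
#' @param sg_window,sg_order Savitzky-Golay differentiator window (samples,
#'   odd; `NULL` = about 15 ms at the trace rate, minimum 5) and
#'   polynomial order.
#' @return A list of class `saccade_config`.
#' @export
saccade_config <- function(threshold_deg_s = 15, hysteresis_frac = 1 / 3,
                           refractory_s = 0.1, amp_window_s = 0.05,
                           drift_correct = TRUE,
                           sg_window = NULL, sg_order = 2L) {
  structure(list(threshold_deg_s = threshold_deg_s,
                 hysteresis_frac = hysteresis_frac,
                 refractory_s = refractory_s, amp_window_s = amp_window_s,
                 drift_correct = drift_correct,
                 sg_window = sg_window, sg_order = as.integer(sg_order)),
            class = "saccade_config")
}

default_sg_window <- function(rate, window) {
  if (!is.null(window)) return(as.integer(window))
  w <- max(5L, as.integer(round(0.015 * rate)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

sg_derivative <- function(x, rate, window, order) {
  n <- length(x)
  if (window > n) stop("differentiation window longer than trace")
  half <- (window - 1L) %/% 2L
  # odd (point-reflection) mirror padding: preserves linear trends at the
  # endpoints, so a ramp differentiates exactly everywhere
  xp <- c(2 * x[1L] - x[(half + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - half)])
  v <- signal::sgolayfilt(xp, p = order, n = window, m = 1, ts = 1 / rate)
  v[(half + 1L):(half + n)]
}

#' Differentiate an eye trace
#'
#' Savitzky-Golay smoothing differentiator (local polynomial fit) applied
#' per axis, with mirror padding at the endpoints. Exact for polynomials up
#' to the configured order, so a linear ramp returns its slope at every
#' sample.
#'
#' @param trace an [eye_trace].
#' @param window filter window in samples (odd); `NULL` picks about 15 ms at
#'   the trace rate (minimum 5).
#' @param order polynomial order, default 2.
#' @return Data frame `time_s`, `vx_deg_s`, `vy_deg_s`, `speed_deg_s`.
#' @export
differentiate <- function(trace, window = NULL, order = 2L) {
  rate <- trace_rate(trace)
  window <- default_sg_window(rate, window)
  vx <- sg_derivative(trace$x_deg, rate, window, order)
  vy <- sg_derivative(trace$y_deg, rate, window, order)
  data.frame(time_s = trace$time_s, vx_deg_s = vx, vy_deg_s = vy,
             speed_deg_s = sqrt(vx^2 + vy^2))
}

empty_saccades <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             amp_x_deg = numeric(0), amp_y_deg = numeric(0),
             amplitude_deg = numeric(0), peak_vel_deg_s = numeric(0),
             dir_x = numeric(0), dir_y = numeric(0))
}

#' Detect saccades in an eye trace
#'
#' Threshold-crossing detector on the 2-D speed trace (see
#' [saccade_config()] for the event definition). Amplitudes are signed per
#' axis; `amplitude_deg` is the Euclidean magnitude and `dir_x`/`dir_y` the
#' unit direction.
#'
#' @param trace an [eye_trace].
#' @param cfg a [saccade_config].
#' @return Data frame with one row per saccade: `onset_s`, `offset_s`,
#'   `amp_x_deg`, `amp_y_deg`, `amplitude_deg`, `peak_vel_deg_s`, `dir_x`,
#'   `dir_y`. An empty frame is a valid result.
#' @export
detect_saccades <- function(trace, cfg = saccade_config()) {
  rate <- trace_rate(trace)
  vel <- differentiate(trace, cfg$sg_window, cfg$sg_order)
  sp <- vel$speed_deg_s
  n <- length(sp)
  hi <- sp > cfg$threshold_deg_s
  if (!any(hi)) return(empty_saccades())
  # the offset bound rides on the ongoing slow-phase speed so that smooth
  # tracking (which can exceed a fixed fraction of the threshold at high
  # gain) does not absorb the whole trace into one event
  bound <- cfg$hysteresis_frac * cfg$threshold_deg_s + stats::median(sp)
  lo <- sp > bound
  max_expand <- max(1L, round(0.15 * rate))

  # expand every supra-threshold run outward to the hysteresis bound
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- cbind(starts[r$values], ends[r$values])
  ev <- t(apply(seeds, 1, function(se) {
    a <- se[1]; b <- se[2]
    while (a > 1L && lo[a - 1L] && se[1] - a < max_expand) a <- a - 1L
    while (b < n && lo[b + 1L] && b - se[2] < max_expand) b <- b + 1L
    c(a, b)
  }))
  # merge events closer than the refractory interval
  gap <- cfg$refractory_s * rate
  merged <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev[i, 1] - merged[nrow(merged), 2] < gap)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], ev[i, 2])
    else merged <- rbind(merged, ev[i, ])
  }

  wlen <- max(1L, round(cfg$amp_window_s * rate))
  out <- lapply(seq_len(nrow(merged)), function(i) {
    a <- merged[i, 1]; b <- merged[i, 2]
    pre <- max(1L, a - wlen):max(1L, a - 1L)
    post <- min(n, b + 1L):min(n, b + wlen)
    amp_x <- stats::median(trace$x_deg[post]) - stats::median(trace$x_deg[pre])
    amp_y <- stats::median(trace$y_deg[post]) - stats::median(trace$y_deg[pre])
    if (cfg$drift_correct) {
      d0 <- max(1L, a - 4L * wlen)
      if (i > 1L) d0 <- max(d0, merged[i - 1L, 2] + wlen)
      drift <- d0:max(1L, a - 1L)
      if (length(drift) >= 4L) {
        dt_centers <- (mean(post) - mean(pre)) / rate
        fx <- stats::lm.fit(cbind(1, trace$time_s[drift]),
                            trace$x_deg[drift])$coefficients[2]
        fy <- stats::lm.fit(cbind(1, trace$time_s[drift]),
                            trace$y_deg[drift])$coefficients[2]
        amp_x <- amp_x - fx * dt_centers
        amp_y <- amp_y - fy * dt_centers
      }
    }
    amp <- sqrt(amp_x^2 + amp_y^2)
    data.frame(onset_s = trace$time_s[a], offset_s = trace$time_s[b],
               amp_x_deg = amp_x, amp_y_deg = amp_y, amplitude_deg = amp,
               peak_vel_deg_s = max(sp[a:b]),
               dir_x = if (amp > 0) amp_x / amp else 0,
               dir_y = if (amp > 0) amp_y / amp else 0)
  })
  do.call(rbind, out)
}

#' Fit the saccadic main sequence
#'
#' Least-squares line on log peak velocity versus log absolute amplitude,
#' the standard power-law summary `v_peak = k * |A|^b` of saccade kinematics.
#'
#' @param saccades data frame from [detect_saccades()] (needs
#'   `amplitude_deg` and `peak_vel_deg_s`), with at least 3 saccades of
#'   distinct non-zero amplitude.
#' @return A list of class `main_sequence_fit`: `k`, `b`, `r` (correlation
#'   on log-log axes) and `n`.
#' @export
main_sequence <- function(saccades) {
  keep <- saccades$amplitude_deg > 0 & saccades$peak_vel_deg_s > 0
  a <- log(saccades$amplitude_deg[keep])
  v <- log(saccades$peak_vel_deg_s[keep])
  if (length(a) < 3) stop("need at least 3 saccades with non-zero amplitude")
  if (stats::var(a) == 0) stop("degenerate input: all amplitudes equal")
  fit <- stats::lm.fit(cbind(1, a), v)
  structure(list(k = exp(fit$coefficients[[1]]), b = fit$coefficients[[2]],
                 r = stats::cor(a, v), n = length(a)),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("<main_sequence_fit> v_peak = %.3g * |A|^%.3g (r = %.3f, n = %d)\n",
              x$k, x$b, x$r, x$n))
  invisible(x)
}

#' Remove saccadic steps from a trace
#'
#' Replaces each saccade interval by a linear bridge and subtracts the
#' saccade's step from all later samples, leaving the smooth (slow-phase)
#' component. Adding back the cumulative saccade steps reconstructs the
#' original trace up to interpolation error inside the events.
#'
#' @param trace an [eye_trace].
#' @param saccades data frame from [detect_saccades()] on the same trace.
#' @return An [eye_trace] with the saccadic displacement removed.
#' @export
desaccade <- function(trace, saccades) {
  x <- trace$x_deg; y <- trace$y_deg
  n <- length(x)
  if (nrow(saccades)) {
    for (i in order(saccades$onset_s)) {
      a <- findInterval(saccades$onset_s[i], trace$time_s)
      b <- findInterval(saccades$offset_s[i], trace$time_s)
      a <- max(1L, a); b <- min(n, max(b, a + 1L))
      sx <- saccades$amp_x_deg[i]; sy <- saccades$amp_y_deg[i]
      x[a:b] <- seq(x[a], x[b] - sx, length.out = b - a + 1L)
      y[a:b] <- seq(y[a], y[b] - sy, length.out = b - a + 1L)
      if (b < n) {
        x[(b + 1L):n] <- x[(b + 1L):n] - sx
        y[(b + 1L):n] <- y[(b + 1L):n] - sy
      }
    }
  }
  out <- eye_trace(trace$time_s, x, y, eye = attr(trace, "eye"),
                   epochs = attr(trace, "epochs"))
  out
}

#' Initial slow-phase velocity after stimulus onset
#'
#' Robust line fit (M-estimation, least-squares fallback) to the desaccaded
#' horizontal position over a window after motion onset; the slope is the
#' initial tracking velocity.
#'
#' @param trace an [eye_trace].
#' @param stim_onset motion onset, s.
#' @param window fit window length, s (default 0.5).
#' @param saccades optional saccade catalog; detected with defaults when
#'   `NULL`.
#' @param axis `"x"` or `"y"`.
#' @return Velocity in deg/s (signed).
#' @export
initial_velocity <- function(trace, stim_onset, window = 0.5,
                             saccades = NULL, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (stim_onset < trace$time_s[1] ||
      stim_onset + window > trace$time_s[nrow(trace)])
    stop("fit window falls outside the trace")
  if (is.null(saccades)) saccades <- detect_saccades(trace)
  sm <- desaccade(trace, saccades)
  idx <- sm$time_s >= stim_onset & sm$time_s <= stim_onset + window
  tt <- sm$time_s[idx]
  pos <- if (axis == "x") sm$x_deg[idx] else sm$y_deg[idx]
  fit <- tryCatch(MASS::rlm(pos ~ tt, maxit = 50),
                  error = function(e) stats::lm(pos ~ tt),
                  warning = function(w) stats::lm(pos ~ tt))
  unname(stats::coef(fit)[2])
}

#' Optokinetic gain
#'
#' Ratio of the initial slow-phase speed to the stimulus speed. The sign of
#' the response is reported separately: a tracking retina moves opposite to
#' the stimulus, so `sign * stimulus_direction` is -1 for a proper
#' optokinetic response.
#'
#' @param iv initial velocity, deg/s (from [initial_velocity()]).
#' @param stimulus_speed stimulus speed, deg/s, non-zero.
#' @return A list with `gain` (`|iv| / speed`) and `sign` (`sign(iv)`).
#' @export
okr_gain <- function(iv, stimulus_speed) {
  if (stimulus_speed == 0) stop("gain undefined for stimulus speed 0")
  list(gain = abs(iv) / abs(stimulus_speed), sign = sign(iv))
}

#' Optomotor index
#'
#' Response strength in the expected optokinetic direction, per motion
#' epoch: the net desaccaded displacement divided by the total absolute
#' desaccaded displacement, signed so that tracking opposite the stimulus
#' scores +1 and movement with the stimulus scores -1; epochs are averaged
#' and the result clipped to \[-1, 1\]. Zero total displacement returns 0 with
#' attribute `flagged = TRUE`.
#'
#' @param trace an [eye_trace] whose `epochs` attribute (or the `epochs`
#'   argument) holds at least one motion epoch with non-zero `direction`.
#' @param epochs optional epoch data frame overriding the trace attribute.
#' @param saccades optional saccade catalog; detected with defaults when
#'   `NULL`.
#' @param axis `"x"` or `"y"`.
#' @return Optomotor index in \[-1, 1\].
#' @export
optomotor_index <- function(trace, epochs = NULL, saccades = NULL,
                            axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (is.null(epochs)) epochs <- attr(trace, "epochs")
  if (is.null(epochs) || !nrow(epochs)) stop("no stimulus epochs")
  epochs <- epochs[epochs$direction != 0, , drop = FALSE]
  if (!nrow(epochs)) stop("no motion epochs")
  if (is.null(saccades)) saccades <- detect_saccades(trace)
  sm <- desaccade(trace, saccades)
  pos <- if (axis == "x") sm$x_deg else sm$y_deg
  oi <- vapply(seq_len(nrow(epochs)), function(i) {
    idx <- sm$time_s >= epochs$start_s[i] & sm$time_s <= epochs$end_s[i]
    p <- pos[idx]
    tot <- sum(abs(diff(p)))
    if (tot == 0) return(NA_real_)
    -sign(epochs$direction[i]) * (p[length(p)] - p[1]) / tot
  }, numeric(1))
  if (all(is.na(oi))) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  max(-1, min(1, mean(oi, na.rm = TRUE)))
}
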