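# Binocular analysis: vergence metric, gap-crossing detection,
# event-triggered averaging with fixed baseline windows, and the associated
# statistics.

#' Vergence time series
#'
#' The sign-inverted product of the baseline-subtracted left- and right-eye
#' horizontal positions, `V(t) = -(x_L - b_L) * (x_R - b_R)` (deg^2). During
#' a convergent movement the two eyes shift in opposite x directions, so V
#' goes positive; a conjugate (same-direction) shift drives it negative.
#'
#' @param session a [gap_session].
#' @param baseline `"global"`: per-eye baseline is the whole-trace mean
#'   (continuous display); `"event"`: each sample uses the baseline of the
#'   nearest event, computed over `baseline_window` relative to that event.
#' @param events event times in seconds (required for `baseline = "event"`).
#' @param baseline_window per-event baseline window relative to the event,
#'   s; default `c(-2.5, -1.5)`.
#' @return Data frame `time_s`, `vergence_deg2`.
#' @export
vergence_series <- function(session, baseline = c("global", "event"),
                            events = NULL, baseline_window = c(-2.5, -1.5)) {
  baseline <- match.arg(baseline)
  if (is.null(session$left) || is.null(session$right))
    stop("both eye traces are required")
  xl <- session$left$x_deg; xr <- session$right$x_deg
  tt <- session$time_s
  if (baseline == "global") {
    v <- -(xl - mean(xl)) * (xr - mean(xr))
  } else {
    if (is.null(events) || !length(events))
      stop("per-event baselining needs event times")
    bl <- vapply(events, function(e) {
      idx <- tt >= e + baseline_window[1] & tt <= e + baseline_window[2]
      c(mean(xl[idx]), mean(xr[idx]))
    }, numeric(2))
    nearest <- vapply(tt, function(t) which.min(abs(events - t)), integer(1))
    v <- -(xl - bl[1, nearest]) * (xr - bl[2, nearest])
  }
  data.frame(time_s = tt, vergence_deg2 = v)
}

schmitt_crossings <- function(tt, w, level, hys) {
  # start armed on the side the trace begins on; re-arming after an event
  # requires a full retreat through the hysteresis band
  armed_fwd <- w[1] < level
  armed_bwd <- w[1] > level
  fwd <- bwd <- numeric(0)
  for (i in seq_along(w)[-1]) {
    if (armed_fwd && w[i] >= level) {
      fwd <- c(fwd, tt[i]); armed_fwd <- FALSE
    }
    if (armed_bwd && w[i] <= level - hys) {
      bwd <- c(bwd, tt[i]); armed_bwd <- FALSE
    }
    if (w[i] <= level - hys) armed_fwd <- TRUE
    if (w[i] >= level + hys) armed_bwd <- TRUE
  }
  list(forward = fwd, backward = bwd)
}

#' Detect gap-crossing events on the wheel trace
#'
#' The wheel carries two gaps per revolution, 180 degrees apart, so the
#' detection threshold repeats every half revolution of the unwrapped wheel
#' angle. Upward (forward) and downward (backward) crossings are found with
#' a Schmitt-trigger hysteresis band, and events of the same direction
#' closer than `min_interval_s` are dropped (first kept).
#'
#' @param session a [gap_session], or a numeric wheel trace (then supply
#'   `time_s`).
#' @param threshold wheel angle of the detection threshold within one
#'   half-revolution; defaults to the session's `threshold` attribute.
#' @param time_s time base when `session` is a bare numeric vector.
#' @param period threshold repetition period, wheel degrees (default 180).
#' @param hysteresis hysteresis band width, wheel degrees.
#' @param min_interval_s minimum same-direction inter-event interval, s.
#'   The default 10 s keeps +/-5 s analysis windows from overlapping.
#' @return Data frame `time_s`, `direction` (`"forward"`/`"backward"`),
#'   `lighting` (label from the session's lighting epochs, `NA` otherwise),
#'   sorted by time.
#' @export
detect_crossings <- function(session, threshold = NULL, time_s = NULL,
                             period = 180, hysteresis = 2,
                             min_interval_s = 10) {
  if (inherits(session, "gap_session")) {
    w <- session$wheel; tt <- session$time_s
    if (is.null(threshold)) threshold <- attr(session, "threshold")
    lighting <- session$lighting
  } else {
    w <- session; tt <- time_s
    lighting <- NULL
  }
  if (is.null(threshold)) stop("no crossing threshold given")
  empty <- data.frame(time_s = numeric(0), direction = character(0),
                      lighting = character(0))
  rng <- range(w)
  ks <- seq(floor((rng[1] - threshold) / period) - 1,
            ceiling((rng[2] - threshold) / period) + 1)
  levels <- threshold + period * ks
  levels <- levels[levels >= rng[1] - hysteresis & levels <= rng[2] + hysteresis]
  if (!length(levels)) return(empty)
  fwd <- bwd <- numeric(0)
  for (L in levels) {
    cr <- schmitt_crossings(tt, w, L, hysteresis)
    fwd <- c(fwd, cr$forward); bwd <- c(bwd, cr$backward)
  }
  prune <- function(times) {
    times <- sort(times)
    if (length(times) < 2) return(times)
    keep <- times[1]
    for (t in times[-1]) if (t - keep[length(keep)] >= min_interval_s)
      keep <- c(keep, t)
    keep
  }
  fwd <- prune(fwd); bwd <- prune(bwd)
  ev <- data.frame(time_s = c(fwd, bwd),
                   direction = c(rep("forward", length(fwd)),
                                 rep("backward", length(bwd))))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  ev$lighting <- rep(NA_character_, nrow(ev))
  if (!is.null(lighting) && nrow(ev)) {
    i <- findInterval(ev$time_s, lighting$start_s)
    ev$lighting <- lighting$label[pmax(i, 1)]
  }
  rownames(ev) <- NULL
  ev
}

#' Event-triggered average
#'
#' Aligns snippets of one or more channels at event times and averages them
#' per lag. Events whose window would leave the trace are excluded and
#' counted. The mean is the plain arithmetic mean of the included snippets.
#'
#' @param time_s shared time base.
#' @param channels named list of numeric vectors on that time base.
#' @param events event times, s.
#' @param window `c(-pre, +post)` in seconds around each event.
#' @return A list of class `triggered_average`: `lag_s`, `mean` (data frame,
#'   one column per channel), `snippets` (named list of lag x event
#'   matrices), `n_events`, `n_excluded`.
#' @export
triggered_average <- function(time_s, channels, events, window = c(-5, 5)) {
  stopifnot(is.list(channels), length(events) >= 1)
  rate <- 1 / stats::median(diff(time_s))
  lags <- seq(round(window[1] * rate), round(window[2] * rate))
  centers <- vapply(events, function(e) which.min(abs(time_s - e)), integer(1))
  n <- length(time_s)
  inside <- centers + lags[1] >= 1 & centers + lags[length(lags)] <= n
  if (!any(inside)) stop("every event window leaves the trace")
  centers <- centers[inside]
  snip <- lapply(channels, function(ch)
    vapply(centers, function(c0) ch[c0 + lags], numeric(length(lags))))
  structure(list(lag_s = lags / rate,
                 mean = as.data.frame(lapply(snip, rowMeans)),
                 snippets = snip,
                 n_events = length(centers),
                 n_excluded = sum(!inside)),
            class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %d event(s) (%d excluded), lags %.3g..%.3g s, channels: %s\n",
              x$n_events, x$n_excluded, min(x$lag_s), max(x$lag_s),
              paste(names(x$mean), collapse = ", ")))
  invisible(x)
}

#' Per-event baseline-window deltas
#'
#' For position-like channels (wheel, per-eye x), the delta is the mean over
#' the 3 s window starting 2 s after the event minus the mean over the 3 s
#' baseline window starting 5 s before it. For a channel named `vergence`
#' the delta is the mean over the 1 s window surrounding the event minus the
#' mean over the 1 s baseline window starting 2.5 s before it.
#'
#' @param ta a [triggered_average()] whose lag axis covers \[-5, +5\] s.
#' @return Data frame with one row per event and one column per channel.
#' @export
event_deltas <- function(ta) {
  lag <- ta$lag_s
  eps <- 1e-6
  if (min(lag) > -5 + eps || max(lag) < 5 - eps)
    stop("event windows must cover [-5, +5] s around the event")
  win_mean <- function(m, from, to) {
    idx <- lag >= from - eps & lag <= to + eps
    colMeans(m[idx, , drop = FALSE])
  }
  out <- lapply(names(ta$snippets), function(nm) {
    m <- ta$snippets[[nm]]
    if (identical(nm, "vergence"))
      win_mean(m, -0.5, 0.5) - win_mean(m, -2.5, -1.5)
    else
      win_mean(m, 2, 5) - win_mean(m, -5, -2)
  })
  names(out) <- names(ta$snippets)
  as.data.frame(out)
}

#' One-sample t-tests on event deltas with Bonferroni correction
#'
#' Two-sided one-sample t-test of each delta distribution against zero,
#' declared significant at `alpha / m_tests`.
#'
#' @param deltas data frame (or named list) of per-fly or per-event delta
#'   vectors, each of length >= 2.
#' @param m_tests number of tests in the Bonferroni family (default 9).
#' @param alpha family-wise level (default 0.05).
#' @return Data frame `channel`, `mean`, `t`, `df`, `p`, `significant`.
#' @export
deltas_ttest <- function(deltas, m_tests = 9, alpha = 0.05) {
  deltas <- as.data.frame(deltas)
  out <- lapply(names(deltas), function(nm) {
    x <- deltas[[nm]]
    if (length(x) < 2) stop("need n >= 2 per distribution")
    if (stats::sd(x) == 0) {
      tstat <- if (mean(x) == 0) 0 else Inf * sign(mean(x))
      p <- if (mean(x) == 0) 1 else 0
      data.frame(channel = nm, mean = mean(x), t = tstat,
                 df = length(x) - 1, p = p,
                 significant = p < alpha / m_tests)
    } else {
      ht <- stats::t.test(x, mu = 0)
      data.frame(channel = nm, mean = mean(x),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, significant = ht$p.value < alpha / m_tests)
    }
  })
  do.call(rbind, out)
}

#' Gap-crossing heights and group comparison
#'
#' For every crossing path, takes the minimum y; per fly, the median over
#' its crossings; per group, mean +/- SEM; groups are compared with a
#' two-sided Welch t-test on the per-fly medians.
#'
#' @param paths_by_group named list of two groups; each group is a list per
#'   fly of crossing paths (data frames with columns `x_mm`, `y_mm`).
#' @return A list of class `crossing_height`: `per_fly` (data frame `group`,
#'   `fly`, `median_min_y_mm`), `summary` (`group`, `mean`, `sem`, `n`) and
#'   `test` (the Welch `htest`, `NULL` if fewer than two groups).
#' @export
crossing_height <- function(paths_by_group) {
  per_fly <- do.call(rbind, lapply(names(paths_by_group), function(g) {
    flies <- paths_by_group[[g]]
    data.frame(group = g, fly = seq_along(flies),
               median_min_y_mm = vapply(flies, function(paths) {
                 if (!length(paths)) stop("every fly needs >= 1 crossing")
                 stats::median(vapply(paths, function(p) min(p$y_mm),
                                      numeric(1)))
               }, numeric(1)))
  }))
  summ <- do.call(rbind, lapply(split(per_fly, per_fly$group), function(d) {
    data.frame(group = d$group[1], mean = mean(d$median_min_y_mm),
               sem = stats::sd(d$median_min_y_mm) / sqrt(nrow(d)),
               n = nrow(d))
  }))
  rownames(summ) <- NULL
  test <- NULL
  gs <- unique(per_fly$group)
  if (length(gs) == 2)
    test <- stats::t.test(per_fly$median_min_y_mm[per_fly$group == gs[1]],
                          per_fly$median_min_y_mm[per_fly$group == gs[2]])
  structure(list(per_fly = per_fly, summary = summ, test = test),
            class = "crossing_height")
}

#' Crossing rate per lighting epoch
#'
#' Forward-crossing count divided by epoch duration, per labeled epoch.
#'
#' @param events data frame from [detect_crossings()].
#' @param epochs lighting epochs (`start_s`, `end_s`, `label`).
#' @return Data frame `label`, `n_forward`, `duration_s`, `rate_per_s`,
#'   `mean_interval_s` (`NA` where no events).
#' @export
crossing_rate <- function(events, epochs) {
  fwd <- events$time_s[events$direction == "forward"]
  out <- lapply(seq_len(nrow(epochs)), function(i) {
    n <- sum(fwd >= epochs$start_s[i] & fwd < epochs$end_s[i])
    dur <- epochs$end_s[i] - epochs$start_s[i]
    data.frame(label = epochs$label[i], n_forward = n, duration_s = dur,
               rate_per_s = n / dur,
               mean_interval_s = if (n > 0) dur / n else NA_real_)
  })
  do.call(rbind, out)
}

#' Compare crossing rates between two epochs across flies
#'
#' Paired two-sided t-test of per-fly crossing rates between two lighting
#' conditions.
#'
#' @param rates_per_fly list (one element per fly) of data frames from
#'   [crossing_rate()].
#' @param label_a,label_b epoch labels to compare. Epochs sharing a label
#'   (e.g. two lights-on blocks) are pooled per fly by total count over
#'   total duration.
#' @return A list with `per_fly` (data frame `fly`, `rate_a`, `rate_b`),
#'   `ratio` (mean rate a / mean rate b) and `test` (paired `htest`).
#' @export
crossing_rate_test <- function(rates_per_fly, label_a, label_b) {
  pick <- function(d, lab) {
    d <- d[d$label == lab, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("no epoch labelled '%s'", lab))
    sum(d$n_forward) / sum(d$duration_s)
  }
  per_fly <- data.frame(fly = seq_along(rates_per_fly),
                        rate_a = vapply(rates_per_fly, pick, numeric(1),
                                        lab = label_a),
                        rate_b = vapply(rates_per_fly, pick, numeric(1),
                                        lab = label_b))
  list(per_fly = per_fly,
       ratio = mean(per_fly$rate_a) / mean(per_fly$rate_b),
       test = stats::t.test(per_fly$rate_a, per_fly$rate_b, paired = TRUE))
}
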