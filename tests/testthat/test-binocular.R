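# Vergence metric, crossing detection, triggered averaging and the
# gap-crossing statistics.

make_session <- function(xl, xr, dt = 0.01, wheel = NULL) {
  tt <- seq(0, by = dt, length.out = length(xl))
  if (is.null(wheel)) wheel <- rep(0, length(xl))
  gap_session(tt, wheel, eye_trace(tt, xl, eye = "left"),
              eye_trace(tt, xr, eye = "right"))
}

test_that("vergence metric signs convergent, conjugate and null shifts", {
  a <- 1.5
  n <- 200
  # first half at baseline, second half shifted
  xl <- c(rep(0, n / 2), rep(a, n / 2))
  xr <- c(rep(0, n / 2), rep(-a, n / 2))
  ses <- make_session(xl, xr)
  v <- vergence_series(ses, baseline = "event", events = 1.5,
                       baseline_window = c(-1.4, -0.8))
  expect_equal(v$vergence_deg2[n], a^2)
  conj <- make_session(xl, xl)
  vc <- vergence_series(conj, baseline = "event", events = 1.5,
                        baseline_window = c(-1.4, -0.8))
  expect_equal(vc$vergence_deg2[n], -a^2)
  # one eye at baseline: metric is zero
  half <- make_session(xl, rep(0, n))
  vh <- vergence_series(half, baseline = "event", events = 1.5,
                        baseline_window = c(-1.4, -0.8))
  expect_equal(vh$vergence_deg2[n], 0)
})

test_that("vergence metric is symmetric under eye swap and null on noise", {
  set.seed(5)
  n <- 5000
  xl <- rnorm(n, 0, 0.1); xr <- rnorm(n, 0, 0.1)
  ses <- make_session(xl, xr)
  swapped <- make_session(xr, xl)
  expect_equal(vergence_series(ses)$vergence_deg2,
               vergence_series(swapped)$vergence_deg2)
  v <- vergence_series(ses)$vergence_deg2
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(n))
})

test_that("crossing detection matches generator ground truth", {
  p <- gap_session_params(n_crossings = 5, seed = 2)
  ses <- gen_gap_session(p)
  gt <- attr(ses, "ground_truth_crossings")
  ev <- detect_crossings(ses)
  fwd <- ev[ev$direction == "forward", ]
  expect_equal(nrow(fwd), 5L)
  expect_equal(fwd$time_s, gt$time_s, tolerance = 1.5 / 100)  # one sample
  expect_equal(fwd$lighting, gt$lighting)
})

test_that("crossing detection respects threshold range and hysteresis", {
  tt <- seq(0, 9.99, by = 0.01)
  # monotone but below threshold: nothing
  ev0 <- detect_crossings(10 * tt / 10, threshold = 50, time_s = tt)
  expect_equal(nrow(ev0), 0L)
  # dither across the threshold within the hysteresis band: one event
  w <- 49 + sin(2 * pi * 2 * tt)  # oscillates 48..50 around threshold 49.5
  ev1 <- detect_crossings(w, threshold = 49.5, time_s = tt, hysteresis = 3)
  expect_equal(sum(ev1$direction == "forward"), 1L)
})

test_that("triggered average equals the brute-force snippet mean exactly", {
  set.seed(9)
  tt <- seq(0, 59.99, by = 0.01)
  ch <- list(a = cumsum(rnorm(length(tt))), b = sin(tt))
  events <- c(8, 21, 33.3, 47)
  ta <- triggered_average(tt, ch, events, window = c(-5, 5))
  expect_equal(ta$n_events, 4L)
  for (nm in names(ch))
    expect_equal(ta$mean[[nm]],
                 oracle_triggered_mean(tt, ch[[nm]], events, c(-5, 5)),
                 tolerance = 1e-12)
  # single event: the average is that snippet
  ta1 <- triggered_average(tt, ch["a"], 30, window = c(-2, 2))
  expect_identical(ta1$mean$a, as.numeric(ta1$snippets$a[, 1]))
  # constant channel stays constant; edge events are excluded and counted
  tac <- triggered_average(tt, list(k = rep(3, length(tt))), c(1, 30),
                           window = c(-5, 5))
  expect_equal(unique(tac$mean$k), 3)
  expect_equal(tac$n_excluded, 1L)
  expect_equal(tac$n_events + tac$n_excluded, 2L)
  expect_error(triggered_average(tt, ch, 0.5, window = c(-5, 5)),
               "leaves the trace")
})

test_that("event deltas read out the configured baseline windows", {
  tt <- seq(0, 29.99, by = 0.01)
  step <- ifelse(tt >= 15, 2, 0)     # 0 before the event, c after
  ta <- triggered_average(tt, list(x_L = step, flatch = rep(1, length(tt))),
                          15, window = c(-5, 5))
  d <- event_deltas(ta)
  expect_equal(d$x_L, 2)
  expect_equal(d$flatch, 0)
  short <- triggered_average(tt, list(x_L = step), 15, window = c(-2, 2))
  expect_error(event_deltas(short), "cover")
})

test_that("vergence deltas are positive for every injected convergent event", {
  p <- gap_session_params(n_crossings = 8, vergence_amplitude = 2, seed = 4)
  ses <- gen_gap_session(p)
  ev <- detect_crossings(ses)
  fwd <- ev$time_s[ev$direction == "forward"]
  vg <- vergence_series(ses, baseline = "event", events = fwd)
  ta <- triggered_average(ses$time_s,
                          list(wheel = ses$wheel, x_L = ses$left$x_deg,
                               x_R = ses$right$x_deg,
                               vergence = vg$vergence_deg2), fwd)
  d <- event_deltas(ta)
  expect_true(all(d$vergence > 0))
  expect_true(all(d$wheel > 0))
  # larger injected amplitude gives larger mean vergence delta
  p2 <- gap_session_params(n_crossings = 8, vergence_amplitude = 4, seed = 4)
  ses2 <- gen_gap_session(p2)
  ev2 <- detect_crossings(ses2)
  f2 <- ev2$time_s[ev2$direction == "forward"]
  vg2 <- vergence_series(ses2, baseline = "event", events = f2)
  ta2 <- triggered_average(ses2$time_s, list(vergence = vg2$vergence_deg2), f2)
  expect_gt(mean(event_deltas(ta2)$vergence), mean(d$vergence))
})

test_that("delta t-tests match the t CDF and apply the Bonferroni bound", {
  zeros <- data.frame(z = rep(0, 10))
  rz <- deltas_ttest(zeros)
  expect_equal(rz$t, 0)
  expect_false(rz$significant)

  set.seed(3)
  tight <- data.frame(d = 1 + rnorm(23, 0, 0.01))
  rt <- deltas_ttest(tight, m_tests = 9)
  expect_true(rt$significant)

  x <- rnorm(15, 0.3, 1)
  rx <- deltas_ttest(data.frame(x = x))
  expect_equal(rx$p, oracle_t_pvalue(x), tolerance = 1e-10)
})

test_that("crossing-height statistics separate the configured groups", {
  g1 <- gen_crossing_trajectories(-1.0, 0.3, 20, 10, seed = 21)
  g2 <- gen_crossing_trajectories(-1.4, 0.3, 20, 10, seed = 22)
  ch <- crossing_height(list(control = g1$paths, silenced = g2$paths))
  expect_equal(ch$summary$mean[ch$summary$group == "control"], -1.0,
               tolerance = 0.1)
  expect_equal(ch$summary$mean[ch$summary$group == "silenced"], -1.4,
               tolerance = 0.1)
  expect_lt(ch$test$p.value, 0.01)
  # identical groups: zero difference
  same <- crossing_height(list(a = g1$paths, b = g1$paths))
  expect_equal(diff(same$summary$mean), 0)
})

test_that("crossing rates per epoch and their paired comparison work", {
  ep <- data.frame(start_s = c(0, 600), end_s = c(600, 1200),
                   label = c("on", "dark"))
  ev <- data.frame(time_s = seq(30, 570, by = 60), direction = "forward")
  cr <- crossing_rate(ev, ep)
  expect_equal(cr$rate_per_s[cr$label == "on"], 10 / 600)
  expect_equal(cr$mean_interval_s[cr$label == "on"], 60)
  expect_equal(cr$rate_per_s[cr$label == "dark"], 0)
  expect_true(is.na(cr$mean_interval_s[cr$label == "dark"]))

  # epoch-dependent Poisson rates: ratio recovered near 2
  set.seed(7)
  rates <- lapply(1:20, function(f) {
    non <- rpois(1, 2 * 900 / 60); noff <- rpois(1, 900 / 60)
    evf <- data.frame(time_s = c(sort(runif(non, 0, 900)),
                                 sort(runif(noff, 900, 1800))),
                      direction = "forward")
    crossing_rate(evf, data.frame(start_s = c(0, 900), end_s = c(900, 1800),
                                  label = c("on", "dark")))
  })
  cmp <- crossing_rate_test(rates, "on", "dark")
  expect_equal(cmp$ratio, 2, tolerance = 0.4)
  expect_lt(cmp$test$p.value, 0.01)
})
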