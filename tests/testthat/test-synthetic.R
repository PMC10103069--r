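# Synthetic-data generators: ground truth bookkeeping and determinism.

test_that("frame generator renders a static pseudopupil reproducibly", {
  tt <- seq(0, 0.04, by = 0.01)
  traj <- trajectory_gt(tt, rep(0, 5))
  noiseless <- scene_params(noise_sigma = 0, seed = 1)
  fr <- gen_frames(traj, noiseless)
  expect_equal(n_frames(fr$stack), 5L)
  for (k in 2:5)
    expect_identical(fr$stack$frames[, , k], fr$stack$frames[, , 1])

  # same seed bit-identical, different seed differs only through noise
  noisy <- scene_params(noise_sigma = 2, seed = 1)
  a <- gen_frames(traj, noisy)
  b <- gen_frames(traj, noisy)
  expect_identical(a$stack$frames, b$stack$frames)
  c2 <- gen_frames(traj, scene_params(noise_sigma = 2, seed = 2))
  expect_false(identical(a$stack$frames, c2$stack$frames))
  diffs <- a$stack$frames - c2$stack$frames
  expect_lt(max(abs(diffs)), 6 * 2 * 2)  # pure noise difference, no structure
  expect_identical(a$px_traj, c2$px_traj)
})

test_that("degree-to-pixel conversion follows the spacing calibration", {
  # one 5-degree step equals one 12-px dot spacing
  tt <- c(0, 0.01)
  traj <- trajectory_gt(tt, c(0, 5))
  fr <- gen_frames(traj, scene_params(dot_spacing_px = 12, noise_sigma = 0),
                   deg_per_spacing = 5)
  expect_equal(diff(fr$px_traj$x_px), 12)
})

test_that("frame generator rejects trajectories leaving the frame", {
  tt <- seq(0, 0.03, by = 0.01)
  traj <- trajectory_gt(tt, c(0, 0, 0, 100))
  expect_error(gen_frames(traj, scene_params()), "sample 4")
})

test_that("okr generator produces the configured slow-phase slope", {
  p <- okr_params(gain = 0.2, stimulus_speed = 15, nystagmus_rate = 0,
                  noise_sigma_deg = 0, seed = 1)
  sim <- gen_okr_trace(p, 4)
  gt <- attr(sim$right, "ground_truth")
  slopes <- diff(gt$smooth_x) / diff(gt$times)
  expect_equal(max(abs(slopes - (-3))), 0, tolerance = 1e-9)

  # null dynamics: flat traces
  p0 <- okr_params(gain = 0, nystagmus_rate = 0, noise_sigma_deg = 0)
  sim0 <- gen_okr_trace(p0, 2)
  expect_equal(sim0$left$x_deg, rep(0, nrow(sim0$left)))
  expect_equal(sim0$right$x_deg, rep(0, nrow(sim0$right)))
})

test_that("unilateral stimulation leaves the unstimulated eye flat", {
  p <- okr_params(gain = 0.3, nystagmus_rate = 0.5, noise_sigma_deg = 0,
                  seed = 4)
  sim <- gen_okr_trace(p, 6, unilateral = "right")
  expect_equal(sim$left$x_deg, rep(0, nrow(sim$left)))
  expect_gt(diff(range(sim$right$x_deg)), 1)
})

test_that("okr ground truth decomposes into smooth plus saccadic steps", {
  p <- okr_params(gain = 0.2, nystagmus_rate = 0.8, noise_sigma_deg = 0,
                  seed = 7)
  sim <- gen_okr_trace(p, 20)
  gt <- attr(sim$right, "ground_truth")
  expect_gt(nrow(gt$saccades), 3)
  # every event lies inside the trace, and the full position equals the
  # smooth component plus the completed steps at the end
  expect_true(all(gt$saccades$onset_s >= min(gt$times)))
  expect_true(all(gt$saccades$offset_s <= max(gt$times)))
  n <- length(gt$times)
  expect_equal(gt$x[n] - gt$smooth_x[n], sum(gt$saccades$amplitude_deg),
               tolerance = 1e-9)
  # main-sequence bookkeeping: recorded peak velocity matches the law
  expect_equal(gt$saccades$peak_velocity_deg_s,
               p$k * abs(gt$saccades$amplitude_deg)^p$b, tolerance = 1e-9)
})

test_that("gap-session generator time-locks vergence pulses to crossings", {
  p <- gap_session_params(n_crossings = 5, vergence_amplitude = 2,
                          noise_sigma_deg = 0, seed = 1)
  ses <- gen_gap_session(p)
  gt <- attr(ses, "ground_truth_crossings")
  expect_equal(nrow(gt), 5L)
  # at each crossing the eyes sit at +A (left) and -A (right):
  # sign-inverted product is +A^2
  for (tc in gt$time_s) {
    i <- which.min(abs(ses$time_s - tc))
    expect_equal(ses$left$x_deg[i], 2, tolerance = 0.01)
    expect_equal(ses$right$x_deg[i], -2, tolerance = 0.01)
    expect_equal(-ses$left$x_deg[i] * ses$right$x_deg[i], 4, tolerance = 0.05)
  }
  # no-crossing session stays below threshold
  ses0 <- gen_gap_session(gap_session_params(n_crossings = 0, seed = 2))
  expect_lt(max(ses0$wheel), attr(ses0, "threshold"))
  expect_equal(nrow(attr(ses0, "ground_truth_crossings")), 0L)
})

test_that("gap-session generator rejects impossible durations", {
  expect_error(gen_gap_session(gap_session_params(n_crossings = 5,
                                                  duration = 10)),
               "too short")
})

test_that("bar-sweep curves shift by the injected amount in both directions", {
  bs <- gen_bar_sweep(5.7, latency_s = 0, noise_sigma = 0, seed = 1)
  meta <- sapply(bs$curves, function(x)
    paste(attr(x, "condition"), attr(x, "direction")))
  peak_of <- function(tc) tc$position_deg[which.max(tc$response)]
  for (d in c(1, -1)) {
    pc <- peak_of(bs$curves[[which(meta == paste("control", d))]])
    pa <- peak_of(bs$curves[[which(meta == paste("activated", d))]])
    expect_equal(pa - pc, 5.7, tolerance = 1.2)  # one 2.25-deg grid step
  }
  # zero shift, zero latency: curve pairs identical
  bs0 <- gen_bar_sweep(0, latency_s = 0, noise_sigma = 0, seed = 1)
  meta0 <- sapply(bs0$curves, function(x)
    paste(attr(x, "condition"), attr(x, "direction")))
  expect_equal(
    bs0$curves[[which(meta0 == "control 1")]]$response,
    bs0$curves[[which(meta0 == "activated 1")]]$response)
})

test_that("latency displaces bar-sweep curves by speed times latency", {
  bs <- gen_bar_sweep(0, latency_s = 0.1, bar_speed = 21, noise_sigma = 0)
  meta <- sapply(bs$curves, function(x)
    paste(attr(x, "condition"), attr(x, "direction")))
  ctrl_p <- bs$curves[[which(meta == "control 1")]]
  ctrl_m <- bs$curves[[which(meta == "control -1")]]
  # analytic offset: the curves are Gaussians centered at +/- 2.1 deg
  est <- estimate_shift(ctrl_p, ctrl_m)
  expect_equal(est$shift_deg, -2 * 2.1, tolerance = 0.1)
})

test_that("flash-grid responses sample the Gaussian receptive field", {
  grid <- expand.grid(az = seq(-10, 10, 5), el = seq(-10, 10, 5))
  rf <- list(center_az = 0, center_el = 5, sigma = 8, amp = 6,
             baseline = -70)
  fg <- gen_flash_grid(rf, grid, noise_sigma = 0, seed = 1)
  m <- rf_map(fg)
  pk <- m[which.max(m$amplitude_mV), ]
  expect_equal(c(pk$position_az, pk$position_el), c(0, 5))

  # zero-amplitude field: every sample equals the baseline exactly
  fg0 <- gen_flash_grid(list(center_az = 0, center_el = 0, sigma = 8,
                             amp = 0, baseline = -70),
                        grid, noise_sigma = 0)
  expect_equal(unique(fg0$records$vm_mV), -70)
})

test_that("crossing-trajectory generator hits the configured group statistics", {
  # degenerate spread pins every minimum at the group mean
  s0 <- gen_crossing_trajectories(-1.2, 0, n_flies = 3, crossings_per_fly = 2)
  expect_equal(s0$ground_truth$min_y_mm, rep(-1.2, 6))
  expect_equal(min(s0$paths[[1]][[1]]$y_mm), -1.2, tolerance = 1e-9)

  # sampled group means land within 2 SEM of their targets
  for (mu in c(-1.0, -1.4)) {
    s <- gen_crossing_trajectories(mu, 0.3, n_flies = 20,
                                   crossings_per_fly = 10, seed = 11)
    sem <- 0.3 / sqrt(nrow(s$ground_truth))
    expect_lt(abs(mean(s$ground_truth$min_y_mm) - mu), 2 * sem)
  }

  # single crossing per fly: the median is that path's minimum
  s1 <- gen_crossing_trajectories(-1.0, 0.3, n_flies = 4,
                                  crossings_per_fly = 1, seed = 3)
  ch <- crossing_height(list(g = s1$paths))
  expect_equal(ch$per_fly$median_min_y_mm,
               s1$ground_truth$min_y_mm, tolerance = 1e-9)
})

test_that("generators are deterministic under a fixed seed", {
  p <- okr_params(seed = 5)
  expect_identical(gen_okr_trace(p, 5), gen_okr_trace(p, 5))
  gp <- gap_session_params(n_crossings = 3, seed = 5)
  expect_identical(gen_gap_session(gp), gen_gap_session(gp))
  expect_identical(gen_crossing_trajectories(-1, 0.3, 5, 3, seed = 5),
                   gen_crossing_trajectories(-1, 0.3, 5, 3, seed = 5))
})
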