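# Velocity estimation, saccade detection, main sequence, optokinetic
# metrics.

test_that("differentiator is exact for low-order signals", {
  tt <- seq(0, 1.99, by = 0.01)
  flat <- eye_trace(tt, rep(2, length(tt)))
  expect_equal(max(abs(differentiate(flat)$vx_deg_s)), 0, tolerance = 1e-10)
  ramp <- eye_trace(tt, 2 * tt)
  v <- differentiate(ramp)
  expect_equal(v$vx_deg_s, rep(2, length(tt)), tolerance = 1e-9)
  expect_error(differentiate(eye_trace(tt[1:3], tt[1:3]), window = 9),
               "longer than trace")
})

test_that("differentiator peak velocity matches the analytic derivative", {
  tt <- seq(0, 2, by = 1 / 200)
  tr <- eye_trace(tt, sin(2 * pi * tt))
  v <- differentiate(tr, window = 5)
  expect_equal(max(v$vx_deg_s), 2 * pi, tolerance = 0.01 * 2 * pi)
})

test_that("flat noisy traces yield no saccades", {
  set.seed(1)
  tt <- seq(0, 9.99, by = 0.01)
  tr <- eye_trace(tt, rnorm(length(tt), 0, 0.02))
  expect_equal(nrow(detect_saccades(tr)), 0L)
})

test_that("generated saccade trains are detected with accurate amplitudes", {
  p <- okr_params(gain = 0, nystagmus_rate = 0, noise_sigma_deg = 0,
                  sample_rate = 500, seed = 1)
  tt <- seq(0, 4, by = 1 / 500)
  sm <- rep(0, length(tt))
  sac <- flyretina:::add_saccades(tt, sm, c(1, 2.5), c(1, 3), p$k, p$b)
  tr <- eye_trace(tt, sac$x)
  det <- detect_saccades(tr, saccade_config(sg_window = 5))
  expect_equal(nrow(det), 2L)
  expect_equal(det$amp_x_deg, c(1, 3), tolerance = 0.05)
  expect_equal(det$onset_s, c(1, 2.5), tolerance = 0.05)
})

test_that("saccade detection is offset-invariant and sign-equivariant", {
  p <- okr_params(gain = 0, nystagmus_rate = 1, noise_sigma_deg = 0.02,
                  sample_rate = 500, seed = 8)
  sim <- gen_okr_trace(p, 30)
  tr <- sim$right
  cfg <- saccade_config(sg_window = 5)
  det <- detect_saccades(tr, cfg)
  expect_gt(nrow(det), 5)

  shifted <- eye_trace(tr$time_s, tr$x_deg + 100, tr$y_deg)
  det2 <- detect_saccades(shifted, cfg)
  expect_equal(det2$amp_x_deg, det$amp_x_deg, tolerance = 1e-9)
  expect_equal(det2$onset_s, det$onset_s)

  flipped <- eye_trace(tr$time_s, -tr$x_deg, tr$y_deg)
  det3 <- detect_saccades(flipped, cfg)
  expect_equal(det3$amp_x_deg, -det$amp_x_deg, tolerance = 1e-9)
  expect_equal(det3$peak_vel_deg_s, det$peak_vel_deg_s, tolerance = 1e-9)
})

test_that("main-sequence fit matches the closed-form regression oracle", {
  set.seed(2)
  amp <- runif(40, 0.3, 4)
  sac <- data.frame(amplitude_deg = amp, peak_vel_deg_s = 50 * amp^0.8)
  fit <- main_sequence(sac)
  expect_equal(fit$b, 0.8, tolerance = 0.01)
  expect_equal(fit$k, 50, tolerance = 1)
  orc <- oracle_power_fit(amp, 50 * amp^0.8)
  expect_equal(fit$b, orc$b, tolerance = 1e-10)
  expect_equal(fit$k, orc$k, tolerance = 1e-8)

  expect_error(main_sequence(sac[1:2, ]), "at least 3")
  same <- data.frame(amplitude_deg = rep(2, 5), peak_vel_deg_s = rep(80, 5))
  expect_error(main_sequence(same), "degenerate")
})

test_that("main sequence is recovered from detected saccades over seeds", {
  for (seed in 1:3) {
    p <- okr_params(gain = 0, nystagmus_rate = 1, noise_sigma_deg = 0,
                    sample_rate = 2000, k = 90, b = 0.8,
                    amp_range = c(0.3, 3), seed = seed)
    sim <- gen_okr_trace(p, 60)
    fit <- main_sequence(detect_saccades(sim$right,
                                         saccade_config(sg_window = 5)))
    expect_equal(fit$b, 0.8, tolerance = 0.02)
    expect_gt(fit$r, 0.99)
  }
})

test_that("desaccading recovers the smooth component", {
  p <- okr_params(gain = 0.2, nystagmus_rate = 1, noise_sigma_deg = 0,
                  sample_rate = 500, seed = 12)
  sim <- gen_okr_trace(p, 30)
  tr <- sim$right
  gt <- attr(tr, "ground_truth")
  cfg <- saccade_config(sg_window = 5)
  det <- detect_saccades(tr, cfg)
  expect_gt(nrow(det), 5)
  sm <- desaccade(tr, det)
  resid <- sm$x_deg - gt$smooth_x
  expect_lt(sqrt(mean((resid - mean(resid))^2)), 0.05)

  # no saccades: identity
  flat <- eye_trace(tr$time_s, gt$smooth_x)
  expect_equal(desaccade(flat, detect_saccades(flat, cfg))$x_deg,
               gt$smooth_x)

  # pure staircase flattens to near-constant
  tt <- seq(0, 10, by = 1 / 500)
  stair <- rep(0, length(tt))
  st <- flyretina:::add_saccades(tt, stair, seq(1, 9, 1), rep(1, 9), 90, 0.8)
  strace <- eye_trace(tt, st$x)
  flatout <- desaccade(strace, detect_saccades(strace, cfg))
  expect_lt(diff(range(flatout$x_deg)), 0.15)
})

test_that("initial velocity and gain recover the generator settings", {
  for (g in c(0, 0.1, 0.2, 0.5)) {
    p <- okr_params(gain = g, nystagmus_rate = 0.2, seed = 3)
    sim <- gen_okr_trace(p, 10)
    iv <- initial_velocity(sim$right, 0, 0.5)
    expect_lt(abs(okr_gain(iv, 15)$gain - g), 0.02)
    if (g == 0.2) {
      expect_equal(iv, -3, tolerance = 0.2)
      expect_equal(okr_gain(iv, 15)$sign, -1)
    }
  }
  flat <- eye_trace(seq(0, 2, 0.01), rep(0, 201))
  expect_equal(initial_velocity(flat, 0, 0.5), 0, tolerance = 1e-9)
  expect_error(okr_gain(1, 0), "undefined")
  expect_error(initial_velocity(flat, 1.9, 0.5), "outside")
})

test_that("optomotor index hits its landmark values", {
  tt <- seq(0, 4.99, by = 0.01)
  ep <- data.frame(start_s = 0, end_s = 5, direction = 1, speed_deg_s = 15)
  tracking <- eye_trace(tt, -2 * tt, epochs = ep)     # opposes the stimulus
  expect_equal(optomotor_index(tracking), 1)
  with_stim <- eye_trace(tt, 2 * tt, epochs = ep)     # follows the stimulus
  expect_equal(optomotor_index(with_stim), -1)
  still <- eye_trace(tt, rep(0, length(tt)), epochs = ep)
  oi <- optomotor_index(still)
  expect_equal(as.numeric(oi), 0)
  expect_true(isTRUE(attr(oi, "flagged")))
})
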