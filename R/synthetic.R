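# Synthetic-data generators: every input the pipeline consumes can be built
# here with recorded ground truth, so downstream stages are testable without
# any recordings.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Minimum-jerk position step, s(0)=0, s(1)=1; peak rate 1.875 at midpoint.
min_jerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Ground-truth trajectory
#'
#' Noise-free eye trajectory split into a smooth component and discrete
#' saccadic steps; the full position is their sum at every sample.
#'
#' @param times sample times, seconds, strictly increasing.
#' @param x,y full position, degrees.
#' @param smooth_x,smooth_y smooth (non-saccadic) component, degrees.
#' @param saccades data frame with columns `onset_s`, `offset_s`,
#'   `amplitude_deg` (signed, x axis), `peak_velocity_deg_s`, `direction`.
#' @return An object of class `trajectory_gt`.
#' @export
trajectory_gt <- function(times, x, y = numeric(length(times)),
                          smooth_x = x, smooth_y = y,
                          saccades = empty_saccade_events()) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, x = x, y = y,
                 smooth_x = smooth_x, smooth_y = smooth_y,
                 saccades = saccades),
            class = "trajectory_gt")
}

empty_saccade_events <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             amplitude_deg = numeric(0), peak_velocity_deg_s = numeric(0),
             direction = numeric(0))
}

#' Scene parameters for synthetic pseudopupil frames
#'
#' The deep pseudopupil appears in infrared video as seven bright dots laid
#' out like a single ommatidium's receptor array: one central dot ringed by a
#' hexagon. Frames are rendered as seven isotropic Gaussian blobs on a flat
#' background with additive Gaussian pixel noise.
#'
#' @param frame_size `c(height, width)` in pixels.
#' @param dot_spacing_px center-to-neighbor distance in pixels, > 0.
#' @param dot_sigma_px Gaussian radius of each dot, pixels.
#' @param dot_amplitude peak intensity of each dot above background.
#' @param noise_sigma SD of additive pixel noise (0 = noiseless).
#' @param background flat background intensity.
#' @param seed integer seed fixing all randomness of the rendered stack.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(frame_size = c(128L, 128L), dot_spacing_px = 12,
                         dot_sigma_px = 2, dot_amplitude = 200,
                         noise_sigma = 2, background = 10, seed = 1L) {
  stopifnot(dot_spacing_px > 0, dot_sigma_px > 0, all(frame_size >= 16))
  structure(list(frame_size = as.integer(frame_size),
                 dot_spacing_px = dot_spacing_px,
                 dot_sigma_px = dot_sigma_px,
                 dot_amplitude = dot_amplitude,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# Offsets of the seven pseudopupil dots (center + hexagon), in px,
# in (col, row) = (x right, y down) order.
pseudopupil_offsets <- function(spacing) {
  ang <- (0:5) * pi / 3
  rbind(c(0, 0), cbind(spacing * cos(ang), spacing * sin(ang)))
}

#' Render a synthetic pseudopupil frame stack
#'
#' Converts a ground-truth trajectory from degrees to pixels via the given
#' degrees-per-spacing calibration and renders one frame per sample: seven
#' Gaussian dots whose common centroid follows the trajectory, plus additive
#' Gaussian noise. Pixel convention is image-style: origin at the top-left
#' pixel center, x rightward (columns), y downward (rows); a positive y in
#' head-centered degrees therefore moves the dots up the image.
#'
#' @param traj a [trajectory_gt] in degrees.
#' @param scene a [scene_params].
#' @param deg_per_spacing degrees per inter-photoreceptor spacing used for
#'   the degree-to-pixel conversion (default 5).
#' @param frame_rate frame rate stored in the output stack; defaults to the
#'   trajectory's own sampling rate.
#' @return A list with elements `stack` (a [frame_stack]), `px_traj`
#'   (data frame `frame`, `x_px`, `y_px`: the ground-truth centroid in pixel
#'   coordinates) and `scene`.
#' @export
gen_frames <- function(traj, scene, deg_per_spacing = 5, frame_rate = NULL) {
  h <- scene$frame_size[1]; w <- scene$frame_size[2]
  px_per_deg <- scene$dot_spacing_px / deg_per_spacing
  cx <- (w + 1) / 2 + traj$x * px_per_deg
  cy <- (h + 1) / 2 - traj$y * px_per_deg   # +y (head frame) is up the image
  off <- pseudopupil_offsets(scene$dot_spacing_px)
  margin <- 3 * scene$dot_sigma_px
  reach <- scene$dot_spacing_px + margin
  bad <- which(cx - reach < 1 | cx + reach > w | cy - reach < 1 | cy + reach > h)
  if (length(bad))
    stop(sprintf("trajectory leaves the frame at sample %d (t = %.4g s)",
                 bad[1], traj$times[bad[1]]))
  xs <- seq_len(w); ys <- seq_len(h)
  n <- length(cx)
  frames <- array(0, dim = c(h, w, n))
  s2 <- 2 * scene$dot_sigma_px^2
  with_seed(scene$seed, {
    for (k in seq_len(n)) {
      fr <- matrix(scene$background, h, w)
      for (d in seq_len(nrow(off))) {
        dx <- xs - (cx[k] + off[d, 1])
        dy <- ys - (cy[k] + off[d, 2])
        fr <- fr + scene$dot_amplitude * outer(exp(-dy^2 / s2), exp(-dx^2 / s2))
      }
      if (scene$noise_sigma > 0)
        fr <- fr + matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w)
      frames[, , k] <- fr
    }
  })
  if (is.null(frame_rate))
    frame_rate <- if (length(traj$times) > 1) 1 / stats::median(diff(traj$times)) else 1
  list(stack = frame_stack(frames, frame_rate),
       px_traj = data.frame(frame = seq_len(n), x_px = cx, y_px = cy),
       scene = scene)
}

#' Optokinetic stimulation parameters
#'
#' Parameters of the synthetic optokinetic response: smooth tracking at
#' sub-unity gain opposing the stimulus, interrupted by nystagmus
#' counter-saccades whose peak velocity follows a main-sequence power law
#' `v_peak = k * |A|^b`. Counter-saccade waveforms are minimum-jerk steps
#' whose duration is set by the main sequence
#' (`d = 1.875 * |A|^(1 - b) / k`), so generated peak velocities equal the
#' law exactly before sampling.
#'
#' @param stimulus_speed grating speed, deg/s.
#' @param gain dimensionless tracking gain, >= 0.
#' @param nystagmus_rate counter-saccade rate during motion epochs, events/s.
#' @param k,b main-sequence coefficient (deg/s at 1 deg) and exponent (> 0).
#' @param amp_range range (deg) from which counter-saccade amplitudes are
#'   drawn uniformly.
#' @param noise_sigma_deg SD of additive position noise, degrees.
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return A list of class `okr_params`.
#' @export
okr_params <- function(stimulus_speed = 15, gain = 0.2, nystagmus_rate = 0.2,
                       k = 90, b = 0.8, amp_range = c(0.5, 3),
                       noise_sigma_deg = 0.02, sample_rate = 100, seed = 1L) {
  stopifnot(gain >= 0, sample_rate > 0, b > 0, k > 0)
  structure(list(stimulus_speed = stimulus_speed, gain = gain,
                 nystagmus_rate = nystagmus_rate, k = k, b = b,
                 amp_range = amp_range, noise_sigma_deg = noise_sigma_deg,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "okr_params")
}

# Place saccade events as a censored Poisson process: rate events/s inside
# [t0, t1], no two onsets closer than min_sep.
draw_event_times <- function(t0, t1, rate, min_sep) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  tt <- numeric(0); t <- t0
  repeat {
    t <- t + stats::rexp(1, rate)
    if (t > t1) break
    if (!length(tt) || t - tt[length(tt)] >= min_sep) tt <- c(tt, t)
  }
  tt
}

# Superimpose minimum-jerk steps on a smooth trace; returns the summed trace
# and the realized event table.
add_saccades <- function(times, smooth, onsets, amps, k, b) {
  x <- smooth
  if (!length(onsets))
    return(list(x = x, events = empty_saccade_events()))
  dur <- 1.875 * abs(amps)^(1 - b) / k
  for (i in seq_along(onsets)) {
    u <- (times - onsets[i]) / dur[i]
    x <- x + amps[i] * min_jerk(u)
  }
  ev <- data.frame(onset_s = onsets, offset_s = onsets + dur,
                   amplitude_deg = amps,
                   peak_velocity_deg_s = 1.875 * abs(amps) / dur,
                   direction = sign(amps))
  list(x = x, events = ev[order(ev$onset_s), , drop = FALSE])
}

#' Generate a binocular optokinetic trace pair
#'
#' Simulates the retinal optokinetic response of both eyes to a moving
#' grating. During motion epochs the smooth component of each stimulated eye
#' moves at `-direction * gain * stimulus_speed` (the retina tracks opposite
#' to the stimulus: because the fixed lenses form an inverted image, moving
#' the retina against the stimulus slows image motion). Counter-saccades are
#' drawn at `nystagmus_rate` and step opposite to the tracking direction.
#'
#' @param params an [okr_params].
#' @param duration trace duration, s, > 0.
#' @param epochs data frame of motion epochs (`start_s`, `end_s`,
#'   `direction`, `speed_deg_s`); default one epoch covering the middle of
#'   the trace at `params$stimulus_speed`, direction +1.
#' @param unilateral `NULL` (both eyes stimulated) or `"left"`/`"right"`:
#'   only that eye is driven; the other eye stays flat apart from noise,
#'   mirroring monocular stimulation.
#' @return A list of class `okr_sim` with elements `left` and `right`, each
#'   an [eye_trace] with the noise-free [trajectory_gt] attached as attribute
#'   `ground_truth`, plus `epochs`.
#' @export
gen_okr_trace <- function(params, duration, epochs = NULL, unilateral = NULL) {
  stopifnot(duration > 0)
  if (is.null(epochs))
    epochs <- data.frame(start_s = 0, end_s = duration, direction = 1,
                         speed_deg_s = params$stimulus_speed)
  dt <- 1 / params$sample_rate
  times <- seq(0, duration, by = dt)
  n <- length(times)
  with_seed(params$seed, {
    eyes <- lapply(c("left", "right"), function(eye) {
      driven <- is.null(unilateral) || identical(unilateral, eye)
      v <- numeric(n)
      if (driven) {
        for (i in seq_len(nrow(epochs))) {
          idx <- times >= epochs$start_s[i] & times < epochs$end_s[i]
          v[idx] <- -epochs$direction[i] * params$gain * epochs$speed_deg_s[i]
        }
      }
      smooth <- cumsum(c(0, v[-n])) * dt
      onsets <- numeric(0); amps <- numeric(0)
      if (driven && params$nystagmus_rate > 0) {
        for (i in seq_len(nrow(epochs))) {
          on <- draw_event_times(epochs$start_s[i], epochs$end_s[i] - 0.2,
                                 params$nystagmus_rate, 0.4)
          if (length(on)) {
            a <- stats::runif(length(on), params$amp_range[1],
                              params$amp_range[2])
            # counter-saccades reset against tracking, i.e. with the stimulus
            onsets <- c(onsets, on)
            amps <- c(amps, epochs$direction[i] * a)
          }
        }
      }
      sac <- add_saccades(times, smooth, onsets, amps, params$k, params$b)
      gt <- trajectory_gt(times, sac$x, smooth_x = smooth,
                          saccades = sac$events)
      noisy <- sac$x + stats::rnorm(n, 0, params$noise_sigma_deg)
      tr <- eye_trace(times, noisy, eye = eye, epochs = epochs)
      attr(tr, "ground_truth") <- gt
      tr
    })
  })
  structure(list(left = eyes[[1]], right = eyes[[2]], epochs = epochs),
            class = "okr_sim")
}

#' Gap-crossing session parameters
#'
#' Conditions of the head-fixed gap-crossing paradigm: a fly walks on a
#' wheel carrying two gaps 180 degrees apart; a wheel-position threshold a
#' little before each gap marks a forward crossing, and at each crossing the
#' two retinas make a mirror-symmetric convergent excursion (left pseudopupil
#' shifts rightward, right pseudopupil leftward).
#'
#' @param wheel_speed mean forward wheel speed, deg/s. The default 3.5 deg/s
#'   yields one forward crossing roughly every 51 s.
#' @param gap_angles wheel angles of the two gaps within one revolution;
#'   must be 180 degrees apart.
#' @param threshold_lead angular distance before each gap at which the
#'   crossing-detection threshold sits, deg.
#' @param vergence_amplitude peak per-eye excursion at each crossing, deg.
#' @param vergence_timecourse full width of the raised-cosine vergence pulse, s.
#' @param n_crossings number of forward crossings to generate; ignored when
#'   `crossing_times` is supplied.
#' @param crossing_times optional explicit forward-crossing times, s; the
#'   wheel trace is built to pass successive thresholds at exactly these
#'   times.
#' @param duration session length, s; defaults to what `n_crossings` needs.
#' @param lighting optional lighting epochs (`start_s`, `end_s`, `label`);
#'   default splits the session into thirds labelled `on1`, `dark`, `on2`.
#' @param noise_sigma_deg eye-trace noise SD, deg.
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return A list of class `gap_session_params`.
#' @export
gap_session_params <- function(wheel_speed = 3.5, gap_angles = c(90, 270),
                               threshold_lead = 10, vergence_amplitude = 2,
                               vergence_timecourse = 1, n_crossings = 10,
                               crossing_times = NULL, duration = NULL,
                               lighting = NULL, noise_sigma_deg = 0.02,
                               sample_rate = 100, seed = 1L) {
  stopifnot(n_crossings >= 0, sample_rate > 0, wheel_speed > 0)
  if (abs(diff(gap_angles)) %% 360 != 180)
    stop("the two gaps must sit 180 degrees apart on the wheel")
  structure(list(wheel_speed = wheel_speed, gap_angles = gap_angles,
                 threshold_lead = threshold_lead,
                 vergence_amplitude = vergence_amplitude,
                 vergence_timecourse = vergence_timecourse,
                 n_crossings = n_crossings, crossing_times = crossing_times,
                 duration = duration, lighting = lighting,
                 noise_sigma_deg = noise_sigma_deg,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "gap_session_params")
}

#' Generate a synthetic gap-crossing session
#'
#' Builds a wheel trace that crosses the detection threshold in the forward
#' direction exactly the configured number of times, with a convergent
#' vergence pulse of the configured amplitude locked to every crossing:
#' the left-eye x shifts by `+vergence_amplitude` and the right-eye x by
#' `-vergence_amplitude` at the pulse peak, so the sign-inverted product of
#' the two shifts goes positive at each event.
#'
#' @param params a [gap_session_params].
#' @return A [gap_session] with attributes `ground_truth_crossings` (data
#'   frame `time_s`, `direction`, `lighting`) and `params`. The crossing
#'   threshold (wheel phase within a half-revolution) is attached as
#'   attribute `threshold`.
#' @export
gen_gap_session <- function(params) {
  dt <- 1 / params$sample_rate
  thr <- params$gap_angles[1] - params$threshold_lead
  if (!is.null(params$crossing_times)) {
    tc <- sort(params$crossing_times)
    if (length(tc) >= 2 && min(diff(tc)) <= 0)
      stop("crossing_times must be strictly increasing")
  } else if (params$n_crossings > 0) {
    # constant speed: one crossing per half revolution
    t1 <- thr / params$wheel_speed
    tc <- t1 + (seq_len(params$n_crossings) - 1) * 180 / params$wheel_speed
  } else tc <- numeric(0)
  duration <- params$duration
  if (is.null(duration))
    duration <- if (length(tc)) max(tc) + 30 else 60
  if (length(tc) && max(tc) >= duration)
    stop(sprintf("duration %.3g s too short for %d crossings (last at %.3g s)",
                 duration, length(tc), max(tc)))
  times <- seq(0, duration, by = dt)
  n <- length(times)

  # piecewise-linear wheel trace hitting threshold k at crossing time k
  knots_t <- c(0, tc, duration)
  knots_w <- c(0, thr + 180 * (seq_along(tc) - 1),
               if (length(tc)) thr + 180 * (length(tc) - 1) +
                 params$wheel_speed * (duration - max(tc))
               else params$wheel_speed * duration * 1e-6)
  if (length(tc) == 0) knots_w[2] <- min(thr * 0.5, 1)  # stay below threshold
  wheel <- stats::approx(knots_t, knots_w, xout = times, rule = 2)$y

  lighting <- params$lighting
  if (is.null(lighting))
    lighting <- data.frame(start_s = duration * c(0, 1, 2) / 3,
                           end_s = duration * c(1, 2, 3) / 3,
                           label = c("on1", "dark", "on2"))
  light_of <- function(t) {
    i <- findInterval(t, lighting$start_s)
    lighting$label[pmax(i, 1)]
  }

  with_seed(params$seed, {
    pulse <- numeric(n)
    tau <- params$vergence_timecourse
    for (t0 in tc) {
      idx <- abs(times - t0) < tau / 2
      pulse[idx] <- pulse[idx] +
        0.5 * (1 + cos(2 * pi * (times[idx] - t0) / tau))
    }
    a <- params$vergence_amplitude
    xl <- a * pulse + stats::rnorm(n, 0, params$noise_sigma_deg)
    xr <- -a * pulse + stats::rnorm(n, 0, params$noise_sigma_deg)
  })
  left <- eye_trace(times, xl, eye = "left")
  right <- eye_trace(times, xr, eye = "right")
  ses <- gap_session(times, wheel, left, right, lighting)
  attr(ses, "ground_truth_crossings") <-
    data.frame(time_s = tc, direction = rep("forward", length(tc)),
               lighting = if (length(tc)) light_of(tc) else character(0))
  attr(ses, "threshold") <- thr
  attr(ses, "params") <- params
  ses
}

#' Generate bar-sweep tuning curves at two retinal positions
#'
#' Emulates membrane-voltage responses of a visual neuron to a bar sweeping
#' across the screen in both directions, under a control condition and a
#' condition in which the retina has been displaced by `shift_deg`: the
#' displaced-condition curves are the control curves translated by
#' `shift_deg` in screen coordinates. A fixed response latency displaces the
#' apparent curve by `direction * bar_speed * latency_s`, equal and opposite
#' for the two sweep directions.
#'
#' @param shift_deg true angular receptive-field shift between conditions,
#'   degrees (screen coordinates).
#' @param latency_s response latency, s.
#' @param rf list with `center` (deg), `sigma` (deg), `amp` (mV) describing
#'   the Gaussian receptive-field profile.
#' @param bar_speed bar speed, deg/s (default 21).
#' @param positions screen position grid, deg; must cover the receptive
#'   field in both conditions.
#' @param n_trials trials per condition and direction.
#' @param noise_sigma per-sample trial noise SD, mV.
#' @param seed integer seed.
#' @return A list of class `bar_sweep_set`: four [tuning_curve] objects
#'   (condition x direction) in `curves`, plus the generating parameters.
#' @export
gen_bar_sweep <- function(shift_deg, latency_s = 0,
                          rf = list(center = 0, sigma = 9, amp = 8),
                          bar_speed = 21,
                          positions = seq(-56.25, 56.25, by = 2.25),
                          n_trials = 7, noise_sigma = 0, seed = 1L) {
  span <- range(positions)
  need <- rf$center + c(-1, 1) * (3 * rf$sigma) + c(min(0, shift_deg),
                                                    max(0, shift_deg))
  if (need[1] < span[1] || need[2] > span[2])
    stop("screen span does not cover the receptive field in both conditions")
  combos <- expand.grid(condition = c("control", "activated"),
                        direction = c(1L, -1L), stringsAsFactors = FALSE)
  with_seed(seed, {
    curves <- lapply(seq_len(nrow(combos)), function(i) {
      cond <- combos$condition[i]; dir <- combos$direction[i]
      center <- rf$center + if (cond == "activated") shift_deg else 0
      # latency: the response to the bar at p is logged at screen position
      # p + dir * speed * latency
      mu <- rf$amp *
        exp(-(positions - center - dir * bar_speed * latency_s)^2 /
              (2 * rf$sigma^2))
      trials <- matrix(mu, length(positions), n_trials) +
        matrix(stats::rnorm(length(positions) * n_trials, 0, noise_sigma),
               length(positions), n_trials)
      tuning_curve(positions, trials, direction = dir, condition = cond)
    })
  })
  structure(list(curves = curves, shift_deg = shift_deg,
                 latency_s = latency_s, bar_speed = bar_speed, rf = rf),
            class = "bar_sweep_set")
}

#' Generate flash-grid responses from a Gaussian receptive field
#'
#' Emulates membrane-voltage records during brief full-contrast flashes at
#' each node of a screen grid. The response amplitude at a grid position is
#' a 2-D Gaussian receptive field evaluated there; the within-trial time
#' course is an exponential rise during the flash and decay after it.
#'
#' @param rf list with `center_az`, `center_el` (deg), `sigma` (deg),
#'   `amp` (mV), `baseline` (mV).
#' @param grid data frame with columns `az`, `el` (deg), non-empty.
#' @param flash_dur flash duration, s (default 0.1).
#' @param n_repeats flashes per grid position.
#' @param noise_sigma per-sample voltage noise SD, mV.
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return A list of class `flash_grid_sim`: `records` (data frame
#'   `position_az`, `position_el`, `trial`, `time_s`, `vm_mV`; flash onset at
#'   time 0), `flash_onset_s`, `flash_dur_s`, and `rf` (ground truth).
#' @export
gen_flash_grid <- function(rf, grid, flash_dur = 0.1, n_repeats = 3,
                           noise_sigma = 0, sample_rate = 500, seed = 1L) {
  if (!nrow(grid)) stop("grid must be non-empty")
  tt <- seq(-0.2, 0.5, by = 1 / sample_rate)
  rise <- 0.02; fall <- 0.1
  g <- ifelse(tt <= 0, 0,
              (1 - exp(-tt / rise)) * exp(-pmax(0, tt - flash_dur) / fall))
  amp <- rf$amp * exp(-((grid$az - rf$center_az)^2 +
                          (grid$el - rf$center_el)^2) / (2 * rf$sigma^2))
  with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      do.call(rbind, lapply(seq_len(n_repeats), function(r) {
        vm <- rf$baseline + amp[i] * g +
          stats::rnorm(length(tt), 0, noise_sigma)
        data.frame(position_az = grid$az[i], position_el = grid$el[i],
                   trial = r, time_s = tt, vm_mV = vm)
      }))
    }))
  })
  structure(list(records = recs, flash_onset_s = 0, flash_dur_s = flash_dur,
                 rf = rf),
            class = "flash_grid_sim")
}

#' Generate free-walking gap-crossing trajectories
#'
#' Emulates side-view x-y paths of flies crossing a gap: each path descends
#' along the near wall to a minimum height drawn from the group distribution,
#' then ascends across to the far side. Ground-truth minima are recorded per
#' crossing.
#'
#' @param group_mean_y group mean of the per-crossing minimum height, mm
#'   (negative = below the gap rim).
#' @param group_sd between-crossing SD of the minimum height, mm.
#' @param n_flies number of flies, >= 1.
#' @param crossings_per_fly crossings per fly.
#' @param gap_length_mm horizontal extent of the gap, mm (default 3.5).
#' @param n_points samples per path; the default (odd) count samples the
#'   mid-gap minimum exactly.
#' @param seed integer seed.
#' @return A list of class `crossing_sim`: `paths` (list per fly of data
#'   frames `x_mm`, `y_mm`) and `ground_truth` (data frame `fly`, `crossing`,
#'   `min_y_mm`).
#' @export
gen_crossing_trajectories <- function(group_mean_y, group_sd, n_flies,
                                      crossings_per_fly, gap_length_mm = 3.5,
                                      n_points = 61, seed = 1L) {
  stopifnot(n_flies >= 1, crossings_per_fly >= 1)
  x <- seq(0, gap_length_mm, length.out = n_points)
  with_seed(seed, {
    gt <- expand.grid(crossing = seq_len(crossings_per_fly),
                      fly = seq_len(n_flies))[, c("fly", "crossing")]
    gt$min_y_mm <- stats::rnorm(nrow(gt), group_mean_y, group_sd)
    paths <- lapply(seq_len(n_flies), function(f) {
      rows <- gt[gt$fly == f, ]
      lapply(seq_len(nrow(rows)), function(i) {
        data.frame(x_mm = x,
                   y_mm = rows$min_y_mm[i] * sin(pi * x / gap_length_mm))
      })
    })
  })
  structure(list(paths = paths, ground_truth = gt), class = "crossing_sim")
}
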