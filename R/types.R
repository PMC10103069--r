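#' Eye-position trace
#'
#' An `eye_trace` is a data frame with columns `time_s`, `x_deg` and `y_deg`
#' holding the 2-D retinal (pseudopupil) position of one eye in degrees on a
#' uniform time base. Stimulus epochs, the eye label and the sample rate
#' travel as attributes so that downstream operations (saccade detection,
#' optokinetic gain, triggered averages) never need side tables.
#'
#' Axis convention: +x is toward the fly's right, +y is up, head-centered,
#' identical for both eyes.
#'
#' @param time_s numeric vector of time stamps in seconds, strictly increasing.
#' @param x_deg,y_deg horizontal and vertical position in degrees.
#' @param eye eye label, `"left"` or `"right"` (or `"unknown"`).
#' @param epochs optional data frame of stimulus epochs with columns
#'   `start_s`, `end_s`, `direction` (+1 rightward / -1 leftward, 0 static),
#'   `speed_deg_s`, and optionally `laterality` and `lighting`.
#' @return An object of class `eye_trace`.
#' @export
eye_trace <- function(time_s, x_deg, y_deg = numeric(length(time_s)),
                      eye = "unknown", epochs = NULL) {
  stopifnot(length(time_s) == length(x_deg), length(x_deg) == length(y_deg))
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  tr <- data.frame(time_s = as.numeric(time_s),
                   x_deg = as.numeric(x_deg),
                   y_deg = as.numeric(y_deg))
  attr(tr, "eye") <- eye
  attr(tr, "epochs") <- epochs
  attr(tr, "sample_rate") <- if (length(time_s) > 1L)
    1 / stats::median(diff(time_s)) else NA_real_
  class(tr) <- c("eye_trace", "data.frame")
  tr
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %s eye, %d samples @ %.6g Hz, %.3g s\n",
              attr(x, "eye"), nrow(x), attr(x, "sample_rate"),
              diff(range(x$time_s))))
  ep <- attr(x, "epochs")
  if (!is.null(ep)) cat(sprintf("  %d stimulus epoch(s)\n", nrow(ep)))
  invisible(x)
}

#' Sample rate of an eye trace
#' @param trace an [eye_trace].
#' @return Sampling rate in Hz.
#' @export
trace_rate <- function(trace) attr(trace, "sample_rate")

#' Frame stack
#'
#' A `frame_stack` wraps an ordered set of equally shaped grayscale frames
#' (stored as a height x width x n array) plus the acquisition rate.
#'
#' @param frames numeric array `[h, w, n]` of pixel intensities, or a list of
#'   matrices of identical dimensions.
#' @param frame_rate acquisition rate in Hz, > 0.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share the same shape")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3L, frame_rate > 0)
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g Hz\n",
              d[3], d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Pixel-to-degree calibration
#'
#' Pseudopupil displacements are measured in pixels; the natural angular unit
#' of the compound eye is the inter-ommatidial angle. A calibration couples
#' the pixel distance between neighboring pseudopupil dots
#' (`px_per_spacing`) with the angular magnitude of one inter-photoreceptor
#' spacing (`deg_per_spacing`, the inter-ommatidial angle, default 5 degrees).
#'
#' @param px_per_spacing pixels per inter-photoreceptor spacing, > 0.
#' @param deg_per_spacing degrees per spacing, > 0. Default 5.
#' @return An object of class `pseudopupil_calibration`.
#' @export
calibration <- function(px_per_spacing, deg_per_spacing = 5) {
  stopifnot(px_per_spacing > 0, deg_per_spacing > 0)
  structure(list(px_per_spacing = px_per_spacing,
                 deg_per_spacing = deg_per_spacing),
            class = "pseudopupil_calibration")
}

#' Binocular gap-crossing session
#'
#' Bundles a wheel-position trace with synchronized left- and right-eye
#' traces and lighting epochs, all on one shared clock.
#'
#' @param time_s shared time base, seconds.
#' @param wheel wheel position, degrees of wheel rotation (unwrapped,
#'   forward = increasing).
#' @param left,right [eye_trace] objects on the same time base.
#' @param lighting data frame with columns `start_s`, `end_s`, `label`.
#' @return An object of class `gap_session`.
#' @export
gap_session <- function(time_s, wheel, left, right, lighting = NULL) {
  stopifnot(length(time_s) == length(wheel),
            nrow(left) == length(time_s), nrow(right) == length(time_s))
  structure(list(time_s = as.numeric(time_s), wheel = as.numeric(wheel),
                 left = left, right = right, lighting = lighting),
            class = "gap_session")
}

#' @export
print.gap_session <- function(x, ...) {
  cat(sprintf("<gap_session> %d samples, %.3g s", length(x$time_s),
              diff(range(x$time_s))))
  if (!is.null(x$lighting))
    cat(sprintf(", %d lighting epoch(s)", nrow(x$lighting)))
  cat("\n")
  invisible(x)
}

#' Stimulus-position tuning curve
#'
#' Mean response (e.g. membrane voltage) indexed by screen position, with
#' the per-trial responses retained, for one sweep direction and condition.
#'
#' @param position_deg screen positions, degrees, strictly monotonic.
#' @param trials numeric matrix, one column per trial, rows matching
#'   `position_deg`.
#' @param direction sweep direction, `+1` (rightward) or `-1` (leftward).
#' @param condition condition label, e.g. `"control"` or `"activated"`.
#' @return An object of class `tuning_curve`: a data frame with columns
#'   `position_deg` and `response` (the trial mean), carrying the trial
#'   matrix, direction and condition as attributes.
#' @export
tuning_curve <- function(position_deg, trials, direction = 1L,
                         condition = "control") {
  trials <- as.matrix(trials)
  stopifnot(nrow(trials) == length(position_deg))
  d <- diff(position_deg)
  if (!(all(d > 0) || all(d < 0))) stop("positions must be strictly monotonic")
  tc <- data.frame(position_deg = position_deg,
                   response = rowMeans(trials))
  attr(tc, "trials") <- trials
  attr(tc, "direction") <- direction
  attr(tc, "condition") <- condition
  class(tc) <- c("tuning_curve", "data.frame")
  tc
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s, direction %+d, %d positions, %d trial(s)\n",
              attr(x, "condition"), attr(x, "direction"), nrow(x),
              ncol(attr(x, "trials"))))
  invisible(x)
}
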