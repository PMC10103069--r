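# Deep-pseudopupil detection and tracking.
#
# The deep pseudopupil is imaged as up to seven bright dots on a darker
# background. Detection thresholds the frame robustly, labels connected
# components, keeps the brightest seven, and takes their intensity-weighted
# centroid as the sub-pixel retinal position.

#' Tracker configuration
#'
#' @param k_mad threshold is background median + `k_mad` * MAD; if nothing
#'   exceeds it the Otsu threshold is used as fallback.
#' @param max_dots components retained (brightest first), default 7.
#' @param max_components more connected components than this raises an
#'   ambiguous-scene error.
#' @param fill policy for frames where detection fails inside a stack:
#'   `"hold"` repeats the last good position, `"gap"` leaves `NA`.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(k_mad = 6, max_dots = 7L, max_components = 50L,
                           fill = c("hold", "gap")) {
  structure(list(k_mad = k_mad, max_dots = as.integer(max_dots),
                 max_components = as.integer(max_components),
                 fill = match.arg(fill)),
            class = "tracker_config")
}

no_pupil <- function(msg)
  stop(errorCondition(msg, class = c("fr_no_pupil", "error", "condition")))
ambiguous_scene <- function(msg)
  stop(errorCondition(msg, class = c("fr_ambiguous_scene", "error", "condition")))

#' Detect the deep pseudopupil in one frame
#'
#' Thresholds the frame at background median + `k_mad` MAD (Otsu fallback
#' when no pixel clears the robust threshold), groups supra-threshold pixels
#' into connected components, ranks components by integrated intensity and
#' retains at most `max_dots`. Per-dot and cluster centroids are
#' intensity-weighted (weights are intensities above the background median),
#' giving sub-pixel positions. Pixel coordinates are image-style: x = column
#' (rightward), y = row (downward), origin at the top-left pixel center.
#'
#' @param frame numeric intensity matrix.
#' @param cfg a [tracker_config].
#' @return A list of class `dot_set`: `dots` (data frame `x_px`, `y_px`,
#'   `intensity`, brightest first), `centroid` (`c(x, y)` over all retained
#'   pixels) and `n_dots`.
#' @export
detect_pseudopupil <- function(frame, cfg = tracker_config()) {
  if (!length(frame)) no_pupil("empty frame")
  med <- stats::median(frame)
  md <- stats::mad(frame)
  thr <- med + cfg$k_mad * md
  # the robust threshold degenerates on noiseless backgrounds (MAD 0) or
  # when it fails to separate dots from background; fall back to Otsu
  if (!any(frame > thr) || md == 0 || mean(frame > thr) > 0.2) {
    rng <- range(frame)
    if (diff(rng) <= 0) no_pupil("no pixel above threshold (flat frame)")
    scaled <- (frame - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
    if (!any(frame > thr)) no_pupil("no pixel above threshold")
  }
  mask <- matrix(as.integer(EBImage::bwlabel(frame > thr)), nrow(frame))
  n_comp <- max(mask)
  if (n_comp > cfg$max_components)
    ambiguous_scene(sprintf("%d components exceed max_components = %d",
                            n_comp, cfg$max_components))
  w <- pmax(frame - med, 0)
  comp_int <- vapply(seq_len(n_comp),
                     function(l) sum(frame[mask == l]), numeric(1))
  keep <- order(comp_int, decreasing = TRUE)[seq_len(min(cfg$max_dots, n_comp))]
  rows <- row(frame); cols <- col(frame)
  dots <- do.call(rbind, lapply(keep, function(l) {
    sel <- mask == l
    ww <- w[sel]
    data.frame(x_px = sum(cols[sel] * ww) / sum(ww),
               y_px = sum(rows[sel] * ww) / sum(ww),
               intensity = sum(frame[sel]))
  }))
  sel <- matrix(mask %in% keep, nrow(frame))
  ww <- w[sel]
  centroid <- c(x = sum(cols[sel] * ww) / sum(ww),
                y = sum(rows[sel] * ww) / sum(ww))
  structure(list(dots = dots, centroid = centroid, n_dots = nrow(dots)),
            class = "dot_set")
}

#' Track the pseudopupil centroid through a frame stack
#'
#' Runs [detect_pseudopupil()] on every frame. Frames where detection fails
#' are flagged (`ok = FALSE`) and their position filled per the configured
#' policy; the trace always has one row per frame.
#'
#' @param stack a [frame_stack].
#' @param cfg a [tracker_config].
#' @return Data frame `frame`, `time_s`, `x_px`, `y_px`, `ok`.
#' @export
track_stack <- function(stack, cfg = tracker_config()) {
  n <- n_frames(stack)
  if (n < 1) stop("stack has no frames")
  x <- y <- rep(NA_real_, n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    ds <- tryCatch(detect_pseudopupil(stack$frames[, , k], cfg),
                   error = function(e) NULL)
    if (!is.null(ds)) {
      x[k] <- ds$centroid["x"]; y[k] <- ds$centroid["y"]; ok[k] <- TRUE
    }
  }
  if (!any(ok)) stop("pseudopupil detection failed on every frame")
  if (cfg$fill == "hold") {
    last <- which(ok)[1]
    for (k in seq_len(n)) {
      if (ok[k]) last <- k else { x[k] <- x[last]; y[k] <- y[last] }
    }
  }
  data.frame(frame = seq_len(n),
             time_s = (seq_len(n) - 1) / stack$frame_rate,
             x_px = x, y_px = y, ok = ok)
}

#' Estimate the inter-dot spacing of a detected pseudopupil
#'
#' Identifies the central dot (nearest the cluster centroid) and returns the
#' median distance from it to the remaining dots — the pixel equivalent of
#' one inter-photoreceptor spacing, used for degree calibration.
#'
#' @param dots a `dot_set` from [detect_pseudopupil()] with at least 2 dots.
#' @return Pixels per spacing (scalar).
#' @export
estimate_spacing <- function(dots) {
  d <- dots$dots
  if (nrow(d) < 2) stop("need at least 2 dots to estimate spacing")
  dc <- sqrt((d$x_px - dots$centroid["x"])^2 + (d$y_px - dots$centroid["y"])^2)
  ctr <- which.min(dc)
  stats::median(sqrt((d$x_px[-ctr] - d$x_px[ctr])^2 +
                       (d$y_px[-ctr] - d$y_px[ctr])^2))
}

#' Convert a pixel trace to degrees
#'
#' Scales pixel displacements by the calibration
#' (`deg = px / px_per_spacing * deg_per_spacing`) relative to a reference
#' position (default: the trace mean) and flips the vertical axis so that
#' the output follows the head-centered convention (+x toward the fly's
#' right, +y up).
#'
#' @param px_trace data frame from [track_stack()] (columns `time_s`,
#'   `x_px`, `y_px`).
#' @param calib a [calibration].
#' @param reference `"mean"` (default), `"first"`, or a numeric `c(x, y)`
#'   pixel position taken as 0 degrees.
#' @param eye eye label for the output trace.
#' @return An [eye_trace] in degrees.
#' @export
to_degrees <- function(px_trace, calib, reference = "mean", eye = "unknown") {
  if (calib$px_per_spacing <= 0) stop("px_per_spacing must be positive")
  ref <- if (is.numeric(reference)) reference
  else if (identical(reference, "first"))
    c(px_trace$x_px[1], px_trace$y_px[1])
  else c(mean(px_trace$x_px, na.rm = TRUE), mean(px_trace$y_px, na.rm = TRUE))
  s <- calib$deg_per_spacing / calib$px_per_spacing
  eye_trace(px_trace$time_s,
            (px_trace$x_px - ref[1]) * s,
            -(px_trace$y_px - ref[2]) * s,   # image y is down; head y is up
            eye = eye)
}
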