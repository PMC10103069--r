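# Receptive-field mapping from flash responses, bar-sweep tuning curves,
# and angular shift estimation between two retinal positions.

#' Receptive-field map from flash responses
#'
#' Per screen position, the response amplitude is the mean voltage in the
#' response window minus the mean in the pre-flash baseline window, averaged
#' over repeats. Constant per-trial offsets cancel in the subtraction.
#'
#' @param records data frame of flash records (`position_az`, `position_el`,
#'   `trial`, `time_s`, `vm_mV`; flash onset at time 0) or a
#'   `flash_grid_sim` from [gen_flash_grid()].
#' @param response_window window relative to flash onset, s (default
#'   `c(0, 0.2)`).
#' @param baseline_window pre-flash window, s (default `c(-0.1, 0)`); must
#'   not extend past the flash onset.
#' @return A data frame of class `rf_map`: `position_az`, `position_el`,
#'   `amplitude_mV`.
#' @export
rf_map <- function(records, response_window = c(0, 0.2),
                   baseline_window = c(-0.1, 0)) {
  if (inherits(records, "flash_grid_sim")) records <- records$records
  if (baseline_window[2] > 0)
    stop("baseline window overlaps the flash")
  if (response_window[1] < 0)
    stop("response window starts before the flash")
  key <- interaction(records$position_az, records$position_el, records$trial,
                     drop = TRUE)
  amp_trial <- vapply(split(records, key), function(d) {
    r <- d$time_s >= response_window[1] & d$time_s <= response_window[2]
    b <- d$time_s >= baseline_window[1] & d$time_s <= baseline_window[2]
    if (!any(r) || !any(b)) stop("windows fall outside the recorded sweep")
    mean(d$vm_mV[r]) - mean(d$vm_mV[b])
  }, numeric(1))
  pos <- do.call(rbind, lapply(split(records, key), function(d)
    d[1, c("position_az", "position_el")]))
  agg <- stats::aggregate(amp_trial,
                          by = list(position_az = pos$position_az,
                                    position_el = pos$position_el),
                          FUN = mean)
  names(agg)[3] <- "amplitude_mV"
  agg <- agg[order(agg$position_el, agg$position_az), ]
  rownames(agg) <- NULL
  class(agg) <- c("rf_map", "data.frame")
  agg
}

#' Full width at half maximum of a response profile
#'
#' Width at half of (peak - minimum), with linear interpolation between
#' samples on both flanks.
#'
#' @param position positions, degrees (strictly monotonic), or a
#'   [tuning_curve] (then `response` is taken from it).
#' @param response responses at those positions.
#' @return FWHM in degrees.
#' @export
rf_width <- function(position, response = NULL) {
  if (inherits(position, "tuning_curve")) {
    response <- position$response
    position <- position$position_deg
  }
  if (diff(range(response)) <= 0) stop("flat profile: width undefined")
  half <- min(response) + (max(response) - min(response)) / 2
  pk <- which.max(response)
  cross <- function(idx_range) {
    # last crossing of `half` walking away from the peak
    for (i in idx_range) {
      if (response[i] < half) {
        j <- if (i < pk) i + 1L else i - 1L
        frac <- (half - response[i]) / (response[j] - response[i])
        return(position[i] + frac * (position[j] - position[i]))
      }
    }
    NA_real_
  }
  left <- if (pk > 1) cross((pk - 1):1) else NA_real_
  right <- if (pk < length(response)) cross((pk + 1):length(response)) else NA_real_
  if (is.na(left) || is.na(right))
    stop("profile does not fall to half maximum on both sides")
  abs(right - left)
}

ncc_at_shift <- function(pa, ra, pb, rb, delta, min_overlap = 5L) {
  # correlate a(p) with b(p + delta) over the overlapping support
  pq <- pa[pa + delta >= min(pb) & pa + delta <= max(pb)]
  if (length(pq) < min_overlap) return(NA_real_)
  bi <- stats::approx(pb, rb, xout = pq + delta)$y
  ai <- ra[match(pq, pa)]
  if (stats::sd(ai) == 0 || stats::sd(bi) == 0) return(NA_real_)
  stats::cor(ai, bi)
}

#' Estimate the angular shift between two tuning curves
#'
#' Finds the displacement that maximizes the normalized cross-correlation
#' between the two curves, scanning at the data's position spacing and
#' refining to sub-sample precision by parabolic interpolation around the
#' peak. The returned shift is the displacement of `curve_b` relative to
#' `curve_a`: `b(p) ~ a(p - shift)`, so `estimate(a, b) = -estimate(b, a)`.
#' Normalization makes the estimate invariant to scaling either curve.
#'
#' @param curve_a,curve_b [tuning_curve] objects (or data frames with
#'   `position_deg`, `response`).
#' @param search_range maximum |shift| scanned, degrees (default 20).
#' @param min_overlap minimum overlapping samples for a valid correlation.
#' @return A list of class `shift_estimate`: `shift_deg`, `quality` (peak
#'   normalized correlation).
#' @export
estimate_shift <- function(curve_a, curve_b, search_range = 20,
                           min_overlap = 5L) {
  pa <- curve_a$position_deg; ra <- curve_a$response
  pb <- curve_b$position_deg; rb <- curve_b$response
  step <- stats::median(abs(diff(pa)))
  deltas <- seq(-search_range, search_range, by = step)
  cc <- vapply(deltas, function(d)
    ncc_at_shift(pa, ra, pb, rb, d, min_overlap), numeric(1))
  if (all(is.na(cc))) stop("insufficient overlap within the search range")
  i <- which.max(cc)
  shift <- deltas[i]
  quality <- cc[i]
  if (i > 1 && i < length(cc) && !is.na(cc[i - 1]) && !is.na(cc[i + 1])) {
    y0 <- cc[i - 1]; y1 <- cc[i]; y2 <- cc[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) {
      frac <- 0.5 * (y0 - y2) / denom
      shift <- deltas[i] + frac * step
      quality <- y1 - 0.25 * (y0 - y2) * frac
    }
  }
  structure(list(shift_deg = shift, quality = quality),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %.3g deg (peak correlation %.4f)\n",
              x$shift_deg, x$quality))
  invisible(x)
}

#' Combine sweep directions into one shift estimate
#'
#' Estimates the condition shift separately for each sweep direction and
#' averages the two. A fixed response latency displaces the two directions'
#' curves by equal and opposite screen offsets
#' (`direction * bar_speed * latency`); because the offset is common to both
#' conditions it cancels within each per-direction estimate, and averaging
#' the directions additionally cancels any residual direction-odd bias, so
#' the combined estimate is latency-free.
#'
#' @param sweeps a `bar_sweep_set` from [gen_bar_sweep()] or a list of four
#'   [tuning_curve]s covering both directions of both conditions.
#' @param conditions the two condition labels, reference first.
#' @return A list of class `combined_shift`: `shift_deg` (combined),
#'   `per_direction` (data frame `direction`, `shift_deg`, `quality`) and
#'   `combined_curves` (per condition, directions averaged).
#' @export
combine_directions <- function(sweeps,
                               conditions = c("control", "activated")) {
  curves <- if (inherits(sweeps, "bar_sweep_set")) sweeps$curves else sweeps
  meta <- data.frame(
    condition = vapply(curves, function(x) attr(x, "condition"), character(1)),
    direction = vapply(curves, function(x) attr(x, "direction"), integer(1)))
  per_dir <- lapply(c(1L, -1L), function(d) {
    ia <- which(meta$condition == conditions[1] & meta$direction == d)
    ib <- which(meta$condition == conditions[2] & meta$direction == d)
    if (!length(ia) || !length(ib))
      stop(sprintf("missing direction %+d for one of the conditions", d))
    est <- estimate_shift(curves[[ia[1]]], curves[[ib[1]]])
    data.frame(direction = d, shift_deg = est$shift_deg,
               quality = est$quality)
  })
  per_dir <- do.call(rbind, per_dir)
  combined_curves <- lapply(conditions, function(cond) {
    idx <- which(meta$condition == cond)
    pos <- curves[[idx[1]]]$position_deg
    resp <- rowMeans(vapply(idx, function(i) curves[[i]]$response,
                            numeric(length(pos))))
    data.frame(position_deg = pos, response = resp)
  })
  names(combined_curves) <- conditions
  # latency bias is observable as equal-and-opposite displacements of the
  # two directions' curves within a condition: half the direction-to-
  # direction shift is the per-direction offset bar_speed * latency
  i1 <- which(meta$condition == conditions[1] & meta$direction == 1L)[1]
  i2 <- which(meta$condition == conditions[1] & meta$direction == -1L)[1]
  lat_off <- -estimate_shift(curves[[i1]], curves[[i2]])$shift_deg / 2
  structure(list(shift_deg = mean(per_dir$shift_deg),
                 per_direction = per_dir,
                 latency_offset_deg = lat_off,
                 combined_curves = combined_curves),
            class = "combined_shift")
}

#' @export
print.combined_shift <- function(x, ...) {
  cat(sprintf("<combined_shift> %.3g deg (per direction: %+.3g / %+.3g)\n",
              x$shift_deg, x$per_direction$shift_deg[1],
              x$per_direction$shift_deg[2]))
  invisible(x)
}
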