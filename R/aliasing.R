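# Correlator model of spatial aliasing.
#
# A 1-D array of photoreceptors with fixed angular spacing dphi feeds
# nearest-neighbor delay-and-multiply (Reichardt) correlator pairs with
# opponent subtraction. For a drifting sinusoidal grating the time-averaged
# opponent output is proportional to sin(2*pi*dphi/lambda): positive
# (veridical direction report) for lambda > 2*dphi, zero at the cut-off
# lambda_L = 2*dphi, and inverted in the aliasing band just below it.

#' Photoreceptor sampling array
#'
#' @param dphi inter-ommatidial angle, degrees, > 0.
#' @param n_receptors number of receptors, >= 2.
#' @param blur_fwhm optional Gaussian acceptance-angle FWHM, degrees;
#'   attenuates contrast at short wavelengths but does not move the zero
#'   crossings of the sinusoidal response.
#' @return A list of class `sampling_array`.
#' @export
sampling_array <- function(dphi = 5, n_receptors = 12L, blur_fwhm = NULL) {
  stopifnot(dphi > 0, n_receptors >= 2)
  structure(list(dphi = dphi, n_receptors = as.integer(n_receptors),
                 blur_fwhm = blur_fwhm),
            class = "sampling_array")
}

#' Drifting grating stimulus
#'
#' @param lambda spatial wavelength, degrees, > 0.
#' @param temporal_freq drift temporal frequency, Hz.
#' @param direction +1 or -1.
#' @param contrast Michelson contrast.
#' @param waveform `"sine"` (default) or `"square"` (the behavioral
#'   stimulus; its odd harmonics alias independently).
#' @return A list of class `grating_stimulus`. The aliasing cut-off for a
#'   given array, `lambda_L = 2 * dphi`, is available via [cutoff_wavelength()].
#' @export
grating_stimulus <- function(lambda, temporal_freq = 1, direction = 1L,
                             contrast = 0.5, waveform = c("sine", "square")) {
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(lambda = lambda, temporal_freq = temporal_freq,
                 direction = direction, contrast = contrast,
                 waveform = match.arg(waveform)),
            class = "grating_stimulus")
}

#' Aliasing cut-off wavelength of a sampling array
#'
#' @param array a [sampling_array].
#' @return `2 * dphi`, degrees.
#' @export
cutoff_wavelength <- function(array) 2 * array$dphi

blur_attenuation <- function(array, lambda) {
  if (is.null(array$blur_fwhm)) return(1)
  sigma <- array$blur_fwhm / (2 * sqrt(2 * log(2)))
  exp(-2 * (pi * sigma / lambda)^2)
}

#' Time-averaged correlator response to a drifting grating
#'
#' Simulates the array of opponent delay-and-multiply correlator pairs
#' (first-order low-pass delay filter, time constant `tau`) and returns the
#' time-averaged opponent output, averaged over pairs and over an integer
#' number of temporal periods after the filter transient. With
#' `normalize = TRUE` (default) the output is divided by the analytic
#' temporal envelope `contrast^2 * w*tau / (1 + (w*tau)^2)` (w = 2*pi*f) of
#' the unblurred correlator, so an unblurred sinusoid at `lambda = 4 * dphi`
#' scores +1 when drifting in the +direction.
#'
#' @param grating a [grating_stimulus].
#' @param array a [sampling_array].
#' @param duration averaging span, s; must cover at least 2 temporal
#'   periods (default 5 periods).
#' @param tau delay-filter time constant, s (default 0.05). Affects the
#'   response magnitude, not its zero crossings.
#' @param dt simulation step, s; default 1/500 of the temporal period.
#' @param normalize divide by the analytic temporal envelope (see above).
#' @return Signed scalar; positive means the veridical direction is
#'   reported.
#' @export
emd_mean_response <- function(grating, array, duration = NULL, tau = 0.05,
                              dt = NULL, normalize = TRUE) {
  f <- grating$temporal_freq
  period <- 1 / f
  if (is.null(duration)) duration <- 5 * period
  if (duration < 2 * period)
    stop("duration must cover at least 2 temporal periods")
  spp <- 500L                      # samples per temporal period
  if (!is.null(dt)) spp <- max(16L, as.integer(round(period / dt)))
  dt <- period / spp
  n_avg_periods <- max(2, floor(duration / period))
  n_warm <- as.integer(ceiling(max(8 * tau, period) / dt))
  n_keep <- n_avg_periods * spp    # exact integer number of periods
  tt <- (seq_len(n_warm + n_keep) - 1L) * dt
  xi <- (seq_len(array$n_receptors) - 1) * array$dphi
  amp <- grating$contrast * blur_attenuation(array, grating$lambda)
  phase <- outer(2 * pi * xi / grating$lambda,
                 -2 * pi * grating$direction * f * tt, "+")
  s <- if (grating$waveform == "sine") amp * sin(phase)
  else amp * sign(sin(phase))
  # exact exponential discretization of the first-order low-pass
  a <- exp(-dt / tau)
  d <- s
  for (k in seq_along(tt)[-1]) d[, k] <- a * d[, k - 1] + (1 - a) * s[, k]
  i <- seq_len(array$n_receptors - 1)
  opp <- d[i, , drop = FALSE] * s[i + 1, , drop = FALSE] -
    s[i, , drop = FALSE] * d[i + 1, , drop = FALSE]
  r <- mean(opp[, n_warm + seq_len(n_keep), drop = FALSE])
  if (normalize) {
    # envelope of the correlator at the drift frequency, using the delay
    # filter's realized (discrete) gain and phase lag
    wdt <- 2 * pi * f * dt
    h <- (1 - a) / (1 - a * exp(-1i * wdt))
    r <- r / (grating$contrast^2 * Mod(h) * sin(-Arg(h)))
  }
  r
}

#' Signed response curve over wavelengths
#'
#' @param array a [sampling_array].
#' @param lambdas spatial wavelengths, degrees, non-empty.
#' @param directions drift directions to evaluate (default both).
#' @param temporal_freq,contrast,waveform stimulus settings, see
#'   [grating_stimulus()].
#' @param ... passed to [emd_mean_response()].
#' @return Data frame `lambda_deg`, `direction`, `response`.
#' @export
response_curve <- function(array, lambdas, directions = c(1L, -1L),
                           temporal_freq = 1, contrast = 0.5,
                           waveform = "sine", ...) {
  if (!length(lambdas)) stop("lambda list must be non-empty")
  out <- expand.grid(lambda_deg = lambdas, direction = directions)
  out$response <- mapply(function(l, d)
    emd_mean_response(grating_stimulus(l, temporal_freq, d, contrast,
                                       waveform), array, ...),
    out$lambda_deg, out$direction)
  out
}

#' Direction-inversion band of a sampling array
#'
#' Scans the wavelength grid for the contiguous interval adjacent to the
#' `2 * dphi` cut-off where the mean correlator response to a +direction
#' grating is negative (the spatial-aliasing band), then refines both edges
#' by root bracketing of the simulated response curve.
#'
#' @param array a [sampling_array].
#' @param lambda_grid wavelength grid, degrees; must span at least
#'   (0.5 * dphi, 4 * dphi).
#' @param tol root-refinement tolerance, degrees.
#' @param temporal_freq,contrast stimulus settings, see
#'   [grating_stimulus()].
#' @param ... passed to [emd_mean_response()].
#' @return Named numeric `c(lambda_low, lambda_high)` in degrees.
#' @export
inversion_band <- function(array, lambda_grid = NULL, tol = 1e-4,
                           temporal_freq = 1, contrast = 0.5, ...) {
  if (is.null(lambda_grid))
    lambda_grid <- seq(0.4 * array$dphi, 4.2 * array$dphi,
                       by = array$dphi / 20)
  if (min(lambda_grid) > 0.5 * array$dphi ||
      max(lambda_grid) < 4 * array$dphi)
    stop("lambda grid must span at least (0.5, 4) * dphi")
  lambda_grid <- sort(lambda_grid)
  resp <- function(l)
    emd_mean_response(grating_stimulus(l, temporal_freq, 1L, contrast),
                      array, ...)
  r <- vapply(lambda_grid, resp, numeric(1))
  neg <- r < 0
  if (!any(neg) || !any(r > 0)) stop("no sign change on the wavelength grid")
  # contiguous negative run nearest below the cut-off
  runs <- rle(neg)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  if (!length(cand)) stop("no negative response on the grid")
  cutoff <- cutoff_wavelength(array)
  mid <- (lambda_grid[starts[cand]] + lambda_grid[ends[cand]]) / 2
  pick <- cand[which.min(abs(mid - 0.75 * cutoff))]
  i1 <- starts[pick]; i2 <- ends[pick]
  refine <- function(ilo, ihi) {
    if (ilo < 1L || ihi > length(lambda_grid)) return(NA_real_)
    stats::uniroot(resp, c(lambda_grid[ilo], lambda_grid[ihi]),
                   tol = tol)$root
  }
  low <- refine(i1 - 1L, i1)
  high <- refine(i2, i2 + 1L)
  c(lambda_low = low, lambda_high = high)
}
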