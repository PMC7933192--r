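#' Resonant scan geometry
#'
#' @param line_rate Lines per second (a bidirectional resonant scanner
#'   acquires one line per half mirror period), e.g. 24000.
#' @param pixels_per_line Pixels digitized per line, e.g. 2048.
#' @param lines_per_frame Lines per frame (default `pixels_per_line`).
#' @param fill_fraction Fraction of the sinusoidal sweep amplitude that is
#'   digitized, in (0, 1]. 1 means the full sweep including the slow
#'   turnarounds.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(line_rate, pixels_per_line,
                          lines_per_frame = pixels_per_line,
                          fill_fraction = 1) {
  stopifnot(line_rate > 0, pixels_per_line > 0, lines_per_frame > 0)
  if (fill_fraction <= 0 || fill_fraction > 1) {
    stop("`fill_fraction` must lie in (0, 1].", call. = FALSE)
  }
  structure(list(line_rate = line_rate,
                 pixels_per_line = as.integer(pixels_per_line),
                 lines_per_frame = as.integer(lines_per_frame),
                 fill_fraction = fill_fraction),
            class = "scan_geometry")
}

#' Peak and average pixel rate of a resonant scan
#'
#' The beam position follows a sinusoid, so pixels of equal spatial size are
#' swept fastest at the center of the line. The average rate is simply
#' `line_rate * pixels_per_line`; the peak (center-of-sweep) rate exceeds it
#' by the sinusoidal velocity factor `asin(f) / f` evaluated at the
#' digitized fill fraction `f`, which rises from 1 (a vanishing, nearly
#' linear central sweep) to `pi/2` for the full sweep.
#'
#' @param scan A [scan_geometry()].
#' @return A list: `average` and `peak` pixel rates in pixels/s, and
#'   `peak_to_average`.
#' @export
resonant_pixel_rates <- function(scan) {
  stopifnot(inherits(scan, "scan_geometry"))
  f <- scan$fill_fraction
  avg <- scan$line_rate * scan$pixels_per_line
  ratio <- if (f < 1e-8) 1 else asin(f) / f
  list(average = avg, peak = avg * ratio, peak_to_average = ratio)
}

#' Maximum shot-noise-limited SNR of a rate-limited detector
#'
#' A detector that saturates at `saturation_flux` photons/s can collect at
#' most `saturation_flux / pixel_rate` photons per pixel; for an otherwise
#' noiseless detector the per-pixel SNR is then bounded by the square root
#' of that photon number. E.g. 2e9 photons/s at 1e7 pixels/s bounds the SNR
#' at `sqrt(200) = 14.1`.
#'
#' @param saturation_flux Detector saturation flux, photons/s.
#' @param pixel_rate Imaging pixel rate, pixels/s.
#' @return Dimensionless SNR bound.
#' @export
max_shot_noise_snr <- function(saturation_flux, pixel_rate) {
  stopifnot(all(saturation_flux > 0), all(pixel_rate > 0))
  sqrt(saturation_flux / pixel_rate)
}

#' PMT parameters
#'
#' @param excess_noise_factor Variance inflation factor F (>= 1) from the
#'   stochastic dynode multiplication; no default, as it depends on the tube
#'   and gain setting.
#' @param saturation_flux Photon flux at which the tube (or its overcurrent
#'   protection) saturates, photons/s.
#' @param quantum_efficiency Photocathode quantum efficiency in [0, 1].
#' @return An object of class `pmt_params`.
#' @export
pmt_params <- function(excess_noise_factor, saturation_flux = 3e9,
                       quantum_efficiency = 1) {
  if (excess_noise_factor < 1) {
    stop("`excess_noise_factor` must be >= 1.", call. = FALSE)
  }
  stopifnot(saturation_flux > 0,
            quantum_efficiency >= 0, quantum_efficiency <= 1)
  structure(list(excess_noise_factor = excess_noise_factor,
                 saturation_flux = saturation_flux,
                 quantum_efficiency = quantum_efficiency),
            class = "pmt_params")
}

#' Shot-noise SNR of a PMT pixel
#'
#' Excess noise from the electron multiplication inflates the variance of
#' the output by the factor F, reducing the SNR below the photon-shot-noise
#' prediction: `SNR = sqrt(n / F)`.
#'
#' @param photons_per_pixel Detected photons per pixel (>= 0).
#' @param pmt A [pmt_params()].
#' @return Dimensionless SNR.
#' @export
pmt_snr <- function(photons_per_pixel, pmt) {
  stopifnot(inherits(pmt, "pmt_params"))
  if (any(photons_per_pixel < 0)) {
    stop("`photons_per_pixel` must be >= 0.", call. = FALSE)
  }
  sqrt(photons_per_pixel / pmt$excess_noise_factor)
}

#' Frames to average to reach a target SNR
#'
#' SNR improves with the square root of the number of frames averaged, so
#' matching a target SNR from a lower single-frame SNR requires
#' `(target / single)^2` frames. Returned real-valued; the caller rounds.
#'
#' @param target_snr Target SNR (> 0).
#' @param single_frame_snr Single-frame SNR (> 0).
#' @return Required frame count (real-valued).
#' @export
frames_to_match_snr <- function(target_snr, single_frame_snr) {
  stopifnot(all(target_snr > 0), all(single_frame_snr > 0))
  (target_snr / single_frame_snr)^2
}

#' Saturating pile-up model calibrated from the Monte Carlo
#'
#' Builds an interpolator mapping expected detected photons per pixel to the
#' mean charge actually released (in photon-equivalents), by running
#' [detected_fraction_curve()] over a flux grid at the given pixel dwell
#' time. Used by [synthesize_frames()] for the `"sipm"` detector tag. The
#' transform acts on the per-pixel expectation only (a mean-field model);
#' the sub-Poisson variance reduction of deep pile-up is not reproduced.
#'
#' @param device A [sipm_device()].
#' @param dwell Pixel dwell time, seconds.
#' @param max_photons Upper end of the calibration range, photons per pixel.
#' @param n_grid Calibration grid size (default 12, log-spaced).
#' @param seed RNG seed for the calibration runs.
#' @return A function mapping expected detected photons (vector) to
#'   pile-up-reduced expected photon-equivalents.
#' @export
sipm_saturation_model <- function(device, dwell, max_photons, n_grid = 12,
                                  seed = 1) {
  stopifnot(inherits(device, "sipm_device"), dwell > 0, max_photons > 1)
  ph_grid <- 10^seq(0, log10(max_photons), length.out = n_grid)
  flux_grid <- ph_grid / (device$pde * dwell)   # launched flux per pixel
  dur <- max(dwell, 200 * device$recharge_time_constant) * 50
  dfc <- detected_fraction_curve(device, flux_grid, dur, seeds = seed)
  frac_fun <- approxfun(log(ph_grid), dfc$detected_fraction, rule = 2)
  function(n_expected) {
    out <- n_expected
    pos <- n_expected > 0
    out[pos] <- n_expected[pos] * frac_fun(log(pmax(n_expected[pos], 1)))
    out
  }
}

#' Synthesize a stack of scanned frames
#'
#' Generates `n_frames` photon-count frames of a static object under shot
#' noise, with optional detector effects: the `"sipm"` tag applies a
#' pile-up saturation transform (see [sipm_saturation_model()]) to the
#' per-pixel expectation; the `"pmt"` tag inflates the count noise by the
#' excess noise factor and clips at the tube's saturation.
#'
#' @param object_map Matrix of nonnegative relative per-pixel brightness.
#' @param photons_at_unit_brightness Expected detected photons per pixel at
#'   brightness 1.
#' @param n_frames Number of frames.
#' @param detector `"ideal"` (default), `"pmt"` or `"sipm"`.
#' @param seed RNG seed.
#' @param pmt A [pmt_params()] (required for `"pmt"`).
#' @param saturation_model Function from [sipm_saturation_model()] (required
#'   for `"sipm"`).
#' @param dwell Pixel dwell time, s (required for `"pmt"` clipping).
#' @return A numeric array `dim(object_map) x n_frames` of photon counts.
#' @export
synthesize_frames <- function(object_map, photons_at_unit_brightness,
                              n_frames,
                              detector = c("ideal", "pmt", "sipm"),
                              seed = NULL, pmt = NULL,
                              saturation_model = NULL, dwell = NULL) {
  detector <- match.arg(detector)
  if (any(object_map < 0)) {
    stop("`object_map` brightness must be >= 0.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lambda <- as.numeric(object_map) * photons_at_unit_brightness
  if (detector == "sipm") {
    if (is.null(saturation_model)) {
      stop("`saturation_model` required for the sipm detector tag.",
           call. = FALSE)
    }
    lambda <- saturation_model(lambda)
  }
  npx <- length(lambda)
  stack <- array(0, dim = c(dim(object_map), n_frames))
  for (k in seq_len(n_frames)) {
    n <- rpois(npx, lambda)
    if (detector == "pmt") {
      if (is.null(pmt)) stop("`pmt` params required.", call. = FALSE)
      n <- lambda + sqrt(pmt$excess_noise_factor) * (n - lambda)
      if (!is.null(dwell)) {
        n <- pmin(n, pmt$saturation_flux * dwell)
      }
      n <- pmax(n, 0)
    }
    stack[, , k] <- n
  }
  stack
}

#' Per-pixel SNR over a frame stack
#'
#' SNR is defined per pixel as the mean pixel value divided by the standard
#' deviation of that pixel over sequential frames.
#'
#' @param stack 3-D array (x, y, frames) with >= 2 frames.
#' @return A list of matrices `mean`, `sd`, `snr` (class `image_stats`).
#'   Pixels with zero temporal standard deviation get `Inf` SNR.
#' @export
per_pixel_snr <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) {
    stop("Need a 3-D stack with at least 2 frames.", call. = FALSE)
  }
  m <- apply(stack, c(1, 2), mean)
  s <- apply(stack, c(1, 2), sd)
  snr <- ifelse(s > 0, m / s, Inf)
  structure(list(mean = m, sd = s, snr = snr), class = "image_stats")
}
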