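#' Photon-transfer flux estimate from a sampled trace
#'
#' The mean and variance of the digitized output of a shot-noise-limited
#' detector are tied by Poisson statistics; for a continuous-time analog
#' output the variance additionally depends on the sampling rate and the
#' analog bandwidth. Correcting with the equivalent bandwidth removes that
#' dependence, giving the absolute detected photon flux
#'
#' `photons/s = mean^2 / variance * equivalent_bandwidth * sample_rate`
#'
#' The estimate is invariant to any positive rescaling of the trace (gain
#' cancels in `mean^2 / variance`), and it counts photons at the detector
#' plane: divide by the PDE to express it as launched flux.
#'
#' @param trace A [sampled_trace()] or numeric vector (then supply
#'   `sample_rate`).
#' @param equivalent_bandwidth Equivalent bandwidth fraction of the chain
#'   that shaped the trace (1 for an unfiltered binned trace; see
#'   [equivalent_bandwidth()]).
#' @param sample_rate Sampling rate in Hz; taken from the trace if omitted.
#' @return Estimated detected photon flux, photons/s.
#' @export
estimate_flux <- function(trace, equivalent_bandwidth = 1,
                          sample_rate = NULL) {
  s <- if (inherits(trace, "sampled_trace")) trace$samples else
    as.numeric(trace)
  fs <- if (inherits(trace, "sampled_trace")) trace$sample_rate else
    sample_rate
  if (is.null(fs)) stop("`sample_rate` required.", call. = FALSE)
  if (length(s) < 2) stop("Need at least 2 samples.", call. = FALSE)
  if (equivalent_bandwidth <= 0 || equivalent_bandwidth > 1) {
    stop("`equivalent_bandwidth` must lie in (0, 1].", call. = FALSE)
  }
  v <- var(s)   # unbiased (n - 1) estimator
  if (v == 0) {
    stop("Zero sample variance: a constant trace carries no shot-noise ",
         "information.", call. = FALSE)
  }
  mean(s)^2 / v * equivalent_bandwidth * fs
}

#' Detector gain from a photon-transfer sweep
#'
#' For a shot-noise-limited detector the sample variance grows linearly with
#' the sample mean across an illumination sweep; the slope is the detector
#' gain times the equivalent bandwidth. The fit is ordinary least squares
#' with a free intercept (the intercept absorbs dark/read noise).
#'
#' @param flux_sweep A data.frame with columns `mean` and `variance`, one row
#'   per illumination level in the linear regime (>= 3 rows).
#' @param equivalent_bandwidth Equivalent bandwidth of the chain (default 1).
#' @return Gain in output units (DN) per detected photon.
#' @export
estimate_gain <- function(flux_sweep, equivalent_bandwidth = 1) {
  if (!all(c("mean", "variance") %in% names(flux_sweep))) {
    stop("`flux_sweep` needs `mean` and `variance` columns.", call. = FALSE)
  }
  if (nrow(flux_sweep) < 3) {
    stop("Need at least 3 sweep points.", call. = FALSE)
  }
  if (diff(range(flux_sweep$mean)) == 0) {
    stop("Degenerate sweep: all mean values identical.", call. = FALSE)
  }
  fit <- lm(variance ~ mean, data = flux_sweep)
  unname(coef(fit)[2]) / equivalent_bandwidth
}

#' Dark noise relative to the single-photon amplitude
#'
#' Ratio of the dark-frame standard deviation to the detector gain, i.e. the
#' dark noise expressed as a fraction of one photon's worth of signal. Values
#' well below 1 mean dark counts contribute negligibly to system noise.
#'
#' @param dark_sd_dn Dark-frame standard deviation, DN.
#' @param gain_dn_per_photon Detector gain, DN per photon.
#' @return Dimensionless fraction.
#' @export
dark_noise_fraction <- function(dark_sd_dn, gain_dn_per_photon) {
  stopifnot(dark_sd_dn >= 0, gain_dn_per_photon > 0)
  dark_sd_dn / gain_dn_per_photon
}

#' Linearity-deviation curve and 10% compression point
#'
#' Fits a linear reference over the low-flux end of a sweep (by default the
#' lowest decade of launched flux, through the origin), then reports the
#' percent deviation of each estimate from that reference and the launched
#' flux at which the deviation first crosses a threshold (default 10%),
#' interpolated linearly in log-flux.
#'
#' @param launched_flux Ascending launched fluxes, photons/s.
#' @param estimated_flux Estimated fluxes on the same scale.
#' @param reference_decades Width of the low-flux reference region in decades
#'   above `min(launched_flux)` (default 1).
#' @param threshold_pct Deviation threshold in percent (default 10).
#' @return A list with `deviation_pct` (per point,
#'   `100 * (1 - estimated / (slope_ref * launched))`), `slope_ref`,
#'   `flux_at_threshold` (NA if the curve never crosses within the grid) and
#'   `crossed` (logical).
#' @export
linearity_curve <- function(launched_flux, estimated_flux,
                            reference_decades = 1, threshold_pct = 10) {
  stopifnot(length(launched_flux) == length(estimated_flux),
            length(launched_flux) >= 3)
  if (any(diff(launched_flux) <= 0)) {
    stop("`launched_flux` must be strictly ascending.", call. = FALSE)
  }
  ref <- launched_flux <= min(launched_flux) * 10^reference_decades
  if (sum(ref) < 1) stop("Empty linear reference region.", call. = FALSE)
  # least squares through the origin over the reference region
  slope_ref <- sum(estimated_flux[ref] * launched_flux[ref]) /
    sum(launched_flux[ref]^2)
  dev_pct <- 100 * (1 - estimated_flux / (slope_ref * launched_flux))
  above <- dev_pct >= threshold_pct
  if (!any(above)) {
    return(list(deviation_pct = dev_pct, slope_ref = slope_ref,
                flux_at_threshold = NA_real_, crossed = FALSE))
  }
  i <- which(above)[1]
  if (i == 1) {
    fx <- launched_flux[1]
  } else {
    lf <- log10(launched_flux)
    fx <- 10^(lf[i - 1] + (threshold_pct - dev_pct[i - 1]) *
                (lf[i] - lf[i - 1]) / (dev_pct[i] - dev_pct[i - 1]))
  }
  list(deviation_pct = dev_pct, slope_ref = slope_ref,
       flux_at_threshold = fx, crossed = TRUE)
}

#' End-to-end Monte Carlo photon-transfer sweep
#'
#' For each launched flux: simulate Poisson arrivals and the microcell
#' response at the given sampling rate, discard the settling transient,
#' optionally pass the trace through a lowpass filter (using that filter's
#' computed equivalent bandwidth in the estimator), and estimate the flux
#' with the photon-transfer formula. The record length per point is chosen
#' so that at least `min_samples` samples and, where the flux allows it
#' within `max_samples`, about `target_events` detected photons enter the
#' estimate.
#'
#' @param device A [sipm_device()].
#' @param flux_grid Launched fluxes, photons/s.
#' @param sample_rate Sampling rate, Hz (default 125 MHz).
#' @param seed Integer seed; per-point substream seeds are derived from it.
#' @param min_samples,max_samples Bounds on samples per flux point.
#' @param target_events Desired detected-photon count per point.
#' @param trim_constants Settling time constants to discard (default 50).
#' @param lowpass_cutoff Optional lowpass cutoff, Hz; `NULL` (default) for
#'   the raw binned trace (equivalent bandwidth 1).
#' @param lowpass_order Butterworth order when filtering (default 4).
#' @return A data.frame (one row per flux) with columns `launched_flux`,
#'   `n_samples`, `sample_mean`, `sample_variance`, `equivalent_bandwidth`,
#'   `estimated_detected_flux`, `estimated_launched_flux` (detected / PDE),
#'   and `agreement_pct` = `100 * (1 - |estimated - launched| / launched)`.
#' @export
simulate_ptc <- function(device, flux_grid, sample_rate = 125e6, seed = 1,
                         min_samples = 1e6, max_samples = 2e7,
                         target_events = 4e6, trim_constants = 50,
                         lowpass_cutoff = NULL, lowpass_order = 4) {
  stopifnot(inherits(device, "sipm_device"))
  set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, length(flux_grid))
  eb <- 1
  if (!is.null(lowpass_cutoff)) {
    eb <- equivalent_bandwidth(
      lowpass_transfer_function(lowpass_cutoff, lowpass_order, sample_rate),
      sample_rate)
  }
  rows <- lapply(seq_along(flux_grid), function(i) {
    flux <- flux_grid[i]
    n_samp <- min(max_samples,
                  max(min_samples,
                      ceiling(target_events * sample_rate /
                                max(flux * device$pde, 1))))
    duration <- n_samp / sample_rate +
      trim_constants * device$recharge_time_constant
    arr <- simulate_arrivals(flux, duration, device, seed = point_seeds[i])
    tr <- simulate_response(arr, device, sample_rate)
    tr <- trim_settling(tr, device, trim_constants)
    if (!is.null(lowpass_cutoff)) {
      tr <- apply_lowpass(tr, lowpass_cutoff, lowpass_order)
      # drop the filter's own startup transient
      tr$samples <- tr$samples[-seq_len(min(1000L, length(tr$samples) %/% 10))]
    }
    est_det <- estimate_flux(tr, equivalent_bandwidth = eb)
    est_launched <- est_det / device$pde
    data.frame(launched_flux = flux,
               n_samples = length(tr$samples),
               sample_mean = mean(tr$samples),
               sample_variance = var(tr$samples),
               equivalent_bandwidth = eb,
               estimated_detected_flux = est_det,
               estimated_launched_flux = est_launched,
               agreement_pct = 100 * (1 - abs(est_launched - flux) / flux))
  })
  do.call(rbind, rows)
}
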