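#' Photon arrival record
#'
#' Time-ordered detected-photon arrival events with microcell assignments.
#' Normally produced by [simulate_arrivals()]; the constructor is exported so
#' deterministic arrival patterns can be built directly for validation.
#'
#' @param times Nondecreasing arrival times in seconds, all within
#'   `[0, duration]`.
#' @param cell_ids Integer microcell index (1-based) per arrival.
#' @param duration Record duration in seconds.
#' @param true_flux Launched photon flux in photons/s (before PDE thinning),
#'   if known.
#' @param seed RNG seed used to generate the record, if any.
#' @return An object of class `photon_arrivals`.
#' @export
photon_arrivals <- function(times, cell_ids, duration, true_flux = NA_real_,
                            seed = NA_integer_) {
  times <- as.numeric(times)
  cell_ids <- as.integer(cell_ids)
  if (length(times) != length(cell_ids)) {
    stop("`times` and `cell_ids` must have equal length.", call. = FALSE)
  }
  if (length(times) && (is.unsorted(times) || times[1] < 0 ||
                        times[length(times)] > duration)) {
    stop("`times` must be nondecreasing and within [0, duration].",
         call. = FALSE)
  }
  structure(
    list(times = times, cell_ids = cell_ids, duration = duration,
         true_flux = true_flux, seed = seed),
    class = "photon_arrivals"
  )
}

#' @export
print.photon_arrivals <- function(x, ...) {
  cat(sprintf("<photon_arrivals> %d events over %.3g s", length(x$times),
              x$duration))
  if (!is.na(x$true_flux)) cat(sprintf(" (launched %.3g ph/s)", x$true_flux))
  cat("\n")
  invisible(x)
}

#' Uniformly sampled detector trace
#'
#' @param samples Numeric sample values in output units (charge per sample
#'   bin, or DN).
#' @param sample_rate Sampling rate in Hz (default 125 MHz).
#' @param t0 Time of the first sample, seconds.
#' @param discard_prefix Seconds of settling data already removed from the
#'   front of the record.
#' @param seed RNG seed used to generate the trace, if any.
#' @return An object of class `sampled_trace`.
#' @export
sampled_trace <- function(samples, sample_rate = 125e6, t0 = 0,
                          discard_prefix = 0, seed = NA_integer_) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be > 0.", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must all be finite.", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, t0 = t0,
         discard_prefix = discard_prefix, seed = seed),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d samples @ %.4g MHz (%.3g s)\n",
              length(x$samples), x$sample_rate / 1e6,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Simulate Poisson photon arrivals onto a SiPM array
#'
#' Launches a homogeneous Poisson photon stream at the sensor, thins it by
#' the photon detection efficiency, and assigns each surviving photon to a
#' microcell drawn from the device illumination profile (uniform by
#' default). PDE thinning is applied before cell assignment. If the device
#' has a nonzero dark-count rate, dark events are superimposed as a second
#' Poisson process and are indistinguishable from photon events downstream.
#'
#' @param flux Launched photon flux in photons/s (>= 0).
#' @param duration Record duration in seconds (> 0).
#' @param device A [sipm_device()].
#' @param seed Integer RNG seed. One seeded generator drives the whole
#'   simulation; the seed is recorded in the output.
#' @return A [photon_arrivals()] record with `true_flux = flux`.
#' @export
simulate_arrivals <- function(flux, duration, device, seed = NULL) {
  stopifnot(inherits(device, "sipm_device"))
  if (!is.numeric(flux) || flux < 0) stop("`flux` must be >= 0.", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be > 0.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rate <- flux * device$pde + device$dark_count_rate
  n <- rpois(1, rate * duration)
  if (n == 0) {
    return(photon_arrivals(numeric(0), integer(0), duration, flux,
                           seed %||% NA_integer_))
  }
  times <- sort(runif(n, 0, duration))
  cells <- if (is.null(device$illumination_profile)) {
    sample.int(device$n_microcells, n, replace = TRUE)
  } else {
    sample.int(device$n_microcells, n, replace = TRUE,
               prob = device$illumination_profile)
  }
  photon_arrivals(times, cells, duration, flux, seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the SiPM photocurrent response to an arrival record
#'
#' Each microcell carries a charge state in `[0, 1]`. Cells start fully
#' charged (an idle detector) and recover as `1 - exp(-dt / tau_rc)` after
#' each avalanche. A photon landing on a cell with charge state `c` releases
#' charge `c * single_cell_gain` and resets the cell to 0 regardless of `c`
#' (a Geiger discharge empties the cell, so a partial avalanche also restarts
#' the recharge clock). Released charge is accumulated wholly into the sample
#' bin containing the arrival time, which keeps charge conservation exact.
#'
#' Because every avalanche resets its cell's clock, the per-event charge
#' depends only on the time since the previous event on the same cell; the
#' event loop therefore reduces to a grouped vectorized computation.
#'
#' @param arrivals A [photon_arrivals()] record.
#' @param device The [sipm_device()] that produced it.
#' @param sample_rate Output sampling rate in Hz (default 125 MHz).
#' @return A [sampled_trace()] covering `[0, duration]` in charge units per
#'   sample bin.
#' @export
simulate_response <- function(arrivals, device, sample_rate = 125e6) {
  stopifnot(inherits(arrivals, "photon_arrivals"),
            inherits(device, "sipm_device"))
  if (length(arrivals$cell_ids) &&
      (max(arrivals$cell_ids) > device$n_microcells ||
       min(arrivals$cell_ids) < 1)) {
    stop("Arrival cell_ids out of range for this device.", call. = FALSE)
  }
  n_samp <- max(1L, as.integer(ceiling(arrivals$duration * sample_rate)))
  n <- length(arrivals$times)
  if (n == 0) {
    return(sampled_trace(numeric(n_samp), sample_rate, seed = arrivals$seed))
  }
  ord <- order(arrivals$cell_ids, arrivals$times, method = "radix")
  t_ord <- arrivals$times[ord]
  c_ord <- arrivals$cell_ids[ord]
  frac <- numeric(n)
  if (n > 1) {
    dt <- t_ord[-1] - t_ord[-n]
    frac[-1] <- 1 - exp(-dt / device$recharge_time_constant)
    frac[c(TRUE, c_ord[-1] != c_ord[-n])] <- 1   # first event on each cell
  } else {
    frac[1] <- 1
  }
  charge <- frac * device$single_cell_gain
  bins <- pmin(as.integer(floor(t_ord * sample_rate)) + 1L, n_samp)
  acc <- rowsum(charge, bins, reorder = TRUE)
  samples <- numeric(n_samp)
  samples[as.integer(rownames(acc))] <- acc[, 1]
  sampled_trace(samples, sample_rate, seed = arrivals$seed)
}

#' Discard the settling transient at the start of a trace
#'
#' Cells start fully charged, so the leading edge of a trace under constant
#' illumination is biased relative to the recharge-equilibrium steady state.
#' This removes the first `n_constants` recharge time constants of data.
#'
#' @param trace A [sampled_trace()].
#' @param device The [sipm_device()] (supplies the recharge time constant).
#' @param n_constants Number of recharge time constants to discard
#'   (default 50).
#' @return The trimmed [sampled_trace()] with `discard_prefix` recorded.
#' @export
trim_settling <- function(trace, device, n_constants = 50) {
  stopifnot(inherits(trace, "sampled_trace"), inherits(device, "sipm_device"))
  if (n_constants == 0) return(trace)
  window <- n_constants * device$recharge_time_constant
  n_drop <- as.integer(ceiling(window * trace$sample_rate))
  if (n_drop >= length(trace$samples)) {
    stop("Trace shorter than the requested settling window (",
         signif(window, 3), " s).", call. = FALSE)
  }
  out <- sampled_trace(trace$samples[-seq_len(n_drop)], trace$sample_rate,
                       t0 = trace$t0 + n_drop / trace$sample_rate,
                       discard_prefix = trace$discard_prefix +
                         n_drop / trace$sample_rate,
                       seed = trace$seed)
  out
}

#' Detected-charge fraction versus launched flux
#'
#' Runs the Monte Carlo at each flux on a grid and reports the mean released
#' charge per detected photon as a fraction of the full single-cell charge:
#' `total released charge / (single_cell_gain * n_detected)`. The fraction is
#' 1 in the no-pile-up limit and decreases as photons increasingly strike
#' cells that have not finished recharging.
#'
#' @param device A [sipm_device()].
#' @param flux_grid Ascending positive launched fluxes, photons/s.
#' @param duration Simulated duration per flux point, seconds.
#' @param seeds Integer seeds, one per replicate; replicates are averaged.
#' @param trim_constants Settling constants to discard before accumulating
#'   charge (default 50).
#' @return A data.frame with columns `launched_flux`, `detected_fraction`,
#'   `se` (standard error over replicates, `NA` for a single seed).
#' @export
detected_fraction_curve <- function(device, flux_grid, duration, seeds = 1L,
                                    trim_constants = 50) {
  if (any(diff(flux_grid) <= 0) || any(flux_grid <= 0)) {
    stop("`flux_grid` must be positive and strictly ascending.", call. = FALSE)
  }
  res <- lapply(flux_grid, function(flux) {
    fr <- vapply(seeds, function(s) {
      arr <- simulate_arrivals(flux, duration, device, seed = s)
      if (length(arr$times) == 0) return(NA_real_)
      keep <- arr$times > trim_constants * device$recharge_time_constant
      if (!any(keep)) return(NA_real_)
      # recompute per-event charge, then restrict to the settled window
      tr_all <- per_event_charge(arr, device)
      sum(tr_all[keep]) / (device$single_cell_gain * sum(keep))
    }, numeric(1))
    c(mean(fr, na.rm = TRUE),
      if (length(seeds) > 1) sd(fr, na.rm = TRUE) / sqrt(sum(!is.na(fr)))
      else NA_real_)
  })
  res <- do.call(rbind, res)
  data.frame(launched_flux = flux_grid, detected_fraction = res[, 1],
             se = res[, 2])
}

# per-event released charge (in gain units) for an arrival record
per_event_charge <- function(arrivals, device) {
  n <- length(arrivals$times)
  if (n == 0) return(numeric(0))
  ord <- order(arrivals$cell_ids, arrivals$times, method = "radix")
  frac <- numeric(n)
  if (n > 1) {
    dt <- arrivals$times[ord][-1] - arrivals$times[ord][-n]
    frac[-1] <- 1 - exp(-dt / device$recharge_time_constant)
    cc <- arrivals$cell_ids[ord]
    frac[c(TRUE, cc[-1] != cc[-n])] <- 1
  } else {
    frac[1] <- 1
  }
  charge <- numeric(n)
  charge[ord] <- frac * device$single_cell_gain
  charge
}
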