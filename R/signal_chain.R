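#' Two-exponential SiPM single-photon impulse response
#'
#' The single-photon response of a SiPM is a sub-nanosecond rise followed by
#' a two-term decay: a fast component set by the array capacitance
#' discharging into the amplifier, plus a slow component set by the single
#' microcell recharging through its quench resistor (the same time constant
#' as the cell recharge, tens of nanoseconds). The slow component carries
#' roughly ten times the charge of the fast one.
#'
#' @param fast_time_constant Fast decay time constant, seconds.
#' @param slow_time_constant Slow decay time constant, seconds (must exceed
#'   the fast one).
#' @param slow_to_fast_charge_ratio Ratio of integrated charge in the slow
#'   component to the fast component (default 10). `0` gives a pure fast
#'   single exponential.
#' @return An object of class `impulse_response_params`.
#' @export
impulse_response_params <- function(fast_time_constant,
                                    slow_time_constant,
                                    slow_to_fast_charge_ratio = 10) {
  if (fast_time_constant <= 0 || slow_time_constant <= 0) {
    stop("Time constants must be > 0.", call. = FALSE)
  }
  if (slow_time_constant <= fast_time_constant) {
    stop("`slow_time_constant` must exceed `fast_time_constant`.",
         call. = FALSE)
  }
  if (slow_to_fast_charge_ratio < 0) {
    stop("`slow_to_fast_charge_ratio` must be >= 0.", call. = FALSE)
  }
  structure(list(fast_time_constant = fast_time_constant,
                 slow_time_constant = slow_time_constant,
                 slow_to_fast_charge_ratio = slow_to_fast_charge_ratio),
            class = "impulse_response_params")
}

#' Sampled single-photon response kernel
#'
#' Samples `A_f exp(-t/tau_f) + A_s exp(-t/tau_s)` with the amplitudes chosen
#' so the integrated charge splits `slow_to_fast_charge_ratio : 1` between
#' slow and fast terms and the total continuous-time integral equals
#' `single_cell_gain`. The numeric (trapezoid) integral of the returned
#' kernel matches the closed form only up to discretization error; a warning
#' is issued when the sampling does not resolve the fast component with at
#' least 2 samples per `tau_f`.
#'
#' @param params An [impulse_response_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param single_cell_gain Total integrated charge of the kernel (default 1).
#' @param n_slow_constants Kernel length in units of the slow time constant
#'   (default 10).
#' @return A [sampled_trace()] holding the kernel (units: charge per second,
#'   sampled).
#' @export
impulse_response <- function(params, sample_rate, single_cell_gain = 1,
                             n_slow_constants = 10) {
  stopifnot(inherits(params, "impulse_response_params"))
  if (sample_rate * params$fast_time_constant < 2) {
    warning("sample_rate does not resolve the fast time constant ",
            "(< 2 samples per tau_f); the sampled kernel is aliased.",
            call. = FALSE)
  }
  r <- params$slow_to_fast_charge_ratio
  A_f <- single_cell_gain / ((1 + r) * params$fast_time_constant)
  A_s <- single_cell_gain * r / ((1 + r) * params$slow_time_constant)
  t <- seq(0, n_slow_constants * params$slow_time_constant, by = 1 / sample_rate)
  k <- A_f * exp(-t / params$fast_time_constant) +
    A_s * exp(-t / params$slow_time_constant)
  sampled_trace(k, sample_rate)
}

#' Pole-zero cancellation filter
#'
#' Applies a first-order pole-zero cancellation stage: a zero placed at the
#' frequency of the recharge pole (`1/tau_pzc`) and a pole at the higher
#' frequency `1/(attenuation * tau_pzc)`. The high-frequency gain is unity,
#' so a fast pulse passes unchanged in amplitude, while a matched slow
#' exponential is collapsed into a short transient. The DC gain of the
#' filter equals `attenuation`, so the transmitted charge is `attenuation`
#' times the input charge; the default `attenuation = 1/11` diverts exactly
#' the slow fraction of the canonical 10:1 slow:fast charge split, leaving
#' the fast-component charge. Discretization uses the matched-z (pole-zero)
#' mapping `z = exp(s / sample_rate)`, which cancels a sampled exponential
#' with a matched time constant exactly.
#'
#' @param x A [sampled_trace()] (kernel or full trace) or numeric vector.
#' @param pzc_time_constant Location of the zero, seconds (> 0). Match this
#'   to the slow time constant to remove the recharge component.
#' @param attenuation DC charge transmission of the filter, dimensionless in
#'   (0, 1); default `1/11` (complement of the default 10:1 slow:fast
#'   charge ratio).
#' @param sample_rate Required if `x` is a bare numeric vector.
#' @return Filtered trace of the same class as the input.
#' @export
apply_pzc <- function(x, pzc_time_constant, attenuation = 1 / 11,
                      sample_rate = NULL) {
  if (pzc_time_constant <= 0) {
    stop("`pzc_time_constant` must be > 0.", call. = FALSE)
  }
  if (attenuation <= 0 || attenuation >= 1) {
    stop("`attenuation` must lie in (0, 1).", call. = FALSE)
  }
  tr <- as_trace(x, sample_rate)
  T <- 1 / tr$sample_rate
  zz <- exp(-T / pzc_time_constant)
  zp <- exp(-T / (attenuation * pzc_time_constant))
  y <- as.numeric(signal::filter(c(1, -zz), c(1, -zp), tr$samples))
  rebuild_trace(x, tr, y)
}

#' Lowpass filter a trace
#'
#' Butterworth lowpass (default 4th order), the shape used for the external
#' anti-alias filters on the detector outputs. Applied as a causal
#' single-pass filter with unity DC gain.
#'
#' @param x A [sampled_trace()] or numeric vector.
#' @param cutoff -3 dB cutoff frequency, Hz; must be below Nyquist.
#' @param order Filter order (default 4).
#' @param sample_rate Required if `x` is a bare numeric vector.
#' @return Filtered trace of the same class as the input.
#' @export
apply_lowpass <- function(x, cutoff, order = 4, sample_rate = NULL) {
  tr <- as_trace(x, sample_rate)
  nyq <- tr$sample_rate / 2
  if (cutoff >= nyq) {
    stop("`cutoff` must be below the Nyquist frequency (",
         signif(nyq, 4), " Hz).", call. = FALSE)
  }
  bw <- signal::butter(order, cutoff / nyq, type = "low")
  y <- as.numeric(signal::filter(bw, tr$samples))
  rebuild_trace(x, tr, y)
}

as_trace <- function(x, sample_rate) {
  if (inherits(x, "sampled_trace")) return(x)
  if (is.null(sample_rate)) {
    stop("`sample_rate` is required for a bare numeric input.", call. = FALSE)
  }
  sampled_trace(as.numeric(x), sample_rate)
}

rebuild_trace <- function(orig, tr, y) {
  if (inherits(orig, "sampled_trace")) {
    sampled_trace(y, tr$sample_rate, t0 = tr$t0,
                  discard_prefix = tr$discard_prefix, seed = tr$seed)
  } else {
    y
  }
}

#' Transfer function (magnitude-squared vs frequency)
#'
#' Frequency-domain magnitude description of the analog chain, normalized so
#' the passband plateau (DC) is 1. This is the object from which the
#' equivalent bandwidth is computed.
#'
#' @param frequency Ascending nonnegative frequency grid, Hz.
#' @param magnitude_squared Nonnegative finite `|H(f)|^2` on that grid.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(frequency, magnitude_squared) {
  if (length(frequency) != length(magnitude_squared) || length(frequency) < 2) {
    stop("Need matching frequency/magnitude vectors of length >= 2.",
         call. = FALSE)
  }
  if (any(diff(frequency) <= 0) || any(frequency < 0)) {
    stop("`frequency` must be ascending and nonnegative.", call. = FALSE)
  }
  if (any(!is.finite(magnitude_squared)) || any(magnitude_squared < 0)) {
    stop("`magnitude_squared` must be finite and nonnegative.", call. = FALSE)
  }
  structure(list(frequency = frequency,
                 magnitude_squared = magnitude_squared),
            class = "transfer_function")
}

#' Ideal brick-wall transfer function
#'
#' `|H|^2 = 1` below the cutoff and 0 above, represented on a grid with a
#' sharp edge (adjacent points at `cutoff` and `cutoff * (1 + 1e-9)`).
#'
#' @param cutoff Cutoff frequency, Hz.
#' @param f_max Upper end of the grid, Hz (use the Nyquist frequency).
#' @return A [transfer_function()].
#' @export
brickwall_transfer_function <- function(cutoff, f_max) {
  stopifnot(cutoff > 0, f_max > cutoff)
  transfer_function(c(0, cutoff, cutoff * (1 + 1e-9), f_max),
                    c(1, 1, 0, 0))
}

#' Transfer function of a designed digital lowpass
#'
#' Evaluates `|H(f)|^2` of the Butterworth lowpass used by
#' [apply_lowpass()] on a dense grid up to Nyquist.
#'
#' @inheritParams apply_lowpass
#' @param sample_rate Sampling rate, Hz.
#' @param n_points Grid size (default 4096).
#' @return A [transfer_function()].
#' @export
lowpass_transfer_function <- function(cutoff, order = 4, sample_rate,
                                      n_points = 4096) {
  nyq <- sample_rate / 2
  stopifnot(cutoff < nyq)
  bw <- signal::butter(order, cutoff / nyq, type = "low")
  w <- seq(0, pi, length.out = n_points)
  h <- signal::freqz(bw$b, bw$a, w)$h
  transfer_function(w / pi * nyq, Mod(h)^2)
}

#' Single-pole (RC) transfer function
#'
#' `|H(f)|^2 = 1 / (1 + (f/fc)^2)`; its equivalent bandwidth against a
#' Nyquist brick-wall has the closed form `fc * atan(fN/fc) / fN`.
#'
#' @param fc Pole frequency, Hz.
#' @param f_max Upper end of the grid, Hz.
#' @param n_points Grid size (default 4096).
#' @return A [transfer_function()].
#' @export
single_pole_transfer_function <- function(fc, f_max, n_points = 4096) {
  f <- seq(0, f_max, length.out = n_points)
  transfer_function(f, 1 / (1 + (f / fc)^2))
}

#' Equivalent bandwidth of a transfer function
#'
#' Total integrated power of `|H(f)|^2` over `[0, sample_rate/2]` divided by
#' the power of an ideal unit-height brick-wall filter at the Nyquist
#' frequency. This is the dimensionless factor by which analog filtering
#' reduces the variance of white (shot) noise relative to the full Nyquist
#' band, and it is the bandwidth correction in the photon-transfer flux
#' estimator. Integration is trapezoidal on the supplied grid; grid density
#' is the caller's responsibility.
#'
#' @param tf A [transfer_function()] whose grid covers `[0, sample_rate/2]`.
#' @param sample_rate Sampling rate, Hz.
#' @return Equivalent bandwidth fraction in (0, 1] for a normalized lowpass.
#' @export
equivalent_bandwidth <- function(tf, sample_rate) {
  stopifnot(inherits(tf, "transfer_function"))
  nyq <- sample_rate / 2
  f <- tf$frequency
  m <- tf$magnitude_squared
  if (min(f) > 0 || max(f) < nyq) {
    stop("Transfer-function grid must cover [0, sample_rate/2].",
         call. = FALSE)
  }
  if (max(f) > nyq) {
    m_nyq <- approx(f, m, xout = nyq)$y
    keep <- f < nyq
    f <- c(f[keep], nyq)
    m <- c(m[keep], m_nyq)
  }
  pracma::trapz(f, m) / nyq
}

#' Amplifier clipping
#'
#' Shifts a trace by a DC offset, then clamps it to the amplifier rails.
#' Offsetting the output above zero lets both rails contribute to the usable
#' dynamic range.
#'
#' @param x A [sampled_trace()] or numeric vector.
#' @param rail_low,rail_high Clamp limits (rail_low < rail_high).
#' @param dc_offset Offset added before clamping (default 0).
#' @return Clipped trace with attribute `clipping_fraction`, the fraction of
#'   samples that hit a rail.
#' @export
clip_amplifier <- function(x, rail_low, rail_high, dc_offset = 0) {
  if (rail_low >= rail_high) {
    stop("`rail_low` must be below `rail_high`.", call. = FALSE)
  }
  s <- if (inherits(x, "sampled_trace")) x$samples else as.numeric(x)
  s <- s + dc_offset
  clipped <- s < rail_low | s > rail_high
  s <- pmin(pmax(s, rail_low), rail_high)
  out <- if (inherits(x, "sampled_trace")) {
    sampled_trace(s, x$sample_rate, t0 = x$t0,
                  discard_prefix = x$discard_prefix, seed = x$seed)
  } else {
    s
  }
  attr(out, "clipping_fraction") <- mean(clipped)
  out
}

#' Bias supply parameters
#'
#' @param max_current Maximum bias current the supply can deliver, amperes
#'   (default 10 mA).
#' @param bias_voltage Nominal bias voltage, volts (default 50 V).
#' @param droop_sharpness Dimensionless shape parameter of the soft knee
#'   (default 1); larger values make the post-knee decline steeper.
#' @return An object of class `bias_supply`.
#' @export
bias_supply <- function(max_current = 10e-3, bias_voltage = 50,
                        droop_sharpness = 1) {
  if (max_current <= 0) stop("`max_current` must be > 0.", call. = FALSE)
  structure(list(max_current = max_current, bias_voltage = bias_voltage,
                 droop_sharpness = droop_sharpness),
            class = "bias_supply")
}

#' Bias-voltage droop under current limiting
#'
#' When the mean photocurrent drawn by the array exceeds the supply's
#' current limit, the bias voltage (and with it the overvoltage, gain and
#' PDE) gradually drops. Modeled as a soft knee: the scale is exactly 1 up
#' to `max_current` and declines smoothly as
#' `1 / (1 + k * (I/Imax - 1))` beyond it. The model is optional and off
#' (scale 1) unless invoked.
#'
#' @param mean_current Mean current drawn, amperes (>= 0).
#' @param supply A [bias_supply()].
#' @return Effective overvoltage scale factor in (0, 1].
#' @export
bias_droop <- function(mean_current, supply) {
  stopifnot(inherits(supply, "bias_supply"))
  if (any(mean_current < 0)) {
    stop("`mean_current` must be >= 0.", call. = FALSE)
  }
  excess <- pmax(mean_current / supply$max_current - 1, 0)
  1 / (1 + supply$droop_sharpness * excess)
}
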