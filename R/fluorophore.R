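#' Fluorophore parameters
#'
#' Single-exponential fluorophore model for pulsed-excitation steady-state
#' calculations. The excitation constraint fixes what "exciting 10% of
#' fluorophores" means for a pulse train; the three conventions supported
#' are:
#'
#' * `"per_pulse"`: each pulse excites a fixed fraction `target_fraction` of
#'   the ground-state molecules it finds.
#' * `"post_pulse"` (default): the pulse energy is adjusted so the excited
#'   fraction immediately after each pulse equals `target_fraction` in
#'   steady state.
#' * `"time_averaged"`: the pulse energy is adjusted so the time-averaged
#'   excited fraction over a period equals `target_fraction`. Under this
#'   convention the fluorescent yield per second is `target_fraction /
#'   lifetime` independent of repetition rate (closed form), so it cannot
#'   produce any rate dependence of yield; it is provided to document that
#'   fact.
#'
#' @param lifetime Fluorescent lifetime, seconds (> 0).
#' @param excitation_constraint One of `"post_pulse"`, `"per_pulse"`,
#'   `"time_averaged"`.
#' @param target_fraction Constrained excited (or excitation) fraction in
#'   (0, 1); default 0.1.
#' @return An object of class `fluorophore_params`.
#' @export
fluorophore_params <- function(lifetime,
                               excitation_constraint = c("post_pulse",
                                                         "per_pulse",
                                                         "time_averaged"),
                               target_fraction = 0.1) {
  if (lifetime <= 0) stop("`lifetime` must be > 0.", call. = FALSE)
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("`target_fraction` must lie in (0, 1).", call. = FALSE)
  }
  structure(list(lifetime = lifetime,
                 excitation_constraint = match.arg(excitation_constraint),
                 target_fraction = target_fraction),
            class = "fluorophore_params")
}

#' Steady-state excitation under a pulse train
#'
#' A periodic pulse train (period `T = 1/rep_rate`) excites a fraction `p`
#' of whatever ground-state population it finds; between pulses the excited
#' population relaxes as `exp(-T/lifetime)`. The excited fraction just after
#' a pulse obeys the recursion
#'
#' `x' = x e + p (1 - x e)`, with `e = exp(-T/lifetime)`,
#'
#' whose fixed point is `x* = p / (1 - e (1 - p))`. Depending on the
#' convention, either `p` is given and `x*` solved, or the target `x*` (or
#' the time-averaged excited fraction) is given and `p` solved. The
#' fluorescent yield per fluorophore per second is the rate of decays,
#' `rep_rate * x* * (1 - e)`.
#'
#' @param rep_rate Laser repetition rate, Hz (> 0).
#' @param fl A [fluorophore_params()].
#' @return A list: `p` (per-pulse excitation probability of a ground-state
#'   molecule), `x_post` (steady-state excited fraction just after a pulse),
#'   `x_avg` (time-averaged excited fraction), `yield_per_s` (fluorescence
#'   photons per fluorophore per second, unit quantum yield).
#' @export
excitation_steady_state <- function(rep_rate, fl) {
  stopifnot(inherits(fl, "fluorophore_params"))
  if (rep_rate <= 0) stop("`rep_rate` must be > 0.", call. = FALSE)
  T <- 1 / rep_rate
  e <- exp(-T / fl$lifetime)
  tgt <- fl$target_fraction
  if (fl$excitation_constraint == "per_pulse") {
    p <- tgt
    x <- p / (1 - e * (1 - p))
  } else if (fl$excitation_constraint == "post_pulse") {
    x <- tgt
    p <- x * (1 - e) / (1 - e * x)
  } else { # time_averaged: mean excited fraction over one period = tgt
    # average of x * exp(-t/tau) over [0, T] is x * tau * (1 - e) / T
    x <- tgt * T / (fl$lifetime * (1 - e))
    if (x >= 1) {
      stop("Constraint unsatisfiable: time-averaged target ", tgt,
           " would require a post-pulse excited fraction >= 1 at this rate.",
           call. = FALSE)
    }
    p <- x * (1 - e) / (1 - e * x)
  }
  x_avg <- x * fl$lifetime * (1 - e) / T
  list(p = p, x_post = x, x_avg = x_avg,
       yield_per_s = rep_rate * x * (1 - e))
}

#' Fluorescent yield and required power versus repetition rate
#'
#' Sweeps the laser repetition rate, solving the steady-state excitation at
#' each rate, and reports the fluorescent yield per second and the required
#' average laser power relative to a reference rate (default 78 MHz). Under
#' two-photon excitation at fixed pulse width the per-pulse excitation
#' probability scales with pulse energy squared, so the required pulse
#' energy is proportional to `sqrt(p)` and the average power to
#' `rep_rate * sqrt(p)`.
#'
#' @param rates Repetition rates to evaluate, Hz.
#' @param fl A [fluorophore_params()].
#' @param reference_rate Rate at which both outputs are normalized to 1
#'   (default 78 MHz); need not be an element of `rates`.
#' @return A data.frame with columns `rate_hz`, `relative_yield`,
#'   `relative_power`, `p`, `x_post`.
#' @export
repetition_sweep <- function(rates, fl, reference_rate = 78e6) {
  stopifnot(inherits(fl, "fluorophore_params"))
  solve_one <- function(r) {
    ss <- excitation_steady_state(r, fl)
    c(yield = ss$yield_per_s, power = r * sqrt(ss$p), p = ss$p,
      x = ss$x_post)
  }
  ref <- solve_one(reference_rate)
  m <- t(vapply(rates, solve_one, numeric(4)))
  data.frame(rate_hz = rates,
             relative_yield = m[, "yield"] / ref["yield"],
             relative_power = m[, "power"] / ref["power"],
             p = m[, "p"], x_post = m[, "x"])
}

#' Unsaturated two-photon signal
#'
#' Below saturation, two-photon excited fluorescence scales with the square
#' of the excitation power (at fixed pulse width and repetition rate).
#'
#' @param power Average power, W (>= 0).
#' @param coefficient Proportionality coefficient (signal units per W^2).
#' @return Signal rate `coefficient * power^2`.
#' @export
twophoton_signal <- function(power, coefficient = 1) {
  if (any(power < 0)) stop("`power` must be >= 0.", call. = FALSE)
  coefficient * power^2
}

#' Onset of two-photon saturation on a power sweep
#'
#' Anchors an intensity-squared law on the low-power end of a measured
#' power/signal sweep and reports the lowest power at which the measured
#' signal falls more than `threshold` (default 10%) below that law,
#' interpolated linearly in power between grid points.
#'
#' @param power Ascending powers, W (>= 3 points).
#' @param signal Measured signal at each power.
#' @param reference_fraction Fraction of the power range (from the low end,
#'   in log space) used to fit the squared-law coefficient; default the
#'   lowest third of the points.
#' @param threshold Deviation threshold as a fraction (default 0.1).
#' @return A list: `deviation` (fractional deviation per point),
#'   `coefficient`, `saturation_power` (NA if never crossed), `crossed`.
#' @export
twophoton_saturation_power <- function(power, signal,
                                       reference_fraction = 1 / 3,
                                       threshold = 0.1) {
  if (length(power) < 3) stop("Need at least 3 grid points.", call. = FALSE)
  stopifnot(length(power) == length(signal))
  if (any(diff(power) <= 0) || any(power <= 0)) {
    stop("`power` must be positive and strictly ascending.", call. = FALSE)
  }
  n_ref <- max(2L, ceiling(length(power) * reference_fraction))
  idx <- seq_len(n_ref)
  coefficient <- sum(signal[idx] * power[idx]^2) / sum(power[idx]^4)
  deviation <- 1 - signal / (coefficient * power^2)
  above <- deviation >= threshold
  if (!any(above)) {
    return(list(deviation = deviation, coefficient = coefficient,
                saturation_power = NA_real_, crossed = FALSE))
  }
  i <- which(above)[1]
  sp <- if (i == 1) power[1] else {
    power[i - 1] + (threshold - deviation[i - 1]) *
      (power[i] - power[i - 1]) / (deviation[i] - deviation[i - 1])
  }
  list(deviation = deviation, coefficient = coefficient,
       saturation_power = sp, crossed = TRUE)
}

#' Pulse energy of a pulsed laser
#'
#' @param average_power Average power, W.
#' @param rep_rate Repetition rate, Hz (> 0).
#' @return Pulse energy in joules, `average_power / rep_rate`.
#' @export
pulse_energy <- function(average_power, rep_rate) {
  if (any(rep_rate <= 0)) stop("`rep_rate` must be > 0.", call. = FALSE)
  average_power / rep_rate
}
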