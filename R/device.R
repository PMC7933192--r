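#' SiPM device parameters
#'
#' Static physical description of a silicon-photomultiplier microcell array.
#' Each microcell is a Geiger-mode avalanche photodiode in series with a
#' quench resistor; after an avalanche the cell recharges through the quench
#' resistor with time constant `tau_rc = quench_resistance *
#' junction_capacitance`.
#'
#' @param n_microcells Number of microcells in the array (>= 1).
#' @param quench_resistance Quench resistor value in ohms. May be `NULL` if
#'   `recharge_time_constant` is given directly.
#' @param junction_capacitance Single-cell junction capacitance in farads.
#'   May be `NULL` if `recharge_time_constant` is given directly.
#' @param recharge_time_constant Cell recharge time constant in seconds.
#'   Defaults to `quench_resistance * junction_capacitance`.
#' @param pde Photon detection efficiency in `[0, 1]`: the probability that a
#'   photon incident on the sensor triggers an avalanche.
#' @param single_cell_gain Output charge released by a fully recharged cell,
#'   in output units (e.g. DN per photon after digitization).
#' @param overvoltage Bias voltage above breakdown, volts. Informational;
#'   gain and PDE are specified directly rather than derived from it.
#' @param illumination_profile Optional vector of `n_microcells` nonnegative
#'   relative weights describing how light is distributed over the array.
#'   Normalized to sum to 1. `NULL` (the default) means uniform.
#' @param dark_count_rate Dark-count rate of the whole array in counts/s.
#'   Dark events are simulated as an additional Poisson process landing on
#'   cells drawn from the illumination profile. Default 0 (off). Optical
#'   crosstalk and afterpulsing are deliberately not modeled.
#' @param dark_sd_dn Standard deviation of a dark frame in output units
#'   (DN); informational, used by [dark_noise_fraction()].
#'
#' @return An object of class `sipm_device`.
#' @seealso [sipm_device_s14420()] for a representative 3 mm / 25 um-pitch
#'   device profile.
#' @export
sipm_device <- function(n_microcells,
                        quench_resistance = NULL,
                        junction_capacitance = NULL,
                        recharge_time_constant = NULL,
                        pde = 1,
                        single_cell_gain = 1,
                        overvoltage = NA_real_,
                        illumination_profile = NULL,
                        dark_count_rate = 0,
                        dark_sd_dn = NA_real_) {
  if (!is.numeric(n_microcells) || length(n_microcells) != 1 ||
      n_microcells < 1 || n_microcells != round(n_microcells)) {
    stop("`n_microcells` must be a single integer >= 1.", call. = FALSE)
  }
  if (is.null(recharge_time_constant)) {
    if (is.null(quench_resistance) || is.null(junction_capacitance)) {
      stop("Give `recharge_time_constant` or both `quench_resistance` and ",
           "`junction_capacitance`.", call. = FALSE)
    }
    recharge_time_constant <- quench_resistance * junction_capacitance
  }
  if (!is.numeric(recharge_time_constant) || recharge_time_constant <= 0) {
    stop("`recharge_time_constant` must be > 0.", call. = FALSE)
  }
  if (!is.numeric(pde) || length(pde) != 1 || pde < 0 || pde > 1) {
    stop("`pde` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(single_cell_gain) || single_cell_gain <= 0) {
    stop("`single_cell_gain` must be > 0.", call. = FALSE)
  }
  if (!is.null(illumination_profile)) {
    if (length(illumination_profile) != n_microcells ||
        any(illumination_profile < 0) || sum(illumination_profile) <= 0) {
      stop("`illumination_profile` must be ", n_microcells,
           " nonnegative weights with positive sum.", call. = FALSE)
    }
    illumination_profile <- illumination_profile / sum(illumination_profile)
  }
  if (!is.numeric(dark_count_rate) || dark_count_rate < 0) {
    stop("`dark_count_rate` must be >= 0.", call. = FALSE)
  }
  structure(
    list(
      n_microcells = as.integer(n_microcells),
      quench_resistance = quench_resistance,
      junction_capacitance = junction_capacitance,
      recharge_time_constant = recharge_time_constant,
      pde = pde,
      single_cell_gain = single_cell_gain,
      overvoltage = overvoltage,
      illumination_profile = illumination_profile,
      dark_count_rate = dark_count_rate,
      dark_sd_dn = dark_sd_dn
    ),
    class = "sipm_device"
  )
}

#' Representative 3 mm, 25 um-pitch SiPM device profile
#'
#' A worked example profile for a Hamamatsu S14420-3025-class sensor
#' (3 x 3 mm active area, 25 um microcell pitch) operated well above
#' breakdown. The microcell count, quench resistance and junction capacitance
#' are datasheet-derived representative values, not values printed in any
#' single reference; the gain and dark-frame noise defaults correspond to a
#' digitized signal chain reading 12.9 DN per photon with a 5.97 DN dark
#' frame standard deviation.
#'
#' @param ... Overrides passed to [sipm_device()].
#' @return A `sipm_device`.
#' @export
sipm_device_s14420 <- function(...) {
  args <- list(
    n_microcells = 14400,
    quench_resistance = 150e3,
    junction_capacitance = 1.5e-13,   # tau_rc = 22.5 ns
    pde = 0.4,
    single_cell_gain = 12.9,          # DN/photon
    overvoltage = 7,
    dark_sd_dn = 5.97
  )
  do.call(sipm_device, modifyList(args, list(...)))
}

#' @export
print.sipm_device <- function(x, ...) {
  cat("<sipm_device>\n")
  cat(sprintf("  microcells: %d\n", x$n_microcells))
  cat(sprintf("  recharge time constant: %.3g ns\n",
              x$recharge_time_constant * 1e9))
  cat(sprintf("  PDE: %.3g   gain: %.3g /photon\n", x$pde, x$single_cell_gain))
  if (!is.null(x$illumination_profile)) {
    cat("  illumination: non-uniform\n")
  }
  if (x$dark_count_rate > 0) {
    cat(sprintf("  dark counts: %.3g /s\n", x$dark_count_rate))
  }
  invisible(x)
}
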