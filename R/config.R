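# Configuration loading and validation.
#
# A run configuration is a single YAML file with nested sections. Every
# physical quantity carries an explicit unit suffix in its key name (_hz,
# _s, _w, _a, _v, _ohm, _f, _pps = photons per second, _dn) so that unit
# mistakes are visible at the call site. Unknown keys are rejected.

config_schema <- function() {
  num <- function(lo = -Inf, hi = Inf, len = 1) {
    list(check = function(x) is.numeric(x) && (is.na(len) || length(x) == len) &&
           all(x >= lo) && all(x <= hi),
         msg = sprintf("numeric in [%g, %g]", lo, hi))
  }
  int <- function(lo = 1) {
    list(check = function(x) is.numeric(x) && length(x) == 1 &&
           x >= lo && x == round(x),
         msg = sprintf("integer >= %d", lo))
  }
  numvec <- function(lo = -Inf) {
    list(check = function(x) is.numeric(x) && length(x) >= 1 && all(x >= lo),
         msg = "numeric vector")
  }
  str_in <- function(choices) {
    list(check = function(x) is.character(x) && length(x) == 1 &&
           x %in% choices,
         msg = paste("one of:", paste(choices, collapse = ", ")))
  }
  list(
    seed = int(0),
    sample_rate_hz = num(1),
    device = list(
      n_microcells = int(1),
      quench_resistance_ohm = num(0),
      junction_capacitance_f = num(0),
      recharge_time_constant_s = num(1e-12),
      pde = num(0, 1),
      single_cell_gain_dn = num(1e-12),
      overvoltage_v = num(0),
      dark_count_rate_hz = num(0),
      dark_sd_dn = num(0),
      illumination_profile = numvec(0)
    ),
    chain = list(
      fast_time_constant_s = num(1e-12),
      slow_time_constant_s = num(1e-12),
      slow_to_fast_charge_ratio = num(0),
      pzc_time_constant_s = num(1e-12),
      pzc_attenuation = num(1e-6, 1 - 1e-6),
      lowpass_cutoff_hz = num(1),
      lowpass_order = int(1),
      bias = list(
        max_current_a = num(1e-9),
        bias_voltage_v = num(0),
        droop_sharpness = num(0)
      )
    ),
    scan = list(
      line_rate_hz = num(1),
      pixels_per_line = int(1),
      lines_per_frame = int(1),
      fill_fraction = num(1e-6, 1)
    ),
    fluorophore = list(
      lifetime_s = numvec(1e-15),
      excitation_constraint = str_in(c("post_pulse", "per_pulse",
                                       "time_averaged")),
      target_fraction = num(1e-9, 1 - 1e-9)
    ),
    laser = list(
      repetition_rate_hz = num(1),
      average_power_w = num(0)
    ),
    pmt = list(
      excess_noise_factor = num(1),
      saturation_flux_pps = num(1),
      quantum_efficiency = num(0, 1)
    ),
    ptc = list(
      flux_min_pps = num(1),
      flux_max_pps = num(1),
      n_flux = int(2),
      min_samples = num(100),
      max_samples = num(100),
      target_events = num(100),
      trim_constants = num(0)
    ),
    sipm_linearity_flux_pps = num(1),
    sweep = list(
      rate_min_hz = num(1),
      rate_max_hz = num(1),
      n_rates = int(2),
      reference_rate_hz = num(1)
    ),
    frames = list(
      size_px = int(2),
      photons_per_pixel = num(0),
      n_frames = int(2),
      detector = str_in(c("ideal", "pmt", "sipm"))
    )
  )
}

config_defaults <- function() {
  list(
    seed = 1,
    sample_rate_hz = 125e6,
    device = list(
      n_microcells = 14400,
      quench_resistance_ohm = 150e3,
      junction_capacitance_f = 1.5e-13,
      pde = 0.4,
      single_cell_gain_dn = 12.9,
      overvoltage_v = 7,
      dark_count_rate_hz = 0,
      dark_sd_dn = 5.97
    ),
    chain = list(
      fast_time_constant_s = 2e-9,
      slow_time_constant_s = 22.5e-9,
      slow_to_fast_charge_ratio = 10,
      pzc_time_constant_s = 22.5e-9,
      pzc_attenuation = 1 / 11,
      lowpass_cutoff_hz = 25e6,
      lowpass_order = 4,
      bias = list(max_current_a = 10e-3, bias_voltage_v = 50,
                  droop_sharpness = 1)
    ),
    scan = list(line_rate_hz = 24000, pixels_per_line = 2048,
                lines_per_frame = 2048, fill_fraction = 1),
    fluorophore = list(lifetime_s = c(0.5e-9, 3e-9, 10e-9),
                       excitation_constraint = "post_pulse",
                       target_fraction = 0.1),
    laser = list(repetition_rate_hz = 78e6, average_power_w = 0.0761),
    pmt = list(excess_noise_factor = 1.5, saturation_flux_pps = 3e9,
               quantum_efficiency = 0.4),
    ptc = list(flux_min_pps = 1e8, flux_max_pps = 1e10, n_flux = 5,
               min_samples = 1e6, max_samples = 2e7, target_events = 4e6,
               trim_constants = 50),
    sipm_linearity_flux_pps = 40e9,
    sweep = list(rate_min_hz = 10e6, rate_max_hz = 1e9, n_rates = 25,
                 reference_rate_hz = 78e6),
    frames = list(size_px = 64, photons_per_pixel = 100, n_frames = 16,
                  detector = "ideal")
  )
}

validate_against <- function(x, schema, path = "") {
  for (key in names(x)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(schema)) {
      stop("Unknown config key: `", here, "`.", call. = FALSE)
    }
    spec <- schema[[key]]
    val <- x[[key]]
    if (is.list(spec) && is.null(spec$check)) {
      if (!is.list(val)) {
        stop("Config field `", here, "` must be a section.", call. = FALSE)
      }
      validate_against(val, spec, here)
    } else {
      # YAML 1.1 leaves some scientific-notation literals as strings
      if (is.character(val) && !is.na(suppressWarnings(as.numeric(val[1])))) {
        val <- as.numeric(val)
        x[[key]] <- val
      }
      if (is.list(val) && all(vapply(val, is.numeric, logical(1)))) {
        val <- unlist(val)
        x[[key]] <- val
      }
      if (!spec$check(val)) {
        stop("Config field `", here, "` is invalid: expected ", spec$msg,
             ".", call. = FALSE)
      }
    }
  }
  x
}

merge_defaults <- function(x, defaults) {
  for (key in names(defaults)) {
    if (!key %in% names(x)) {
      x[[key]] <- defaults[[key]]
    } else if (is.list(defaults[[key]]) && is.list(x[[key]])) {
      x[[key]] <- merge_defaults(x[[key]], defaults[[key]])
    }
  }
  x
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, validates every field
#' against its type and range, fills unset fields from documented defaults,
#' and coerces scientific-notation strings to numerics. The derived recharge
#' time constant is computed if not given directly.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `run_config`.
#' @seealso [save_config()], [run_command()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("Config must be a YAML mapping.", call. = FALSE)
  cfg <- validate_against(raw, config_schema())
  cfg <- merge_defaults(cfg, config_defaults())
  cfg <- validate_against(cfg, config_schema())
  if (is.null(cfg$device$recharge_time_constant_s)) {
    cfg$device$recharge_time_constant_s <-
      cfg$device$quench_resistance_ohm * cfg$device$junction_capacitance_f
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Save a run configuration
#'
#' @param config A config list (as from [load_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Build a [sipm_device()] from a config
#'
#' @param config A `run_config`.
#' @return A `sipm_device`.
#' @export
device_from_config <- function(config) {
  d <- config$device
  sipm_device(
    n_microcells = d$n_microcells,
    quench_resistance = d$quench_resistance_ohm,
    junction_capacitance = d$junction_capacitance_f,
    recharge_time_constant = d$recharge_time_constant_s,
    pde = d$pde,
    single_cell_gain = d$single_cell_gain_dn,
    overvoltage = d$overvoltage_v %||% NA_real_,
    illumination_profile = d$illumination_profile,
    dark_count_rate = d$dark_count_rate_hz %||% 0,
    dark_sd_dn = d$dark_sd_dn %||% NA_real_
  )
}
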