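#' Run a named analysis from a configuration
#'
#' Dispatches one of the toolkit's end-to-end analyses, writes its tabular
#' outputs (with unit-naming header comments) into `out_dir`, and records a
#' run manifest (`run_manifest.json`: subcommand, config hash, seed,
#' package and R versions, output files). Outputs are deterministic given
#' the config and seed.
#'
#' Subcommands:
#' * `simulate-ptc` — Monte Carlo photon-transfer sweep: launched flux vs
#'   estimated flux and agreement (`ptc_sweep.<ext>`).
#' * `linearity` — deviation-from-linear curve from the PTC sweep plus the
#'   10%-compression flux (`linearity.<ext>`).
#' * `snr-plan` — shot-noise SNR bounds for the configured scan geometry and
#'   detector saturation limits (`snr_plan.<ext>`).
#' * `repetition-sweep` — relative fluorescent yield and required average
#'   power vs laser repetition rate, one table per configured lifetime
#'   (`repetition_sweep_<lifetime_ns>ns.<ext>`).
#' * `synth-frames` — synthetic Poisson frame stack of a smooth test object
#'   plus per-pixel SNR statistics (`frame_stats.<ext>`, and
#'   `frames.tif` if the tiff package is installed).
#'
#' @param subcommand One of `"simulate-ptc"`, `"linearity"`, `"snr-plan"`,
#'   `"repetition-sweep"`, `"synth-frames"`.
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return Invisibly, a list with `outputs` (file paths), `summary` (a
#'   data.frame or list of headline numbers) and `manifest`.
#' @export
run_command <- function(subcommand, config, out_dir = ".", seed = NULL,
                        format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- format
  res <- switch(
    subcommand,
    "simulate-ptc" = cmd_simulate_ptc(config, out_dir, ext),
    "linearity" = cmd_linearity(config, out_dir, ext),
    "snr-plan" = cmd_snr_plan(config, out_dir, ext),
    "repetition-sweep" = cmd_repetition_sweep(config, out_dir, ext),
    "synth-frames" = cmd_synth_frames(config, out_dir, ext),
    stop("Unknown subcommand: `", subcommand, "`. Valid: simulate-ptc, ",
         "linearity, snr-plan, repetition-sweep, synth-frames.",
         call. = FALSE)
  )
  manifest <- list(
    subcommand = subcommand,
    config_hash = object_hash(config),
    seed = config$seed,
    package_version = as.character(packageVersion("sipmsim")),
    r_version = as.character(getRversion()),
    outputs = basename(unlist(res$outputs))
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(c(res, list(manifest = manifest_path)))
}

ptc_flux_grid <- function(cfg) {
  10^seq(log10(cfg$ptc$flux_min_pps), log10(cfg$ptc$flux_max_pps),
         length.out = cfg$ptc$n_flux)
}

run_ptc_sweep <- function(cfg) {
  device <- device_from_config(cfg)
  simulate_ptc(device, ptc_flux_grid(cfg),
               sample_rate = cfg$sample_rate_hz, seed = cfg$seed,
               min_samples = cfg$ptc$min_samples,
               max_samples = cfg$ptc$max_samples,
               target_events = cfg$ptc$target_events,
               trim_constants = cfg$ptc$trim_constants)
}

cmd_simulate_ptc <- function(cfg, out_dir, ext) {
  sweep <- run_ptc_sweep(cfg)
  path <- file.path(out_dir, paste0("ptc_sweep.", ext))
  write_table_out(sweep, path, ext,
                  "launched_flux [photons/s], sample_mean [DN], sample_variance [DN^2], estimated fluxes [photons/s], agreement [%]")
  list(outputs = list(path), summary = sweep)
}

cmd_linearity <- function(cfg, out_dir, ext) {
  sweep <- run_ptc_sweep(cfg)
  lin <- linearity_curve(sweep$launched_flux, sweep$estimated_launched_flux)
  df <- data.frame(launched_flux = sweep$launched_flux,
                   estimated_launched_flux = sweep$estimated_launched_flux,
                   deviation_pct = lin$deviation_pct)
  path <- file.path(out_dir, paste0("linearity.", ext))
  write_table_out(df, path, ext,
                  "launched_flux [photons/s], deviation_pct [%]")
  list(outputs = list(path),
       summary = list(flux_at_10pct = lin$flux_at_threshold,
                      crossed = lin$crossed))
}

cmd_snr_plan <- function(cfg, out_dir, ext) {
  scan <- scan_geometry(cfg$scan$line_rate_hz, cfg$scan$pixels_per_line,
                        cfg$scan$lines_per_frame, cfg$scan$fill_fraction)
  rates <- resonant_pixel_rates(scan)
  limits <- c(pmt = cfg$pmt$saturation_flux_pps,
              sipm = cfg$sipm_linearity_flux_pps)
  df <- expand.grid(detector = names(limits),
                    pixel_rate = unname(c(rates$average, rates$peak)),
                    stringsAsFactors = FALSE)
  df$rate_kind <- rep(c("average", "peak"), each = 2)
  df$saturation_flux <- unname(limits[df$detector])
  df$max_snr <- max_shot_noise_snr(df$saturation_flux, df$pixel_rate)
  path <- file.path(out_dir, paste0("snr_plan.", ext))
  write_table_out(df, path, ext,
                  "pixel_rate [pixels/s], saturation_flux [photons/s], max_snr [-]")
  list(outputs = list(path), summary = df)
}

cmd_repetition_sweep <- function(cfg, out_dir, ext) {
  rates <- 10^seq(log10(cfg$sweep$rate_min_hz), log10(cfg$sweep$rate_max_hz),
                  length.out = cfg$sweep$n_rates)
  rates <- sort(unique(c(rates, cfg$sweep$reference_rate_hz)))
  outputs <- list()
  for (tau in cfg$fluorophore$lifetime_s) {
    fl <- fluorophore_params(tau, cfg$fluorophore$excitation_constraint,
                             cfg$fluorophore$target_fraction)
    sw <- repetition_sweep(rates, fl,
                           reference_rate = cfg$sweep$reference_rate_hz)
    path <- file.path(out_dir,
                      sprintf("repetition_sweep_%.3gns.%s", tau * 1e9, ext))
    write_table_out(sw, path, ext,
                    "rate_hz [Hz], relative_yield [-], relative_power [-] (reference rate = 1.0)")
    outputs <- c(outputs, path)
  }
  list(outputs = outputs, summary = list(lifetimes_s = cfg$fluorophore$lifetime_s))
}

cmd_synth_frames <- function(cfg, out_dir, ext) {
  n <- cfg$frames$size_px
  # smooth synthetic test object: offset Gaussian blob on a dim background
  xy <- seq(-1, 1, length.out = n)
  obj <- outer(xy, xy, function(x, y) {
    0.1 + exp(-((x - 0.2)^2 + (y + 0.1)^2) / 0.18)
  })
  set.seed(cfg$seed)
  args <- list(object_map = obj,
               photons_at_unit_brightness = cfg$frames$photons_per_pixel,
               n_frames = cfg$frames$n_frames,
               detector = cfg$frames$detector)
  if (cfg$frames$detector == "pmt") {
    args$pmt <- pmt_params(cfg$pmt$excess_noise_factor,
                           cfg$pmt$saturation_flux_pps,
                           cfg$pmt$quantum_efficiency)
  } else if (cfg$frames$detector == "sipm") {
    rates <- resonant_pixel_rates(
      scan_geometry(cfg$scan$line_rate_hz, cfg$scan$pixels_per_line,
                    cfg$scan$lines_per_frame, cfg$scan$fill_fraction))
    dwell <- 1 / rates$average
    args$dwell <- dwell
    args$saturation_model <- sipm_saturation_model(
      device_from_config(cfg), dwell,
      max_photons = 10 * max(obj) * cfg$frames$photons_per_pixel,
      seed = cfg$seed)
  }
  stack <- do.call(synthesize_frames, args)
  stats <- per_pixel_snr(stack)
  df <- data.frame(pixel_mean = as.numeric(stats$mean),
                   pixel_sd = as.numeric(stats$sd),
                   pixel_snr = as.numeric(stats$snr))
  path <- file.path(out_dir, paste0("frame_stats.", ext))
  write_table_out(df, path, ext,
                  "per-pixel statistics over the frame stack [photon counts]")
  outputs <- list(path)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tif <- file.path(out_dir, "frames.tif")
    mx <- max(stack)
    pages <- lapply(seq_len(dim(stack)[3]),
                    function(k) stack[, , k] / max(mx, 1))
    tiff::writeTIFF(pages, tif)
    outputs <- c(outputs, tif)
  }
  list(outputs = outputs,
       summary = list(median_snr = stats::median(df$pixel_snr)))
}
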