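# Columnar trace and transfer-function IO with metadata sidecars.

#' Write a sampled trace to a columnar file with a metadata sidecar
#'
#' The trace samples go to a one-column numeric text file; `sample_rate`,
#' `t0`, `discard_prefix` and the RNG seed go to a `<path>.meta.json`
#' sidecar.
#'
#' @param trace A [sampled_trace()].
#' @param path Output file path.
#' @param device Optional [sipm_device()]; a hash of its parameters is
#'   recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, device = NULL) {
  stopifnot(inherits(trace, "sampled_trace"))
  write.table(data.frame(sample = trace$samples), path, row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  meta <- list(sample_rate_hz = trace$sample_rate, t0_s = trace$t0,
               discard_prefix_s = trace$discard_prefix,
               seed = trace$seed)
  if (!is.null(device)) meta$device_hash <- object_hash(device)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sampled trace written by [write_trace()]
#'
#' @param path Path to the columnar trace file.
#' @return A [sampled_trace()].
#' @export
read_trace <- function(path) {
  samples <- read.table(path, header = TRUE)$sample
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    sampled_trace(samples, meta$sample_rate_hz, t0 = meta$t0_s %||% 0,
                  discard_prefix = meta$discard_prefix_s %||% 0,
                  seed = meta$seed %||% NA_integer_)
  } else {
    sampled_trace(samples)
  }
}

#' Read a transfer function from a two-column numeric file
#'
#' Columns: frequency (Hz) and `|H|^2`. Lines starting with `#` are
#' comments.
#'
#' @param path Input path.
#' @return A [transfer_function()].
#' @export
read_transfer_function <- function(path) {
  d <- read.table(path, header = FALSE, comment.char = "#")
  transfer_function(d[[1]], d[[2]])
}

#' Write a transfer function as a two-column numeric file
#'
#' @param tf A [transfer_function()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer_function <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frequency_hz  magnitude_squared", con)
  write.table(data.frame(tf$frequency, tf$magnitude_squared), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# stable md5 hash of an R object via its canonical YAML rendering
object_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(x), tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

write_table_out <- function(df, path, format = c("csv", "tsv"),
                            unit_comment = NULL) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(unit_comment)) writeLines(paste0("# ", unit_comment), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
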