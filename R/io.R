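# Shared CSV dialect: plain comma-separated values with optional
# '# key: value' metadata lines before the header.

read_metadata_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  list(data = df, meta = meta)
}

write_metadata_csv <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a titration series from CSV
#'
#' Expects columns `conc_M,fret_ratio,fret_ratio_sd` with metadata lines
#' `# temperature_K: ...`, `# pqr: ...`, `# lectin: ...` before the header.
#'
#' @param path CSV file path.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path) {
  x <- read_metadata_csv(path)
  titration_series(x$data$conc_M, x$data$fret_ratio,
                   if (is.null(x$data$fret_ratio_sd)) 0
                   else x$data$fret_ratio_sd,
                   temperature_K = x$meta$temperature_K %||% 298.15,
                   pqr = x$meta$pqr %||% 1,
                   lectin = x$meta$lectin %||% "")
}

#' Write a titration series to CSV
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  write_metadata_csv(as.data.frame(series),
                     list(temperature_K = attr(series, "temperature_K"),
                          pqr = attr(series, "pqr"),
                          lectin = attr(series, "lectin")),
                     path)
}

#' Read temperature-dependent Kd values from CSV
#'
#' Expects columns `temperature_C,kd_nM,kd_sd_nM,lectin`; converts to K
#' and molar units.
#'
#' @param path CSV file path.
#' @return Data frame with `lectin`, `temperature_K`, `Kd` (M), `Kd_sd`
#'   (M).
#' @export
read_kd_temperature_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  data.frame(lectin = df$lectin,
             temperature_K = df$temperature_C + 273.15,
             Kd = df$kd_nM * 1e-9,
             Kd_sd = if (is.null(df$kd_sd_nM)) NA_real_ else df$kd_sd_nM * 1e-9)
}

#' Read a raw stopped-flow channel from CSV
#'
#' Expects columns `time_s,intensity` with metadata lines `# emission_nm`,
#' `# replicate_id`, `# role`.
#'
#' @param path CSV file path.
#' @return A [kinetic_channel()].
#' @export
read_kinetic_channel_csv <- function(path) {
  x <- read_metadata_csv(path)
  kinetic_channel(x$data$time_s, x$data$intensity,
                  emission_nm = x$meta$emission_nm,
                  replicate_id = x$meta$replicate_id %||% 1L,
                  role = x$meta$role %||% "sample")
}

#' Write a fit result (or any plain result list) to JSON
#'
#' @param result A fit-result object (its class is recorded as `type`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  payload <- unclass(result)
  payload$series <- NULL
  payload$residuals <- NULL
  payload$fitted <- NULL
  payload$type <- class(result)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged temperature-dependent affinity table
#'
#' The fitted apparent Kd values (nM, with fitting errors) for the three
#' lectin constructs at 20/25/30 degrees C, shipped as a plain-text CSV in
#' `inst/extdata/affinity_vs_temperature.csv`.
#'
#' @return Data frame with `lectin`, `temperature_K`, `Kd` (M), `Kd_sd`
#'   (M).
#' @export
affinity_temperature_table <- function() {
  read_kd_temperature_csv(system.file("extdata",
                                      "affinity_vs_temperature.csv",
                                      package = "qdfret"))
}

#' Packaged stopped-flow kinetic parameter table
#'
#' The fitted association (y_max, k_on, a) and dissociation
#' (y_0, y_eq, k_off', a) parameters for the three lectin constructs,
#' shipped in `inst/extdata/kinetic_parameters.csv`. Rates in SI units.
#'
#' @return Data frame, one row per lectin.
#' @export
kinetic_parameter_table <- function() {
  utils::read.csv(system.file("extdata", "kinetic_parameters.csv",
                              package = "qdfret"), comment.char = "#")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
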