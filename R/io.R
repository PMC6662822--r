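# CSV readers/writers for the assay table formats and JSON fit reports.
# Concentrations are molar, energies kJ/mol, temperatures K internally
# (degC only in the nanoDSF ramp column, as the instrument reports it).

.read_csv_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  d
}

#' Read and write assay tables
#'
#' Plain-CSV readers for the five table formats the fitting functions
#' consume, with column checks: MS peak lists (`mz,intensity,run`),
#' relaxation decays (`delay_s,region,intensity`), titrations
#' (`conc_M,signal,replicate`), melting curves (`temp_C,ratio`), ITC
#' injections (`injection_ul,heat_uJ`) and dose-response tables
#' (`conc_M,response,replicate`). `write_table_csv()` writes any of them
#' back without row names, so a write/read round trip preserves the
#' payload.
#'
#' @param path File path.
#' @return The checked data frame.
#' @name assay_io
NULL

#' @rdname assay_io
#' @export
read_peaks_csv <- function(path) .read_csv_checked(path, c("mz", "intensity"))

#' @rdname assay_io
#' @export
read_relaxation_csv <- function(path) {
  d <- .read_csv_checked(path, c("delay_s", "region", "intensity"))
  class(d) <- c("relaxation_series", "data.frame")
  d
}

#' @rdname assay_io
#' @export
read_titration_csv <- function(path) .read_csv_checked(path, c("conc_M", "signal"))

#' @rdname assay_io
#' @export
read_melting_csv <- function(path) .read_csv_checked(path, c("temp_C", "ratio"))

#' @rdname assay_io
#' @export
read_itc_csv <- function(path) .read_csv_checked(path, c("injection_ul", "heat_uJ"))

#' @rdname assay_io
#' @export
read_dose_response_csv <- function(path)
  .read_csv_checked(path, c("conc_M", "response"))

#' @rdname assay_io
#' @param data Data frame to write.
#' @export
write_table_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a fit report as JSON
#'
#' Serialises any of the package's fit objects (their numeric fields and
#' parameter tables) to JSON and restores them as plain lists. Used to pass
#' stage results between pipeline runs.
#'
#' @param fit A fit object or plain list.
#' @param path Output path.
#' @return `write_fit_json()` the path, invisibly; `read_fit_json()` a list.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
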