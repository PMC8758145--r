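# CSV schemas and JSON fit reports. All readers validate the declared
# schema and fail with a config error on mismatch.

#' Read and write dose-response tables
#'
#' CSV schema: `effector,conc_uM,response,response_kind,replicate`
#' (UTF-8, header required, dot decimal separator).
#'
#' @param path File path.
#' @return `read_dose_response()` returns a validated tibble.
#' @export
read_dose_response <- function(path) {
  tbl <- read_csv_checked(path,
                          c("effector", "conc_uM", "response",
                            "response_kind", "replicate"))
  validate_dose_response(tbl)
}

#' @rdname read_dose_response
#' @param data Dose-response tibble.
#' @export
write_dose_response <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write assay time courses
#'
#' CSV schema (long format): `time_min,analyte,conc_uM`, with the assay
#' context (`s0_uM`, `enzyme_ug_per_ml`) in a sidecar config — either a
#' YAML/JSON file path or a named list.
#'
#' @param path CSV path.
#' @param config Sidecar config: list or path to YAML/JSON with keys
#'   `s0_uM` and `enzyme_ug_per_ml`.
#' @return A [time_course()].
#' @export
read_time_course <- function(path, config) {
  tbl <- read_csv_checked(path, c("time_min", "analyte", "conc_uM"))
  cfg <- load_config(config)
  for (key in c("s0_uM", "enzyme_ug_per_ml"))
    if (is.null(cfg[[key]]))
      abort_config(sprintf("Time-course config is missing `%s`.", key))
  times <- sort(unique(tbl$time_min))
  products <- purrr::map(split(tbl, tbl$analyte), function(d) {
    d <- d[order(d$time_min), ]
    if (!identical(d$time_min, times))
      abort_config("Every analyte must be sampled at every time point.")
    d$conc_uM
  })
  time_course(times, products, s0 = cfg$s0_uM,
              enzyme_conc = cfg$enzyme_ug_per_ml)
}

#' @rdname read_time_course
#' @param tc A [time_course()].
#' @export
write_time_course <- function(tc, path) {
  readr::write_csv(tc$data, path)
  invisible(path)
}

#' Read and write ITC isotherms
#'
#' CSV schema: `injection,volume_uL,heat_uJ`.
#'
#' @param path File path.
#' @return `read_isotherm()` returns an `isotherm` tibble.
#' @export
read_isotherm <- function(path) {
  tbl <- read_csv_checked(path, c("injection", "volume_uL", "heat_uJ"))
  class(tbl) <- c("isotherm", class(tbl))
  tbl
}

#' @rdname read_isotherm
#' @param iso Isotherm tibble.
#' @export
write_isotherm <- function(iso, path) {
  readr::write_csv(tibble::as_tibble(iso)[, c("injection", "volume_uL",
                                              "heat_uJ")], path)
  invisible(path)
}

read_csv_checked <- function(path, columns) {
  if (!file.exists(path)) abort_config(sprintf("File not found: %s", path))
  tbl <- try(readr::read_csv(path, show_col_types = FALSE,
                             progress = FALSE), silent = TRUE)
  if (inherits(tbl, "try-error") || !nrow(tbl))
    abort_config(sprintf("Could not read a non-empty CSV from %s.", path))
  missing <- setdiff(columns, names(tbl))
  if (length(missing))
    abort_config(sprintf("%s is missing column(s): %s", basename(path),
                         paste(missing, collapse = ", ")))
  tbl
}

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      abort_config(sprintf("Config file not found: %s", config))
    ext <- tolower(tools::file_ext(config))
    cfg <- if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
           else yaml::read_yaml(config)
    if (!is.list(cfg)) abort_config("Config must parse to a mapping.")
    return(cfg)
  }
  abort_config("Config must be a named list or a YAML/JSON file path.")
}

#' Serialise a fit as a JSON report
#'
#' Writes parameter estimates (with fixed/pinned flags where the fit
#' carries them), residual sum of squares, the number of points, the seed
#' and the package version, so any fit can be reproduced from its report.
#'
#' @param fit A `dual_effector_fit`, `mm_fit` or `one_site_fit`.
#' @param path Output path (`.json`).
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    fit_class = class(fit)[1],
    estimates = tidy(fit),
    summary = glance(fit),
    package_version = as.character(utils::packageVersion("sarmact"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
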