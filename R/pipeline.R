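# Config-driven entry points tying the stages into a runnable pipeline.
# Each accepts a named list or a YAML/JSON file path. A thin command-line
# wrapper over these functions ships in inst/cli/sarmact.R.

provenance <- function(cfg, seed) {
  list(seed = seed, config = cfg,
       package_version = as.character(utils::packageVersion("sarmact")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

cfg_get <- function(cfg, key, default = NULL, required = FALSE) {
  val <- cfg[[key]]
  if (is.null(val)) {
    if (required) abort_config(sprintf("Config is missing `%s`.", key))
    return(default)
  }
  val
}

cfg_params <- function(block) {
  if (is.null(block)) abort_config("Config is missing a `params` block.")
  do.call(dual_effector_params, block)
}

#' Run a simulation described by a config
#'
#' Dispatches on `config$generator` (`"dose_response"`, `"time_course"` or
#' `"isotherm"`), writes the simulated CSV to `config$output`, and writes a
#' JSON provenance record (seed, parameters, package version) alongside it.
#' A missing seed defaults to 1 and is recorded.
#'
#' @param config Named list or YAML/JSON path. Common keys: `generator`,
#'   `output`, `seed`. Generator-specific blocks: `preset`, `replicates`,
#'   `noise_cv` (dose-response); `params`, `s0_uM`, `i_conc_uM`,
#'   `enzyme_ug_per_ml`, `times_min`, `cadpr_fraction`, `noise_sd`
#'   (time course); `protocol`, `binding`, `noise_sd` (isotherm).
#' @return Paths of the files written, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  generator <- cfg_get(cfg, "generator", required = TRUE)
  output <- cfg_get(cfg, "output", required = TRUE)
  seed <- cfg_get(cfg, "seed", default = 1)

  if (generator == "dose_response") {
    preset <- scenario_preset(cfg_get(cfg, "preset", required = TRUE))
    tbl <- gen_dose_response(preset,
                             replicates = cfg_get(cfg, "replicates", 3),
                             noise_cv = cfg_get(cfg, "noise_cv", 0.05),
                             seed = seed)
    write_dose_response(tbl, output)
  } else if (generator == "time_course") {
    tc <- gen_time_course(
      cfg_params(cfg$params),
      s0 = cfg_get(cfg, "s0_uM", 250),
      i_conc = cfg_get(cfg, "i_conc_uM", 0),
      enzyme_conc = cfg_get(cfg, "enzyme_ug_per_ml", 10),
      times = cfg_get(cfg, "times_min", 0:10),
      cadpr_fraction = cfg_get(cfg, "cadpr_fraction", 0.1),
      noise_sd = cfg_get(cfg, "noise_sd", 0), seed = seed)
    write_time_course(tc, output)
  } else if (generator == "isotherm") {
    prot <- do.call(itc_protocol, cfg_get(cfg, "protocol", list()))
    bp <- do.call(binding_params, cfg_get(cfg, "binding", required = TRUE))
    iso <- gen_isotherm(prot, bp, noise_sd = cfg_get(cfg, "noise_sd", 0),
                        seed = seed)
    write_isotherm(iso, output)
  } else {
    abort_config(sprintf("Unknown generator '%s'.", generator))
  }
  prov_path <- paste0(tools::file_path_sans_ext(output), "_provenance.json")
  jsonlite::write_json(provenance(cfg, seed), prov_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(c(output, prov_path))
}

#' Run a fit described by a config
#'
#' Dispatches on `config$model`: `"dual_effector"` (dose-response CSV),
#' `"michaelis_menten"` (CSV with `s_uM,rate`) or `"one_site"` (isotherm
#' CSV plus a `protocol` block). Writes a JSON fit report to
#' `config$output` and returns the fit.
#'
#' @param config Named list or YAML/JSON path.
#' @return The fit object, invisibly.
#' @export
run_fit <- function(config) {
  cfg <- load_config(config)
  model <- cfg_get(cfg, "model", required = TRUE)
  input <- cfg_get(cfg, "input", required = TRUE)
  output <- cfg_get(cfg, "output", required = TRUE)
  seed <- cfg_get(cfg, "seed", default = 1)

  fit <- if (model == "dual_effector") {
    fit_dual_effector(read_dose_response(input),
                      s_conc = cfg_get(cfg, "s_conc_uM", 250),
                      fixed = cfg_get(cfg, "fixed", list()),
                      n_starts = cfg_get(cfg, "n_starts", 32),
                      seed = seed)
  } else if (model == "michaelis_menten") {
    fit_michaelis_menten(read_csv_checked(input, c("s_uM", "rate")))
  } else if (model == "one_site") {
    prot <- do.call(itc_protocol, cfg_get(cfg, "protocol", list()))
    fit_one_site(read_isotherm(input), prot,
                 fix = cfg_get(cfg, "fix", list()),
                 n_starts = cfg_get(cfg, "n_starts", 16), seed = seed)
  } else {
    abort_config(sprintf("Unknown model '%s'.", model))
  }
  write_fit_report(fit, output)
  invisible(fit)
}

#' Run a structural superposition described by a config
#'
#' Loads two coordinate files (`reference`, `mobile` blocks, each with
#' `path`, `chain` and optional `range`), superposes the mobile chain onto
#' the reference, writes a JSON report and optionally the transformed
#' mobile coordinates as CSV.
#'
#' @param config Named list or YAML/JSON path. Keys: `reference`, `mobile`,
#'   `output`, optional `reject_cycles`, `reject_sigma`,
#'   `transformed_output`.
#' @return The `superposition`, invisibly.
#' @export
run_superpose <- function(config) {
  cfg <- load_config(config)
  load_block <- function(block, label) {
    if (is.null(block)) abort_config(sprintf("Missing `%s` block.", label))
    load_calpha(cfg_get(block, "path", required = TRUE),
                chain = cfg_get(block, "chain", required = TRUE),
                range = unlist(block$range))
  }
  a <- load_block(cfg$reference, "reference")
  b <- load_block(cfg$mobile, "mobile")
  sp <- superpose(a, b,
                  reject_cycles = cfg_get(cfg, "reject_cycles", 5),
                  reject_sigma = cfg_get(cfg, "reject_sigma", 2.0))
  output <- cfg_get(cfg, "output", required = TRUE)
  report <- list(rmsd = sp$rmsd, paired_count = sp$paired_count,
                 initial_pairs = sp$initial_pairs,
                 cycles_used = sp$cycles_used,
                 rotation = sp$rotation, translation = sp$translation,
                 reference = attr(a, "source"), mobile = attr(b, "source"),
                 package_version =
                   as.character(utils::packageVersion("sarmact")))
  jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  if (!is.null(cfg$transformed_output))
    readr::write_csv(apply_transform(b, sp), cfg$transformed_output)
  invisible(sp)
}
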