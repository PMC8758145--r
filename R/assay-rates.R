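#' Construct a discontinuous-assay time course
#'
#' A time course records product concentrations sampled at discrete times
#' from a quenched NAD-consumption assay, together with the initial
#' substrate concentration and the enzyme load needed to convert slopes to
#' specific activities.
#'
#' @param times Sampling times in minutes; strictly increasing, >= 0.
#' @param products Named list of numeric vectors (one per analyte, same
#'   length as `times`) or a data frame with one column per analyte.
#'   Recognised analytes: ADPR, cADPR, NAM, NaMN.
#' @param s0 Initial substrate (NAD) concentration, µM.
#' @param enzyme_conc Enzyme concentration, µg/ml.
#' @return An object of class `time_course`; `$data` holds a long tibble
#'   with columns `time_min`, `analyte`, `conc_uM`.
#' @examples
#' tc <- time_course(0:5, list(ADPR = 0.18 * (0:5), cADPR = 0.02 * (0:5)),
#'                   s0 = 250, enzyme_conc = 10)
#' product_rate(tc)
#' @export
time_course <- function(times, products, s0 = 250, enzyme_conc = 10) {
  check_nonneg(times, "times")
  if (is.unsorted(times, strictly = TRUE))
    abort_domain("`times` must be strictly increasing.")
  check_pos(s0, "s0")
  check_pos(enzyme_conc, "enzyme_conc")
  products <- as.list(products)
  if (is.null(names(products)) || any(names(products) == ""))
    abort_domain("`products` must be a named list of analyte series.")
  known <- c("ADPR", "cADPR", "NAM", "NaMN")
  bad <- setdiff(names(products), known)
  if (length(bad))
    abort_domain(paste0("Unknown analyte(s): ", paste(bad, collapse = ", ")))
  for (nm in names(products)) {
    if (length(products[[nm]]) != length(times))
      abort_domain(sprintf("Analyte `%s` length differs from `times`.", nm))
    check_nonneg(products[[nm]], nm)
  }
  data <- purrr::imap_dfr(products, function(v, nm)
    tibble::tibble(time_min = times, analyte = nm, conc_uM = v))
  structure(list(data = data, times = times, s0 = s0,
                 enzyme_conc = enzyme_conc),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d time points, analytes: %s; s0 = %g uM, enzyme = %g ug/ml\n",
              length(x$times), paste(unique(x$data$analyte), collapse = ", "),
              x$s0, x$enzyme_conc))
  invisible(x)
}

analyte_series <- function(tc, analytes) {
  present <- intersect(analytes, unique(tc$data$analyte))
  if (!length(present)) return(rep(0, length(tc$times)))
  wide <- tidyr::pivot_wider(tc$data[tc$data$analyte %in% present, ],
                             names_from = "analyte",
                             values_from = "conc_uM")
  rowSums(wide[, present, drop = FALSE])
}

#' Retained time window under the substrate-consumption cutoff
#'
#' Initial rates from a discontinuous assay are only meaningful while
#' product accumulation remains approximately linear. Following the standard
#' practice for this assay, points are retained while estimated substrate
#' consumed stays at or below `max_fraction` of the initial NAD. Consumption
#' is estimated as the sum of ADPR and cADPR (each mole of either represents
#' one mole of NAD cleaved; NAM is co-produced and would double-count). The
#' window is a prefix of the series: once the threshold is crossed no later
#' point is re-admitted, since consumption is physically monotone.
#'
#' @param tc A [time_course()].
#' @param max_fraction Maximum allowed consumed fraction of `s0`
#'   (default 0.2, i.e. the 20% rule); boundary inclusive.
#' @return Integer vector of retained time indices (1-based).
#' @export
consumption_window <- function(tc, max_fraction = 0.2) {
  stopifnot(inherits(tc, "time_course"))
  if (!is.numeric(max_fraction) || max_fraction <= 0 || max_fraction >= 1)
    abort_domain("`max_fraction` must lie in (0, 1).")
  consumed <- analyte_series(tc, c("ADPR", "cADPR"))
  thresh <- max_fraction * tc$s0
  over <- which(consumed > thresh)
  n_keep <- if (length(over)) over[1] - 1L else length(tc$times)
  if (n_keep < 1L)
    abort_domain("No linear window: first point already exceeds the consumption cutoff.")
  seq_len(n_keep)
}

#' Initial rate from linearly accumulating products
#'
#' Ordinary least-squares slope (free intercept) of summed analyte
#' concentration vs time over the consumption window. The free intercept
#' tolerates small t = 0 backgrounds. The default analytes are ADPR and
#' cADPR, the products whose accumulation defines the NADase rate.
#'
#' @inheritParams consumption_window
#' @param analytes Analytes whose concentrations are summed before
#'   regression.
#' @return An object of class `rate_result`: `slope` (µM/min), `window`
#'   (retained indices), `specific_activity` (milliU/mg, computed with the
#'   time course's enzyme concentration), `r_squared`, and a
#'   `negative_slope` flag.
#' @export
product_rate <- function(tc, analytes = c("ADPR", "cADPR"),
                         max_fraction = 0.2) {
  stopifnot(inherits(tc, "time_course"))
  window <- consumption_window(tc, max_fraction)
  if (length(window) < 2L)
    abort_domain("Fewer than 2 points retained; cannot fit a rate.")
  y <- analyte_series(tc, analytes)[window]
  t <- tc$times[window]
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  # R^2 is undefined for a flat response (and numerically meaningless for
  # an exact fit, where summary.lm would return noise)
  r2 <- if (tss < 1e-20) NA_real_ else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(
    slope = slope, window = window,
    specific_activity = specific_activity(slope, tc$enzyme_conc),
    r_squared = r2, negative_slope = slope < 0,
    analytes = analytes, n_points = length(window)
  ), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> slope %.5g uM/min over %d points (R2 %.4f) -> %.5g milliU/mg\n",
              x$slope, x$n_points,
              ifelse(is.na(x$r_squared), NaN, x$r_squared),
              x$specific_activity))
  if (x$negative_slope) cat("  flag: negative slope\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rate_result <- function(x, ...) {
  tibble::tibble(slope_uM_min = x$slope,
                 specific_activity_milliU_mg = x$specific_activity,
                 r_squared = x$r_squared, n_points = x$n_points,
                 negative_slope = x$negative_slope)
}

#' Convert a product-accumulation slope to specific activity
#'
#' One unit (U) of activity is the enzyme amount forming 1 µmol of product
#' per minute. A slope in µM/min equals nmol ml^-1 min^-1, so dividing by
#' the enzyme concentration in mg/ml gives nmol min^-1 mg^-1 = milliU/mg.
#'
#' @param slope Product accumulation rate, µM/min.
#' @param enzyme_conc Enzyme concentration, µg/ml.
#' @return Specific activity in milliU/mg.
#' @examples
#' specific_activity(0.1812, 10) # 18.12 milliU/mg
#' @export
specific_activity <- function(slope, enzyme_conc) {
  if (!is.numeric(slope) || anyNA(slope) || any(!is.finite(slope)))
    abort_domain("`slope` must be finite.")
  check_pos(enzyme_conc, "enzyme_conc")
  slope / (enzyme_conc * 1e-3)
}

#' Fold change of activity relative to a control
#'
#' @param test,control Specific activities (milliU/mg); `control` must be
#'   positive.
#' @return `test / control` (dimensionless).
#' @export
fold_change <- function(test, control) {
  if (!is.numeric(control) || anyNA(control) || any(control <= 0))
    abort_domain("`control` must be strictly positive.")
  check_nonneg(test, "test")
  test / control
}

#' Activities as relative percentages of a control
#'
#' @param rates Vector of activities (milliU/mg).
#' @param control Control activity (> 0).
#' @return Percentages, `100 * rates / control`.
#' @export
relative_percent <- function(rates, control) {
  100 * fold_change(rates, control)
}
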