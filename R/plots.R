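# autoplot methods: quick diagnostic figures for each result type

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.dual_effector_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  pos <- d$conc_uM[d$conc_uM > 0]
  lo <- if (length(pos)) min(pos) / 3 else 0.01
  hi <- max(d$conc_uM) * 1.5
  grid <- c(0, exp(seq(log(lo), log(hi), length.out = n_curve)))
  pred <- if (object$response_kind == "fold")
    fold_activation(grid, object$params)
  else nadase_rate(object$s_conc, grid, object$params)
  curve <- tibble::tibble(conc_uM = grid, response = pred)
  ylab <- if (object$response_kind == "fold") "Fold activation"
          else "Rate (milliU/mg)"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_uM, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::scale_x_continuous(
      trans = scales_pseudo_log(), name = "Effector (µM)") +
    ggplot2::labs(y = ylab) +
    ggplot2::theme_minimal()
}

# pseudo-log axis without a hard scales dependency: log1p-style transform
scales_pseudo_log <- function() {
  scales_installed <- requireNamespace("scales", quietly = TRUE)
  if (scales_installed) scales::pseudo_log_trans(base = 10) else "sqrt"
}

#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  grid <- seq(0, max(d$s_uM) * 1.05, length.out = n_curve)
  km <- if (is.na(object$km)) Inf else object$km
  curve <- tibble::tibble(s_uM = grid,
                          rate = object$vmax * grid / (km + grid))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s_uM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "[NAD] (µM)", y = "Rate (milliU/mg)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.time_course <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$conc_uM,
                               colour = .data$analyte)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Product (µM)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.isotherm <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$molar_ratio, y = .data$heat_uJ)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Molar ratio (titrant/protein)",
                  y = "Injection heat (µJ)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.one_site_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  mr <- simulate_isotherm(object$protocol, object$params)
  d$molar_ratio <- mr$molar_ratio[match(d$injection, mr$injection)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_uJ)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Molar ratio (titrant/protein)",
                  y = "Injection heat (µJ)") +
    ggplot2::theme_minimal()
}
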