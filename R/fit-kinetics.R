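# Bounded multi-start least squares for the dual-site effector model and the
# plain Michaelis-Menten hyperbola. Levenberg-Marquardt steps come from
# minpack.lm::nls.lm; the model functions, start generation and model
# selection are defined here.

# box constraints; optimiser never leaves these
.de_bounds <- list(
  vmax  = c(1e-6, 1e6),
  x_act = c(0, 1e3),
  y_res = c(1e-6, 1),
  ka    = c(1e-3, 1e6),
  ki    = c(1e-3, 1e6),
  n_act = c(0.25, 8),
  n_inh = c(0.25, 8)
)

# ranges used to seed multi-starts (log space; tighter than the hard bounds
# so starts land in the plausible region)
.de_start_ranges <- list(
  vmax  = c(0.1, 1e3),
  x_act = c(0.5, 200),
  y_res = c(0.01, 1),
  ka    = c(0.01, 1e4),
  ki    = c(0.01, 1e4),
  n_act = c(0.5, 4),
  n_inh = c(0.5, 4)
)

validate_dose_response <- function(data) {
  need <- c("conc_uM", "response")
  missing <- setdiff(need, names(data))
  if (length(missing))
    abort_domain(paste0("Dose-response data must have columns: ",
                        paste(missing, collapse = ", "), " (missing)."))
  if (!"response_kind" %in% names(data)) data$response_kind <- "fold"
  kind <- unique(data$response_kind)
  if (length(kind) != 1L || !kind %in% c("rate", "fold"))
    abort_domain("`response_kind` must be uniformly 'rate' or 'fold'.")
  check_nonneg(data$conc_uM, "conc_uM")
  if (anyNA(data$response) || any(!is.finite(data$response)))
    abort_domain("Responses must be finite.")
  if (length(unique(data$conc_uM)) < 4L)
    abort_domain("At least 4 distinct effector concentrations are required.")
  tibble::as_tibble(data)
}

#' Fit the dual-site effector model to a dose-response table
#'
#' Estimates activation/inhibition parameters of the dual-site model from a
#' table of effector concentration vs response, by bounded multi-start
#' weighted least squares. The response is either fold activation relative to
#' the effector-free control (`response_kind == "fold"`, the form reported
#' for SARM1 activation by NMN and VMN; the baseline is then fixed at 1 and
#' `vmax` is not estimable) or absolute specific activity
#' (`response_kind == "rate"`, in which case `vmax` is fitted and `km` is
#' taken as given via `fixed` or the default, since a single substrate
#' concentration carries no information about it).
#'
#' Starts are drawn as a deterministic Latin-hypercube in log-parameter
#' space; each start is refined by bounded Levenberg–Marquardt and the
#' solution with the lowest residual sum of squares wins, with ties broken
#' by the lowest `ka` (the biphasic surface has mirror optima with the
#' activation and inhibition sites swapped). Any estimate within 1% of a box
#' bound is flagged as pinned rather than silently returned — a pinned `ki`
#' with no inhibition limb in the sampled range signals an underdetermined
#' design, not a failure.
#'
#' @param data Data frame with columns `conc_uM`, `response`, and optionally
#'   `response_kind` ("fold" default) and `replicate`.
#' @param s_conc Substrate (NAD) concentration of the assay, µM. Only used
#'   for rate-kind data.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(n_act = 2)`).
#' @param share_hill If `TRUE` (default) one Hill coefficient is shared by
#'   the activation and inhibition terms; set `FALSE` to fit them
#'   independently.
#' @param weighting `"unit"` (default) or `"relative"` (weights
#'   1/response^2).
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Seed for the deterministic start set.
#' @return An object of class `dual_effector_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' p <- dual_effector_params(x_act = 12, y_res = 0.15, ka = 2, ki = 400,
#'                           n_act = 2)
#' d <- gen_dose_response(scenario_preset("hSARM1_VMN"), noise_cv = 0)
#' fit <- fit_dual_effector(d, n_starts = 8)
#' tidy(fit)
#' @export
fit_dual_effector <- function(data, s_conc = 250, fixed = list(),
                              share_hill = TRUE,
                              weighting = c("unit", "relative"),
                              n_starts = 32, seed = 1) {
  data <- validate_dose_response(data)
  weighting <- match.arg(weighting)
  kind <- data$response_kind[1]

  fixed <- as.list(fixed)
  if (kind == "fold") {
    # fold data fixes the baseline to 1: vmax/km cancel out of the model
    fixed$vmax <- fixed$vmax %||% 18.12
    fixed$km <- fixed$km %||% 70
  } else {
    fixed$km <- fixed$km %||% 70
  }
  all_pars <- c("vmax", "x_act", "y_res", "ka", "ki", "n_act", "n_inh")
  free <- setdiff(all_pars, names(fixed))
  if (kind == "fold") free <- setdiff(free, "vmax")
  if (share_hill && !"n_inh" %in% names(fixed)) free <- setdiff(free, "n_inh")
  if (!length(free)) abort_domain("No free parameters left to fit.")

  wts <- if (weighting == "relative") {
    if (any(data$response == 0))
      abort_domain("Relative weighting requires nonzero responses.")
    1 / abs(data$response)
  } else rep(1, nrow(data))

  make_params <- function(theta) {
    p <- fixed
    p[free] <- as.list(exp_log_scale(theta, free))
    if (share_hill && !"n_inh" %in% names(fixed)) p$n_inh <- p$n_act
    p$vmax <- p$vmax %||% 18.12
    do.call(dual_effector_params, p)
  }
  model_fun <- function(p) {
    if (kind == "fold") fold_activation(data$conc_uM, p)
    else nadase_rate(s_conc, data$conc_uM, p)
  }
  resid_fun <- function(theta) {
    p <- try(make_params(theta), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, nrow(data)))
    wts * (model_fun(p) - data$response)
  }

  starts <- lhs_starts(free, n_starts, split_seed(seed, 4L),
                       .de_start_ranges)
  lower <- log_scale(vapply(.de_bounds[free], `[`, 0, 1), free)
  upper <- log_scale(vapply(.de_bounds[free], `[`, 0, 2), free)

  sols <- purrr::map(seq_len(nrow(starts)), function(i) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    out <- try(suppressWarnings(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12))),
      silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    list(theta = out$par, rss = sum(out$fvec^2), info = out$info)
  })
  sols <- purrr::compact(sols)
  if (!length(sols)) abort_fit("All multi-start fits failed to converge.")

  rss <- vapply(sols, `[[`, 0, "rss")
  best_rss <- min(rss)
  near <- which(rss <= best_rss * (1 + 1e-8) + 1e-12)
  # tie-break: among equally good optima, take the lowest activation constant
  if ("ka" %in% free) {
    kas <- vapply(sols[near], function(s) exp_log_scale(s$theta, free)[["ka"]],
                  0)
    best <- near[which.min(kas)]
  } else best <- near[which.min(rss[near])]
  sol <- sols[[best]]

  est <- exp_log_scale(sol$theta, free)
  params <- make_params(sol$theta)
  pinned <- pinned_flags(est, .de_bounds[free])
  fitted_vals <- model_fun(params)

  estimates <- tibble::tibble(
    term = all_pars,
    estimate = vapply(all_pars, function(nm) params[[nm]], 0,
                      USE.NAMES = FALSE),
    fixed = all_pars %in% names(fixed) |
      (share_hill & all_pars == "n_inh" & !"n_inh" %in% free),
    pinned = vapply(all_pars, function(nm)
      isTRUE(pinned[nm]), logical(1))
  )
  if (kind == "fold") {
    # fold data carries no information about the absolute rate scale
    estimates$estimate[estimates$term == "vmax"] <- NA_real_
  }

  structure(list(
    params = params, estimates = estimates, rss = sol$rss,
    residuals = fitted_vals - data$response, fitted = fitted_vals,
    data = data, response_kind = kind, s_conc = s_conc,
    weighting = weighting, n_points = nrow(data), n_starts = n_starts,
    seed = seed, free = free,
    identifiable = !any(pinned)
  ), class = "dual_effector_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameters are optimised on log scale except x_act which may be 0
.log_pars <- c("vmax", "y_res", "ka", "ki", "n_act", "n_inh")

log_scale <- function(x, names) {
  out <- x
  lg <- names %in% .log_pars
  out[lg] <- log(pmax(x[lg], 1e-300))
  out[!lg] <- x[!lg]
  out
}

exp_log_scale <- function(theta, names) {
  out <- theta
  lg <- names %in% .log_pars
  out[lg] <- exp(theta[lg])
  stats::setNames(out, names)
}

lhs_starts <- function(free, n_starts, seed, ranges) {
  u <- with_seed(seed, lhs::randomLHS(n_starts, length(free)))
  lo <- log_scale(vapply(ranges[free], `[`, 0, 1), free)
  hi <- log_scale(vapply(ranges[free], `[`, 0, 2), free)
  starts <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- free
  starts
}

# a parameter within 1% of either box bound is reported as pinned
pinned_flags <- function(est, bounds, tol = 0.01) {
  vapply(names(est), function(nm) {
    b <- bounds[[nm]]
    near_lower <- if (b[1] == 0) est[[nm]] <= tol * (b[2] - b[1]) * 1e-6
                  else abs(est[[nm]] - b[1]) <= tol * abs(b[1])
    near_upper <- abs(est[[nm]] - b[2]) <= tol * abs(b[2])
    near_lower || near_upper
  }, logical(1))
}

#' Fit a two-parameter Michaelis-Menten hyperbola
#'
#' Least-squares fit of `v = Vmax * s / (Km + s)` to rate vs substrate data,
#' used for the basal (effector-free) NAD saturation curve. Starting values
#' come from a linearisation; refinement is bounded Levenberg–Marquardt.
#'
#' @param data Data frame with columns `s_uM` (substrate, µM) and `rate`
#'   (milliU/mg); or pass two numeric vectors via `s_uM` and `rate`.
#' @param s_uM,rate Optional numeric vectors, used when `data` is missing.
#' @return Object of class `mm_fit` with `tidy()`/`glance()`/`autoplot()`
#'   methods; `$vmax` and `$km` hold the estimates. `$flags` records
#'   degenerate designs: all-zero rates leave `km` undefined, and data
#'   sampled entirely far above `km` leave it weakly identified.
#' @examples
#' s <- c(10, 25, 50, 70, 100, 250, 500, 1000)
#' fit <- fit_michaelis_menten(data.frame(s_uM = s, rate = 18.12 * s / (70 + s)))
#' c(fit$vmax, fit$km)
#' @export
fit_michaelis_menten <- function(data = NULL, s_uM = NULL, rate = NULL) {
  if (is.null(data)) data <- tibble::tibble(s_uM = s_uM, rate = rate)
  if (!all(c("s_uM", "rate") %in% names(data)))
    abort_domain("Michaelis-Menten data needs columns `s_uM` and `rate`.")
  s <- data$s_uM; v <- data$rate
  check_nonneg(s, "s_uM")
  if (anyNA(v) || any(!is.finite(v))) abort_domain("Rates must be finite.")
  if (length(unique(s)) < 3L)
    abort_domain("At least 3 distinct substrate concentrations are required.")

  flags <- character()
  if (all(v == 0)) {
    return(structure(list(
      vmax = 0, km = NA_real_, rss = 0, fitted = rep(0, length(v)),
      data = tibble::as_tibble(data), n_points = length(v),
      flags = "km_undefined: all rates zero"), class = "mm_fit"))
  }

  # linearised start (Hanes: s/v = s/Vmax + Km/Vmax), guarded against zeros
  ok <- v > 0 & s > 0
  vmax0 <- max(v) * 1.2
  km0 <- if (sum(ok) >= 2) {
    h <- stats::coef(stats::lm(I(s[ok] / v[ok]) ~ s[ok]))
    k <- unname(h[1] / h[2])
    if (is.finite(k) && k > 0) k else stats::median(s[ok])
  } else stats::median(s[s > 0])

  resid_fun <- function(theta) {
    vm <- exp(theta[1]); km <- exp(theta[2])
    vm * s / (km + s) - v
  }
  out <- suppressWarnings(minpack.lm::nls.lm(
    par = c(log(vmax0), log(km0)),
    lower = log(c(1e-9, 1e-6)), upper = log(c(1e9, 1e9)),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-14,
                                         ftol = 1e-14)))
  vmax_hat <- exp(out$par[1]); km_hat <- exp(out$par[2])
  if (km_hat < min(s[s > 0]) / 10)
    flags <- c(flags,
               "km_weak: estimate far below the sampled substrate range")

  structure(list(
    vmax = vmax_hat, km = km_hat, rss = sum(out$fvec^2),
    fitted = vmax_hat * s / (km_hat + s),
    data = tibble::as_tibble(data), n_points = length(v), flags = flags
  ), class = "mm_fit")
}

#' @export
print.dual_effector_fit <- function(x, ...) {
  cat(sprintf("<dual_effector_fit> %s data, %d points, RSS %.4g\n",
              x$response_kind, x$n_points, x$rss))
  print(x$estimates)
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax %.5g milliU/mg, Km %.5g uM (RSS %.3g, n = %d)\n",
              x$vmax, x$km, x$rss, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dual_effector_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.dual_effector_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points, n_starts = x$n_starts,
                 response_kind = x$response_kind, seed = x$seed,
                 identifiable = x$identifiable)
}

#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("vmax", "km"), estimate = c(x$vmax, x$km))
}

#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points,
                 flagged = length(x$flags) > 0)
}
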