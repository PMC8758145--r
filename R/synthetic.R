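#' Scenario presets for synthetic dose-response generation
#'
#' Named parameter sets reproducing the qualitative shapes of the SARM1
#' activation experiments:
#'
#' * `hSARM1_VMN` — biphasic: strong activation at low µM effector
#'   (activation site saturating well before the inhibitory site,
#'   `ka < ki`), with activity dropping at high concentration.
#' * `hSARM1_NMN` — monotone activation on the tested range (no detectable
#'   inhibition limb, `y_res = 1`), with a higher `ka` and lower maximal
#'   induction than VMN.
#' * `K193R_any` — flat: the binding-pocket mutant responds to neither
#'   effector (`x_act = 1`, `y_res = 1`), basal activity 17.75 milliU/mg.
#' * `neutral` — flat at the wild-type basal activity, for negative
#'   controls.
#'
#' Numeric values of `X`, `Y`, `Ka`, `Ki` and the Hill coefficients are
#' package defaults chosen to match the documented qualitative constraints;
#' `vmax` and `km` are the reported basal activity and NAD half-saturation.
#'
#' @param name One of `"hSARM1_VMN"`, `"hSARM1_NMN"`, `"K193R_any"`,
#'   `"neutral"`.
#' @return A list of class `scenario_preset` with elements `name`,
#'   `params` ([dual_effector_params()]), `grid` (µM dose grid) and
#'   `noise_cv` (default replicate noise).
#' @export
scenario_preset <- function(name = c("hSARM1_VMN", "hSARM1_NMN",
                                     "K193R_any", "neutral")) {
  name <- match.arg(name)
  grid <- c(0, 0.5, 1, 2, 5, 10, 20, 50, 100, 200, 500)
  params <- switch(name,
    hSARM1_VMN = dual_effector_params(vmax = 18.12, km = 70, x_act = 15,
                                      y_res = 0.1, ka = 0.5, ki = 300,
                                      n_act = 2),
    hSARM1_NMN = dual_effector_params(vmax = 18.12, km = 70, x_act = 8,
                                      y_res = 1, ka = 20, ki = 1e5,
                                      n_act = 2),
    K193R_any = dual_effector_params(vmax = 17.75, km = 70, x_act = 1,
                                     y_res = 1, ka = 10, ki = 1e5),
    neutral = dual_effector_params(vmax = 18.12, km = 70, x_act = 1,
                                   y_res = 1, ka = 10, ki = 1e5)
  )
  structure(list(name = name, params = params, grid = grid,
                 noise_cv = 0.05),
            class = "scenario_preset")
}

#' Generate a synthetic fold-activation dose-response table
#'
#' Evaluates [fold_activation()] on the preset's dose grid and multiplies
#' by lognormal replicate noise with coefficient of variation `noise_cv`
#' (mean-preserving: the expected value at each dose equals the model
#' value). Responses are ratios and strictly positive, which is why the
#' noise is multiplicative lognormal rather than additive Gaussian.
#'
#' @param preset A [scenario_preset()] (or a preset name).
#' @param replicates Replicates per dose (the experiments report n = 3).
#' @param noise_cv Coefficient of variation of replicate noise; 0 gives
#'   exact model evaluations.
#' @param seed Seed; the table is a pure function of (arguments, seed).
#' @return A dose-response tibble with columns `effector`, `conc_uM`,
#'   `response`, `response_kind` ("fold"), `replicate`.
#' @export
gen_dose_response <- function(preset, replicates = 3, noise_cv = 0.05,
                              seed = 1) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  if (replicates < 1) abort_domain("`replicates` must be >= 1.")
  check_nonneg(noise_cv, "noise_cv")
  base <- tidyr::expand_grid(conc_uM = preset$grid,
                             replicate = seq_len(replicates))
  mu <- fold_activation(base$conc_uM, preset$params)
  response <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(split_seed(seed, 1L),
              mu * stats::rlnorm(nrow(base), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog))
  } else mu
  tibble::tibble(effector = preset$name, conc_uM = base$conc_uM,
                 response = response, response_kind = "fold",
                 replicate = base$replicate)
}

#' Generate a synthetic discontinuous-assay time course
#'
#' Products accumulate linearly at the rate predicted by the dual-site
#' model at the given substrate and effector concentrations, converted to
#' µM/min through the enzyme load, split between ADPR and cADPR by
#' `cadpr_fraction`, capped at the initial substrate concentration (mass
#' conservation), with optional additive Gaussian noise.
#'
#' @param params A [dual_effector_params()].
#' @param s0 Initial NAD concentration, µM.
#' @param i_conc Effector concentration, µM.
#' @param enzyme_conc Enzyme concentration, µg/ml.
#' @param times Sampling times, minutes.
#' @param cadpr_fraction Fraction of cleaved NAD appearing as cADPR
#'   (default 0.1; cADPR is the minor product).
#' @param noise_sd Additive Gaussian noise on concentrations, µM.
#' @param seed Seed for the noise stream.
#' @return A [time_course()].
#' @export
gen_time_course <- function(params, s0 = 250, i_conc = 0, enzyme_conc = 10,
                            times = 0:10, cadpr_fraction = 0.1,
                            noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "dual_effector_params"))
  if (cadpr_fraction < 0 || cadpr_fraction > 1)
    abort_domain("`cadpr_fraction` must lie in [0, 1].")
  check_nonneg(noise_sd, "noise_sd")
  v <- nadase_rate(s0, i_conc, params)        # milliU/mg = nmol/min/mg
  slope <- v * enzyme_conc * 1e-3             # uM/min
  total <- pmin(slope * times, s0)
  adpr <- (1 - cadpr_fraction) * total
  cadpr <- cadpr_fraction * total
  if (noise_sd > 0) {
    noise <- with_seed(split_seed(seed, 2L),
                       stats::rnorm(2 * length(times), sd = noise_sd))
    adpr <- pmax(adpr + noise[seq_along(times)], 0)
    cadpr <- pmax(cadpr + noise[length(times) + seq_along(times)], 0)
  }
  time_course(times, list(ADPR = adpr, cADPR = cadpr), s0 = s0,
              enzyme_conc = enzyme_conc)
}

#' Generate a synthetic ITC isotherm
#'
#' [simulate_isotherm()] plus additive Gaussian heat noise.
#'
#' @inheritParams simulate_isotherm
#' @param noise_sd Additive Gaussian noise on integrated heats, µJ.
#' @param seed Seed for the noise stream.
#' @return An `isotherm` tibble.
#' @export
gen_isotherm <- function(protocol, params, noise_sd = 0, seed = 1) {
  iso <- simulate_isotherm(protocol, params)
  check_nonneg(noise_sd, "noise_sd")
  if (noise_sd > 0) {
    iso$heat_uJ <- iso$heat_uJ +
      with_seed(split_seed(seed, 3L),
                stats::rnorm(nrow(iso), sd = noise_sd))
  }
  iso
}
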