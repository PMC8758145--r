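#' Titration geometry of an ITC experiment
#'
#' Describes the calorimeter cell and injection schedule. The defaults
#' follow the geometry used for the dSARM1 ARM-domain titrations: 0.6 mM
#' titrant delivered as 25 injections of 1.96 µL into 45 µM protein. The
#' cell volume of the low-volume instrument class is 170 µL.
#'
#' @param cell_volume Active cell volume V0, µL.
#' @param cell_conc Protein concentration in the cell, µM.
#' @param syringe_conc Titrant concentration in the syringe, µM.
#' @param injection_volumes Per-injection volumes, µL.
#' @param discard_first Drop the first injection from simulated/fitted
#'   isotherms (a common guard against diffusion across the syringe tip
#'   during equilibration). Off by default.
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume = 170, cell_conc = 45,
                         syringe_conc = 600,
                         injection_volumes = rep(1.96, 25),
                         discard_first = FALSE) {
  check_pos(cell_volume, "cell_volume")
  check_pos(cell_conc, "cell_conc")
  check_nonneg(syringe_conc, "syringe_conc")
  check_pos(injection_volumes, "injection_volumes")
  if (sum(injection_volumes) >= cell_volume)
    abort_domain("Total injected volume must stay below the cell volume.")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 discard_first = isTRUE(discard_first)),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf("<itc_protocol> %d x %.3g uL of %g uM titrant into %g uM protein (V0 = %g uL)\n",
              length(x$injection_volumes), mean(x$injection_volumes),
              x$syringe_conc, x$cell_conc, x$cell_volume))
  invisible(x)
}

#' One-site binding parameters
#'
#' Thermodynamic description of a single class of equivalent sites:
#' stoichiometry `n` (sites per protein), dissociation constant `Kd`, molar
#' enthalpy `dh` (negative = exothermic) and a per-injection background
#' heat.
#'
#' @param stoich Sites per protein molecule (> 0).
#' @param kd Dissociation constant, µM (> 0).
#' @param dh Molar binding enthalpy, kJ/mol.
#' @param q_offset Per-injection background heat, µJ.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(stoich = 1, kd = 2.83, dh = -40, q_offset = 0) {
  check_pos(stoich, "stoich")
  check_pos(kd, "kd")
  if (!is.numeric(dh) || !is.finite(dh)) abort_domain("`dh` must be finite.")
  if (!is.numeric(q_offset) || !is.finite(q_offset))
    abort_domain("`q_offset` must be finite.")
  structure(list(stoich = stoich, kd = kd, dh = dh, q_offset = q_offset),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> n = %.3g, Kd = %.4g uM, dH = %.4g kJ/mol, offset = %.3g uJ\n",
              x$stoich, x$kd, x$dh, x$q_offset))
  invisible(x)
}

#' Cell concentrations after each injection (overflow-cell model)
#'
#' In a fixed-volume (overflow) cell each injection displaces an equal
#' volume of cell liquid. With cumulative injected volume `Vk` the standard
#' continuous-dilution bookkeeping gives total protein
#' `M = M0 * exp(-Vk/V0)` and total titrant
#' `X = Xs * (1 - exp(-Vk/V0))`.
#'
#' @param protocol An [itc_protocol()].
#' @param k Injection index or indices (1-based).
#' @return Tibble with columns `injection`, `m_total`, `x_total` (µM).
#' @export
concentrations_after_injection <- function(protocol, k) {
  stopifnot(inherits(protocol, "itc_protocol"))
  n <- length(protocol$injection_volumes)
  if (any(k < 1L) || any(k > n) || any(k != as.integer(k)))
    abort_domain(sprintf("Injection index must lie in 1..%d.", n))
  vk <- cumsum(protocol$injection_volumes)[k]
  dil <- exp(-vk / protocol$cell_volume)
  tibble::tibble(injection = as.integer(k),
                 m_total = protocol$cell_conc * dil,
                 x_total = protocol$syringe_conc * (1 - dil))
}

#' Equilibrium concentration of the 1:1 complex
#'
#' Solves the one-site mass-action equilibrium for total protein `M`, total
#' ligand `X`, `n` equivalent sites and dissociation constant `Kd`:
#' the physical root of the binding quadratic,
#' `[MX] = ((nM + X + Kd) - sqrt((nM + X + Kd)^2 - 4 nMX)) / 2`,
#' evaluated in the cancellation-free form `2nMX / (b + sqrt(b^2 - 4nMX))`
#' so the tight-binding limit stays accurate.
#'
#' @param m_total Total protein concentration(s), µM.
#' @param x_total Total titrant concentration(s), µM.
#' @param params A [binding_params()].
#' @return Bound-complex concentration(s), µM; always within
#'   `[0, min(n * m_total, x_total)]`.
#' @export
bound_complex <- function(m_total, x_total, params) {
  stopifnot(inherits(params, "binding_params"))
  check_nonneg(m_total, "m_total")
  check_nonneg(x_total, "x_total")
  nm <- params$stoich * m_total
  b <- nm + x_total + params$kd
  disc <- pmax(b^2 - 4 * nm * x_total, 0)
  2 * nm * x_total / (b + sqrt(disc))
}

#' Simulate a one-site ITC isotherm
#'
#' Forward model for the integrated heat of each injection: the enthalpic
#' heat of newly formed complex in the cell, corrected for complex carried
#' out by the displaced volume, plus a constant per-injection background,
#'
#' `q_k = dh * V0 * ([MX]_k - [MX]_(k-1) * (1 - v_k/V0)) * 1e-3 + q_offset`
#'
#' with `[MX]_0 = 0`; the factor 1e-3 converts µM * µL * kJ/mol to µJ.
#'
#' @inheritParams concentrations_after_injection
#' @param params A [binding_params()].
#' @return A tibble of class `isotherm` with columns `injection`,
#'   `volume_uL`, `molar_ratio` (cumulative titrant over cell protein) and
#'   `heat_uJ`. If the protocol discards the first injection, it is absent
#'   from the output (but still dilutes the cell).
#' @examples
#' iso <- simulate_isotherm(itc_protocol(), binding_params(kd = 2.83))
#' head(iso)
#' @export
simulate_isotherm <- function(protocol, params) {
  stopifnot(inherits(protocol, "itc_protocol"),
            inherits(params, "binding_params"))
  n <- length(protocol$injection_volumes)
  conc <- concentrations_after_injection(protocol, seq_len(n))
  mx <- bound_complex(conc$m_total, conc$x_total, params)
  mx_prev <- c(0, mx[-n])
  carry <- 1 - protocol$injection_volumes / protocol$cell_volume
  q <- params$dh * protocol$cell_volume * (mx - mx_prev * carry) * 1e-3 +
    params$q_offset
  out <- tibble::tibble(injection = seq_len(n),
                        volume_uL = protocol$injection_volumes,
                        molar_ratio = conc$x_total / conc$m_total,
                        heat_uJ = q)
  if (protocol$discard_first) out <- out[-1L, ]
  class(out) <- c("isotherm", class(out))
  out
}

#' Wiseman c-value of a titration
#'
#' `c = n * [protein] / Kd`, the standard diagnostic of how well an ITC
#' experiment determines `Kd`: the isotherm transition is sharp and
#' informative for c roughly between 1 and 1000.
#'
#' @inheritParams simulate_isotherm
#' @return Dimensionless c-value.
#' @examples
#' c_value(itc_protocol(cell_conc = 45), binding_params(kd = 2.83)) # ~15.9
#' @export
c_value <- function(protocol, params) {
  stopifnot(inherits(protocol, "itc_protocol"),
            inherits(params, "binding_params"))
  params$stoich * protocol$cell_conc / params$kd
}
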