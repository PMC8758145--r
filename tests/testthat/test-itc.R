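default_prot <- itc_protocol() # 25 x 1.96 uL of 600 uM into 45 uM, V0 170 uL

test_that("overflow-cell dilution follows the exponential bookkeeping", {
  prot <- default_prot
  conc <- concentrations_after_injection(prot, 1:25)
  # first small injection: first-order expansion
  v1 <- prot$injection_volumes[1]
  expect_equal(conc$m_total[1], prot$cell_conc * exp(-v1 / prot$cell_volume))
  expect_equal(conc$x_total[1],
               prot$syringe_conc * v1 / prot$cell_volume,
               tolerance = v1 / prot$cell_volume)
  # half-dilution at Vk = V0 ln 2 (build a protocol that lands there)
  vk <- prot$cell_volume * log(2)
  prot2 <- itc_protocol(injection_volumes = c(vk / 10, rep(vk * 9 / 100, 10)))
  c2 <- concentrations_after_injection(prot2, 11)
  expect_equal(c2$m_total, prot2$cell_conc / 2, tolerance = 1e-10)
  # no titrant in the syringe
  prot0 <- itc_protocol(syringe_conc = 0)
  expect_equal(concentrations_after_injection(prot0, 1:25)$x_total,
               rep(0, 25))
  expect_error(concentrations_after_injection(prot, 0),
               class = "sarmact_domain_error")
  expect_error(concentrations_after_injection(prot, 26),
               class = "sarmact_domain_error")
})

test_that("binding quadratic matches a bisection oracle to 1e-9 uM", {
  # printed-geometry spot check
  bp <- binding_params(stoich = 1, kd = 2.83)
  expect_equal(bound_complex(45, 45, bp),
               bound_complex_bisect(45, 45, 1, 2.83), tolerance = 1e-9)
  # 1000 seeded random draws
  set.seed(2024)
  for (i in 1:1000) {
    m <- runif(1, 0.1, 500); x <- runif(1, 0, 1500)
    n <- runif(1, 0.3, 4); kd <- 10^runif(1, -3, 3)
    got <- bound_complex(m, x, binding_params(n, kd))
    want <- bound_complex_bisect(m, x, n, kd)
    expect_close(got, want, 1e-9)
    expect_true(got >= 0 && got <= min(n * m, x) + 1e-12)
  }
})

test_that("tight-binding and zero-ligand limits are exact", {
  bp_tight <- binding_params(stoich = 1, kd = 1e-9)
  expect_equal(bound_complex(45, 20, bp_tight), 20, tolerance = 1e-6)
  expect_equal(bound_complex(45, 0, bp_tight), 0)
})

test_that("simulated heats obey scaling, saturation and conservation", {
  prot <- default_prot
  # dh = 0 gives exactly zero heats
  expect_equal(simulate_isotherm(prot, binding_params(1, 2.83, dh = 0))$heat_uJ,
               rep(0, 25))
  # linearity in dh for offset-free isotherms
  iso1 <- simulate_isotherm(prot, binding_params(1, 2.83, dh = -20))
  iso2 <- simulate_isotherm(prot, binding_params(1, 2.83, dh = -40))
  expect_equal(iso2$heat_uJ, 2 * iso1$heat_uJ, tolerance = 1e-12)

  # tight binding: heats collapse past molar ratio = stoich
  iso_t <- simulate_isotherm(prot, binding_params(1, 1e-4, dh = -40))
  post <- iso_t$heat_uJ[iso_t$molar_ratio > 1.3]
  pre <- iso_t$heat_uJ[iso_t$molar_ratio < 0.7]
  expect_lt(max(abs(post)), 0.02 * max(abs(pre)))

  # conservation: total offset-free heat equals the enthalpy ledger of
  # complex now in the cell plus complex expelled with the displaced volume
  for (kd in c(0.5, 2.83, 50)) {
    bp <- binding_params(1, kd, dh = -37)
    iso <- simulate_isotherm(prot, bp)
    n <- nrow(iso)
    conc <- concentrations_after_injection(prot, 1:n)
    mx <- bound_complex(conc$m_total, conc$x_total, bp)
    expelled <- sum(mx[-n] * prot$injection_volumes[-1])
    ledger <- bp$dh * (mx[n] * prot$cell_volume + expelled) * 1e-3
    expect_equal(sum(iso$heat_uJ), ledger, tolerance = 1e-6 * abs(ledger))
  }
})

test_that("one-site fit recovers the generating thermodynamics from noiseless data", {
  prot <- default_prot
  for (kd in c(2.83, 6.39)) {
    truth <- binding_params(stoich = 1, kd = kd, dh = -45, q_offset = 0)
    fit <- fit_one_site(simulate_isotherm(prot, truth), prot,
                        n_starts = 8, seed = 1)
    est <- tidy(fit)
    expect_equal(est$estimate[est$term == "kd"], kd, tolerance = 0.01)
    expect_equal(est$estimate[est$term == "stoich"], 1, tolerance = 0.01)
    expect_equal(est$estimate[est$term == "dh"], -45, tolerance = 0.01)
  }
})

test_that("round-trip recovery holds across the informative c range", {
  prot <- default_prot
  for (c_target in c(5, 50, 500)) {
    kd <- prot$cell_conc / c_target
    truth <- binding_params(stoich = 1, kd = kd, dh = -30, q_offset = 0.5)
    fit <- fit_one_site(simulate_isotherm(prot, truth), prot,
                        n_starts = 8, seed = 2)
    est <- tidy(fit)
    for (nm in c("stoich", "kd", "dh")) {
      expect_equal(est$estimate[est$term == nm], truth[[nm]],
                   tolerance = 0.01, label = sprintf("%s at c=%g", nm, c_target))
    }
  }
})

test_that("median Kd bias stays under 5% with 2% heat noise over seeded replicates", {
  prot <- default_prot
  truth <- binding_params(stoich = 1, kd = 2.83, dh = -45)
  q_max <- max(abs(simulate_isotherm(prot, truth)$heat_uJ))
  bias <- vapply(1:50, function(i) {
    iso <- gen_isotherm(prot, truth, noise_sd = 0.02 * q_max, seed = i)
    fit <- fit_one_site(iso, prot, n_starts = 4, seed = 1)
    fit$params$kd / truth$kd - 1
  }, 0)
  expect_lt(abs(stats::median(bias)), 0.05)
})

test_that("c-value diagnostic and its flag behave as documented", {
  expect_equal(c_value(itc_protocol(cell_conc = 45), binding_params(1, 45)), 1)
  expect_equal(c_value(itc_protocol(cell_conc = 45), binding_params(1, 2.83)),
               15.90, tolerance = 1e-3)
  expect_equal(c_value(default_prot, binding_params(1, 1e12)), 0,
               tolerance = 1e-9)
  # weakly informative titration is flagged, not rejected
  weak <- binding_params(1, 5e4, dh = -40)
  fit <- fit_one_site(simulate_isotherm(default_prot, weak), default_prot,
                      fix = list(stoich = 1), n_starts = 4, seed = 1)
  expect_false(fit$c_value_ok)
})

test_that("protocol validation enforces the overflow assumption", {
  expect_error(itc_protocol(injection_volumes = rep(10, 20)),
               class = "sarmact_domain_error")
  expect_error(itc_protocol(cell_volume = -1),
               class = "sarmact_domain_error")
  expect_error(fit_one_site(tibble::tibble(injection = 1:4,
                                           heat_uJ = rnorm(4)),
                            default_prot),
               class = "sarmact_domain_error")
})
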