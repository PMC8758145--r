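# sarmact

Quantitative analysis of allosteric SARM1 activation by pyridine
mononucleotide effectors.

SARM1 is the NAD-cleaving enzyme that executes programmed axon death. Its
armadillo-repeat (ARM) domain carries an allosteric pocket where the
endogenous metabolite NMN — and, far more potently, the vacor metabolite
VMN — binds and switches catalysis on. Strikingly, activity *drops* again
at high effector concentration, pointing to a second, inhibitory binding
site. `sarmact` packages the quantitative workflow for studying this dual
regulation: enzymologists and drug-discovery groups can simulate and fit
biphasic dose–response data, extract rates from discontinuous NADase
assays, analyse ITC binding isotherms, and compare ARM-domain
conformations, all from tidy tables.

## The model

NADase rate at substrate concentration [S] and effector concentration [I]:

```
V = Vmax · ( X + (1 − X) / (1 + ([I]/Ka)^n_act) )
         · ( Y + (1 − Y) / (1 + ([I]/Ki)^n_inh) )
         · [S] / (Km + [S])
```

a Michaelis–Menten law multiplied by two Hill-type regulatory factors for
a single readily reversible effector acting through distinct activation
and inhibition sites. `X` is the fold activation at saturating effector,
`Y` the residual activity fraction, `Ka`/`Ki` the site affinity
constants, and both factors equal exactly 1 at [I] = 0, so fold-activation
curves are anchored at 1. Around this core the package provides:

- **Rate extraction** from product time courses (ADPR + cADPR), using the
  ≤ 20% substrate-consumption rule and the unit convention
  1 U = 1 µmol/min (specific activity in milliU/mg).
- **One-site ITC analysis**: overflow-cell dilution bookkeeping, the
  binding-quadratic equilibrium, isotherm simulation and bounded
  multi-start fitting of (n, Kd, ΔH, offset).
- **Structural comparison**: Kabsch (SVD) superposition of Cα traces with
  iterative outlier rejection, residue pairing by author numbering with a
  sequence-alignment fallback, and N/O polar-contact enumeration.
- **Seeded synthetic data** emulating each experiment, so the whole
  pipeline is testable without downloads.

## Worked example

Simulate a VMN-like biphasic fold-activation experiment (3 replicates,
5% CV noise), fit the dual-site model, and locate the response peak:

```r
library(sarmact)

d <- gen_dose_response(scenario_preset("hSARM1_VMN"),
                       replicates = 3, noise_cv = 0.05, seed = 42)
fit <- fit_dual_effector(d, n_starts = 16, seed = 1)
tidy(fit)
#> # A tibble: 7 × 4
#>   term  estimate fixed pinned
#>   <chr>    <dbl> <lgl> <lgl>
#> 1 vmax    NA     TRUE  FALSE
#> 2 x_act   15.0   FALSE FALSE
#> 3 y_res    0.149 FALSE FALSE
#> 4 ka       0.506 FALSE FALSE
#> 5 ki     279.    FALSE FALSE
#> 6 n_act    2.01  FALSE FALSE
#> 7 n_inh    2.01  TRUE  FALSE

peak_effector_response(fit$params)
#> # A tibble: 1 × 2
#>   i_star fold_star
#>    <dbl>     <dbl>
#> 1   12.2      15.0
```

The generating scenario used X = 15, Y = 0.1, Ka = 0.5 µM, Ki = 300 µM
and a Hill coefficient of 2: the noisy fit lands close on every free
parameter (`vmax` is not estimable from fold data and is reported `NA`),
and the activation peak sits near 12 µM effector at ~15-fold induction.
`autoplot(fit)` draws the data and fitted curve.

Rate extraction and ITC follow the same tibble-in/tibble-out pattern:

```r
tc <- gen_time_course(fit$params, s0 = 250, i_conc = 0,
                      enzyme_conc = 10, times = 0:10)
product_rate(tc)
#> <rate_result> slope 0.14156 uM/min over 11 points (R2 1.0000) -> 14.156 milliU/mg

prot <- itc_protocol()  # 25 x 1.96 uL of 600 uM titrant into 45 uM protein
fit_one_site(simulate_isotherm(prot, binding_params(1, 2.83, -45)), prot)
#> <one_site_fit> n = 1, Kd = 2.83 uM, dH = -45 kJ/mol (RSS 3.093e-14, c = 15.9)
```

The extracted specific activity (14.16 milliU/mg at 250 µM NAD) is the
basal Vmax of 18.12 milliU/mg scaled by the substrate term
250/(70 + 250), and the ITC round trip recovers the dissociation constant
and 1:1 stoichiometry it was simulated with.

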