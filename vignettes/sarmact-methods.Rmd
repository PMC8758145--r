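---
title: "Models and methods in sarmact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sarmact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarmact)
```

`sarmact` quantifies how pyridine mononucleotide effectors — the
endogenous NMN and the far more potent vacor metabolite VMN — switch on
the axon-degeneration NADase SARM1, and why activity declines again at
high effector doses. This vignette is the package's own account of its
models, numerical choices and limitations.

## The dual-site effector model

A single reversible effector I acts on one enzyme through two
independent sites: an activating site with affinity constant $K_a$ and an
inhibitory site with affinity constant $K_i$. The rate law multiplies the
Michaelis–Menten substrate term by two Hill-type regulatory factors:

$$V = V_{max}
\left( X + \frac{1 - X}{1 + ([I]/K_a)^{n_{act}}} \right)
\left( Y + \frac{1 - Y}{1 + ([I]/K_i)^{n_{inh}}} \right)
\frac{[S]}{K_m + [S]}$$

Assumptions worth stating explicitly:

- the effector is *readily reversible* and not consumed, so a single
  equilibrium occupancy per site describes each dose;
- the two sites act independently and multiplicatively — there is no
  coupling term between activation and inhibition;
- both factors are exactly 1 at $[I] = 0$, so $V_{max}$ is the basal
  (effector-free) maximal rate and fold-activation curves are anchored
  at 1 by construction, not by normalisation of data.

When $X > 1$, $Y < 1$ and $K_a \ll K_i$ the fold-activation curve
$A \cdot B$ is bell-shaped: activation saturates first, inhibition takes
over at higher dose. `peak_effector_response()` locates the maximum by a
dense log-spaced grid (4000 points by default) refined with a local
golden-section search; a flat or monotone curve simply returns the
appropriate boundary of the search range.

### Hill-exponent placement

Where exactly the cooperativity exponent sits in the published form of
such equations is often ambiguous. The package parameterises the two
limbs independently (`n_act`, `n_inh`), with `n_inh` defaulting to
`n_act`, and the fitter shares one coefficient across both limbs unless
`share_hill = FALSE`. This covers every reading: fixing `n_inh = 1`
reproduces a non-cooperative inhibition limb, and freeing both
reproduces fully independent cooperativity. Positive cooperativity
($n > 1$) in effector binding is the empirically relevant regime for
SARM1.

### Parameters and defaults

| parameter | meaning | units | default | bounds (fit) |
|---|---|---|---|---|
| `vmax` | basal specific activity | milliU/mg | 18.12 | $[10^{-6}, 10^6]$ |
| `km`   | NAD half-saturation | µM | 70 | fixed (see below) |
| `x_act` | fold activation at saturating I | — | 1 | $[0, 10^3]$ |
| `y_res` | residual fraction at saturating I | — | 1 | $[10^{-6}, 1]$ |
| `ka` | activation-site affinity | µM | 1 | $[10^{-3}, 10^6]$ |
| `ki` | inhibition-site affinity | µM | 1000 | $[10^{-3}, 10^6]$ |
| `n_act`, `n_inh` | Hill coefficients | — | 1 | $[0.25, 8]$ |

Units are fixed package-wide: concentrations in µM, time in minutes,
specific activity in milliU/mg (nmol min⁻¹ mg⁻¹; 1 U = 1 µmol/min). The
defaults for `vmax` and `km` are the basal activity and NAD
half-saturation of wild-type hSARM1 under the standard assay (250 µM
NAD); they matter only for rate-kind data, since fold data cancel the
substrate term entirely.

### Fitting

`fit_dual_effector()` minimises (optionally 1/response-weighted) squared
residuals with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
started from 32 deterministic Latin-hypercube points in log-parameter
space (`x_act` is handled on the natural scale because 0 — a complete
loss of the activation limb — is a legitimate value). Multi-start matters
here: the biphasic residual surface has mirror optima in which the
activation and inhibition sites swap roles, and single-start fits can
land in the wrong basin. Solutions tied on residual sum of squares (to
within $10^{-8}$ relative) are resolved to the lowest $K_a$, i.e. the
labelling in which the *higher-affinity* site is the activating one —
the physically meaningful convention for an activator whose effect
precedes its own inhibition.

Two deliberate restrictions keep the fit honest:

- **Fold data never estimate `vmax`** — a ratio to the zero-effector
  control carries no information about the absolute rate scale, so
  `vmax` is reported `NA` rather than a pseudo-estimate.
- **A single assay substrate concentration never estimates `km`** — the
  substrate term is a constant factor at fixed [S]; `km` is taken from
  `fixed` (default 70 µM) and only matters for converting fold to rate.

Any estimate within 1% of a box bound is flagged `pinned` in `tidy()`
output and the fit is marked non-identifiable, rather than silently
returned. A design with no inhibition limb sampled (all doses below
$K_i$) typically pins `ki` at its upper bound — that is a statement
about the design, not a failure.

`fit_michaelis_menten()` fits the two-parameter hyperbola on log-scaled
parameters from a Hanes-linearisation start. All-zero rates return
`vmax = 0` with `km` flagged undefined; data sampled entirely far above
`km` flag the estimate as weakly identified (estimate below one tenth of
the smallest sampled concentration).

## Rate extraction from discontinuous assays

The NADase assay quenches aliquots at discrete times and quantifies
products by HPLC; the package starts from analyte concentrations.

- **Consumption rule.** Points are retained while estimated substrate
  consumed is ≤ 20% of the initial NAD (boundary inclusive;
  `max_fraction` is exposed). Consumption is estimated as ADPR + cADPR:
  each mole of either product represents one NAD cleaved, while
  nicotinamide is co-produced with both and would double-count.
- **Prefix window.** The retained window is a prefix of the series —
  once the threshold is crossed, later points are never re-admitted,
  because consumption is physically monotone and apparent dips are
  noise.
- **Free-intercept regression.** The slope comes from ordinary least
  squares of summed product concentration on time with a free intercept,
  tolerating small $t = 0$ backgrounds. Whether one sums concentrations
  and fits once, or fits each analyte and sums slopes, is mathematically
  equivalent over a shared window; the package sums concentrations.
- **Units.** A slope in µM/min equals nmol ml⁻¹ min⁻¹; dividing by the
  enzyme concentration in mg/ml gives milliU/mg directly, with no hidden
  constants. `specific_activity(0.1812, 10)` is 18.12 milliU/mg.

Negative slopes are flagged, not rejected: they occur legitimately in
noisy near-zero-activity series (e.g. loss-of-function mutants).

## One-site ITC analysis

The titration geometry mirrors the ARM-domain binding experiments:
0.6 mM titrant delivered as 25 × 1.96 µL injections into 45 µM protein.
Choices the instrument documentation leaves open are fixed as follows:

- **Cell volume** is not part of the published protocol; the default is
  170 µL, typical of the low-volume perfusion-cell instrument class. All
  recovery analyses are self-consistent in the cell volume, so the
  choice does not move any recovered constant.
- **Dilution model.** The overflow cell keeps constant volume; with
  cumulative injected volume $V_k$, totals follow the continuous
  convention $M = M_0 e^{-V_k/V_0}$,
  $X = X_s (1 - e^{-V_k/V_0})$ — smooth in $V_k$ and standard for
  perfusion cells.
- **Equilibrium.** The 1:1 complex concentration is the physical root of
  the binding quadratic, evaluated in the cancellation-free form
  $2nMX / (b + \sqrt{b^2 - 4nMX})$ with $b = nM + X + K_d$, so
  tight-binding titrations ($K_d \to 0$) remain accurate to machine
  precision.
- **Heat model.** Injection heat is the enthalpy of newly formed complex
  corrected for complex expelled with the displaced volume, plus a
  constant per-injection background; negative ΔH is exothermic and heats
  are in µJ. The fit operates on absolute heats; a per-mole-of-injectant
  normalised view is a display transformation, not a different
  objective.
- **First-injection discard** is available but off by default.

`fit_one_site()` multi-starts from a deterministic Latin hypercube
(log-spaced in $K_d$, ΔH scaled from the observed total heat) and
reports the Wiseman $c = n[M]/K_d$; outside $c \in [1, 1000]$ the $K_d$
is weakly identifiable and the fit is flagged. At the documented
geometry and a $K_d$ of a few µM, $c \approx 16$ — comfortably
informative.

## Structural comparison

- **Pairing** is by author residue numbering (the compared ARM-domain
  structures share numbering); if residue-name identity on the
  intersection falls below 90%, pairing falls back to a global
  sequence alignment and uses aligned, non-gapped positions — the guard
  for cross-species comparisons with unrelated numbering.
- **Superposition** is the closed-form SVD solution with the
  proper-rotation (reflection) correction, followed by iterative outlier
  rejection: up to 5 cycles, dropping pairs deviating by more than 2.0 ×
  the current RMSD, re-superposing each cycle. This mimics the trimmed
  refinement of common structure viewers, whose reported atom counts sit
  below the full common length; cycles and threshold are configurable
  because no single convention is universal. Published trimmed RMSDs for
  this family of comparisons depend on the (usually unstated) rejection
  protocol — the package therefore treats ±0.2 Å and ±10 retained atoms
  as the meaningful agreement scale for cross-implementation
  comparisons.
- **Polar contacts** are approximated by heavy-atom N/O pairs within
  3.5 Å, with no angular term: deposited models at typical resolution
  carry no hydrogens, and a distance-only criterion is reproducible
  without placement heuristics. This proxy can overcount (it admits
  N···N donor pairs and strained geometries a hydrogen-bond definition
  with angles would reject).
- **Alternate locations** resolve to the highest-occupancy conformer,
  ties to conformer A.

## Synthetic data

The generators reproduce the statistical *structure* of each experiment,
under one global seed that fans out to fixed per-stream seeds
(dose-response 1, time course 2, isotherm 3, fitting starts 4), so every
randomised result in the package is a pure function of its seed.

- **Dose-response**: fold activation on an 11-point dose grid
  (0–500 µM), 3 replicates, multiplied by mean-preserving lognormal
  noise. Replicate scatter in this kind of assay is proportional to
  signal and responses are positive ratios, which is what multiplicative
  lognormal noise encodes; the default 5% CV is a nominal figure of the
  right order for published mean ± SEM of n = 3, and is configurable.
- **Scenario presets** encode the qualitative biology: `hSARM1_VMN`
  (X = 15, Y = 0.1, Ka = 0.5 µM, Ki = 300 µM, n = 2 — potent, biphasic),
  `hSARM1_NMN` (X = 8, Y = 1, Ka = 20 µM, n = 2 — weaker, monotone on
  the tested range), `K193R_any` (X = 1, Y = 1 — the binding-pocket
  mutant responds to neither effector, basal 17.75 milliU/mg) and
  `neutral`. The preset affinities and amplitudes are package choices
  consistent with the documented ordering (VMN binds tighter and
  induces more than NMN); they are *not* measured constants, and tests
  built on them demonstrate recovery of known inputs, not agreement
  with any laboratory value.
- **Time courses**: exactly linear product accumulation at the
  model-predicted rate, split 90/10 between ADPR and cADPR (the minor
  product; the exact split is a package default), capped at $s_0$, with
  additive Gaussian noise — appropriate for concentration readouts with
  roughly constant absolute error.
- **Isotherms**: the forward model plus additive Gaussian heat noise.

What the generators deliberately do **not** emulate: systematic HPLC
calibration error, injection-volume drift and baseline curvature in ITC,
radiation damage or model bias in crystallographic coordinates, and any
cellular metabolite dynamics. Passing recovery tests therefore shows the
estimators are correct and well-conditioned under the declared noise
families — not that real instruments are free of systematic error.

## Numerical choices and degenerate inputs

- Optimisation runs on log-scale for strictly positive parameters;
  residual tolerances are $10^{-12}$–$10^{-14}$ so noiseless round trips
  recover generating values to ~$10^{-6}$ relative or better.
- Ties between equal-RSS optima break to the lowest $K_a$
  (dual-effector) and lowest RSS (elsewhere).
- Degenerate inputs error with typed conditions
  (`sarmact_domain_error`, `sarmact_config_error`, `sarmact_fit_error`),
  which the command-line wrapper maps to exit codes 2/2/3.
- Identity superpositions short-circuit rejection (nothing exceeds
  2 × 0 RMSD in a cycle where all deviations are zero).
- Problem sizes used in the shipped tests — 1000 equilibrium draws
  against the bisection oracle, 100 peak-location draws against a
  200,000-point grid, 50 replicated noisy fits for the bias studies —
  were chosen as the smallest sets that stabilise the checked medians
  and extremes.

## Known limitations

- The dual-site model is phenomenological: it encodes equilibrium
  occupancies, not the conformational kinetics of ARM-domain compaction,
  and cannot distinguish two sites on one protomer from inter-protomer
  sites in the SARM1 octamer.
- Confidence intervals are not produced by profile likelihood; residual
  bootstrap on the returned objects is the intended route.
- The ITC module fits integrated heats only; raw thermogram baseline
  correction and peak integration are upstream of the package.
- Structural comparisons against deposited accessions require the
  coordinate files locally; the package ships no third-party
  coordinates. Buried-surface-area analysis is out of scope.
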