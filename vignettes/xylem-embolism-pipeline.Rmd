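---
title: "Methods: vulnerability-curve fitting, trait simulation and the inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vulnerability-curve fitting, trait simulation and the inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(xylemvc)
```

This vignette documents the models implemented in `xylemvc`, what the
synthetic-data generator does and does not emulate, the numerical choices
made in the estimators, and the package's known limitations. The package
targets stem hydraulics studies in which vulnerability curves are measured
by centrifugation (a Cavitron) on several *Arabidopsis thaliana* accessions
and related to anatomical cross-section traits.

## 1. The vulnerability-curve model

Percent loss of hydraulic conductivity is defined from a stem's measured
conductance `K` relative to its maximum `K_max`:

$$\mathrm{PLC} = 100\,\bigl(1 - K / K_\mathrm{max}\bigr).$$

`plc()` keeps small negative values produced by measurement noise (when
`K > K_max`) rather than clamping; the fitting layer treats them as ordinary
observations, which keeps the noise model unbiased.

The curve of PLC against xylem pressure `P` (MPa, negative under tension) is
the two-parameter sigmoid

$$\mathrm{PLC}(P) = \frac{100}{1 + \exp\!\bigl(\tfrac{S}{25}(P - P_{50})\bigr)},$$

with `P50` the pressure at 50 % loss and `S` the absolute slope of the
curve at its inflexion, in % MPa⁻¹. The closed-form inverse used by
`pressure_at_loss()` is

$$P_x = P_{50} + \frac{25}{S}\,\ln\!\frac{100 - x}{x},$$

so `P12` (air entry) and `P88` (full embolism) are symmetric about `P50`
with gap `(25/S)\,\ln(88/12)` on each side. These identities are verified
against a bisection inverse and a central-difference slope in the test
suite.

## 2. Fitting: `fit_curve()`

`fit_curve()` accepts either a `conductance_series` (pressure/conductance
pairs plus `K_max`) or a data frame with `pressure_MPa` and `plc` columns,
and performs nonlinear least squares on the sigmoid.

Numerical choices:

* **Parameterisation.** The slope is fitted on the log scale
  (`S = exp(logS)`), which enforces `S > 0` and improves conditioning when
  the transition is steep.
* **Engine.** Levenberg–Marquardt via `minpack.lm::nlsLM`, which is robust
  to poor starts and to the near-flat residual surface that occurs when few
  points fall inside the transition.
* **Initialisation.** `P50` starts at the pressure of the observation whose
  PLC is nearest 50; `S` starts at the median absolute finite-difference
  slope of the ordered points, floored at 5 % MPa⁻¹ (non-finite differences
  from duplicated pressures are dropped first).
* **Restarts.** Up to 5 additional starts with jittered initial values; the
  converged fit with the lowest residual sum of squares wins. Curves where
  no start converges are returned with `converged = FALSE` rather than
  erroring, so batch fitting (`fit_curves()`) can proceed.
* **Uncertainty.** Standard errors for `(P50, S)` come from the delta
  method applied to the `(P50, logS)` covariance of the converged fit.

Degenerate inputs — fewer than 4 points, zero PLC variance, pressures that
are not strictly negative — are rejected with itemised messages at
validation time, not during optimisation.

`mean_curve()` evaluates each converged fitted sigmoid on a shared pressure
grid and reports the pointwise mean and standard error (`sd/sqrt(n)`)
across curves; this is a summary of fitted curves, not a pooled refit.

## 3. Anatomy layer

`derive_traits()` computes the trait table from raw microscopy measurement
lists (`anatomy_raw`): vessel lumen areas, maximum vessel diameters and
double wall thicknesses per vessel pair, pit membrane thicknesses, pit
chamber depths, counts of vessels and vessel groupings, and sectional
areas. Key definitions:

* equivalent-circle vessel diameter $D = \sqrt{4A/\pi}$;
* hydraulically weighted diameter $D_H = \bigl(\sum D^4 / N\bigr)^{1/4}$
  (the quartic mean, weighting by hydraulic contribution);
* implosion resistance $(T_{VW}/D_{MAX})^2$ from the thickness-to-span
  ratio of vessel pairs;
* grouping index $V_G$ = vessels per vessel grouping (1 when all solitary);
* area fractions (`P_LIG`, `P_FW_F_A`, ...) as ratios of measured sectional
  areas.

Centre statistics default to the mean; `centre = "median"` is available for
heavy-tailed measurement lists. Lists shorter than conventional minimum
counts trigger warnings, not errors. `aggregate_by_accession()` averages
per-stem records for accession-level tables.

## 4. The synthetic-data generator

The generator exists so that the entire pipeline — curve fitting, trait
derivation, ANOVA/post hoc, model selection and importance decomposition —
can be exercised and validated without laboratory data. Its defaults
describe the emulated study design and are deliberately not tuned to any
test.

### 4.1 Cavitron experiments (`simulate_spin_experiment`)

Each synthetic stem has a true `(P50, S)` from its `accession_profile`. The
pressure schedule starts at −0.5 MPa and descends in steps drawn uniformly
from 0.2–0.4 MPa until the true PLC reaches 95 % (all tunable via
`simulation_config()`). Conductance is generated as
`K = K_max (1 - PLC/100)` with multiplicative lognormal noise
(`noise_sd`, default 0.05 on the log scale) applied relative to a reference
measurement at −0.01 MPa, mirroring how `K_max` is measured first in a real
Cavitron run. With `noise_sd = 0`, fitting the simulated series returns the
generating parameters to machine-level accuracy (a tested contract).

In `simulate_study()`, each stem's generating `P50` is drawn from
`N(P50, P50_sd)` using the accession's reported between-stem standard
deviation, so fitted per-accession spreads resemble real within-accession
variation. Noise is batch-level only: no drift within a spin sequence, no
open-vessel artefacts, no cavitation fatigue.

### 4.2 Trait tables (`simulate_trait_table`)

Traits are generated with a Gaussian copula linked to stem `P50`:

1. the stem's (pooled, standardised) `P50` gives a latent normal score;
2. each trait's latent score correlates with it at an **inflated** latent
   correlation $r_\mathrm{lat} = r\,\sqrt{e^{\sigma^2}-1}/\sigma$ (with
   $\sigma$ the trait's lognormal `sdlog`), chosen analytically so the
   post-transform *Pearson* correlation hits the target $r$ in expectation;
3. latent scores are mapped through lognormal marginals with the
   configured trait means and coefficients of variation, so all traits are
   positive by construction.

Default link targets are the correlations the package is calibrated around
(`T_PM` −0.93, implosion −0.88, `T_V` −0.86, `V_G` −0.77, `P_LIG` −0.67,
`P_FW_F_A` −0.73; unlinked traits 0). Trait–trait correlations follow a
single-factor structure ($R_{ij} = r_i r_j$) unless overridden; requested
matrices are checked pair-by-pair for copula feasibility and repaired to
the nearest positive semi-definite matrix by eigenvalue clipping, with an
informative error when a pair is infeasible outright.

Trait means are shared across the default accession profiles: accession
differences in traits emerge entirely through the `P50` link, which is the
structure under study. A 500-replicate calibration test confirms the
realised mean Pearson correlation for `T_PM` lands within ±0.05 of −0.93.

Each synthetic stem also receives raw microscopy lists, constructed by
scaling template measurement lists so that `derive_traits()` reproduces the
copula-generated targets exactly for mean-type traits (`T_PM`, `T_V`,
`D_PC`, `D_H`, implosion, `P_LIG`) and approximately, through integer
counts, for `V_G` and `V_D`. With `measurement_cv = 0` the raw lists are
deterministic given the targets.

### 4.3 What is not emulated

No spatial structure within sections, no ontogenetic or positional trends
along the stem, no measurement operator effects, no missing data, and no
non-sigmoid (e.g. bimodal or r-shaped) vulnerability curves.

## 5. Statistics layer

* **`one_way_anova()`** computes between/within sums of squares directly
  (cross-checked against `anova(lm())`; the direct form keeps 5000-replicate
  null simulations fast). Its type-I error is verified to sit in
  [0.03, 0.07] at the 5 % level.
* **`newman_keuls()`** is a step-down studentized-range (SNK) procedure:
  group means are ordered, the widest span is tested first against
  `qtukey(1 - alpha, r, df_within)` with `r` the span size, and standard
  errors use the Tukey–Kramer form
  $\sqrt{\mathrm{MS_w}\,(1/n_i + 1/n_j)/2}$ for unbalanced groups. A
  non-significant span *blankets* all pairs inside it as homogeneous
  (pairs within it are not tested further), which is what makes SNK a
  coherent step-down procedure. Letter displays are built from maximal runs
  of mutually non-distinct means. With `k = 2` groups SNK coincides with
  Tukey's HSD; its familywise error there is verified at ≈ 0.05, and on
  balanced designs every Tukey-significant pair is also SNK-significant
  (tested over random instances).
* **`vif()`** uses the definitional auxiliary-regression form
  $1/(1 - R_j^2)$, returning `Inf` on exact collinearity
  ($1 - R_j^2 < 10^{-12}$).
* **`backward_aic()`** wraps `stats::step()` (backward direction), whose
  `extractAIC` convention $n\ln(\mathrm{RSS}/n) + 2k$ is the one used for
  the reported AIC values; the elimination trail is recovered from the
  step object.
* **`robust_irls()`** is M-estimation with the Tukey bisquare
  ($c = 4.685$), scale re-estimated each iteration as
  $1.4826 \times \mathrm{median}|r|$, initialised from an
  $\varepsilon$-regularised least-absolute-deviations fit; convergence
  tolerance $10^{-8}$, at most 200 iterations. When the scale collapses
  (exact-fit data) it returns the ordinary least-squares solution with unit
  weights. Standard errors are sandwich-form with normal-theory z and p
  values. This is an M-estimator, not a full MM-estimator: it does not have
  a high-breakdown S-estimation stage, so leverage outliers in the
  predictors are down-weighted less aggressively than `MASS::rlm(method =
  "MM")` would. Tests cross-check coefficients against `MASS::rlm` on
  response-outlier data.
* **`lmg_importance()`** decomposes the OLS model $R^2$ by exact
  enumeration of all $2^p$ predictor subsets (Lindeman–Merenda–Gold):
  the $R^2$ increment of each predictor is averaged first within subset
  size, then across sizes, which equals the average over all orderings.
  Enumeration is guarded at $p \le 12$. Shares are non-negative up to
  rounding and sum to the full-model $R^2$ exactly. Note the decomposition
  is of the OLS $R^2$; the robust coefficients reported alongside come from
  a different fit.
* **`run_inference_chain()`** runs, in order: VIF screen, backward AIC
  selection, robust refit of the selected model, LMG decomposition, and a
  raw Pearson correlation table of every candidate against the response.
  With `holm = TRUE` the correlation table additionally carries
  Holm-adjusted p values.

## 6. The pipeline

`run_study(run_config(...))` is the end-to-end path: simulate the study,
fit all curves, build per-accession mean curves, aggregate traits, test
accession differences in fitted `P50` (ANOVA + Newman–Keuls), and run the
inference chain for each requested response (`P50`, `P12`, `P88`). With an
`out_dir` it writes `fitted_curves.csv`, per-accession mean-curve CSVs,
`traits.csv`, one `report_<response>.json` per response and a `run.log`.
Reports round numeric values to 10 significant digits before serialisation
so that identical seeds produce byte-identical JSON — a tested contract.

## 7. Known limitations

* **Post-selection inference.** The robust p values reported for the final
  model are computed *after* backward-AIC selection and are therefore
  anti-conservative: under a pure-null response (permuted `P50`, 8
  candidates, n = 36) roughly half of replicates retain at least one
  nominally significant coefficient. The raw Pearson table holds its
  nominal per-trait size, and `holm = TRUE` controls the familywise rate
  for that table; treat the post-selection coefficient p values as
  descriptive.
* **Noise model.** Conductance noise is independent multiplicative
  lognormal per measurement; real Cavitron series can show serially
  correlated drift and occasional non-sigmoid shapes, which the simulator
  does not produce.
* **SNK and unbalanced designs.** The Tukey–Kramer SE makes the procedure
  well defined for unequal group sizes, but SNK's familywise-error control
  beyond `k = 2` is the usual approximate one; for strict FWER control use
  the pairwise results conservatively or a single-step procedure.
* **LMG scale.** Shares are computed on the OLS fit of the selected model;
  if the robust fit down-weights influential stems heavily, the OLS-based
  decomposition may weight predictors differently than the robust
  coefficients suggest.
* **Replicate counts in the validation suite** (e.g. 200–5000 simulation
  replicates, tolerance bands such as ±0.05 on calibrated correlations) are
  package testing choices balancing statistical power against runtime, not
  field-standard constants.

## 8. Tunable parameters at a glance

| Parameter (`simulation_config`) | Default | Units | Role |
|---|---|---|---|
| `pressure_start` | −0.5 | MPa | first spin pressure |
| `pressure_step_range` | c(0.2, 0.4) | MPa | uniform pressure-step range |
| `plc_stop` | 95 | % | stop once true PLC reaches this |
| `reference_pressure` | −0.01 | MPa | pressure of the `K_max` reference measurement |
| `noise_sd` | 0.05 | log scale | multiplicative conductance noise |
| `measurement_cv` | 0.1 | — | within-stem anatomical measurement spread |
| `vessel_diam_cv`, `fibre_area_cv` | 0.25, 0.3 | — | raw-list dispersion |
| `seed` | `NULL` | — | set for reproducibility |

`accession_profile()` defines the generating truth per accession (`P50`,
`S`, between-stem `P50_sd`, curve and stem counts — defaults 10 curves and
9 anatomy stems per accession); `default_profiles()` returns the four
built-in accessions. `run_config()` exposes the pipeline-level knobs
(`responses`, `candidates`, `alpha`, `seed`, `noise_sd`, `out_dir`).
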