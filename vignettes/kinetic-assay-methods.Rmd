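---
title: "Kinetic spectrophotometric quantitation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic spectrophotometric quantitation: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinspec)
```

## The assay and its model

kinspec models a kinetic spectrophotometric assay in which an analyte (here,
the antifungal amorolfine) is oxidised by permanganate in alkaline medium and
quantified through the absorbance of the coloured manganate product at
610 nm. Because the oxidant is in large excess, the analyte is consumed by
pseudo-nth-order kinetics,

$$\frac{dc}{dt} = -k' c^{\,n},$$

and the chromophore accumulates in proportion to the analyte consumed, so
the detector sees

$$A(t) = A_0 + \varepsilon\ell\, r\,\bigl(c_0 - c(t)\bigr) + e_t,
\qquad e_t \sim \mathcal{N}(0, \sigma^2),$$

with $A_0$ the blank (baseline) absorbance, $\varepsilon\ell$ the molar
absorptivity times path length, $r$ the product:analyte stoichiometric
ratio, and $\sigma$ the detector noise SD. For $n = 1$ the analyte profile is
the closed form $c(t) = c_0 e^{-k't}$; for $n \ne 1$ the generator integrates
the ODE with fixed-step RK4 (deSolve) on a mesh no coarser than 1 s,
clamping the concentration at zero because sub-unit orders reach extinction
in finite time. The problem is non-stiff, so a fixed-step explicit scheme is
both adequate and exactly reproducible.

### Default parameters and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `epsilon_l` | 1.364e4 | AU L mol⁻¹ | slope of the standards calibration line |
| `baseline` | 5.20e-3 | AU | intercept of the same line |
| `noise_sd` | 9.90e-3 | AU | SD of replicate reagent blanks |
| `k_prime` | 1.7e-3 | s⁻¹ | gives ≥ 95 % conversion at 1800 s, so the fixed-time response plateaus at 30 min |
| `order_n` | 1 | — | the assay's operating regime (estimated order ≈ 0.94) |
| `stoich_ratio` | 1 | — | the 1:1 molar ratio found by the limit-logarithmic method |

The noise model is additive, homoscedastic Gaussian on absorbance — the
simplest model consistent with a constant blank SD. Temperature enters the
scenarios only through the value of `k_prime`; no Arrhenius law is fitted
because no activation parameters are available, and the response-surface
stage models the temperature effect empirically instead.

A literature value of $k' = 4.70\ \mathrm{s^{-1}}$ exists for this reaction
but implies completion within seconds, irreconcilable with a 30-minute
fixed-time assay; the generator therefore does not adopt it as a default.
It is retained as the reference coefficient in the order/rate recovery
checks, where only the internal consistency of the power law matters.

## The three kinetic quantitation methods

* **Initial rate** — `estimate_initial_rate()` takes the slope of a local
  OLS line in a symmetric window (default half-width 50 s) centred at
  250 s. A windowed regression is a deterministic, noise-robust surrogate
  for a hand-drawn tangent; for the default kinetics the window bias against
  the analytic derivative $\varepsilon\ell\, c_0 k' e^{-k't}$ is below
  0.5 %.
* **Rate constant (constant rate)** — `estimate_log_slope_rate()` regresses
  $\log_{10} A$ on $t$ and multiplies the slope by 2.303 (the decadic
  convention; the factor fixes the logarithm base). It is applied to the
  absorbance as measured, i.e. the product signal, for which log-linearity
  is only approximate; points with $A \le 10^{-3}$ AU are excluded to keep
  logarithms finite.
* **Fixed time** — `fixed_time_absorbance()` reads $A$ at a preselected
  time (linear interpolation between grid points) and
  `fixed_time_calibration()` regresses it on concentration.

`select_fixed_time()` formalises the choice of "optimal" time: a candidate
must have a significant calibration (correlation
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ above the two-tailed critical value at 95 %
with $n-2$ df) and a slope at least 95 % of the maximum slope among
significant candidates; the earliest such time wins. On the published
candidate table this rule returns 30 min, and on noiseless synthetic runs
with the default kinetics it also returns 30 min (conversion is 95.3 % at
30 min and within 5 % of its plateau thereafter). Under realistic noise the
late candidates' slopes differ by less than the slope standard error, so the
selected time legitimately varies between 30 and 60 min from run to run.

Reaction order and rate come from `estimate_order_and_rate()`, the OLS fit
of $\log_{10} v$ on $\log_{10} c$: slope = order, $10^{\text{intercept}}$ =
$k'$. `rate_pairs_from_curves()` extracts exact $(c, v)$ pairs from
simulated traces by Beer–Lambert inversion and a central finite difference;
since every point of a trajectory lies on $v = k'c^n$, the generator values
are recovered to $10^{-6}$ relative from noiseless curves.

## Stoichiometry

The limit-logarithmic method regresses $\log_{10} A$ (at the fixed time, on
the optimised conditions) on $\log_{10}$ of each reactant concentration with
the other held constant; the ratio of the two slopes, snapped to a small
coprime integer pair, is the molar ratio. `molar_ratio()` minimises the
*log-scale* distance $|\log(\text{ratio}) - \log(p/q)|$ over coprime
$p, q \le 4$ (ties to smaller $p+q$). The log metric is chosen over the
absolute difference because it makes the operation exactly reciprocal —
swapping the two slopes swaps the pair — which an absolute-difference argmin
does not guarantee; both criteria agree on all realistic inputs, including
the empirical slopes 0.723 and 0.685 (→ 1:1). No snapping tolerance is
applied, but the residual is returned so callers can flag poor rational
approximations.

Because the curve generator is pseudo-first-order in the analyte only (no
oxidant dependence), the stoichiometry stage's inputs are generated by
`simulate_stoich_blocks()` as power-law signal blocks with the empirical
exponents as defaults — an emulation of the measured log–log behaviour, not
a mechanistic model.

## Design of experiments

`full_factorial()` builds the 2^k screening design in standard order;
`main_effects()` reports mean-difference effects (and coefficients =
effect/2 — bar-plot conventions differ between softwares, so both are
carried). `ccc_design()` augments a 2² factorial with axial points at
$\pm\sqrt{2}$ coded units and (default) 3 centre replicates. The assay's
published factor triples list only three levels per factor; treating them as
(−1, 0, +1) and circumscribing at $\pm\sqrt 2$ reproduces the reported model
optimum: the axial high temperature is $65 + 15\sqrt{2} \approx 86.2$ °C,
matching the reported 86 °C stationary point. Centre replicates affect only
noise averaging, not noiseless recovery.

`make_doe_scenario()` constructs the "true" quadratic surface the responses
are simulated from. It is pinned by two empirical facts: the unconstrained
stationary maximum (86 °C, 0.26 mol L⁻¹ NaOH) and the conditional maximum
over alkali at 50 °C (0.34 mol L⁻¹ — on the feasible boundary, since
working above 65 °C precipitates MnO₂). The interaction coefficient is the
unique solution of the conditional-argmax identity
$s^*(T) = s_0 - \tfrac{b_{12}}{2 b_{22}}(T - T_0)$; the curvatures default
to values giving realistic absorbance variation (~0.05–0.12 AU) across the
design region, and the constructor rejects geometries with no
negative-definite solution. `fit_quadratic()` + `stationary_point()` +
`constrained_optimum()` then recover both optima from noiseless responses —
the end-to-end identity the acceptance checks exercise. Both the analytic
stationary point and the box-constrained search are exposed because a
surface's reported "optimum" may be either.

## Validation statistics

All SDs use the $n-1$ denominator; this is the convention consistent with
the published SE = SD/√6 and CI = 2.571 × SE structure (the t quantile at
95 % with 5 df for 6 replicates — a printed footnote value of 4.3
corresponds to 2 df and does not reproduce the printed CI/SE ratios, so it
is not used). LOD and LOQ are 3.3σ/S and 10σ/S; the linear range runs from
the LOQ to the highest calibration standard. Recovery is 100 × found/added;
the bias test is the standard one-sample t. Published recovery cells that
are internally inconsistent with their own added/found values (e.g. a row
printing 103.9 % where found/added gives 107.3 %) are flagged by the tests
as inconsistent rather than forced. Reported values are rounded half-up at
the reporting layer only (`round_half_up()`); internal computation is never
rounded.

## What the generator does and does not emulate

The synthetic data reproduce the *statistical structure* the analysis
assumes: Beer–Lambert proportionality, pseudo-nth-order product formation,
homoscedastic Gaussian detector noise with the published blank SD, and a
quadratic response surface with the published optima. They do **not**
emulate real-matrix features — oxidant self-decomposition, MnO₂
precipitation above 65 °C, matrix interferences in tap water, drift, or
heteroscedastic noise at high absorbance. Passing tests therefore
demonstrate the correctness of the estimators and the internal consistency
of the published figures of merit, not the field performance of the assay.

A consequence worth stating explicitly: with 11 blanks the sample SD has a
relative sampling SD of about $1/\sqrt{2\cdot 10} \approx 22\,\%$, so a
*single* seeded run's LOD can differ from its expected value by more than
20 %. Distribution-level checks (means across seeds) are the meaningful
ones, and that is how the test suite asserts them.

## Problem sizes

The default study conditions are deliberately small and mirror the assay:
5 calibration standards (6.0×10⁻⁶–3.0×10⁻⁵ mol L⁻¹) with traces sampled
every 30 s over 0–61 min, candidate fixed times every 10 min, 11 reagent
blanks, a 5-standard tap-water calibration up to 3.22×10⁻⁵ mol L⁻¹, and
three spiked levels (8.0, 10.0, 30.0 ×10⁻⁶ mol L⁻¹) with 6 replicates.
Monte-Carlo style tests use 8–100 repetitions, sized so the whole suite runs
in well under a minute.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
res$fixed_time$selected_min
tidy(res$validation)
glance(res$validation)
autoplot(res$doe$rsm)
```

## Known limitations

* Only the three linearised quantitation methods are implemented; there is
  no global nonlinear fit of the integrated rate law.
* The constant-rate method inherits the approximation of log-linearising a
  product-formation signal.
* The DoE stage fits exactly the six-coefficient quadratic; no lack-of-fit
  or desirability analysis is offered.
* `bias_t()` with zero replicate spread and a (floating-point) nonzero bias
  returns `Inf` by contract; noiseless end-to-end runs hit this degenerate
  case.
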