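---
title: "Methods: water-use efficiency, aridity thresholds and nitrogen deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-use efficiency, aridity thresholds and nitrogen deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treewue)
```

## The scientific problem

Intrinsic water-use efficiency, `W = A/g_s` (net CO2 assimilation per unit
stomatal conductance, µmol mol⁻¹), summarises the carbon-for-water exchange
rate of a leaf. Tree-ring carbon isotopes record `W` annually over decades,
which makes them the main archive for asking how `W` responds to climate
aridity, rising atmospheric CO2 and nitrogen deposition. This package
implements that analysis chain end to end: isotope conversion, climate and
deposition covariates, breakpoint detection in the `W`–aridity relationship,
mixed-model variance partitioning, and a stomatal-optimization model that
predicts *why* the `W`–aridity relationship should have a threshold near an
aridity index of 1. A seeded synthetic-study generator reproduces the
statistical structure of a global tree-ring survey so that every stage is
testable without external downloads.

## Isotopes to W

Discrimination of plant tissue against ¹³C relative to the atmosphere is

    Δ = (δ¹³C_atm − δ¹³C_plant) / (1 + δ¹³C_plant/1000)   (permil)

The division by `(1 + δ_plant/1000)` is the standard exact form; the choice
is documented here because some older work uses the linear approximation.
A bundled smooth monotone spline through historical anchor values of
atmospheric δ¹³C (−6.4‰ in 1850 to −8.4‰ in 2015) is provided for
simulation and testing only (`delta13c_atm_default()`); real analyses
should supply a measured series.

Two discrimination models convert Δ to `c_i/c_a`:

* **simple**: `c_i/c_a = (Δ − a)/(b − a)` with `a = 4.4‰` (stomatal
  diffusion) and `b = 27‰` (carboxylation);
* **corrected**: adds mesophyll-conductance and photorespiration terms,
  `c_i/c_a = [Δ − a + (b − a_m)(A/c_a)/g_m + f·Γ*/c_a]/(b − a)` with
  `b = 30‰`, `a_m = 1.8‰`, `f = 12‰`, `g_m = 0.2 mol m⁻² s⁻¹`,
  `Γ* = 43 µmol mol⁻¹`.

Then `W = (c_a/1.6)(1 − c_i/c_a)`.

The corrected model contains the assimilation rate `A`, which the
formulation does not pin down. Two modes are offered: a configurable
constant (default `A = 10 µmol m⁻² s⁻¹`, a mid-range canopy value), and an
iterative mode that solves `A = k(c_i − Γ*)` jointly with `c_i/c_a` by
fixed-point iteration (tolerance 1e-8, at most 100 iterations). The constant
mode is the default because it is reproducible without a biochemical slope
estimate. `c_i/c_a` outside `[0, 1]` is physically impossible but can arise
from measurement error in Δ; such records are returned with a
`qc_flag = "cica_out_of_range"` rather than silently dropped, so downstream
filtering is explicit.

Which of the two `W` variants feeds the analysis is a configuration switch
(`pipeline_config(w_variant =)`); both columns are always computed. The
default is the simple variant, whose inverse
(`invert_w_to_delta()`) is exact and is what the synthetic generator uses —
round-tripping `W → Δ → W` is exact to better than 1e-9 relative across the
physical range, which the test suite asserts.

## Climate covariates

* **Aridity index** `AI = P/PET` (annual sums). Annual AI is the ratio of
  annual sums, *not* the mean of monthly ratios: the monthly ratio is
  unstable when monthly PET approaches zero in winter, and the two
  definitions genuinely differ on seasonal climates (a unit test constructs
  the counterexample). Calendar-year aggregation is used, with no
  hydrological-year or Southern-Hemisphere offset; the aggregation is
  isolated in `annualize()` if a different convention is needed.
* **VPD** by the August–Roche–Magnus form
  `es(T) = 0.61094·exp(17.625·T/(T + 243.04))` kPa,
  `VPD = es(T)(1 − RH/100)`. The method fixes the approach, not the
  constants; the constants above are the common modern fit and are frozen
  here so results are reproducible.
* **CO2-adjusted PET** (optional): rising CO2 closes stomata and lowers the
  true evaporative demand relative to a Penman–Monteith PET computed with a
  fixed surface resistance. The published correction is not restated in a
  closed form in the sources this package follows, so the bundled default is
  this package's own reading: a multiplicative Penman–Monteith factor in
  which the bulk surface resistance grows linearly with `(c_a − 300)` ppm
  (`pet_co2_adjust()`). It is exactly 1 at the 300 ppm reference and
  monotonically reduces PET as CO2 rises. The strategy is pluggable
  (`factor_fn`) so an alternative formulation can be substituted without
  touching the pipeline.

## Nitrogen-deposition zones and cumulative N

Sites are assigned to nominal deposition zones by geography: **high**
(central Europe 45–60 N, 15 W–45 E; eastern USA 23.5–50 N, 100–60 W),
**mid** (eastern Asia 0–45 N, 70–150 E), **low (south)** (Southern
Hemisphere), **low (north)** (remaining Northern Hemisphere: western North
America, the boreal zone). Box edges are inclusive below and exclusive
above, with west/south negative. The published zone prose does not close the
partition of the Northern Hemisphere (e.g. mid-latitude sites between 45 E
and 70 E); such sites are assigned to low (north) with a warning rather than
guessed into a box.

Because cumulative inputs, not single-year rates, drive ecosystem change,
the covariate is the trailing 20-year sum of annual deposition
(`cumulative_n()`). Windows not fully covered by the series are an error by
default — the generator therefore emits deposition from 1945 so the 1965
start of the analysis window is fully covered — with an opt-in scaling mode
for exploratory use. The conversion helper `ndep_rate_kg_ha_yr()` makes the
unit identity explicit: 17 g N m⁻² per 20 yr ≡ 8.5 kg N ha⁻¹ yr⁻¹.

## Breakpoint (segmented) regression

`fit_segmented()` fits the continuous broken line
`y = b0 + b1·x + b2·(x − ψ)₊` by profiling the breakpoint ψ: a coarse grid
over the central 80% of the x range (step 0.01 AI units) followed by
golden-section refinement of the SSE profile. This is this package's own
estimator — deliberately simple, exhaustive and deterministic. Numerical
choices:

* the grid is restricted to the central 80% so segments always retain
  support on both sides;
* the breakpoint confidence interval is a case-resampling bootstrap
  (default 500 replicates, percentile interval, seeded, coarser grid inside
  the bootstrap);
* per-segment slopes are `b1` and `b1 + b2` with t-tests from the
  conditional linear fit at the estimated ψ — a reporting convention of this
  package, since two-segment inference after breakpoint estimation has no
  single standard;
* if a single line fits essentially as well as any broken line (relative
  SSE improvement below 1e-6, or an exactly-fit line), the result is flagged
  non-identifiable instead of reporting an arbitrary ψ.

Quartiles in the AI-class summary (`bin_summary()`) use linear-interpolation
(type 7) quantiles; the choice is stated because quartile values depend on
it. Bins are lower-inclusive with the final edge included, and observations
with AI > 5 are excluded (strict inequality) before any fit, mirroring the
survey convention.

## Mixed models, AICc search and importance

`fit_lmm()` fits `W ~ polynomial fixed effects + (1 | tree)` via `lme4`.
The random structure is a tree-level intercept only (site was considered and
rejected in the source analysis; tree-to-tree differences dominate).
Coefficient p-values use the normal approximation to the Wald statistic.
Covariates enter on natural scales — no centring or standardisation — so
coefficients are in response units; collinearity of polynomial terms is
detected by a QR rank check that names the offending columns rather than
silently aliasing them.

* **AICc**: `AICc = −2logL + 2k + 2k(k+1)/(n − k − 1)` with `k` = fixed
  coefficients (incl. intercept) + 2 variance components. The composition of
  `k` is a package convention (the source does not state one); it matches
  the degrees of freedom `lme4` attributes to the likelihood.
* **Search**: exhaustive enumeration over candidate variables with *nested*
  polynomial sets (a variable enters with powers 1..d, d ≤ 3) — no stepwise
  shortcuts. All fits use ML so likelihoods are comparable. Ties in AICc are
  broken toward the model with fewest covariates. The ranking object keeps
  the ten best models.
* **R²**: marginal = var(fixed)/(var(fixed) + var(tree) + var(resid));
  conditional adds var(tree) to the numerator.
* **Relative importance**: sequential ANOVA on the fitted model with terms
  entering in the canonical order CO2 → climate variable(s) → nitrogen,
  polynomial terms pooled under their parent variable, normalised to
  proportions of the fixed-effect variance. Sequential shares are
  order-dependent for correlated covariates, so
  `relative_importance(fit, diagnostics = TRUE)` also reports the
  reverse-order decomposition as a diagnostic. For orthogonal standardized
  predictors the shares reduce to β²-proportions (the 0.8/0.2 split for
  β = (2, 1) is asserted in tests).

Estimation (`ML`/`REML`) is a per-model switch; ML is the default because
the search compares fixed structures. Lagged covariates are not implemented —
the source analysis found they did not improve fits — and would be added as
extra columns by the caller if wanted.

## The stomatal-optimization model

Carbon is invested in hydraulic conductance `K`; water acquired through `K`
is spent through stomata to buy CO2. At the profit-maximising stomatal
behaviour the marginal revenue of transpiration equals its marginal cost:

    dA/dE = W² / (1.6·D·(c_a − Γ))
    dC/dE = 1 / ((ψ_soil − ψ_leaf)·dK/dC) + f⁺(−ψ_leaf)/K
    W*    = sqrt(1.6·D·(c_a − Γ)) · sqrt(dC/dE)

`f⁺` is a generic non-negative, non-decreasing cost of low leaf water
potential (embolism risk and repair); it is deliberately left generic in the
theory, so the package default is linear with a configurable coefficient,
with a power form available (`fplus_spec()`). Effects of ψ_leaf on `K`
itself are neglected, as in the source derivation. The model is exercised in
illustrative units; no calibration of `K` or `dK/dC` to field values is
attempted, and the W(ψ_soil) curves from the two hydric strategies are
meaningful up to scale (tests use ratios and signs only).

Two strategy endpoints map soil to leaf water potential: **isohydric**
(ψ_leaf fixed; the gradient widens as soil wets) and **isohydrodynamic**
(gradient fixed; f⁺ falls as soil wets). Both make W non-increasing in
ψ_soil.

The hydrological closure: annually `P ≈ T + r + d`, and at the precipitation
that just saturates the soil `T ≈ PET`, giving the threshold
`AI* = 1 + (r + d)/PET` (`ai_threshold()`), ≈ 1 when runoff and drainage are
small against PET. `predict_w_ai_curve()` combines the two parts through a
minimal monotone map `ψ_soil(AI) = ψ_min·max(0, 1 − AI/AI*)` — the theory
fixes the saturation point, not the pre-threshold shape, so the simplest
shape is used and the map is replaceable. The predicted curve declines
strictly below AI*, is constant above, and is continuous at AI* (a kink,
not a jump).

## The synthetic study generator

`gen_wue_dataset()` emulates the survey structure the analysis assumes:
349 sites (about 411 trees; roughly 11,000 tree-year observations inside
1965–2015 once series lengths vary by tree), site coordinates drawn inside
the deposition-zone boxes, aridity indices spread over 0–5 with
zone-specific gamma distributions (high-N sites mostly moist, low-N-north
widest), CO2 rising smoothly through 320 ppm (1965) and 395 ppm (2015),
and zone-specific deposition histories (high: logistic rise from 1950
slowing around 2000; mid: strong rise from ~1980; low: slow rise). The
deposition trajectories are scaled internally so zone-mean cumulative
20-year deposition over the analysis window equals the survey-level values
(high 17, mid 8, low-north 5, low-south 3 g N m⁻²) — an analytic
calibration, not a fitted one.

True W is generated *structurally* — piecewise-linear in AI with the kink
at 1 (slope −22 µmol mol⁻¹ per AI unit below, flat at 55 µmol mol⁻¹
above, at reference CO2), plus a CO2 effect (0.15 µmol mol⁻¹ per ppm), a
zone-specific cumulative-N effect, a gymnosperm/angiosperm offset
(±3 µmol mol⁻¹), a tree random intercept and residual noise — rather than
from the optimization module, so threshold-recovery tests are not circular.
δ¹³C series are then emitted by exact inversion of the simple
discrimination model. Unprinted variances were chosen once:
σ²_tree = 81 and σ²_resid = 36 with a fixed-effect variance around 40–50,
which reproduces the qualitative marginal ≈ 0.15–0.3 / conditional
≈ 0.6–0.8 R² pattern of the source tables with tree variance dominating.
The zone-specific N coefficients (0.05 high, 0.25 mid/low-north, 1.2
low-south) encode the published gradient in which cumulative N matters
least where deposition history is uniform (high zone) and most in the
Southern Hemisphere.

What the generator does **not** emulate: spatial autocorrelation of climate
fields, species-level ecology beyond the group mean offset, observation
gaps/missingness, and measurement error in δ¹³C beyond the residual noise.
Passing recovery tests therefore show the pipeline is correct and well
calibrated under the assumed generating structure — not that real tree-ring
data satisfy that structure.

## Problem sizes and runtime choices

The packaged tests run the full default-size generator (349 sites) once and
reuse it across assertions; Monte-Carlo calibrations use 200 replicates of
n = 3000 for breakpoint recovery (estimate within ±0.1 of the true
breakpoint in ≥ 95% of replicates) and 100 replicates of 100 trees × 30
years for mixed-model recovery (all generating parameters within 2
Monte-Carlo standard errors). The end-to-end smoke profile uses 30 sites,
chosen so a complete pipeline run (including a 100-replicate bootstrap and
a 63-model search) remains interactive. Reruns with the same seed produce
byte-identical reports; no output contains timestamps.

## Known limitations

* The breakpoint CI is a percentile bootstrap; no smoothed/BCa refinement.
* The negative-exponential alternative to the broken line is acknowledged
  but not implemented.
* The CO2–PET adjustment is one reading of the published correction, clearly
  marked and replaceable.
* Zone assignment mirrors nominal boxes; it is not a deposition
  classification, and the uncovered Northern-Hemisphere gap is surfaced as a
  warning by design.
* Reproducing the published survey's numerical tables requires the external
  tree-ring, climate and deposition downloads, which are outside this
  package's scope; the package reproduces the *methods* and their
  self-contained quantitative properties.
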