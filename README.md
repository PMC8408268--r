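# treewue

Analysis of intrinsic water-use efficiency (`W = A/g_s`, µmol CO2 per mol
H2O) derived from tree-ring carbon isotopes, in relation to climate aridity,
atmospheric CO2 and nitrogen deposition. The package is aimed at
ecophysiologists and global-change ecologists working with annual tree-ring
δ¹³C chronologies joined to site-level climate and deposition series.

It implements, as tested R functions:

* **Isotopes → W**: Δ = (δ_atm − δ_plant)/(1 + δ_plant/1000), then
  `c_i/c_a = (Δ − a)/(b − a)` (a = 4.4‰, b = 27‰) or the
  mesophyll/photorespiration-corrected form
  `c_i/c_a = [Δ − a + (b − a_m)(A/c_a)/g_m + f·Γ*/c_a]/(b − a)`,
  and `W = (c_a/1.6)(1 − c_i/c_a)`; plus the exact inverse used for
  simulation.
* **Climate covariates**: aridity index `AI = P/PET` from annual sums,
  August–Roche–Magnus VPD, optional CO2 adjustment of Penman–Monteith PET.
* **Nitrogen**: nominal deposition-zone assignment from coordinates and
  trailing 20-year cumulative deposition.
* **Threshold detection**: segmented regression of W on AI (profiled
  breakpoint + golden-section refinement, bootstrap CI), AI-class summary
  tables, tree/site-level views, AI > 5 exclusion.
* **Mixed models**: `W ~ polynomial(c_a, AI | P+PET | VPD, N) + (1 | tree)`
  via lme4, exhaustive AICc model search with a fewest-covariates tie-break,
  marginal/conditional R², and sequential-ANOVA relative importance.
* **Stomatal optimization**: the marginal revenue/cost model whose optimum
  `W* = sqrt(1.6·D·(c_a − Γ))·sqrt(dC/dE)` predicts that W declines with AI
  only up to the water-balance threshold `AI* = 1 + (r + d)/PET ≈ 1`.
* **Synthetic study generator**: a seeded, fully deterministic emulation of
  a global tree-ring survey (349 sites, ≈411 trees, 1965–2015) with the
  threshold structure planted, so the entire pipeline is testable offline.

See the methods vignette (`vignettes/wue-aridity-threshold.Rmd`) for the
models, assumptions, numerical choices and limitations.

## Worked example

```r
library(treewue)

# one ring: delta13C -> discrimination -> ci/ca -> W
D <- big_delta(-26, -8)         # 18.4805 permil
cc <- cica_simple(D)            # 0.623
wue_from_cica(400, cc)          # 94.24 umol mol-1

# water-balance threshold with modest runoff + drainage
ai_threshold(hydro_params(pet_PET = 1000, runoff_r = 50, drainage_d = 30))
# 1.08

# a complete synthetic study through the full pipeline
rep <- run_pipeline(pipeline_config(profile = "small", seed = 1, n_boot = 100))
print(rep)
```

The pipeline prints its stage log (abridged):

```
stage simulate: 961 observations over 30 sites
stage segmented: breakpoint 1.3658 on 961 rows
stage bins: counts [222, 141, 341, 128, 129] sum 961
stage models: 63 candidates; best [ca + ai + ai^2 + ndep_cum] AICc 6304.25 R2m 0.168 R2c 0.742
stage importance: [ca=0.951, ai=0.029, ndep_cum=0.020]
```

meaning: on this 30-site simulation the W–AI breakpoint is estimated at
AI ≈ 1.37 (the small profile is noisy; at the default 349-site size the
estimate falls within ±0.1 of the planted breakpoint at 1), the best AICc
model keeps CO2, aridity and cumulative N terms, fixed effects explain 17%
of variance and fixed-plus-tree effects 74%, and CO2 carries most of the
fixed-effect variance. `rep$bins` holds the AI-class summary (n, median,
mean, min, max, quartiles per bin) and `rep$segmented` the full breakpoint
report with its bootstrap confidence interval.

A thin command-line front end over the same functions ships in
`inst/cli/treewue.R` (subcommands `simulate`, `run`, `threshold`, `optim`).

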