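# strataMR

Collider-safe stratified Mendelian randomization.

## What problem this solves

Mendelian randomization (MR) estimates the causal effect of an exposure *X*
on an outcome *Y* using a genetic instrument *G* (a variant or weighted
genetic risk score). With a single instrument the estimator is the ratio
(Wald) estimate

&nbsp;&nbsp;&nbsp;&nbsp;θ̂ = β̂<sub>YG</sub> / β̂<sub>XG</sub>,

the instrument–outcome association over the instrument–exposure association.

Epidemiologists frequently want these estimates *within strata* of a third
variable *C* — say, the effect of smoking on bladder cancer across
bodyweight groups. If *C* is influenced by the exposure it is a **collider**:
stratifying on it opens a path between the instrument and the confounders,
and the stratum estimates become biased and spuriously heterogeneous even
when the true effect is the same everywhere.

`strataMR` implements the remedy: stratify on the **residual collider**
C₀ = C − Ĉ, the residual from regressing *C* on *G*. C₀ is independent of
the instrument by construction, so quantile strata of C₀ are safe, while
remaining close to strata of *C* whenever the instrument explains little of
*C*. The package provides:

* the estimator suite — `linear_assoc()` / `logistic_assoc()`,
  `ratio_estimate()`, `residualize()`, `assign_strata()`,
  `stratified_mr()`, `cochran_q()` (homogeneity),
  `trend_meta_regression()` (gradient across strata),
  `first_stage_diagnostics()` (instrument strength R², F);
* the complete simulation framework — nine scenario presets
  (`build_scenario()`: null / constant / effect-modified causal effects ×
  exposure-driven collider, outcome-driven collider, binary outcome),
  `simulate_cohort()`, the Monte-Carlo engine `run_replications()` /
  `run_grid()` and table renderers (`summarize_to_table()`), with fully
  reproducible content-keyed seeding;
* an applied-analysis layer — `read_cohort_table()`, `compute_grs()`,
  `analyze_cohort()` (odds-ratio reporting for binary outcomes),
  `make_applied_fixture()` (a fully synthetic biobank-shaped dataset), and a
  thin command-line interface (`strata-mr simulate|analyze|grid|grs|fixture`
  via the shim in `inst/cli/`, or `cli_main()` from R).

See the vignette `vignettes/residual-collider-stratification.Rmd` for the
model, assumptions, defaults and design choices.

## Worked example

Simulate cohorts in which the collider loads negatively on exposure and
confounder (µ₁ = µ₂ = −1), with a constant true causal effect of **0.5**,
and compare direct versus residual-collider stratification over 200
replicates:

```r
library(strataMR)
params <- build_scenario("A2", list(mu1 = -1, mu2 = -1))  # true effect 0.5
direct <- run_replications(params, analysis_plan("stratify_collider"),
                           m = 200, base_seed = 42)
resid  <- run_replications(params, analysis_plan("stratify_residual"),
                           m = 200, base_seed = 42)
print(direct)
print(resid)
```

```
replication summary: mode = stratify_collider, m = 200 (0 failed)
  median stratum estimates: 0.085, 0.030, 0.011, 0.146
  heterogeneity rejected in 5.0% of replicates (alpha = 0.05)
  mean first stage: R^2 = 0.005988, F = 60.3
replication summary: mode = stratify_residual, m = 200 (0 failed)
  median stratum estimates: 0.468, 0.524, 0.510, 0.524
  heterogeneity rejected in 4.0% of replicates (alpha = 0.05)
  mean first stage: R^2 = 0.005988, F = 60.3
```

Stratifying directly on the collider drags every quartile's median estimate
far from the true 0.5 (down to ~0.01–0.15) — yet Cochran's Q rejects at
roughly the nominal 5% rate, so the bias would go unnoticed. Stratifying on
the residual collider recovers ~0.5 in all four quartiles. The first-stage
diagnostics (R² ≈ 0.006, F ≈ 60) describe a realistically weak instrument.

The same analysis on user data, from the shell:

```sh
Rscript inst/cli/strata-mr analyze --data cohort.csv \
    --instrument grs --exposure smoker --outcome cancer \
    --stratifier bodyweight --covariates age,sex \
    --outcome-type binary --exposure-type binary \
    --method residual --k 4 --or-scale --out strata.csv
```

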