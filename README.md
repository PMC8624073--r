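# ghrelkit

Test–retest reliability analysis for repeated biomarker panels, built
around fasting gastrointestinal hormones (ghrelin, leptin, GLP-1,
pancreatic polypeptide) measured at baseline and follow-up.

Longitudinal and interventional studies of appetite and weight control
can only use a hormone as a biomarker if repeated measurements of the
same person are stable. ghrelkit is for biostatisticians and study teams
who need to quantify that stability in small cohorts: it estimates
per-hormone reliability, asks how much of it survives adjustment for
metabolic and lifestyle covariates, and tests for systematic shifts
between assessments — all reproducibly, from one seed.

## What it computes

* **ICC(A,1)** — the single-measurement, absolute-agreement intra-class
  correlation from the two-way mean squares,

  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))`,

  with F-based confidence limits (Satterthwaite denominator df), an F
  test of ICC = 0, and the conventional reliability bands
  (< 0.5 poor, 0.5–0.75 moderate, 0.75–0.90 good, > 0.90 excellent).
* **Adjusted ICC** — `σ²_between / (σ²_between + σ²_residual)` from a
  REML random-intercept model (`lme4`) with glucose, HbA1c, physical
  activity and dietary habits as fixed effects; CI by seeded parametric
  bootstrap.
* **Paired permutation tests** — Monte Carlo sign-flip test of the
  baseline-vs-follow-up mean difference (add-one p-value), with an exact
  2^n enumeration oracle for n ≤ 22.
* **Assay censoring rules** — below-detection samples → 0 pg/mL, values
  above the highest standard censored to it (PP: 2276.02 pg/mL),
  dilution correction (ghrelin 1:10, leptin 1:50, GLP-1 1:6, PP 1:2).
* **Lifestyle indices** — a 37-item food-frequency diet score (maximum
  127 points = maximally healthy) and physical-activity hour/MET-energy
  indices.
* **Synthetic cohorts** — a seeded generator with log-normal hormone
  marginals, controllable true ICC per hormone (presets 0.99 / 0.51 /
  0.79 / 0.89), covariate effects on the log scale, and optional
  between-assessment weight drift.

## Worked example

```r
library(ghrelkit)

cohort <- simulate_cohort(simulation_config(n_participants = 17, seed = 42))
report <- run_pipeline(cohort, analysis_config(
  permutation_iterations = 10000, bootstrap_reps = 500,
  log_transform = TRUE, seed = 42))
print(report)
```

```
Reliability report: 17 participants, 4 hormone(s)
 hormone n_pairs                  icc icc_category    perm_p
 ghrelin      17 0.991 [0.976, 0.997]    excellent 0.4122588
  leptin      17 0.580 [0.139, 0.826]     moderate 0.6357364
    GLP1      17 0.822 [0.581, 0.931]         good 0.4868513
      PP      17 0.909 [0.769, 0.966]    excellent 0.5585441
                  adj adj_category
 0.991 [0.971, 0.998]    excellent
 0.679 [0.348, 0.884]     moderate
 0.782 [0.412, 0.923]         good
 0.889 [0.701, 0.960]         good
Covariate permutation tests (FU - BL):
 covariate    perm_p observed_diff
   glucose 0.1505849    0.30687690
     hba1c 0.2097790    0.07678122
  activity 0.1159884   -5.89742727
      diet 0.3575642    3.23529412
```

Reading it: this simulated 17-participant cohort was generated at the
true-ICC presets, and the analysis recovers their character — ghrelin
near-perfectly stable (0.991, "excellent"), leptin only moderately so
(0.580, with a wide interval at n = 17), GLP-1 and PP in between. The
`adj` column conditions each hormone on the four covariates; with zero
simulated covariate effects it stays close to the unadjusted ICC. No
covariate shifts significantly between assessments (all permutation
p > 0.05). `report_to_forest_csv(report, "forest.csv")` exports
`label,estimate,ci_low,ci_high,panel` rows ready for a forest plot, and
`report_to_tsv()` writes the per-hormone table.

A thin command-line wrapper ships in `inst/exec/ghrelkit.R`
(`simulate`, `analyze`, `report`, `permtest`, `icc` subcommands over the
same functions).

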