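---
title: "Methods: test-retest reliability of gastrointestinal hormone panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of gastrointestinal hormone panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghrelkit)
```

## The problem

Gastrointestinal hormones — ghrelin, leptin, GLP-1 and pancreatic
polypeptide (PP) — are candidate biomarkers for studies of appetite and
weight control, but a biomarker is only useful longitudinally if repeated
measurements of the same person are stable. ghrelkit quantifies that
stability for a cohort measured at baseline (BL) and follow-up (FU): it
estimates the absolute-agreement intra-class correlation ICC(A,1) per
hormone, re-estimates it after conditioning on metabolic and lifestyle
covariates (glucose, HbA1c, physical activity, dietary habits), and tests
for systematic BL-vs-FU shifts with a paired permutation test. Because
participant-level hormone panels of this kind are rarely published, the
package pairs the analysis with a seeded synthetic cohort generator whose
reliability structure is controllable, so every stage is testable end to
end.

## ICC(A,1)

For an $n \times k$ participant-by-assessment matrix (here $k = 2$), the
two-way decomposition gives mean squares for participants (MSR),
assessments (MSC) and residual error (MSE). The single-measurement,
absolute-agreement ICC is

$$\widehat{ICC}(A,1) =
  \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)},$$

which, unlike the consistency form, charges systematic BL-vs-FU shifts
against reliability. Confidence limits use the standard F-based procedure
with a Satterthwaite approximation for the denominator degrees of freedom;
the p-value tests ICC $= 0$ via $F = MSR/MSE$ on $(n-1,\,(n-1)(k-1))$
degrees of freedom. `icc_a1()` agrees with an independent sums-of-squares
oracle to $10^{-10}$ and reproduces the estimate, p-value and interval of
an independent reference implementation (pingouin's `intraclass_corr`) on
a fixed matrix; both checks are in the test suite.

Estimates are interpreted with the conventional bands: below 0.5 poor,
0.5-0.75 moderate, 0.75-0.90 good, above 0.90 excellent. The printed
ranges overlap at their joints, so `classify_reliability()` fixes a
convention: intervals are left-closed (0.5 opens moderate, 0.75 opens
good) and 0.90 itself is good — only estimates strictly above 0.90 are
excellent, matching the strict inequality in the quoted "excellent" rule.
Negative estimates are reported as computed (not truncated at zero), so
simulation studies see the estimator's true sampling distribution, but are
classified as poor.

Degenerate inputs are flagged rather than forced into a number: a matrix
with zero total variance returns a result with `degenerate = TRUE` and no
estimate; identical columns with distinct rows (perfect absolute
agreement) return exactly 1 with a point interval.

## Adjusted ICC from mixed-model variance components

To ask how much of a hormone's stability survives conditioning on
lifestyle and glycemic state, `fit_random_intercept_lmm()` fits, by REML,

$$y_{it} = \beta_0 + x_{it}^\top\beta + b_i + e_{it}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad e_{it} \sim N(0, \sigma_e^2),$$

with the covariates as fixed effects and a participant random intercept.
The fit is delegated to `lme4::lmer` — a deliberate choice of an
established, heavily validated REML optimizer over a bespoke one; the test
suite still verifies the estimand independently, checking the closed-form
balanced one-way solution and that the returned components beat a
$50 \times 50$ brute-force grid on the restricted likelihood. The adjusted
ICC is then the variance ratio

$$\widehat{ICC}_{adj} = \frac{\hat\sigma_b^2}{\hat\sigma_b^2 + \hat\sigma_e^2},$$

i.e. reliability conditional on the covariates. No analytic interval is
available for this ratio at $n = 17$, so `adjusted_icc()` uses a seeded
parametric bootstrap: simulate response vectors from the fitted model,
refit, and take the percentile interval of the bootstrap ratios
(default 500 replicates; non-converged refits are dropped and counted).
Missing covariate cells fail loudly — the analysis is complete-case by
design, with no imputation. Non-convergence is flagged on the result,
never silent.

When every covariate effect is truly zero, the adjusted ICC and ICC(A,1)
estimate the same quantity; the acceptance suite verifies a mean absolute
difference below 0.05 over 100 simulated cohorts of $n = 100$.

## Paired permutation test

Systematic BL-vs-FU differences are tested without distributional
assumptions. Under the null, a participant's two values are exchangeable,
so the null distribution of $T = \overline{FU} - \overline{BL}$ is
generated by swapping each participant's pair independently with
probability 1/2 — equivalently, sign-flipping the paired differences.
`paired_permutation_test()` draws `iterations` such assignments (default
100,000) and reports the two-sided Monte Carlo p-value with the add-one
convention $p = (1 + b)/(1 + m)$, where $b$ counts null statistics with
$|T_{perm}| \ge |T_{obs}|$. The add-one form guarantees $p > 0$ and a
valid level-$\alpha$ test for any $m$; ties are counted as extreme
(comparison by $\ge$, with a $10^{-12}$-scale guard so the identity
assignment always ties the observed statistic despite floating-point
summation).

`exact_sign_flip_test()` enumerates all $2^n$ assignments (up to
$n = 22$) and is the package's own oracle: within-pair label permutation
and sign-flipping are the same group action, so the Monte Carlo test must
converge to the exact p-value, and does — at $10^6$ iterations the two
agree within three binomial standard errors on random 8-pair data sets.
On 2000 simulated exchangeable cohorts of $n = 17$ the empirical
rejection rate at the two-sided 0.05 level stays at or below
$0.05 + 3\sqrt{0.05 \cdot 0.95/2000}$.

## Assay censoring and lifestyle indices

`apply_assay_limits()` reproduces the ELISA reporting rules as data
transformations: below-detection samples (the "BDL" sentinel or `NA`)
become 0 pg/mL, samples above the assay's highest standard are censored
to it — for PP, 2276.02 pg/mL — and dilution correction
(`apply_dilution()`; ghrelin 1:10, leptin 1:50, GLP-1 1:6, PP 1:2)
precedes censoring, because the ceiling applies to the final reported
concentration. Censoring is idempotent and range-bounded; no
standard-curve (4PL) math is modeled, only the reporting endpoints. "BDL"
is an explicit sentinel rather than a magic number because 0 is also a
legal *output* of the rule. Kit detection limits are configuration
inputs, defaulting to 0, since they are not package-known constants.

The dietary habits index sums per-item points over a 37-item
food-frequency list with six consumption categories ("almost daily" ...
"never"); a maximally healthy profile scores exactly 127 points. The
original instrument's per-item weights are not public, so the packaged
`diet_scheme.json` is an explicit modeling choice: 16 items with a 4-point
maximum and 21 with a 3-point maximum (summing to 127), each directed
`healthy_frequent` (fruits, vegetables, whole grains, fish, unsaturated
fats, ...) or `healthy_rare` (fatty and cured products, sweets, soft
drinks, butter, salt habits, ...), with monotone per-category maps and
minima of 0. Any user scheme is accepted if it passes the same self-checks
(37 items, six categories each, non-negative points, maxima summing
to 127).

The physical-activity index is the plain sum of weekly hours over all
recorded activities. For activity energy, two conventions are exposed
because the source formulations conflict: `met_energy(mode = "standard")`
computes $\sum \text{MET} \times h \times \text{kg}$ in kcal/week (1 MET
$\approx$ 1 kcal kg$^{-1}$ h$^{-1}$), while `mode = "weight_squared"`
(the default) follows the alternative stated rule
$\sum \text{MET} \times h / \text{kg}^2$ verbatim. The pipeline does not
guess which was intended; callers choose, and both can be reported.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure of a small longitudinal
reliability study: by default 17 participants at two assessments,
four hormones, and the covariate panel. Choices, and their reasons:

* **Log-normal hormone marginals.** Published summaries show strongly
  right-skewed concentrations described only by medians and interquartile
  ranges, so marginals are log-normal with `log_median = log(median)` and
  the log-scale SD recovered from the quartile ratio by the method of
  quantiles ($\hat\sigma = \log(q_3/q_1) / (2\,z_{0.75})$). The
  distributional family is an assumption, not an inference. One preset's
  printed baseline quartiles are internally inconsistent with the printed
  median (the GLP-1 row); the preset keeps the median for location and
  uses the quartile *ratio* for spread, which is all the ratio is needed
  for.
* **Reliability structure on the log scale.** Per hormone,
  $\sigma_b^2 = \text{ICC} \cdot \sigma_{tot}^2$ and
  $\sigma_e^2 = (1-\text{ICC}) \cdot \sigma_{tot}^2$; true ICC presets are
  0.99 (ghrelin), 0.51 (leptin), 0.79 (GLP-1), 0.89 (PP). `true_icc = 1`
  is rejected (zero residual variance is degenerate). Because the truth is
  defined on the log scale, recovery analyses log-transform before
  estimating; the analysis pipeline itself defaults to raw pg/mL (the
  scale such panels are analyzed on) with `log_transform` as an explicit
  switch.
* **Covariates** enter additively on the log-hormone scale, centered at
  their baseline means, with all effect sizes defaulting to 0 so the
  default cohort has pure reliability structure. Glucose and HbA1c are
  normal with assessment-specific moments; activity is log-normal; the
  diet index is integer-valued and clamped to $[0, 127]$; weight is drawn
  once per participant, with follow-up weight equal to baseline plus a
  $N(0, \texttt{weight\_drift\_sd}^2)$ drift. With a weight-to-hormone
  effect configured, positive drift adds within-participant variance and
  demonstrably lowers the estimated ICC — the mechanism proposed for
  degraded leptin reliability under small weight fluctuations.
* **Censoring pathway, not truncation.** Raw values are generated first
  and then passed through `apply_assay_limits()`, so simulated data reach
  the analysis through the same censoring code as real data.
* **Seeding.** One master seed; each hormone, the covariate block, the
  permutation stream and the bootstrap derive independent substreams from
  a deterministic hash of their name, so adding a hormone leaves the
  others' values bit-identical.

What the generator does **not** emulate: within-person covariate
correlation across assessments (except weight), hormone-hormone
correlation within participant, assay batch effects, diurnal or
fasting-state effects, and any non-log-normal tail behavior. Passing
tests therefore certify the statistical machinery under the stated
generative model, not the biology of any particular cohort.

## Numerical choices and problem sizes

Tie comparisons in both permutation tests use $\ge$ with an absolute
guard of $10^{-12}(1 + \max|d|)$. The exact enumerator builds all $2^n$
signed sums by doubling, capped at $n = 22$ (about 4M sums). ICC
degenerate-input detection uses a $10^{-12}$-scaled total-variance
threshold. Bootstrap refits that fail are dropped, never imputed. The
pipeline's log transform maps censored zeros to half the smallest
positive value before taking logs, and reports are serialized
deterministically so identical config and seed give byte-identical JSON.

The shipped checks use problem sizes chosen to give tight Monte Carlo
error at interactive runtimes: 2000 null cohorts for the type-I-error
study, $10^6$ iterations against the exact oracle, $n = 500$ cohorts for
preset recovery, 500 replicates for CI coverage at true ICC 0.8 and
$n = 17$, and 100 cohorts of $n = 100$ for the adjusted-ICC null
equivalence.

## Limitations

ICC(A,1) machinery only; the (C,1) and average-measure forms are out of
scope, as are Bayesian variance components. The adjusted-ICC interval is
a parametric bootstrap, with all the model-trust that implies at
$n = 17$. The diet scheme's per-item weights are a package default, not
the original instrument's. At $n = 17$ the ICC interval is wide by
nature; the package reports that honestly rather than narrowing it.
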