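---
title: "Two-point DCP half-life analysis after radiofrequency ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-point DCP half-life analysis after radiofrequency ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcpkinetics)
```

## The clinical question and the statistic

Radiofrequency ablation (RFA) destroys small hepatocellular carcinomas
thermally, but the standard of truth for treatment success — absence of
contrast enhancement on CT/MRI — is only read one month later. Serum
des-γ-carboxy prothrombin (DCP, also called PIVKA-II) is secreted by the
tumor and cleared quickly from blood (a half-life of a few days at most), so
the *rate* at which it falls right after ablation carries information about
residual tumor well before imaging does.

`dcpkinetics` estimates that rate from just two measurements: the baseline
concentration $C_0$ (drawn before ablation) and the first-day concentration
$C_1$ (drawn $\Delta t$ hours after the ablation ends). Under first-order
clearance,

$$N(t) = N_0 \left(\tfrac{1}{2}\right)^{t/t_{1/2}},$$

inverting the decay law gives the two-point estimate

$$\widehat{t}_{1/2} \;=\; \frac{\log_{10} 2 \cdot \Delta t}{\log_{10}(C_0 / C_1)}.$$

`compute_half_life()` implements exactly this. Two conventions are worth
making explicit:

* **The constant.** The clinical literature writes the numerator constant as
  the rounded 0.3 rather than $\log_{10} 2 = 0.30103\ldots$. The package
  defaults to the exact value; `constant = 0.3` reproduces printed numbers
  literally. The difference is a uniform 0.34% scaling of every half-life
  and cannot move a patient across a cutoff except within that margin. All
  count-based results are identical under either choice.
* **The interval.** Published two-point half-lives are often quoted without
  the draw interval. Back-solving the formula from published serial values
  and their printed half-lives implies intervals of roughly 11–17 h
  (an evening ablation, a next-morning draw), not 24 h. The package
  therefore treats $\Delta t$ as an explicit per-patient input
  (`draw_interval_h` in the cohort table) with a configurable default of
  15 h when unrecorded. Half-lives are linear in $\Delta t$, so misstating
  the interval rescales them proportionally.

A marker that fails to decline ($C_1 \ge C_0$) has no finite clearance
half-life. The estimate is reported as `Inf` with status `non_declining`
rather than dropped: `Inf` sorts above every finite half-life, so such
patients are classified "long" at any cutoff and participate in the ROC as
the most response-negative score. Time is in hours everywhere inside the
package; months are used only for survival follow-up.

## Eligibility: when a half-life is measurable at all

A half-life needs room to fall. Two exclusions, applied in order,
reproduce the standard analysis flow (`assess_eligibility()`):

1. baseline in the normal range, $C_0 < 40$ mAU/mL — the marker was never
   informative for this tumor;
2. baseline below twice the upper limit of normal, $C_0 < 80$ mAU/mL, or a
   first-day value that has already normalized, $C_1 < 40$ mAU/mL — the
   concentration plateaus near the normal range, so the observed drop no
   longer reflects clearance kinetics.

The printed rules are strict inequalities, so the boundary values
$C_0 = 80$ and $C_1 = 40$ are eligible. The two baseline exclusions are
counted separately so the full flow diagram can be rebuilt from the
pipeline's cascade counts; patients with a missing first-day value get a
dedicated count rather than silently vanishing.

## Dichotomization, diagnostic accuracy, ROC

`dichotomize()` calls a half-life "short" iff it is strictly below the
cutoff (default 48 h). Short half-life is the test-positive state and
complete radiological response at one month the condition-positive state;
`build_confusion()` and `diagnostic_metrics()` derive sensitivity,
specificity, accuracy, PPV and NPV with Wilson-score 95% intervals (the
source analyses report no intervals; Wilson behaves well at the small
denominators involved). A metric with a zero denominator is returned as
`NA`, never as 0.

`roc_analysis()` builds the empirical ROC with score $=-\widehat{t}_{1/2}$.
Candidate cutoffs are the midpoints between adjacent distinct observed
half-lives plus one point below and one above the observed range — the
construction that naturally yields cutoffs like 47.5 h between observed
values of 47 and 48. The AUC is the Mann–Whitney concordance probability
(ties count one half), and the reported cutoff maximizes Youden's
$J = \text{sens} + \text{spec} - 1$, breaking ties toward higher
specificity. One orientation caveat is documented rather than "fixed": the
published ROC figure quotes an operating point (sens 87.5%, spec 72.1%)
that is inconsistent with the printed 2×2 counts at 48 h (79.1%/90.0%);
which class the original software treated as positive is unstated. The
package fixes the orientation as short-half-life-positive-for-complete-
response throughout, matching the printed counts.

## Re-elevation and discordant cases

`detect_reelevation()` flags any non-missing measurement after day 1 that
strictly exceeds the day-1 value, reporting the earliest qualifying day;
lost measurements are skipped, never imputed. `list_discordant()` returns
the cases where the half-life group contradicts the imaging read — short
half-life despite incomplete ablation (watch for re-elevation: residual
tumor) and long half-life despite complete response (watch for early
recurrence). By construction the discordant count always equals
$fp + fn$ of the confusion matrix.

## Survival stratification

Recurrence-free survival (months from ablation to first recurrence) is
compared between half-life groups with the Kaplan–Meier product-limit
estimator, the two-sample log-rank test, and Cox proportional-hazards
models, all computed via the `survival` package. Cox models use the Efron
tie correction — the source reports do not state their tie handling, and
Efron is the less biased default with the heavily tied month-granularity
follow-up. In the combined mode, `cox_fit()` enters into the multivariate
model every covariate with univariate Wald $p$ below a configurable
threshold (default 0.05). The published multivariate table carries only the
short-half-life indicator forward even though tumor size sat at $p=0.047$
univariately; their entry rule is unstated, so the package makes the rule
explicit and configurable instead of hard-coding that outcome. $p$-values
print to three decimals with a `<0.001` floor.

One bookkeeping point: the published group sizes disagree by one patient
(the 2×2 table implies 27 long-half-life patients, the survival figure
says 26). The built-in `reference_cohort()` resolves this by giving one
long-group patient unresolved follow-up, so 63 patients are
half-life-analyzable but 36 + 26 enter the survival analysis.

## The synthetic generator

No patient-level data are distributed, so `generate_cohort()` simulates
cohorts with the structure the analysis assumes. Per patient:

| parameter | default | rationale |
|---|---|---|
| normal-baseline fraction | 0.374 | published exclusion margin |
| complete-response fraction | 0.706 | published response margin |
| baseline DCP, normal stratum | log-normal, median 20 mAU/mL, sdlog 0.4, truncated < 40 | plausible sub-ULN spread |
| baseline DCP, elevated stratum | log-normal, median 70 mAU/mL, sdlog 1.0, truncated ≥ 40 | puts ~38% of elevated baselines in [40, 80), matching the second exclusion stage |
| true half-life, complete / incomplete | log-normal, median 30 h / 90 h, sdlog 0.35 | separates the groups across the 48 h cutoff at roughly the published accuracy |
| regrowth (incomplete only) | prob 0.5, rate 0.10/day, initial 5% of baseline | drives day-7/30 re-elevation of the kind seen in discordant cases |
| draw interval | normal(15, 1) h, truncated > 0 | back-solved interval scale |
| measurement noise | multiplicative log-normal, sdlog 0.05 | typical immunoassay CV |
| 12-month recurrence, short / long group | 0.39 / 0.92 | published recurrence fractions, converted to exponential hazards |

Serial values at days 0, 1, 7 and 30 follow
$N_0 (1/2)^{t/h}$ plus the regrowth component, then noise. The recurrence
hazard is tied to the *true* half-life group (dichotomized at 48 h) rather
than to the response label, reproducing the survival stratification by
half-life; a response-linked mode exists for sensitivity analysis.
Administrative censoring is at 12 months, matching the follow-up design;
3-month visit granularity is emulated in fixtures where needed. Cohorts are
a pure function of `(config, seed)` and the generator restores the global
RNG state.

What the generator does **not** emulate: covariate-dependent kinetics, AFP
co-dynamics beyond a decorative column, imaging error in the response
label, inter-assay drift, or dependence between baseline level and
clearance rate. Tests passing on synthetic cohorts therefore validate the
*computational pipeline* under its stated generative assumptions, not the
clinical claim on real patients.

### The generative expectation used for calibration checks

`expected_classification()` returns the probability that the *estimated*
half-life falls below the cutoff given the response group — the generative
expectation of the pipeline's sensitivity/specificity. Measurement noise on
the two draws adds a normal error of SD $\sqrt{2}\,\sigma/\ln 10$ to the
measured $\log_{10}$ ratio, which matters: at the default 5% noise it moves
expected specificity by about 0.09 from its noise-free value, because
long-half-life patients show only a small true drop over 15 h. The
expectation is computed by Gaussian quadrature over the half-life and
interval distributions, independent of both the simulator and the
estimator, and reduces to the log-normal tail probability when
`noise_cv = 0`. The calibration test compares the 50-seed mean pipeline
sensitivity/specificity at $n = 630$ against this expectation within
±0.05; small residual gaps come from the eligibility selection (slow
clearers are slightly more likely to keep $C_1 \ge 40$) and regrowth, both
deliberately ignored by the quadrature.

## Numerical and testing choices

* Exhaustive ROC validation runs all $2^n - 2$ label assignments over
  fixed half-life multisets at $n \le 8$, plus randomized continuous
  cohorts, against a brute-force pairwise concordance oracle.
* Cox parameter recovery uses $n = 2000$ uncensored exponential draws at a
  true hazard ratio of 0.12 (log-scale tolerance ±0.1); CI coverage is
  checked over 200 simulations at $n = 500$ for log-hazard-ratios in
  $\{-2,-1,0,1\}$ against a [0.90, 0.99] band.
* Log-rank null calibration uses 500 label permutations of a 60-patient
  null cohort and a Kolmogorov–Smirnov uniformity check at $\alpha = 0.01$.
* The pipeline calibration sweep uses 50 seeds at $n = 630$.

These problem sizes keep the full suite under half a minute while leaving
the Monte-Carlo tolerances comfortably wide relative to their standard
errors.

## Known limitations

The two-point estimate inherits every limitation of its inputs: it assumes
one-compartment first-order clearance between exactly two draws, cannot
separate slow clearance from ongoing secretion (that is what the
re-elevation monitor is for), and is undefined in the direction of rising
markers. The eligibility rules restrict the analysis to markedly
DCP-positive tumors; nothing here applies to normal or mildly elevated
baselines. The reference cohort is a synthetic fixture built to match
published *margins* — it reproduces counts and the worked serial profiles,
not the unpublished patient-level half-life distribution, so quantities
that depend on that distribution (the ROC AUC and optimal cutoff, Cox
hazard ratios) are structurally similar but not numerically identical to
the published ones.
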