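# dcpkinetics

Early prediction of radiofrequency-ablation (RFA) outcome in hepatocellular
carcinoma from the clearance kinetics of serum des-γ-carboxy prothrombin
(DCP / PIVKA-II). Imaging confirms treatment success only a month after
ablation; the speed at which DCP falls on the first post-ablation day is an
earlier signal. This package is for biostatisticians and hepatology
researchers who want that analysis as reusable, tested code: the two-point
half-life statistic, the eligibility cascade, diagnostic-accuracy and ROC
evaluation against the 1-month radiological response, serial re-elevation
monitoring, and recurrence-free-survival stratification — plus a calibrated
synthetic-cohort generator, since no patient-level data are distributed.

## The statistic

Under first-order clearance $N(t) = N_0 (1/2)^{t/t_{1/2}}$, two
measurements bracketing an interval $\Delta t$ give

$$\widehat{t}_{1/2} = \frac{\log_{10}2 \cdot \Delta t}{\log_{10}(C_0/C_1)},$$

with $C_0$ the pre-ablation baseline and $C_1$ the first-day value. A
half-life shorter than 48 h predicts complete ablation; patients whose DCP
cannot support the estimate (baseline < 80 mAU/mL, i.e. below twice the
upper limit of normal, or a first-day value already back under 40 mAU/mL)
are excluded by the same cascade used in the clinical analysis flow.
Short-vs-long half-life then stratifies 12-month recurrence-free survival
(Kaplan–Meier, log-rank, Cox).

## Worked example

The built-in `reference_cohort()` is a synthetic 174-patient fixture laid
out to match the published analysis margins. Running the whole pipeline:

```r
library(dcpkinetics)
report <- run_pipeline(reference_cohort())
print(report)
```

```
DCP half-life analysis
======================
Enrolled patients:                 174
  missing baseline DCP:            0
  normal baseline DCP (excluded):  65 (37.4%)
Response-assessed:                 109
  complete response:               77 (70.6%)
  recurrence-free at 12 mo among complete: 45 (58.4%)
  low baseline < threshold (excluded):     42
  day-1 value normalized (excluded):       4
  missing day-1 value (excluded):          0
Half-life analyzable:              63

Confusion at cutoff 48 h (short HL = test positive):
  tp=34 fp=2 fn=9 tn=18
  sensitivity   79.1%  (95% CI 64.8-88.6%)
  specificity   90.0%  (95% CI 69.9-97.2%)
  accuracy      82.5%  (95% CI 71.4-90.0%)
  ppv           94.4%  (95% CI 81.9-98.5%)
  npv           66.7%  (95% CI 47.8-81.4%)
ROC: AUC = 0.886, optimal cutoff = 57.39 h (Youden J = 0.737)
Discordant cases: 11
Log-rank: chi-square = 18.52 (df 1), p <0.001
Cox (univariate) short_hl: HR 0.25 (95% CI 0.13-0.49), p <0.001
Cox (multivariate) short_hl: HR 0.25 (95% CI 0.13-0.49), p <0.001
```

Reading it: of 174 enrolled patients, 65 had a normal baseline DCP and are
excluded up front; of the 109 whose 1-month response is assessed, 77
ablated completely; a further 42 + 4 cannot support a half-life estimate,
leaving 63. Dichotomizing their half-lives at 48 h recovers the 2×2 table
(34/2/9/18) whose five accuracy metrics are the headline percentages, the
11 discordant cases, and a strong survival split — 12-month recurrence-free
survival of 61.1% (short) vs 7.7% (long), log-rank p < 0.001, with a short
half-life protective against recurrence (HR ≪ 1).

Individual pieces work standalone:

```r
compute_half_life(177.85, 121.24, 15.13, constant = 0.3)$half_life_h
#> [1] 27.27634
diagnostic_metrics(confusion_matrix(34, 2, 9, 18))
km_estimate(c(3, 6, 8, 8), c(1, 1, 0, 0))
generate_cohort(synthetic_config(n_patients = 200, seed = 1))
```

## Analysis workflow

The `analysis/` scripts run the study end-to-end on a simulated cohort and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # synthetic cohort -> cohort.csv
Rscript analysis/02_half_life.R               # cascade + half-life table
Rscript analysis/03_diagnostics.R             # confusion, metrics, ROC
Rscript analysis/04_survival.R                # KM, log-rank, Cox
Rscript analysis/05_reference_reproduction.R  # reference-cohort report bundle
```

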