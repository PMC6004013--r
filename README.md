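# urometab

Urinary metabolomics for bladder-cancer recurrence surveillance:
QC-anchored batch correction of LC-MS peak tables, PLS-DA classification
with patient-wise cross-validation and VIP feature screening, diagnostic
figures of merit with exact confidence intervals, and longitudinal
trajectories of the discriminant score.

## The problem

Non-muscle-invasive bladder cancer (NMIBC) is managed by transurethral
resection (TURBT) followed by years of cystoscopic surveillance —
invasive, costly, and unpleasant. Urine is in direct contact with the
tumor, so the urinary metabolome is a natural non-invasive readout.
The analysis this package implements asks two questions of untargeted
LC-MS peak tables from such cohorts:

1. Does the urinary metabolic profile shift measurably after tumor
   resection (pre-TURBT `BC` samples vs post-TURBT `CTRL` samples)?
2. Tracked per patient over surveillance visits (`MONITOR` samples),
   does a BC-vs-CTRL discriminant score drift back toward the BC profile
   before a cystoscopy-confirmed recurrence?

Peak intensities from multi-batch LC-MS runs are dominated by nuisance
structure — within-batch sensitivity drift, between-batch offsets,
urine-dilution differences — so most of the package is careful, QC-anchored
conditioning of the data before any biology is asked of it.

## The method

* **Drift correction (QC-SVRC).** A pooled QC sample injected every few
  runs traces the instrument's sensitivity. Per feature and batch, a
  support-vector regression (RBF kernel) of QC intensity on injection
  order is fitted with epsilon = 2.5% of the median QC intensity, cost
  C = the median itself, and gamma chosen from 2^-3..2^9 by 10-fold CV;
  all samples are rescaled by `median(QC) / f(order)`. Between batches,
  per-feature QC medians are equalized exactly. Features failing a blank
  test (blank/QC median ratio >= 1/3) or a QC repeatability test
  (RSD > 15%) are removed.
* **Scaling.** Multiplicative scatter correction against the median QC
  profile (removing per-sample dilution/gain), then Pareto scaling
  `z = (x - m)/sqrt(s)` with train-set statistics only.
* **PLS-DA.** Univariate-response NIPALS PLS on CTRL = 0 / BC = 1, latent
  variables chosen by leave-one-patient-out RMSECV (whole patients held
  out; fold-wise scaling refits). Feature screening by Variable
  Importance in Projection, `sum(VIP^2) = p`, keeping VIP > 3, then an
  optimized refit on the selected features.
* **Figures of merit.** Sensitivity/specificity/accuracy with exact
  Clopper-Pearson 95% CIs, likelihood ratios with log-method CIs, rank-sum
  AUROC, and Bayes-rule predictive values at external recurrence-risk
  prevalences.
* **Surveillance.** Per-patient trajectories of the predicted score with
  a Spearman-trend flag (`rising_toward_BC` / `stable` / `inconsistent`).
* **Synthetic cohorts.** A generator emulating the acquisition design
  (two batches, conditioning QCs, periodic pooled QCs, blanks, smooth
  drift, batch offsets, constant-CV multiplicative noise, class effects,
  relapse trajectories) with full ground truth, so every stage is
  testable without instrument data.

## Worked example

```r
library(urometab)

cohort <- generate_cohort(synthetic_config(
  n_features = 120, n_discriminant = 15, n_patients_bc = 16,
  n_monitor_visits = 4, recurrence_fraction = 0.5,
  noise_rsd = 0.2, effect_log2fc = 0.5, seed = 42))

corr <- correct_batch_effects(cohort$table, rsd_threshold = 25)
# median QC RSD: 26.7% raw -> 2.6% corrected; 114 of 120 features retained

tbl <- corr$table
pts <- sort(unique(tbl$patient_id[tbl$role == "STUDY"]))
assignment <- setNames(ifelse(seq_along(pts) %% 2 == 1, "train", "validation"), pts)
plan <- split_by_patient(tbl, assignment)

fit <- fit_discriminant(tbl, plan$train_sample_ids, n_lv = 3, vip_threshold = 2)
glance(fit)
#>    n_lv rmsecv n_features n_selected n_train
#> 1     3     NA        114          5      16

pred <- predict(fit, tbl, sample_ids = plan$validation_sample_ids)
val  <- dplyr::filter(pred, class_label %in% c("BC", "CTRL"))
evaluate_discriminant(val$y_hat, val$predicted, val$class_label,
                      positive = "BC", prevalences = c(0.15, 0.61))
#> Confusion: tp=7 fn=1 tn=7 fp=1 (positive = BC)
#> AUROC: 0.969
#>   metric      estimate   lower  upper
#> 1 sensitivity   87.5   47.3    99.7
#> 2 specificity   87.5   47.3    99.7
#> 3 accuracy      87.5   61.7    98.4
#> 4 plr            7      1.10   44.6
#> 5 nlr            0.143  0.0224  0.910
#>   prevalence   ppv   npv
#> 1       0.15 0.553 0.975
#> 2       0.61 0.916 0.817

traj <- patient_trajectory(fit, tbl, "P003")
trend_flag(traj[traj$class_label %in% c("CTRL", "MONITOR"), ])
#> patient P003: rising_toward_BC (spearman rho = 0.90, first crossing: 5)
```

Reading the output: on the 16 held-out validation samples the classifier
recovers the post-resection shift (7/8 BC and 7/8 CTRL correct; AUROC
0.97), the exact binomial intervals are wide at this sample size, and the
positive likelihood ratio of 7 means a positive score multiplies the
recurrence odds sevenfold. At a low-risk prior of 15% a negative score
leaves a 97.5% probability of no recurrence; at a high-risk prior of 61%
only 81.7%. Patient P003, a ground-truth relapser, shows a monotone rise
of the discriminant score that crosses the decision threshold at visit 5.
Plot helpers (`autoplot()` on CV curves, `plot_qc_trend()`,
`plot_rsd_cdf()`, `plot_vip()`, `plot_trajectory()`) draw the standard
figures for each stage.

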