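---
title: "Methods: QC-anchored correction and PLS-DA surveillance of urinary metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC-anchored correction and PLS-DA surveillance of urinary metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

urometab implements an end-to-end analysis for untargeted urinary LC-MS
metabolomics in the surveillance of non-muscle-invasive bladder cancer
(NMIBC). Patients provide urine before transurethral resection of the
bladder tumor (label `BC`), shortly after resection (`CTRL`), and during
follow-up between cystoscopies (`MONITOR`). The scientific questions the
pipeline addresses are (i) whether the urinary metabolic profile shifts
measurably after tumor resection, and (ii) whether the discriminant score
of a BC-vs-CTRL classifier, tracked per patient over surveillance visits,
drifts back toward the BC profile before a confirmed recurrence.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic-cohort tests demonstrate.

## Data model

A peak table is a tibble with one row per injection: seven reserved
metadata columns (`sample_id`, `patient_id`, `batch`, `injection_order`,
`role`, `class_label`, `visit_index`) followed by one numeric column per
LC-MS feature (arbitrary intensity units; `NA` is a missing measurement,
distinct from zero). Feature m/z (Da) and retention time (min) travel in
a feature-metadata tibble. Injection order restarts at 1 in each batch
because every drift model is per batch. The `class_label` token `"NA"`
(cystoscopy outcome unknown) is a real category, so files must encode
missing cells as empty strings, and the readers/writers do.

Roles: `CONDITIONING_QC` (column-conditioning replicates at the head of
each batch, always excluded), `QC` (pooled aliquot of all study samples,
injected periodically), `BLANK`, and `STUDY`.

## Batch-effect correction

Within-batch drift is corrected per feature and batch by support-vector
regression of QC intensity on injection order (RBF kernel), the
QC-anchored approach commonly called QC-SVRC. The hyperparameters follow
fixed rules rather than free optimization:

* epsilon (tube half-width) = 2.5% of the feature's median QC intensity —
  the expected instrumental precision;
* cost C = the median QC intensity itself;
* gamma picked from the dyadic grid 2^-3 ... 2^9 (13 candidates) by
  10-fold root-mean-square cross-validation error of the QC fit, with
  contiguous folds over injection order (preserving temporal structure);
  ties go to the smallest gamma, the smoothest model. With fewer QCs than
  folds the CV degrades to leave-one-out; fewer than 3 QCs is an error.

Every sample in the batch (all roles) is then rescaled by
`qc_reference / f(order)` where `qc_reference` is the per-batch QC median
and `f` the fitted drift. Dividing by the fitted curve and re-anchoring at
the QC median preserves the intensity scale and makes the between-batch
step well defined. Two guards keep the correction safe: constant QC
series short-circuit to an exactly constant model (so an undisturbed
table passes through unchanged bit for bit), and degenerate fits
(non-positive predictions, or an epsilon tube that swallows every point
and leaves libsvm without support vectors) fall back to a constant at the
QC reference/mean rather than dropping the feature, keeping feature sets
aligned across batches.

Between batches, each feature's intensities in batch *k* are multiplied
by `median(QC, pooled) / median(QC, batch k)`. Multiplied in this
direction the per-batch QC medians become exactly equal; the literal
opposite ratio would amplify batch differences, so the package uses the
converging direction.

Reliability filtering: features whose blank-to-QC median ratio reaches
1/3 are removed as background (source contaminants, plasticizers); the
ratio is a conventional sample-to-blank threshold of 3, since no value is
standard in the field beyond that convention. Features whose
post-correction QC relative standard deviation (RSD = sd/mean x 100)
exceeds 15% are removed as unreliable; the boundary is strict, so a
feature at exactly 15.0% is retained. RSD filtering uses the
post-correction RSD only; the pre-correction value is kept in the report
for diagnostics. `qc_trend_diagnostics()` exposes the standard visual
checks: QC principal-component scores against injection order and the
cumulative RSD distribution.

## Scaling

Study samples are scaled in two frozen steps. Multiplicative scatter
correction (MSC) regresses each sample profile on a reference profile
over features (`x = a + b ref`) and returns `(x - a)/b`, removing
per-sample dilution and injection-volume gain — the dominant nuisance in
urine. The reference is the per-feature median over the corrected QC
injections. Because pooled QCs contain material from every sample and
carry no class or patient information, using all QC injections for the
reference cannot leak validation labels; this is the one place the
package deliberately relaxes a train-only rule, and it is revisited
inside cross-validation only for the Pareto statistics. Pareto scaling
then centers each feature at its train mean and divides by the square
root of its train standard deviation — a compromise between no scaling
(high-abundance features dominate) and autoscaling (noise features are
inflated). Validation samples are always transformed with the train-set
parameters.

## PLS-DA, cross-validation and VIP screening

The classifier is univariate-response partial least squares (NIPALS
deflation) on the coded classes CTRL = 0, BC = 1, with the decision
threshold at the coding midpoint 0.5 (the convention is arbitrary; the
package exposes both). The number of latent variables is chosen by
leave-one-patient-out cross-validation: folds are patients, every sample
of the held-out patient is excluded from fitting, and Pareto statistics
are recomputed inside each fold so no held-out information shapes the
scaling. The RMSECV minimum picks the component count, ties toward the
smaller model; a fixed override (the study-style 3-component model) is
supported and skips the scan.

Feature importance uses the Variable Importance in Projection,

VIP_j = sqrt( p * sum_a q_a^2 t_a't_a (w_ja/||w_a||)^2 /
              sum_a q_a^2 t_a't_a ),

whose squares always average to 1 over the p features. Screening keeps
features with VIP strictly above 3, then refits an "optimized" model on
the selected features (3 components by default, preprocessing refitted on
the reduced feature set). Screening and refit see train samples only.

## Figures of merit

Binary performance is summarized by sensitivity, specificity and accuracy
with exact (Clopper-Pearson) binomial 95% intervals from beta quantiles;
likelihood ratios PLR = sens/(1-spec), NLR = (1-sens)/spec with
log-method (Simel-type) intervals `exp(log LR +/- 1.96 SE)`; and the
rank-sum AUROC (ties count one half). Degenerate tables are flagged, not
smoothed: zero false positives give PLR = +Inf with the CI side
undefined, and when only one variance term vanishes (perfect
specificity) that term is dropped and the NLR interval is still reported.
Predictive values at external prevalences use Bayes' rule, so a negative
test's reassurance can be restated per recurrence-risk stratum (the
package's worked examples use priors of 15%, 24%, 28% and 61%).

## Longitudinal surveillance

`patient_trajectory()` scores every visit of a patient with the frozen
discriminant model. The trend statistic is the Spearman rank correlation
of the score with visit order — chosen because the shape of a
pre-recurrence drift is unknown and only its monotonicity is claimed. A
series is flagged `rising_toward_BC` when the correlation reaches 0.6 and
the final score is within 0.1 below the threshold or above it; `stable`
when the correlation is weak and the score never crosses; `inconsistent`
otherwise. Fewer than 3 visits withholds the flag. MONITOR samples are
never used to fit models. Note the purely statistical limit: with n
visits the null rank correlation has spread ~ 1/sqrt(n-1), so short
series (4-5 visits) cannot be reliably called stable; about ten visits
(roughly a year of monthly surveillance) are needed before |rho| < 0.5
holds in >= 80% of null series.

## The synthetic cohort generator

`generate_cohort()` produces tables with the statistical structure the
pipeline assumes, plus ground truth. Per feature f, batch k, injection
order t:

x = b_f * e_f(class) * d_fk(t) * g_fk * eta

* baselines b_f ~ log-normal, median 1e4, sdlog 0.4 (about one order of
  magnitude between the 5th and 95th percentile — see the caveat below);
* class effect e_f = 2^(+/- log2FC) on discriminant features (sign random
  per feature, acting on the log scale), 1 elsewhere; MONITOR samples of
  relapsing patients interpolate e_f linearly from the CTRL level to the
  BC level, reached at the recurrence visit;
* drift d_fk: a random cubic in normalized injection order, rescaled so
  its maximum deviation from 1 equals `drift_amplitude` — the weakest
  smooth nonlinear form an RBF-kernel SVR should recover;
* batch factor g_fk = 2^u, u ~ Uniform(-r, r);
* noise eta: mean-1 log-normal with coefficient of variation `noise_rsd`
  (constant CV, matching the RSD-based quality metric and the
  heteroscedastic variance seen in real peak areas).

QCs carry the pooled feature baseline (no class effect) under the same
drift, batch and noise terms, mirroring the physical pooling of study
aliquots; blanks carry only a designated set of background features. The
layout puts the conditioning QCs first in each batch, then one QC ahead
of every block of `qc_interval` study/blank injections, with the study
order randomized and all samples of a patient confined to one batch.

Defaults (two batches, QC every 5 injections, 8 conditioning QCs,
drift amplitude 0.3, between-batch log2 range 0.5, noise CV 10%) were
chosen once so that raw cohorts show a median QC RSD near 20% — the
regime in which the correction stage has realistic work to do — and are
not adjusted per experiment.

What the generator does **not** emulate: chromatographic peak shapes and
co-elution, adduct/isotope structure, patient-level biological variance
beyond the class effect, batch-dependent missingness, and wide
cross-feature abundance ranges. The last point matters for interpreting
the feature-recovery tests: Pareto-scaled PLS weights scale with the
square root of a feature's abundance, so with abundances spread over
several orders of magnitude a fixed VIP threshold is structurally blind
to low-abundance markers, however clean their effect. The generator's
sdlog 0.4 keeps the recovery property about the method rather than about
abundance; on real tables, recovery of low-abundance markers should be
expected to degrade, and a per-feature test (or rank-based selection)
used alongside VIP.

## Numerical choices and degenerate inputs

* Constant QC series, constant features under Pareto scaling (mapped to
  0 and flagged), MSC slopes below 1e-12 (sample returned uncorrected
  with a warning), and empty VIP selections (error advising a lower
  threshold) are all handled explicitly.
* SVR predictions are floored at a small positive multiple of the QC
  reference so correction factors stay finite.
* PLS components are capped at the rank of the centered train matrix;
  the CV scan uses A_max = min(15, rank - 1).
* The drift-fit tests allow libsvm's convergence tolerance (~1e-3
  relative) on top of the epsilon tube.
* All randomness flows from explicit integer seeds; the generator is
  bit-reproducible given a seed.

## Problem sizes used in the tests

The shipped suite exercises cohorts of 10-60 features and 8-16 patients
for correction and calibration properties, 1000 features and 35 patients
(five cohorts) for VIP recovery, 20 null cohorts for AUROC calibration,
and 10,000 binomial draws for interval coverage — sizes chosen to make
the properties statistically decidable while keeping the suite quick to
run during development.
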