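---
title: "Methods: the composite five-marker prognostic score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite five-marker prognostic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioscore)
```

This vignette is the package's account of its statistical methods: the
model behind the composite score, the conventions that were genuinely open
when the pipeline was designed and how they were resolved, what the
synthetic-cohort generator does and does not emulate, and the numerical
choices that affect results.

## The problem and the data

The setting is a small retrospective cohort of prostate cancer patients
(acinar adenocarcinoma, biopsy followed by prostatectomy) with 3–6 years
of follow-up, of whom roughly a quarter progress (biochemical, local, or
metastatic recurrence). The question is whether five molecular markers
measured on the diagnostic biopsy — eNOS, HIF-2α and β4 integrin protein
by immunohistochemistry; H19 and CDH1 transcripts by droplet digital
PCR — predict progression better than the clinical standards (PSA,
Gleason score).

Two marker modalities feed the pipeline:

* **IHC score.** Staining is read as Intensity (0 = negative … 3 = high)
  times Quantity, a binned percentage of positive cells (0 = none,
  1 = 1–9%, 2 = 10–39%, 3 = 40–69%, 4 = 70–100%), giving an integer score
  0–12 whose attainable values are exactly the products
  {0, 1, 2, 3, 4, 6, 8, 9, 12}. Bins are defined on integer percentages;
  fractional input is rounded to integer percent first. When several cores
  are read per patient the default per-patient value is the *maximum*
  tumor-area score (worst-region grading, the common pathology
  convention); a mean is available (`aggregate_cores`).
* **ddPCR concentration.** With k positive droplets out of n, target
  copies distribute as Poisson across droplets and the concentration is
  λ/v with λ = −ln(1 − k/n) and v the droplet volume. The default
  v = 0.85 nL is the QX200 partition volume, configurable. Wells with
  n ≤ 12,000 droplets fail QC (strict bound). Replicate wells are merged
  by summing droplets *before* estimation, which is the lower-variance
  choice; whether the original analysis merged or averaged replicates is
  not recoverable, so this is a package decision. Targets are normalized
  to a housekeeping gene (GAPDH by default; the assay also carries P0).
  The 14-cycle preamplification is treated as a constant factor that
  cancels in the ratio. Samples with failing or zero housekeeping signal
  are excluded and logged, never imputed.

## Dichotomization and the binary-test AUC

Every variable enters the univariate analysis dichotomized by an explicit
cut-off rule (threshold + inequality direction). The headline AUC is the
**binary-test AUC**,

$$\mathrm{AUC} = \frac{\mathrm{sensitivity} + \mathrm{specificity}}{2},$$

the exact area under the single-bend ROC curve of a dichotomous test. This
convention was fixed after verifying, by brute-force pair counting on the
packaged clinical table, that the published clinical-variable AUCs (0.568
for PSA at 6.3 ng/mL, 0.716 for pathologic Gleason ≥ 4+3) equal
(sens+spec)/2 of the dichotomized variable and *not* the continuous
all-pairs AUC of the raw values (0.398 for PSA). The continuous
Mann–Whitney AUC is still reported as a supplementary column
(`auc_continuous`).

Two conventions follow from that identity:

* **Orientation auto-flip.** When the dichotomized AUC falls below 0.5
  the rule's direction is reversed and 1 − AUC reported; the returned
  rule records the effective direction and a `flipped` field marks the
  reversal. This is not cosmetic: the published PSA figure of 0.568 is
  only reachable as the flip of 0.432 — in this cohort *low* PSA tracks
  progression.
* **Gleason ordering.** Gleason 7 (3+4) ranks below 7 (4+3); the
  dichotomization "≥ 4+3" is total > 7, or total = 7 with primary
  pattern 4. Internally an ordinal code (total × 10 + primary) makes the
  ordering monotone for continuous-AUC purposes.

Cut-off re-derivation (`optimal_cutoff`) scans every observed value as a
threshold in both directions and maximizes the Youden index
J = sens + spec − 1, breaking ties by higher specificity, then smaller
threshold, then direction. It reproduces an exhaustive brute-force scan on
random instances, but its output is *not* asserted to equal the published
cut-offs (e.g. H19 ≤ 1.1392): how those were chosen is not reproducible
from printed data, so the default pipeline applies them as fixed rules and
re-derivation is exploratory.

Inference on an AUC uses, by default, a class-stratified percentile
bootstrap (events and non-events resampled separately, so no resample is
degenerate; B = 2000, seeded, deterministic), with the DeLong
variance-based interval as the fast alternative. The p-value against
AUC = 0.5 is the normal-approximation Mann–Whitney test with tie and
continuity corrections; the continuity correction is what keeps it within
10% of the exact rank test at the cohort sizes involved (n per class ≤ 10
in validation subsets). No method for the published intervals/p-values is
stated in the source material, so these are package choices.

## The composite score

The five default rules are eNOS > 1, HIF-2α > 0, β4 integrin > 4 (IHC
scores, strict), H19 ≤ 1.1392 (*low* H19 is the risk state) and
CDH1 ≥ 0.0051 (non-strict), exactly as published, mixed inequalities
included. Each satisfied rule contributes **1** to the score — an
indicator sum, not a sum of raw marker values — and score ≥ 3 defines the
high-risk class. The indicator-sum reading is the only one that makes "a
value of 3 or more" consistent with "three factors among" the five
dysregulations; the score is then monotone in each marker's dysregulation
and invariant to rule order, properties the test suite enforces by
enumeration of all 32 flag patterns.

Variable selection for multivariate modelling nominally retains variables
with univariate p < 0.10 (`uva_filter`, strict inequality). The composite
nevertheless includes markers whose univariate p exceeds 0.10, because
that is the five-marker set the published analysis actually combined; the
pipeline therefore defaults to the full five-marker rule set and leaves
selection configurable rather than silently dropping markers.

## Survival evaluation

Progression-free survival runs on (time, event) pairs where events carry
the recurrence time and censored patients an explicit follow-up time. The
clinical table prints recurrence times only, so censoring times must come
from the user or the generator; survival stages are skipped with a notice
(ROC stages still run) when they are absent. Kaplan–Meier estimation,
log-rank testing and Cox fitting are delegated to the `survival` package
(product-limit with log-log bands; Efron tie handling by default since
months-resolution times guarantee ties, Breslow available for
cross-checks). The package's own tests pin these wrappers to hand-computed
product-limit and O−E/V tabulations and to direct partial-likelihood
maximization on toy data.

The Cox model for the score codes **high risk as the reference level**,
so the reported hazard ratio is for low- versus high-risk patients and a
*protective* HR (< 1) means the high-risk class progresses faster. The
published HR of 0.090 is only interpretable under some such coding — the
source does not state which group is the reference — so the coding is
interpretive, explicit in every report (`hr_coding`), and recoverable in
either convention. Whether the multivariate model should carry the single
risk class or the five marker indicators is equally ambiguous; both are
implemented (`mva_mode`), defaulting to the single class variable, which
matches the Kaplan-Meier/HR presentation. The "clustered" qualifier
attached to the ROC analysis in the source could refer to multiple cores
per patient, but the printed data are patient-level, so no cluster
correction is applied. No multiplicity adjustment is applied across the
univariate rows, matching the source; a Benjamini–Hochberg column is
available but off by default.

## The synthetic-cohort generator

Per-patient marker values were never published, so the generator stands in
for them. Its defaults *are* the study conditions: 30 patients, target
observed-progression fraction 8/30, censoring uniform on 36–72 months, PSA
in 1.79–18.5 ng/mL and Gleason/stage categories at the printed
frequencies. Mechanistically, a shared standard-normal "aggressiveness"
latent variable with loading 0.5 induces correlated dysregulation
indicators (probit model) at configurable prevalences (default 0.4 per
marker — the published circuitry implies coordinated dysregulation in a
substantial minority of tumors but gives no rates, so these are labelled
assumptions). Conditional on its flag, each IHC marker draws intensity and
quantity from categorical distributions whose product always lands on the
flag's side of that marker's cut-off, and each transcript draws from a
lognormal restricted (by inverse-CDF) to the flag's side. Progression time
is exponential with hazard baseline × HR_flag^(number of flags), default
HR_flag = 2.5, a strongly prognostic panel. The baseline hazard is
calibrated deterministically — the flag-count distribution is integrated
numerically over the latent variable (801-point grid) and the expected
observed-event fraction solved to the target by root finding (tolerance
1e-9) — so no simulation is needed for calibration.

What the generator deliberately does **not** emulate: measurement error
around the cut-offs (flags and observed dysregulation coincide by
construction, so simulated marker AUCs are upper bounds on what noisy
assays would give), inter-marker structure beyond a single latent factor,
non-exponential hazards, and the independent 11-patient validation
cohort's exact values. Passing tests on synthetic data therefore
demonstrate correctness of the *computations* and calibration of the
*statistics*, not clinical performance of the markers.

## Numerical choices and problem sizes

Degenerate inputs are resolved by convention, not error, where a
convention is defensible: identical paired samples give t = 0, p = 1; a
zero-variance nonzero shift gives p = 0; an all-tied AUC gives 0.5 with
p = 1; a constant marker yields a degenerate cut-off rule with J = 0 and
a warning. Saturated ddPCR wells and zero housekeeping signal are errors
(excluded and logged) because no finite estimate exists. Seeds enter every
stochastic step explicitly and are echoed in reports.

The simulation-based checks in the test suite use problem sizes chosen to
keep Monte-Carlo error well inside the asserted bounds at interactive
runtimes: 200 random instances for the oracle-equality properties, 1000
replicates for the ddPCR round trip and the null-size and calibration
checks, and 30 cohorts of n = 1000 per true hazard ratio for Cox
recovery.

## Known limitations

The pipeline evaluates the published rules; it does not validate them.
With 8 events in 30 patients every interval is wide, the bootstrap can
degenerate at the extremes (a perfectly separated resample has an AUC of
exactly 1), and dichotomized markers discard information relative to
continuous modelling. The Cox model with five binary covariates and 8
events is overfit by any standard rule of thumb and is provided because
the source analysis fits it, flagged as such. TNM stage is stored but not
modelled. No competing-risks or time-varying extensions are attempted.
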