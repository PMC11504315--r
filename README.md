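# bioscore

Prognostic evaluation of a five-marker composite score ("BioScore") for
prostate cancer at the biopsy stage.

About 20–40% of clinically localized prostate cancers progress after
curative treatment, and the standard clinical predictors — serum PSA,
Gleason score, pathological stage — separate recurrent from non-recurrent
patients poorly. This package implements, as a tested pipeline, an analysis
that combines five molecular markers measured on FFPE biopsies: three
protein markers scored by immunohistochemistry (eNOS, HIF-2α, β4 integrin)
and two transcripts quantified by droplet digital PCR (the lncRNA H19 and
the E-cadherin transcript CDH1, each normalized to a housekeeping gene). It
is intended for biostatisticians and translational researchers evaluating
composite dichotomized-marker scores against time-to-progression outcomes
in small retrospective cohorts.

## The statistic

Each marker *m* is dichotomized by a published cut-off rule
*r<sub>m</sub>* (eNOS IHC score > 1, HIF-2α > 0, β4 integrin > 4,
H19 ≤ 1.1392, CDH1 ≥ 0.0051; low H19 counts as dysregulated). The
composite score for patient *i* is the indicator sum

> BioScore<sub>i</sub> = Σ<sub>m</sub> 1[ r<sub>m</sub>(x<sub>im</sub>) ],  BioScore ∈ {0,…,5},

and patients with BioScore ≥ 3 are classed high risk. Each dichotomized
variable is evaluated as a binary prognostic test against observed
progression, with

> AUC = (sensitivity + specificity) / 2,

the exact area under the one-bend ROC curve of a binary test; orientation
is flipped when the AUC falls below 0.5. Continuous markers are also
summarized by the all-pairs (Mann–Whitney) AUC, and Youden-optimal
cut-offs (max sens + spec − 1) can be re-derived from data. The prognostic
value of the high/low classification is assessed by Kaplan–Meier curves,
the log-rank test, and Cox proportional-hazards models (Efron ties), with
the hazard ratio reported for low- versus high-risk patients.

The package also implements the upstream quantifications: the
semiquantitative IHC score (staining Intensity 0–3 × positive-cell
Quantity bin 0–4), and ddPCR Poisson inversion
λ = −ln(1 − k/n), concentration = λ/v copies/µL, with the strict
\>12,000-droplet QC rule and housekeeping normalization. A synthetic-cohort
generator reproduces the study design (30 patients, ~27% progression,
3–6 year follow-up, correlated marker dysregulation raising an exponential
progression hazard) so every stage is testable without patient data.

## Worked example

The package ships the study's printed 30-patient clinical table. The
univariate report on it:

```r
library(bioscore)
cohort <- read_cohort(table1_path())
uva <- run_uva(cohort, seed = 1)
uva[, c("variable", "cutoff", "direction", "auc", "ci_low", "ci_high", "p")]
#>   variable cutoff   direction   auc ci_low ci_high      p
#> 1      PSA    6.3       below 0.568  0.375   0.756 0.5253
#> 2      pGS   74.0 at_or_above 0.716  0.528   0.886 0.0406
```

PSA dichotomized at 6.3 ng/mL gives a binary AUC of 0.568 — note the
effective direction is `below`: in this cohort low PSA tracks progression,
so the orientation was auto-flipped — and pathologic Gleason ≥ 4+3 gives
0.716 (the `74` cut-off is the internal ordinal code for grade 7 with
primary pattern 4). Neither is a convincing predictor on its own. The full
pipeline on a synthetic cohort with marker panels:

```r
sim <- generate_cohort(sim_config(seed = 7))
report <- run_full(sim$cohort, sim$markers, seed = 1)
report
#> BioScore (>= 3 = high risk): 14 high / 16 low; 0 excluded
#>   binary AUC 0.903 (0.785-1.000), sens 92.3%, spec 88.2%, p = 1.835e-05
#>   log-rank chi-square 22.999, p = 1.621e-06
#>   Cox HR [low vs high (high = reference)] 0.033 (0.004-0.257), p = 0.00116
```

Here the composite score separates recurrent from non-recurrent patients
far better than any clinical variable: sensitivity 92.3% and specificity
88.2% average to the reported AUC of 0.903, and the low-risk class has a
strongly protective hazard ratio. `write_report(report, "out/")` serializes
the tables to CSV and the summaries (with the rule set and seed) to JSON.

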