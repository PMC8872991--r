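# absimets

Metabolic syndrome (MetS) diagnosis with **A Body Shape Index (ABSI)** in
place of waist circumference, and survival analysis of how each definition
predicts **new-onset renal function decline** (eGFR < 60 mL/min/1.73 m²)
over four annual screening visits.

## The problem

All major MetS criteria — Japanese committee, IDF, NCEP-ATPIII — judge
abdominal obesity by waist circumference (WC). But WC is nearly collinear
with BMI, and BMI partly reflects vasoprotective body composition, so
WC-based MetS correlates poorly with arterial stiffness and renal risk.
ABSI normalizes WC by its allometric expectation,

    ABSI = WC / (BMI^(2/3) · height^(1/2)),    WC and height in metres,

making it statistically independent of BMI while tracking visceral
adiposity. This package is for epidemiologists and biostatisticians who
want to (a) classify cohorts under the six definitions (3 criteria sets ×
{WC, ABSI ≥ 0.080}) with the exact treatment-counting semantics, and
(b) quantify each definition's prediction of incident renal decline with
Kaplan-Meier/log-rank, Cox proportional-hazards models (arterial stiffness,
CAVI ≥ 9.0, as covariate), age-adjusted ANCOVA of CAVI, and ROC/Youden
cutoff estimation. Because the motivating screening data are private, a
seeded synthetic cohort generator reproduces the study conditions
(n = 5,438, published baseline medians/IQRs, ~7% excluded at baseline,
~8.7% cumulative incidence) with a known discrete-time hazard, so every
estimate the pipeline produces can be validated against ground truth.

## Worked example

```r
library(absimets)

cohort <- generate_cohort(default_cohort_config(n_subjects = 5438, seed = 17))
study  <- run_study(cohort$visits)
study
```

```
absimets study result
  subjects analyzed: 5421
  exclusions: incomplete 0 | ABI 17 | baseline eGFR<60 357
  incident events: 486 of 5064 at risk
  MetS prevalence (%):
          definition n_positive n_total prevalence_pct
    mets_japanese_wc        119    5421            2.2
  mets_japanese_absi        101    5421            1.9
         mets_idf_wc        193    5421            3.6
       mets_idf_absi        115    5421            2.1
        mets_ncep_wc        126    5421            2.3
      mets_ncep_absi        197    5421            3.6
```

The exclusion ledger mirrors the study design: subjects without four
consecutive visits, then ankle-brachial index < 0.90 (CAVI invalid), are
removed before analysis; subjects already below eGFR 60 at baseline are
excluded from incidence analyses only. Cox Model 2 (confounders + Japanese
ABSI-MetS) on this cohort:

```r
study$cox_model2
```

```
                term    beta      se    hr ci_low ci_high        p
1                age  0.0104 0.00406 1.010  1.002    1.02 1.04e-02
2               male  0.2141 0.09089 1.239  1.037    1.48 1.85e-02
3          high_cavi  1.3879 0.12343 4.006  3.146    5.10 2.45e-29
8 mets_japanese_absi  0.8328 0.23698 2.300  1.445    3.66 4.41e-04
```

(rows 4-7: proteinuria and treatment flags, all non-significant here). The
generator attached a true hazard ratio of 1.623 to Japanese ABSI-MetS; the
fitted 2.30 with CI (1.45, 3.66) covers it — across replicates the mean
estimate is unbiased (see the simulation tests). `study$roc` gives the
Youden-optimal ABSI cutoff for predicting decline (0.0815 on this cohort,
AUC 0.540).

The numbered scripts under `analysis/` run the same workflow as a narrative:
`01_simulate.R` (cohort + ground truth), `02_classify_mets.R` (validation,
six classifications, baseline tables), `03_survival.R` (KM, log-rank, Cox
Models 1-2 and gender-specific analyses), `04_roc_cutoff.R`. Tables land in
`results/tables/`.

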