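# ahfid

Rule-based EHR phenotyping of **acute heart failure** (including acute
exacerbation of chronic heart failure) from the three coded data sources of
Japanese hospital information systems — SS-MIX2-standardised electronic
medical records, DPC case-mix data, and health-insurance claims — together
with the statistical machinery used to validate such algorithms against
chart review.

The package is for pharmacoepidemiologists and medical informaticians who
need to identify AHF cases in multi-hospital databases where imaging and
free text are unavailable and an ICD-10 code alone cannot distinguish an
acute decompensation from stable chronic disease, renal BNP elevation, or a
billing code attached to justify a blood test.

## What it implements

* **21 atomic conditions** (`hf_condition_events()`): six diagnosis
  conditions over the three sources (DPC any-field / three-field, SS-MIX2
  with/without suspected names, claims, and DPC with hospital stay ≥ 3
  days), eight drug classes, six natriuretic-peptide thresholds
  (BNP 100/400, NT-proBNP 400/3,000 pg/ml), and transthoracic
  echocardiography.
* **The All-Possible-Cases (APC) screen and 18 identification algorithms**
  (`hf_algorithms()`, `hf_evaluate()`, `hf_run_panel()`). Each algorithm is
  a disjunction of branches, each branch a conjunction of condition groups,
  evaluated in an inclusive symmetric window (±7, ±14 or ±30 days) around
  the **index date** — the first qualifying diagnosis date. The screen
  (HF diagnosis in any source plus BNP ≥ 100 or NT-proBNP ≥ 400 within ±30
  days) anchors the validation: its positives are sampled per hospital
  (`hf_sample_population()`) for chart review and assumed to contain every
  true case.
* **Chart-review classification** (`classify_case()`): three judgements
  (Framingham criteria; comprehensive clinical assessment; AHF treatment)
  map to the ordered categories True A > True B > Suspected > Other.
* **Validity statistics** (`hf_confusion()`, `validity_measures()`,
  `hf_validity_report()`): PPV = tp/(tp+fp), sensitivity = tp/(tp+fn) with
  the screen-anchored denominator, NPV and specificity when a total patient
  count is supplied (tn by subtraction), all ×100 with exact
  Clopper–Pearson 95% intervals; quadratic-weighted (Fleiss–Cohen) kappa
  with its large-sample standard error for inter-reviewer agreement
  (`hf_weighted_kappa()`, with `tidy()`/`glance()` methods).
* **A seeded synthetic cohort generator** (`generate_cohort()`): a mixture
  of eight clinical archetypes — acute presentations plus the documented
  false-positive mechanisms (stable chronic HF, renal BNP elevation,
  cardiac screening, respiratory disease, stable arrhythmia, post-operative
  circulatory support) — with latent judgement-level ground truth, plus a
  Monte-Carlo match-probability oracle (`expected_match_probability()`)
  for parameter-recovery testing.

Reference results of the original three-hospital validation (the pooled
4×4 reviewer agreement table and the per-algorithm count/PPV/sensitivity
summaries) ship as data (`ahf_agreement()`, `ahf_reported_validity()`).

## Worked example

Generate a synthetic three-hospital cohort, run the screen and the full
algorithm panel on a 100-per-hospital chart-review sample, and compute the
validity report:

```r
library(ahfid)
library(dplyr)

cohort <- generate_cohort(n_patients = 2000, seed = 20210308)
panel  <- hf_run_panel(cohort$records, seed = 20210308, min_per_hospital = 100)
panel
#> <hf_panel>
#>   APC screen: 1731 of 1999 patients matched
#>   study population: 300 sampled case(s)
#>   possible cases per algorithm: ALG1=142 ALG10=188 ALG11=125 ...

report <- hf_validity_report(panel, cohort$adjudications, modes = "primary")
format_validity_report(report) |>
  select(algorithm_id, possible_cases, tp, fp, fn,
         ppv, ppv_ci_low, ppv_ci_high, sensitivity)
#> # A tibble: 19 × 9
#>   algorithm_id possible_cases    tp    fp    fn   ppv ppv_ci_low ppv_ci_high
#> 1 APC                     300    86   214     0  28.7       23.6        34.1
#> 2 ALG1                    142    76    66    10  53.5       45.0        61.9
#> 3 ALG2                    163    85    78     1  52.2       44.2        60.0
#> 4 ALG3                    137    82    55     4  59.8       51.1        68.1
#> 5 ALG4                    105    69    36    17  65.7       55.8        74.7
#> 6 ALG5                     99    79    20     7  79.8       70.5        87.2
#> # ... 13 more rows
```

Here 86 of the 300 sampled screen positives are adjudicated true in the
primary analysis (screen PPV 28.7%), and each algorithm trades PPV against
sensitivity relative to those 86 anchored true cases — e.g. ALG2 recovers
85 of them (sensitivity 98.8% on this synthetic mixture) at PPV 52.2%.

Inter-reviewer agreement, on the simulated reviews and on the reference
table from the original validation:

```r
glance(hf_weighted_kappa(cohort$adjudications))
#> # A tibble: 1 × 7
#>   kappa std.error conf.low conf.high p.observed p.expected     n
#> 1 0.980   0.00198    0.977     0.984      0.994      0.703  2000

hf_weighted_kappa(ahf_agreement())
#> Quadratic-weighted (Fleiss-Cohen) kappa
#>   kappa = 0.9393  (SE 0.0184, 95% CI 0.9033-0.9753), n = 348
```

`autoplot(report)` draws the PPV/sensitivity forest plot and
`plot_agreement(ahf_agreement())` the reviewer cross-tabulation.

See the vignette (`vignettes/acute-hf-phenotyping.Rmd`) for the model, the
decisions behind window and threshold boundaries, and what the synthetic
cohort does and does not emulate.

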