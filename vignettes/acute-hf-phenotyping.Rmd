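---
title: "Phenotyping acute heart failure from multi-source hospital data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping acute heart failure from multi-source hospital data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahfid)
library(dplyr)
```

## The problem

Pharmacoepidemiological studies of acute heart failure (AHF) — including
acute exacerbations of chronic heart failure — need to find cases in
hospital information systems without reading every chart. Japanese
multi-hospital databases hold three coded sources per patient:
SS-MIX2-standardised electronic medical records (diagnoses with a
*suspected* modifier, drug orders, laboratory results), DPC case-mix data
(ICD-10 diagnoses in six defined fields, dated by admission), and health
insurance claims (diagnoses, drugs, procedures). None of these is a
diagnosis: an ICD-10 code for congestive heart failure cannot by itself
separate an acute decompensation from stable chronic disease, a renal
patient with elevated BNP, or a billing code attached to authorise a blood
test.

`ahfid` implements a family of rule-based identification algorithms over
these sources, together with the machinery used to validate them: a broad
screening definition whose positives are chart-reviewed, an ordinal
chart-review classification, and validity statistics with exact intervals.
Because the patient-level data behind the original validation are not
public, the package also ships a seeded synthetic cohort generator with
latent ground truth, so the entire pipeline is exercisable and testable
end-to-end.

## Data model

Records arrive as four tidy tables (`hf_records()`): diagnoses, drugs, labs
and procedures, each keyed by `(hospital_id, patient_id)`. Design choices a
user should know:

* **One case per patient.** A patient is at most one case within the study
  period; the pipeline evaluates patients, not admissions.
* **Dates.** DPC diagnoses are dated by admission date (even for
  complications arising during the stay); SS-MIX2 and claims rows by their
  recorded start date. All dates are ISO-8601 calendar days; windows are
  computed in whole days.
* **Codes are configuration.** The exact disease/drug/procedure code lists
  behind each condition are site-specific and not published, so every list
  lives in `hf_code_config()`; the shipped defaults are labelled
  placeholders (ICD-10 prefixes `I110`, `I130`, `I132`, `I50`; WHO-ATC-style
  drug classes). ICD-10 matching is by prefix, the standard dialect for code
  families. The configuration enforces the class hierarchy: loop and
  potassium-sparing diuretic codes must be subsets of the diuretics class.

## Conditions

Twenty-one atomic conditions generate dated evidence events
(`hf_condition_events()`): six diagnosis conditions (DPC any-field,
DPC three-field, SS-MIX2 with/without suspected names, claims, and DPC with
a stay of three or more days), eight drug classes (carperitide,
catecholamines/pimobendan, potassium-sparing diuretics, digitalis, any
diuretic, loop diuretics, tolvaptan, PDE inhibitors — any source), six
natriuretic-peptide thresholds, and transthoracic echocardiography (DPC or
claims only; SS-MIX2 carries no procedure records).

Two places needed a decision the published definitions leave open:

* **Threshold boundary ownership.** "Between 100 and 400 pg/ml" is
  implemented as the half-open interval `[100, 400)`, so the moderate and
  high bands partition the abnormal range exactly: every abnormal
  measurement satisfies precisely one band. A BNP of exactly 400 is "high",
  not "moderate". This keeps the two-branch algorithm designs mutually
  exclusive within a measurement and is asserted as a property test.
* **Length of stay.** "Three days or more" counts both admission and
  discharge day (`stay = discharge − admission + 1`), the Japanese
  hospital-day convention, so a two-night admission qualifies. A DPC record
  without a discharge date conservatively never satisfies the
  length-of-stay condition.

## Algorithms, index dates and windows

An algorithm (`hf_algorithm_spec()`) is a disjunction of branches; each
branch conjoins condition groups; a group is satisfied by at least one
in-window event among its members. The built-in registry
(`hf_algorithms()`) holds the All-Possible-Cases screen plus the eighteen
identification designs; the registry can be replaced from YAML for other
code systems or variants.

* **Index date.** The earliest qualifying diagnosis date for the
  algorithm's disease conditions, one per patient and algorithm — even when
  a later diagnosis would let more conditions fall in-window. This follows
  the "first date of diagnosis" rule and keeps evaluation deterministic.
* **Windows.** Symmetric and inclusive: "within 28 days" means
  `[index − 14, index + 14]`. Inclusive bounds are the conventional reading
  and make the boundary testable (an event exactly 14 days out matches; 15
  days out does not).
* **Conjunctions across dates.** "Digitalis *and* a diuretic" does not
  require same-day records; each conjunct is independently in-window.
* **The screen's index set.** The screen's written definition combines a
  diagnosis in *any* source with an abnormal peptide value, yet anchors the
  index on the DPC/EMR diagnosis dates only. For claims-only patients the
  definition provides no anchor; the package falls back to the earliest
  claims diagnosis date and flags such rows `index_fallback = TRUE`. This
  is a documented package choice, not part of the written definition.
* **Evidence.** For a matched patient the evaluator reports one qualifying
  event per group of the first satisfied branch (branches in printed
  order); ties within a group resolve to the earliest date, then the
  group's condition order, then record order. Matching itself is
  order-independent.

The vectorised evaluator is checked against a naive enumerator (loops over
branches, groups and events) on 1,000 randomised boundary-rich bundles for
all nineteen designs, and the family's structural guarantees — widening a
window or dropping a conjunct can only add matches — are asserted on every
synthetic cohort the tests generate.

## Chart review and validity statistics

Chart reviews classify each sampled case by three judgements (Framingham
criteria; comprehensive clinical assessment; treatment for acute HF) into
the ordered categories True A, True B, Suspected, Other
(`classify_case()`). The mapping is total: treatment-negative cases are
Other regardless of the other judgements; the published branch labels
beyond the three quoted rules are not recoverable, so the catch-all to
Other is a stated assumption. The primary analysis counts True A/B as true;
the sensitivity analysis also counts Suspected.

Validity is computed under the screen-anchored design
(`hf_confusion()`, `hf_validity_report()`): the adjudicated sample of
screen positives is assumed to contain every true case (a 100%-sensitive
screen), so false negatives are unmatched true cases *within that sample*,
and true negatives exist only relative to a supplied total patient count —
the package therefore computes NPV and specificity only when
`total_population` is given, and never invents a denominator.

* **Intervals.** All proportions get central exact (Clopper–Pearson)
  95% intervals via beta quantiles; the test suite cross-checks against
  direct binomial-tail inversion by bisection.
* **Agreement.** Inter-reviewer agreement is the quadratic-weighted
  (Fleiss–Cohen) kappa over the ordinal categories. The published analysis
  names the statistic but not the interval method; the package uses the
  Fleiss–Cohen–Everitt large-sample standard error with a normal
  approximation truncated to `[-1, 1]`, which reproduces the published
  interval. A table with all mass in one cell leaves kappa undefined
  (`NA`), flagged rather than thrown.
* **Rounding.** Percentages are held at full precision and rounded only at
  presentation (`format_validity_report()`), half away from zero to match
  SAS-style printed tables; base R's round-half-to-even would disagree at
  `.005` boundaries.

## The synthetic cohort

`generate_cohort()` emulates a screened hospital population as a seeded
mixture of eight archetypes: the two genuinely acute presentations plus the
six false-positive mechanisms reported from chart review (stable chronic
heart failure, renal-failure BNP elevation, cardiac-function screening,
respiratory disease, stable arrhythmia, post-operative circulatory
support). Each archetype sets source-specific diagnosis probabilities,
log-normal peptide distributions straddling the 100/400 and 400/3,000
pg/ml thresholds (e.g. acute BNP median 600 pg/ml, stable chronic 180,
renal 300 — the published definitions give thresholds, not distributions,
so these are package defaults chosen once), drug-product exposures,
echocardiography probability, and uniform event-date offsets around an
anchor date drawn from the study period, wide enough to exercise window
boundaries.

Ground truth is drawn archetype-conditionally and *independently of the
emitted records*: each patient's three judgements are Bernoulli draws with
archetype-specific probabilities, classified by the same `classify_case()`
the pipeline uses. This independence is deliberate — it makes the
mixture algebra of expected PPV and sensitivity exact, so
`expected_match_probability()` (a Monte-Carlo per-archetype match-rate
oracle) yields closed-form targets that cohort-level estimates must
recover within sampling error. Reviewer disagreement is simulated by
moving one reviewer to an adjacent ordinal category with probability 0.06,
matching the ~6% off-diagonal mass of the pooled published review table.

What the generator does *not* emulate: clinically realistic trajectories,
correlations between judgements and the specific records reviewers would
see, seasonality (AHF incidence is temperature-dependent), episode
structure (multiple admissions per patient), or hospital-level case-mix
differences. Passing recovery tests therefore demonstrates that the
pipeline's arithmetic is right, not that the algorithms would achieve any
particular PPV on real data.

## Problem sizes and numerical choices

The test suite runs the enumerator comparison on 1,000 random bundles,
structural-monotonicity checks on a 1,200-patient cohort, and parameter
recovery on 2,000-patient cohorts against per-archetype Monte-Carlo oracles
of 3,000 draws, with recovery asserted within three standard errors
(empirical and oracle variances combined by the delta method). These sizes
give comfortable statistical resolution for the checks while keeping a
desk-scale run; all randomness flows from fixed integer seeds, and the
generator and samplers restore the caller's RNG state.

Degenerate inputs are defined rather than accidental: patients with no
qualifying diagnosis have no index date and never match; empty record files
read as empty tables; zero denominators flag a measure undefined; sampling
more cases than a hospital holds returns all of them.

## Limitations

The shipped code lists are placeholders, to be replaced with site lists
before any real extraction. The pipeline is patient-level, not
episode-level. The screen-anchored sensitivity is relative to the screen's
own catchment: true cases the screen misses (no coded diagnosis, or no
peptide measurement within ±30 days) are invisible to every downstream
estimate, which is exactly the 100%-sensitivity assumption the published
design states. Claims diagnoses with suspected-name semantics are included
in the claims condition — the source format carries no such flag — which
may overcount in systems that do record it.
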