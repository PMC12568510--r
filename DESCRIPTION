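Package: ahfid
Title: Multi-Source EHR Phenotyping Algorithms for Acute Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based electronic-health-record phenotyping of acute heart
    failure (and acute exacerbation of chronic heart failure) from three
    linked hospital data sources: SS-MIX2-standardised electronic medical
    records, DPC case-mix data, and health-insurance claims. Implements the
    broad All-Possible-Cases screen and eighteen identification algorithms
    built from coded diagnoses, natriuretic-peptide thresholds, drug-class
    exposures and echocardiography within symmetric day windows around an
    index diagnosis date; the three-judgement chart-review classification of
    cases; validity statistics (PPV, sensitivity, NPV, specificity) with
    Clopper-Pearson exact confidence intervals; quadratic-weighted
    (Fleiss-Cohen) kappa for inter-reviewer agreement; and a seeded synthetic
    cohort generator with latent ground truth for end-to-end testing of the
    pipeline without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
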