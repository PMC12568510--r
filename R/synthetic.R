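#' Archetype configuration for the synthetic cohort
#'
#' The generator draws each patient from a mixture of eight clinical
#' archetypes chosen to reproduce the mechanisms that drive true and false
#' positives in acute-HF phenotyping: genuinely acute patients, and the
#' documented false-positive patterns — stable chronic heart failure without
#' exacerbation, BNP elevated by renal failure, cardiac-function screening
#' (e.g. before or during cancer treatment), respiratory disease, stable
#' treated arrhythmia, and post-operative circulatory support.
#'
#' Each archetype sets the probability of carrying an HF diagnosis in each
#' source (with DPC field and suspected-flag behaviour), log-normal
#' natriuretic-peptide distributions positioned around the 100/400 (BNP) and
#' 400/3000 (NT-proBNP) pg/ml decision thresholds, per-product drug exposure
#' probabilities, an echocardiography probability, uniform event-date offsets
#' relative to the patient's anchor date, and the three judgement
#' probabilities that determine the chart-review category via
#' [classify_case()].
#'
#' @param name One of `ACUTE_HF`, `ACUTE_ON_CHRONIC_HF`, `STABLE_CHRONIC_HF`,
#'   `RENAL_FAILURE_HIGH_BNP`, `CARDIAC_SCREENING`, `RESPIRATORY_DISEASE`,
#'   `STABLE_ARRHYTHMIA`, `POSTOP_CIRCULATORY`.
#' @param weight Non-negative mixture proportion (weights of a mixture must
#'   sum to 1).
#' @param p_dpc,p_ssmix,p_claims Probability of an HF diagnosis record in
#'   each source.
#' @param dpc_field_probs Probability vector over the six DPC diagnosis
#'   fields (normalised internally).
#' @param p_discharge Probability a DPC record carries a discharge date.
#' @param stay_range Inclusive range (days, admission and discharge counted)
#'   of the length of stay when a discharge date is present.
#' @param p_ssmix_suspected Probability the SS-MIX2 diagnosis is flagged
#'   suspected.
#' @param diag_offset_range Uniform day-offset range of diagnosis dates
#'   relative to the anchor date.
#' @param p_lab Probability the patient has any natriuretic-peptide result.
#' @param n_labs_range Range of the number of results when present.
#' @param p_bnp Probability a result is BNP (otherwise NT-proBNP).
#' @param bnp_median,bnp_sdlog,nt_median,nt_sdlog Log-normal location
#'   (median, pg/ml) and scale of the two analytes.
#' @param lab_offset_range Uniform day-offset range of lab dates.
#' @param drug_probs Named exposure probabilities for the eight generated
#'   drug products: `carperitide`, `catecholamine`, `ksparing`, `digitalis`,
#'   `thiazide`, `loop`, `tolvaptan`, `pde` (a loop or potassium-sparing
#'   diuretic is also a diuretic, so those records satisfy both conditions).
#' @param drug_offset_range Uniform day-offset range of drug dates.
#' @param p_tte Probability of a transthoracic echocardiogram (DPC or
#'   claims).
#' @param tte_offset_range Uniform day-offset range of the echo date.
#' @param p_j1_pos,p_j2_pos,p_j3_pos Probabilities that Judgement 1/2/3 is
#'   positive; drawn independently of the emitted records given the
#'   archetype.
#' @return A list of class `hf_archetype`.
#' @seealso [hf_archetypes()] for the shipped mixture,
#'   [generate_cohort()] for the generator.
#' @export
hf_archetype <- function(name, weight,
                         p_dpc = 0, dpc_field_probs = c(1, 1, 1, 0.5, 0.5, 0.5),
                         p_discharge = 0.9, stay_range = c(5, 21),
                         p_ssmix = 0, p_ssmix_suspected = 0.1,
                         p_claims = 0,
                         diag_offset_range = c(-2, 2),
                         p_lab = 1, n_labs_range = c(1, 3), p_bnp = 0.8,
                         bnp_median = 300, bnp_sdlog = 0.5,
                         nt_median = 2000, nt_sdlog = 0.5,
                         lab_offset_range = c(-5, 7),
                         drug_probs = c(carperitide = 0, catecholamine = 0,
                                        ksparing = 0, digitalis = 0,
                                        thiazide = 0, loop = 0,
                                        tolvaptan = 0, pde = 0),
                         drug_offset_range = c(-3, 10),
                         p_tte = 0, tte_offset_range = c(-3, 7),
                         p_j1_pos = 0, p_j2_pos = 0, p_j3_pos = 0) {
  archetype_names <- c("ACUTE_HF", "ACUTE_ON_CHRONIC_HF", "STABLE_CHRONIC_HF",
                       "RENAL_FAILURE_HIGH_BNP", "CARDIAC_SCREENING",
                       "RESPIRATORY_DISEASE", "STABLE_ARRHYTHMIA",
                       "POSTOP_CIRCULATORY")
  if (!name %in% archetype_names) {
    abort(sprintf("unknown archetype `%s`", name))
  }
  if (weight < 0) abort("`weight` must be non-negative")
  products <- c("carperitide", "catecholamine", "ksparing", "digitalis",
                "thiazide", "loop", "tolvaptan", "pde")
  dp <- rep(0, 8); names(dp) <- products
  dp[names(drug_probs)] <- drug_probs
  if (any(is.na(dp))) abort("unknown drug product in `drug_probs`")
  structure(
    list(name = name, weight = weight,
         p_dpc = p_dpc,
         dpc_field_probs = dpc_field_probs / sum(dpc_field_probs),
         p_discharge = p_discharge, stay_range = stay_range,
         p_ssmix = p_ssmix, p_ssmix_suspected = p_ssmix_suspected,
         p_claims = p_claims, diag_offset_range = diag_offset_range,
         p_lab = p_lab, n_labs_range = n_labs_range, p_bnp = p_bnp,
         bnp_median = bnp_median, bnp_sdlog = bnp_sdlog,
         nt_median = nt_median, nt_sdlog = nt_sdlog,
         lab_offset_range = lab_offset_range,
         drug_probs = dp, drug_offset_range = drug_offset_range,
         p_tte = p_tte, tte_offset_range = tte_offset_range,
         p_j1_pos = p_j1_pos, p_j2_pos = p_j2_pos, p_j3_pos = p_j3_pos),
    class = "hf_archetype"
  )
}

#' Default archetype mixture
#'
#' A mixture of the eight archetypes whose weights and parameters emulate a
#' screened hospital population in which roughly a quarter of APC-screened
#' patients are genuinely acute: acute patients carry confirmed diagnoses,
#' high peptides (BNP median 600 pg/ml) and intravenous acute-HF drugs within
#' days of the anchor admission; stable chronic patients carry HF diagnoses
#' with moderate peptides (median 180) and oral diuretics only; renal-failure
#' patients have elevated BNP (median 300) without acute-HF treatment;
#' screening/respiratory/arrhythmia patients have lower peptide
#' distributions, frequent echocardiography and suspected-flagged or
#' claims-only diagnoses; post-operative patients receive carperitide or
#' catecholamines around surgery without heart-failure symptoms.
#'
#' @return Named list of [hf_archetype()] objects whose weights sum to 1.
#' @export
hf_archetypes <- function() {
  a <- list(
    hf_archetype("ACUTE_HF", 0.18,
      p_dpc = 0.90, dpc_field_probs = c(4, 3, 3, 1, 0.5, 0.5),
      p_ssmix = 0.85, p_ssmix_suspected = 0.05, p_claims = 0.90,
      diag_offset_range = c(-2, 2),
      p_lab = 0.97, p_bnp = 0.8, bnp_median = 600, bnp_sdlog = 0.6,
      nt_median = 5000, nt_sdlog = 0.6, lab_offset_range = c(-3, 7),
      drug_probs = c(carperitide = 0.45, catecholamine = 0.30,
                     ksparing = 0.25, digitalis = 0.10, thiazide = 0.10,
                     loop = 0.90, tolvaptan = 0.20, pde = 0.05),
      drug_offset_range = c(-2, 10),
      p_tte = 0.85, p_j1_pos = 0.75, p_j2_pos = 0.90, p_j3_pos = 0.97),
    hf_archetype("ACUTE_ON_CHRONIC_HF", 0.07,
      p_dpc = 0.85, dpc_field_probs = c(3, 3, 3, 1, 1, 1),
      p_ssmix = 0.90, p_ssmix_suspected = 0.05, p_claims = 0.90,
      diag_offset_range = c(-3, 3),
      p_lab = 0.97, p_bnp = 0.75, bnp_median = 500, bnp_sdlog = 0.6,
      nt_median = 4000, nt_sdlog = 0.6, lab_offset_range = c(-5, 10),
      drug_probs = c(carperitide = 0.35, catecholamine = 0.20,
                     ksparing = 0.30, digitalis = 0.15, thiazide = 0.15,
                     loop = 0.92, tolvaptan = 0.30, pde = 0.05),
      drug_offset_range = c(-5, 12),
      p_tte = 0.80, p_j1_pos = 0.55, p_j2_pos = 0.88, p_j3_pos = 0.95),
    hf_archetype("STABLE_CHRONIC_HF", 0.25,
      p_dpc = 0.15, p_ssmix = 0.90, p_ssmix_suspected = 0.20, p_claims = 0.85,
      diag_offset_range = c(-5, 5),
      p_lab = 0.95, p_bnp = 0.8, bnp_median = 180, bnp_sdlog = 0.5,
      nt_median = 1200, nt_sdlog = 0.5, lab_offset_range = c(-10, 10),
      drug_probs = c(ksparing = 0.25, digitalis = 0.10, thiazide = 0.20,
                     loop = 0.70, tolvaptan = 0.10),
      drug_offset_range = c(-14, 14),
      p_tte = 0.40, p_j1_pos = 0.02, p_j2_pos = 0.20, p_j3_pos = 0.10),
    hf_archetype("RENAL_FAILURE_HIGH_BNP", 0.12,
      p_dpc = 0.10, p_ssmix = 0.60, p_ssmix_suspected = 0.60, p_claims = 0.70,
      diag_offset_range = c(-4, 4),
      p_lab = 0.95, p_bnp = 0.85, bnp_median = 300, bnp_sdlog = 0.6,
      nt_median = 2500, nt_sdlog = 0.7, lab_offset_range = c(-7, 10),
      drug_probs = c(loop = 0.60, thiazide = 0.10, ksparing = 0.05),
      drug_offset_range = c(-10, 14),
      p_tte = 0.30, p_j1_pos = 0.02, p_j2_pos = 0.08, p_j3_pos = 0.06),
    hf_archetype("CARDIAC_SCREENING", 0.15,
      p_dpc = 0.05, p_ssmix = 0.50, p_ssmix_suspected = 0.80, p_claims = 0.90,
      diag_offset_range = c(-1, 1),
      p_lab = 0.98, p_bnp = 0.8, bnp_median = 130, bnp_sdlog = 0.5,
      nt_median = 700, nt_sdlog = 0.6, lab_offset_range = c(-2, 2),
      drug_probs = c(loop = 0.08, thiazide = 0.05),
      drug_offset_range = c(-20, 20),
      p_tte = 0.90, p_j1_pos = 0.01, p_j2_pos = 0.05, p_j3_pos = 0.03),
    hf_archetype("RESPIRATORY_DISEASE", 0.10,
      p_dpc = 0.25, dpc_field_probs = c(1, 1, 1, 2, 2, 1),
      p_ssmix = 0.55, p_ssmix_suspected = 0.55, p_claims = 0.70,
      diag_offset_range = c(-3, 3),
      p_lab = 0.90, p_bnp = 0.75, bnp_median = 160, bnp_sdlog = 0.6,
      nt_median = 900, nt_sdlog = 0.7, lab_offset_range = c(-4, 8),
      drug_probs = c(loop = 0.30, catecholamine = 0.05),
      drug_offset_range = c(-4, 10),
      p_tte = 0.35, p_j1_pos = 0.03, p_j2_pos = 0.08, p_j3_pos = 0.06),
    hf_archetype("STABLE_ARRHYTHMIA", 0.08,
      p_dpc = 0.10, p_ssmix = 0.75, p_ssmix_suspected = 0.30, p_claims = 0.80,
      diag_offset_range = c(-5, 5),
      p_lab = 0.92, p_bnp = 0.8, bnp_median = 150, bnp_sdlog = 0.5,
      nt_median = 800, nt_sdlog = 0.6, lab_offset_range = c(-8, 8),
      drug_probs = c(digitalis = 0.25, loop = 0.20, thiazide = 0.10),
      drug_offset_range = c(-12, 12),
      p_tte = 0.60, p_j1_pos = 0.02, p_j2_pos = 0.06, p_j3_pos = 0.04),
    hf_archetype("POSTOP_CIRCULATORY", 0.05,
      p_dpc = 0.60, dpc_field_probs = c(0.5, 0.5, 1, 1, 1, 4),
      p_ssmix = 0.45, p_ssmix_suspected = 0.35, p_claims = 0.60,
      diag_offset_range = c(-1, 3),
      p_lab = 0.92, p_bnp = 0.7, bnp_median = 350, bnp_sdlog = 0.7,
      nt_median = 2500, nt_sdlog = 0.8, lab_offset_range = c(-2, 6),
      drug_probs = c(carperitide = 0.55, catecholamine = 0.55, loop = 0.45,
                     pde = 0.10),
      drug_offset_range = c(-2, 8),
      p_tte = 0.70, p_j1_pos = 0.03, p_j2_pos = 0.12, p_j3_pos = 0.20)
  )
  stats::setNames(a, vapply(a, `[[`, character(1), "name"))
}

# product -> concrete drug code, derived from the code config so generated
# records always fall in the configured classes
product_codes <- function(config) {
  pure_diuretic <- setdiff(config$drug_class_codes$DRUG5,
                           c(config$drug_class_codes$DRUG6,
                             config$drug_class_codes$DRUG3))
  c(carperitide = config$drug_class_codes$DRUG1[[1]],
    catecholamine = config$drug_class_codes$DRUG2[[1]],
    ksparing = config$drug_class_codes$DRUG3[[1]],
    digitalis = config$drug_class_codes$DRUG4[[1]],
    thiazide = if (length(pure_diuretic)) pure_diuretic[[1]]
               else config$drug_class_codes$DRUG5[[1]],
    loop = config$drug_class_codes$DRUG6[[1]],
    tolvaptan = config$drug_class_codes$DRUG7[[1]],
    pde = config$drug_class_codes$DRUG8[[1]])
}

hf_code_for <- function(config) {
  p <- config$hf_disease_codes[[1]]
  if (nchar(p) < 4) paste0(p, "0") else p
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

# all records for a block of same-archetype patients, generated column-wise
generate_archetype_block <- function(a, pid, hid, anchor, config, codes, hf_code) {
  n <- length(pid)
  dx <- list(); drg <- NULL; lab <- NULL; prc <- NULL

  has <- stats::runif(n) < a$p_dpc
  if (any(has)) {
    m <- sum(has)
    adm <- anchor[has] + runif_int(m, a$diag_offset_range)
    disch <- rep(as.Date(NA), m)
    hd <- stats::runif(m) < a$p_discharge
    disch[hd] <- adm[hd] + runif_int(sum(hd), a$stay_range) - 1L
    dx$dpc <- tibble::tibble(
      patient_id = pid[has], hospital_id = hid[has], source = "DPC",
      icd10_code = hf_code, date = adm, suspected = NA,
      dpc_field = sample(dpc_fields, m, replace = TRUE,
                         prob = a$dpc_field_probs),
      discharge_date = disch)
  }
  has <- stats::runif(n) < a$p_ssmix
  if (any(has)) {
    m <- sum(has)
    dx$ssmix <- tibble::tibble(
      patient_id = pid[has], hospital_id = hid[has], source = "SSMIX2",
      icd10_code = hf_code,
      date = anchor[has] + runif_int(m, a$diag_offset_range),
      suspected = stats::runif(m) < a$p_ssmix_suspected,
      dpc_field = NA_character_, discharge_date = as.Date(NA))
  }
  has <- stats::runif(n) < a$p_claims
  if (any(has)) {
    m <- sum(has)
    dx$claims <- tibble::tibble(
      patient_id = pid[has], hospital_id = hid[has], source = "CLAIMS",
      icd10_code = hf_code,
      date = anchor[has] + runif_int(m, a$diag_offset_range),
      suspected = NA, dpc_field = NA_character_, discharge_date = as.Date(NA))
  }

  has <- stats::runif(n) < a$p_lab
  if (any(has)) {
    counts <- runif_int(sum(has), a$n_labs_range)
    take <- rep(which(has), counts)
    m <- length(take)
    is_bnp <- stats::runif(m) < a$p_bnp
    value <- ifelse(is_bnp,
                    stats::rlnorm(m, log(a$bnp_median), a$bnp_sdlog),
                    stats::rlnorm(m, log(a$nt_median), a$nt_sdlog))
    lab <- tibble::tibble(
      patient_id = pid[take], hospital_id = hid[take],
      analyte = ifelse(is_bnp, "BNP", "NTPROBNP"),
      value = value, date = anchor[take] + runif_int(m, a$lab_offset_range))
  }

  drg_parts <- list()
  for (prod in names(a$drug_probs)) {
    p <- a$drug_probs[[prod]]
    if (p <= 0) next
    has <- stats::runif(n) < p
    if (!any(has)) next
    m <- sum(has)
    drg_parts[[prod]] <- tibble::tibble(
      patient_id = pid[has], hospital_id = hid[has],
      source = sample(source_tags, m, replace = TRUE),
      drug_code = codes[[prod]],
      date = anchor[has] + runif_int(m, a$drug_offset_range))
  }
  if (length(drg_parts) > 0) drg <- dplyr::bind_rows(drg_parts)

  has <- stats::runif(n) < a$p_tte
  if (any(has)) {
    m <- sum(has)
    prc <- tibble::tibble(
      patient_id = pid[has], hospital_id = hid[has],
      source = sample(c("DPC", "CLAIMS"), m, replace = TRUE),
      procedure_code = config$tte_procedure_codes[[1]],
      date = anchor[has] + runif_int(m, a$tte_offset_range))
  }
  list(diagnoses = dplyr::bind_rows(dx), drugs = drg, labs = lab,
       procedures = prc)
}

#' Generate a synthetic multi-hospital cohort with latent ground truth
#'
#' Draws `n_patients` patients from the archetype mixture, emits their record
#' tables, and assigns each patient a latent judgement set (and hence a final
#' chart-review category via [classify_case()]) from the archetype's
#' judgement probabilities — independently of the emitted records, which
#' keeps the mixture algebra of match probabilities exact for
#' parameter-recovery checks. Reviewer disagreement is simulated by moving
#' one reviewer's category to an adjacent ordinal category with probability
#' `disagreement_rate`; the final category is the latent truth.
#'
#' Identical `(archetypes, n_patients, n_hospitals, period, seed)` yield an
#' identical cohort; the caller's RNG state is left untouched.
#'
#' @param archetypes List of [hf_archetype()]s; weights must sum to 1.
#' @param n_patients Number of patients to generate.
#' @param n_hospitals Number of hospitals (labelled `A`, `B`, ...).
#' @param period Length-2 date vector; anchor dates are uniform over it.
#' @param seed Integer seed (required).
#' @param config Code configuration used to pick concrete codes.
#' @param disagreement_rate Probability of an adjacent-category reviewer
#'   disagreement (default 0.06, matching the ~6% off-diagonal mass seen in
#'   pooled chart reviews of this design).
#' @return A list of class `hf_cohort`: `records` ([hf_records()]), `truth`
#'   (patient, hospital, archetype, judgements, final category) and
#'   `adjudications` (reviewer A/B and final categories).
#' @examples
#' coh <- generate_cohort(n_patients = 50, seed = 1)
#' coh$records
#' dplyr::count(coh$truth, archetype, final)
#' @export
generate_cohort <- function(archetypes = hf_archetypes(), n_patients,
                            n_hospitals = 3,
                            period = as.Date(c("2021-03-08", "2021-03-31")),
                            seed, config = default_code_config(),
                            disagreement_rate = 0.06) {
  if (missing(seed)) abort("`seed` is required")
  n_patients <- stopifnot_scalar_int(n_patients, "n_patients")
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  weights <- vapply(archetypes, `[[`, numeric(1), "weight")
  if (abs(sum(weights) - 1) > 1e-8) {
    abort(sprintf("archetype weights must sum to 1 (got %.6f)", sum(weights)))
  }
  period <- as.Date(period)
  codes <- product_codes(config)
  hf_code <- hf_code_for(config)

  with_preserved_seed({
    set.seed(seed)
    pid <- sprintf("P%06d", seq_len(n_patients))
    hid <- LETTERS[sample.int(n_hospitals, n_patients, replace = TRUE)]
    arch_idx <- sample.int(length(archetypes), n_patients, replace = TRUE,
                           prob = weights)
    anchor <- period[1] +
      sample.int(as.integer(period[2] - period[1]) + 1L, n_patients,
                 replace = TRUE) - 1L

    parts <- vector("list", length(archetypes))
    j1 <- j2 <- j3 <- character(n_patients)
    for (k in seq_along(archetypes)) {
      a <- archetypes[[k]]
      sel <- which(arch_idx == k)
      if (length(sel) == 0) next
      parts[[k]] <- generate_archetype_block(a, pid[sel], hid[sel],
                                             anchor[sel], config, codes,
                                             hf_code)
      j1[sel] <- ifelse(stats::runif(length(sel)) < a$p_j1_pos,
                        "POSITIVE", "INCONCLUSIVE")
      j2[sel] <- ifelse(stats::runif(length(sel)) < a$p_j2_pos,
                        "POSITIVE", "INCONCLUSIVE")
      j3[sel] <- ifelse(stats::runif(length(sel)) < a$p_j3_pos,
                        "POSITIVE", "NEGATIVE")
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    final <- classify_case(j1, j2, j3)
    reviewer_b <- perturb_adjacent(final, disagreement_rate)

    nonempty <- function(x) if (is.null(x) || nrow(x) == 0) NULL else x
    records <- hf_records(
      diagnoses = nonempty(dplyr::bind_rows(purrr::map(parts, "diagnoses"))),
      drugs = nonempty(dplyr::bind_rows(purrr::map(parts, "drugs"))),
      labs = nonempty(dplyr::bind_rows(purrr::map(parts, "labs"))),
      procedures = nonempty(dplyr::bind_rows(purrr::map(parts, "procedures")))
    )
    truth <- tibble::tibble(
      patient_id = pid, hospital_id = hid,
      archetype = vapply(archetypes, `[[`, character(1), "name")[arch_idx],
      j1 = j1, j2 = j2, j3 = j3, final = final)
    adjudications <- tibble::tibble(
      patient_id = pid, hospital_id = hid,
      reviewer_a = final, reviewer_b = reviewer_b, final = final)
    structure(list(records = records, truth = truth,
                   adjudications = adjudications),
              class = "hf_cohort")
  })
}

# move a category to a random adjacent ordinal category with probability p
perturb_adjacent <- function(category, p) {
  idx <- match(as.character(category), case_categories)
  flip <- stats::runif(length(idx)) < p
  step <- ifelse(stats::runif(length(idx)) < 0.5, -1L, 1L)
  moved <- pmin(pmax(idx + step, 1L), length(case_categories))
  # at the ends the only adjacent category is inward
  moved[moved == idx] <- idx[moved == idx] +
    ifelse(idx[moved == idx] == 1L, 1L, -1L)
  out <- idx
  out[flip] <- moved[flip]
  factor(case_categories[out], levels = case_categories, ordered = TRUE)
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat("<hf_cohort>", nrow(x$truth), "patient(s),",
      length(unique(x$truth$hospital_id)), "hospital(s)\n")
  print(table(x$truth$archetype))
  invisible(x)
}

#' Monte-Carlo match probability of an archetype
#'
#' Simulates `n_mc` single-archetype patients and reports, for each
#' algorithm, the fraction that it matches — the oracle against which
#' cohort-level PPV and sensitivity estimates are checked: if archetype `k`
#' has mixture weight `w_k`, truth probability `t_k` and (APC-joint) match
#' probability `q_ak`, the expected PPV of algorithm `a` in the screened
#' population is `sum_k w_k q_ak t_k / sum_k w_k q_ak`.
#'
#' @param archetype An [hf_archetype()].
#' @param algorithms A single [hf_algorithm_spec()] or a named list of them.
#' @param config Code configuration.
#' @param n_mc Number of Monte-Carlo patients.
#' @param seed Integer seed (required).
#' @param within_apc If `TRUE`, report the probability of matching the
#'   algorithm *and* the APC screen (the relevant quantity inside the
#'   screened study population); if `FALSE`, the marginal match probability.
#' @return Tibble with `algorithm_id`, `prob`, `n_mc`.
#' @export
expected_match_probability <- function(archetype, algorithms = hf_algorithms(),
                                       config = default_code_config(),
                                       n_mc = 1000, seed,
                                       within_apc = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  if (inherits(algorithms, "hf_algorithm_spec")) {
    algorithms <- stats::setNames(list(algorithms), algorithms$algorithm_id)
  }
  n_mc <- stopifnot_scalar_int(n_mc, "n_mc")
  arch <- archetype
  arch$weight <- 1
  coh <- generate_cohort(list(arch), n_patients = n_mc, n_hospitals = 1,
                         seed = seed, config = config)
  events <- hf_condition_events(coh$records, config)
  patients <- coh$truth[c("hospital_id", "patient_id")]
  apc_ok <- if (within_apc) {
    hf_evaluate_apc(events, patients = patients, evidence = FALSE)$matched
  } else rep(TRUE, n_mc)
  purrr::map(algorithms, function(spec) {
    res <- hf_evaluate(events, spec, patients = patients, evidence = FALSE)
    tibble::tibble(algorithm_id = spec$algorithm_id,
                   prob = mean(res$matched & apc_ok), n_mc = n_mc)
  }) %>%
    dplyr::bind_rows()
}
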