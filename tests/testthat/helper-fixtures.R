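# Shared builders: tiny record sets, randomised small bundles, and a naive
# enumeration oracle for windowed algorithm evaluation. The oracle is kept
# deliberately loop-based and independent of the package's vectorised
# evaluator.

suppressPackageStartupMessages(library(dplyr))

`%||%` <- function(a, b) if (is.null(a)) b else a

CATS <- c("TRUE_A", "TRUE_B", "SUSPECTED", "OTHER")
DPC_FIELDS <- c("MAIN", "ADMISSION_PRECIPITATING", "MOST_RESOURCE",
                "SECOND_MOST_RESOURCE", "COMORBIDITY_ON_ADMISSION",
                "COMPLICATION_DURING_ADMISSION")

day0 <- as.Date("2021-03-15")

# presentation rounding used by the printed reference tables (half away
# from zero)
rh2 <- function(x) floor(x * 100 + 0.5) / 100

dx_row <- function(pid = "p1", hid = "A", source = "DPC", code = "I500",
                   date = day0, suspected = NA, dpc_field = if (source == "DPC") "MAIN" else NA_character_,
                   discharge = as.Date(NA)) {
  tibble::tibble(patient_id = pid, hospital_id = hid, source = source,
                 icd10_code = code, date = date, suspected = suspected,
                 dpc_field = dpc_field, discharge_date = discharge)
}

lab_row <- function(pid = "p1", hid = "A", analyte = "BNP", value, date = day0) {
  tibble::tibble(patient_id = pid, hospital_id = hid, analyte = analyte,
                 value = value, date = date)
}

drug_row <- function(pid = "p1", hid = "A", source = "SSMIX2", code, date = day0) {
  tibble::tibble(patient_id = pid, hospital_id = hid, source = source,
                 drug_code = code, date = date)
}

proc_row <- function(pid = "p1", hid = "A", source = "CLAIMS", code = "TTE001",
                     date = day0) {
  tibble::tibble(patient_id = pid, hospital_id = hid, source = source,
                 procedure_code = code, date = date)
}

# Randomised small record sets (a handful of records per patient) with
# boundary-rich dates, codes and lab values.
random_small_records <- function(n_patients, seed) {
  set.seed(seed)
  pid <- sprintf("p%05d", seq_len(n_patients))
  hid <- sample(c("A", "B", "C"), n_patients, replace = TRUE)
  rdate <- function(m) day0 + sample(-40:40, m, replace = TRUE)

  n_dx <- sample(0:3, n_patients, replace = TRUE)
  take <- rep(seq_len(n_patients), n_dx)
  m <- length(take)
  src <- sample(c("SSMIX2", "DPC", "CLAIMS"), m, replace = TRUE)
  date <- rdate(m)
  disch <- rep(as.Date(NA), m)
  has_disch <- src == "DPC" & stats::runif(m) < 0.7
  disch[has_disch] <- date[has_disch] + sample(0:12, sum(has_disch), replace = TRUE)
  dx <- tibble::tibble(
    patient_id = pid[take], hospital_id = hid[take], source = src,
    icd10_code = sample(c("I500", "I110", "J189", "N189"), m,
                        replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1)),
    date = date,
    suspected = ifelse(src == "SSMIX2", stats::runif(m) < 0.4, NA),
    dpc_field = ifelse(src == "DPC",
                       sample(DPC_FIELDS, m, replace = TRUE), NA_character_),
    discharge_date = disch)

  n_lab <- sample(0:3, n_patients, replace = TRUE)
  take <- rep(seq_len(n_patients), n_lab)
  m <- length(take)
  boundary_values <- c(50, 99, 100, 150, 399, 400, 401, 450,
                       2999, 3000, 3001, 5000)
  lb <- tibble::tibble(
    patient_id = pid[take], hospital_id = hid[take],
    analyte = sample(c("BNP", "NTPROBNP"), m, replace = TRUE),
    value = sample(boundary_values, m, replace = TRUE),
    date = rdate(m))

  n_drug <- sample(0:3, n_patients, replace = TRUE)
  take <- rep(seq_len(n_patients), n_drug)
  m <- length(take)
  dr <- tibble::tibble(
    patient_id = pid[take], hospital_id = hid[take],
    source = sample(c("SSMIX2", "DPC", "CLAIMS"), m, replace = TRUE),
    drug_code = sample(c("CARPERITIDE", "C01CA04", "C03DA01", "C01AA05",
                         "C03AA03", "C03CA01", "TOLVAPTAN", "C01CE02",
                         "ZZZ999"), m, replace = TRUE),
    date = rdate(m))

  n_pr <- sample(0:2, n_patients, replace = TRUE)
  take <- rep(seq_len(n_patients), n_pr)
  m <- length(take)
  pr <- tibble::tibble(
    patient_id = pid[take], hospital_id = hid[take],
    source = sample(c("DPC", "CLAIMS"), m, replace = TRUE),
    procedure_code = sample(c("TTE001", "XRAY01"), m, replace = TRUE),
    date = rdate(m))

  list(records = hf_records(diagnoses = dx, drugs = dr, labs = lb,
                            procedures = pr),
       patients = tibble::tibble(patient_id = pid, hospital_id = hid))
}

# Naive oracle: enumerate branches, groups and events one by one.
oracle_evaluate <- function(pevents, spec) {
  idx_dates <- pevents$date[pevents$condition %in% spec$index_group]
  if (length(idx_dates) == 0 && !is.null(spec$index_fallback_group)) {
    idx_dates <- pevents$date[pevents$condition %in% spec$index_fallback_group]
  }
  if (length(idx_dates) == 0) {
    return(list(matched = FALSE, index_date = as.Date(NA),
                branch = NA_integer_))
  }
  index <- min(idx_dates)
  branch <- NA_integer_
  for (b in seq_along(spec$branches)) {
    all_groups_ok <- TRUE
    for (g in spec$branches[[b]]) {
      group_ok <- FALSE
      for (r in seq_len(nrow(pevents))) {
        if (pevents$condition[r] %in% g &&
            abs(as.integer(pevents$date[r] - index)) <= spec$half_window_days) {
          group_ok <- TRUE
          break
        }
      }
      if (!group_ok) {
        all_groups_ok <- FALSE
        break
      }
    }
    if (all_groups_ok) {
      branch <- b
      break
    }
  }
  list(matched = !is.na(branch), index_date = index, branch = branch)
}

# An archetype that matches the APC screen with certainty and whose
# chart-review category is deterministic.
forced_apc_archetype <- function(name, weight, true_case) {
  hf_archetype(
    name, weight,
    p_dpc = 1, dpc_field_probs = c(1, 0, 0, 0, 0, 0), p_discharge = 1,
    stay_range = c(10, 10), p_ssmix = 1, p_ssmix_suspected = 0, p_claims = 1,
    diag_offset_range = c(0, 0),
    p_lab = 1, n_labs_range = c(1, 1), p_bnp = 1,
    bnp_median = 600, bnp_sdlog = 0, lab_offset_range = c(0, 0),
    drug_probs = c(loop = 1), drug_offset_range = c(0, 0),
    p_j1_pos = as.numeric(true_case), p_j2_pos = as.numeric(true_case),
    p_j3_pos = as.numeric(true_case)
  )
}
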