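#' Atomic phenotyping conditions
#'
#' Twenty-one dated conditions are the building blocks of every identification
#' algorithm. Each is evaluated against the record tables and yields zero or
#' more *condition events*, one per qualifying record, dated by that record's
#' date (admission date for DPC diagnoses).
#'
#' Diagnosis conditions (HF code = any configured ICD-10 prefix match):
#' * `DISEASE1` — HF code in DPC, any of the six diagnosis fields.
#' * `DISEASE2` — HF code in DPC, restricted to the three primary fields
#'   (main diagnosis, diagnosis causing admission, most resource-consuming).
#' * `DISEASE3` — HF code in SS-MIX2, suspected diagnoses included.
#' * `DISEASE4` — HF code in SS-MIX2, suspected diagnoses excluded.
#' * `DISEASE5` — HF code in health-insurance claims.
#' * `DISEASE6` — `DISEASE1` with a hospital stay of three days or more,
#'   counting both admission and discharge day
#'   (stay = discharge − admission + 1); records without a discharge date
#'   never qualify.
#'
#' Drug conditions `DRUG1`..`DRUG8` match drug records from *any* source whose
#' code falls in the configured class list (see [hf_code_config()]).
#'
#' Blood-test conditions threshold the natriuretic peptides (pg/ml):
#' `BLOOD1` BNP ≥ 100; `BLOOD2` BNP ≥ 400; `BLOOD3` 100 ≤ BNP < 400;
#' `BLOOD4` NT-proBNP ≥ 400; `BLOOD5` NT-proBNP ≥ 3000;
#' `BLOOD6` 400 ≤ NT-proBNP < 3000. The "between" bands are half-open on the
#' right so that \{`BLOOD2`, `BLOOD3`\} partitions `BLOOD1` exactly (and
#' \{`BLOOD5`, `BLOOD6`\} partitions `BLOOD4`): each measurement satisfies the
#' moderate or the high band, never both.
#'
#' `MEDPRACTICE1` matches transthoracic echocardiography codes in DPC or
#' claims (procedures are never sourced from SS-MIX2).
#'
#' @param records An [hf_records()] object.
#' @param config An [hf_code_config()]; defaults to the shipped placeholder
#'   lists.
#' @param conditions Character vector of condition identifiers to evaluate
#'   (default: all 21).
#' @return A tibble of condition events with columns `patient_id`,
#'   `hospital_id`, `condition`, `date`, `source`, `record_type`, `record_row`
#'   (row index into the originating table), ordered by patient, condition,
#'   date.
#' @examples
#' recs <- hf_records(labs = tibble::tibble(
#'   patient_id = "p1", hospital_id = "A", analyte = "BNP",
#'   value = 250, date = as.Date("2021-03-15")
#' ))
#' hf_condition_events(recs, conditions = c("BLOOD1", "BLOOD2", "BLOOD3"))
#' @export
hf_condition_events <- function(records, config = default_code_config(),
                                conditions = all_condition_ids) {
  stopifnot(inherits(records, "hf_records"), inherits(config, "hf_code_config"))
  bad <- setdiff(conditions, all_condition_ids)
  if (length(bad) > 0) {
    abort(sprintf("unknown condition id(s): %s", paste(bad, collapse = ", ")))
  }
  out <- purrr::map(conditions, function(id) match_condition(records, id, config))
  dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$hospital_id, .data$patient_id, .data$condition,
                   .data$date, .data$record_row)
}

#' Evaluate a single condition
#'
#' Lower-level entry point behind [hf_condition_events()]; dispatches on the
#' condition family. Calling it with an identifier from the wrong family (for
#' example asking `match_disease()` for a drug condition) is a contract error.
#'
#' @inheritParams hf_condition_events
#' @param id One condition identifier.
#' @return A tibble of condition events (possibly empty) for that condition.
#' @export
match_condition <- function(records, id, config = default_code_config()) {
  if (id %in% disease_ids) return(match_disease(records, id, config))
  if (id %in% drug_ids) return(match_drug(records, id, config))
  if (id %in% blood_ids) return(match_blood(records, id))
  if (id %in% practice_ids) return(match_procedure(records, config))
  abort(sprintf("unknown condition id: %s", id))
}

event_tibble <- function(rows, id, record_type, date = rows$date,
                         source = rows$source) {
  tibble::tibble(
    patient_id = rows$patient_id,
    hospital_id = rows$hospital_id,
    condition = rep(id, nrow(rows)),
    date = date,
    source = source,
    record_type = rep(record_type, nrow(rows)),
    record_row = rows$.row
  )
}

matches_hf_code <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' @rdname match_condition
#' @export
match_disease <- function(records, id, config = default_code_config()) {
  if (!id %in% disease_ids) {
    abort(sprintf("`%s` is not a disease condition", id))
  }
  d <- records$diagnoses
  d$.row <- seq_len(nrow(d))
  d <- d[matches_hf_code(d$icd10_code, config$hf_disease_codes), , drop = FALSE]
  keep <- switch(id,
    DISEASE1 = d$source == "DPC",
    DISEASE2 = d$source == "DPC" & d$dpc_field %in% dpc_three_fields,
    DISEASE3 = d$source == "SSMIX2",
    DISEASE4 = d$source == "SSMIX2" & !is.na(d$suspected) & !d$suspected,
    DISEASE5 = d$source == "CLAIMS",
    DISEASE6 = d$source == "DPC" & !is.na(d$discharge_date) &
      as.integer(d$discharge_date - d$date) + 1L >= 3L
  )
  event_tibble(d[keep, , drop = FALSE], id, "diagnoses")
}

#' @rdname match_condition
#' @export
match_drug <- function(records, id, config = default_code_config()) {
  if (!id %in% drug_ids) {
    abort(sprintf("`%s` is not a drug condition", id))
  }
  d <- records$drugs
  d$.row <- seq_len(nrow(d))
  keep <- d$drug_code %in% config$drug_class_codes[[id]]
  event_tibble(d[keep, , drop = FALSE], id, "drugs")
}

blood_rules <- list(
  BLOOD1 = list(analyte = "BNP", lo = 100, hi = Inf),
  BLOOD2 = list(analyte = "BNP", lo = 400, hi = Inf),
  BLOOD3 = list(analyte = "BNP", lo = 100, hi = 400),
  BLOOD4 = list(analyte = "NTPROBNP", lo = 400, hi = Inf),
  BLOOD5 = list(analyte = "NTPROBNP", lo = 3000, hi = Inf),
  BLOOD6 = list(analyte = "NTPROBNP", lo = 400, hi = 3000)
)

#' @rdname match_condition
#' @export
match_blood <- function(records, id) {
  if (!id %in% blood_ids) {
    abort(sprintf("`%s` is not a blood-test condition", id))
  }
  rule <- blood_rules[[id]]
  d <- records$labs
  d$.row <- seq_len(nrow(d))
  keep <- d$analyte == rule$analyte & d$value >= rule$lo & d$value < rule$hi
  # labs live in SS-MIX2 only
  event_tibble(d[keep, , drop = FALSE], id, "labs",
               source = rep("SSMIX2", sum(keep)))
}

#' @rdname match_condition
#' @export
match_procedure <- function(records, config = default_code_config()) {
  d <- records$procedures
  d$.row <- seq_len(nrow(d))
  keep <- d$source %in% c("DPC", "CLAIMS") &
    d$procedure_code %in% config$tte_procedure_codes
  event_tibble(d[keep, , drop = FALSE], "MEDPRACTICE1", "procedures")
}
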