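#' Multi-source clinical record tables
#'
#' A record set holds the four longitudinal tables the phenotyping algorithms
#' consume, covering any number of patients across hospitals:
#'
#' * `diagnoses` — coded diagnoses from any of the three sources. DPC rows are
#'   dated by *admission date* and carry one of the six DPC diagnosis fields
#'   (main diagnosis, diagnosis causing admission, most / second-most
#'   resource-consuming diagnosis, comorbidity on admission, complication
#'   during admission) plus an optional discharge date; SS-MIX2 and claims
#'   rows are dated by the recorded start date. The `suspected` flag is the
#'   SS-MIX2 suspected-diagnosis modifier and is only meaningful there.
#' * `drugs` — drug orders/dispensations from any source.
#' * `labs` — BNP / NT-proBNP results in pg/ml (laboratory results live in
#'   SS-MIX2 only).
#' * `procedures` — coded procedures from DPC or claims (never SS-MIX2).
#'
#' Column schemas (all tables also carry `patient_id` and `hospital_id`):
#'
#' | table | columns |
#' |---|---|
#' | diagnoses | `source`, `icd10_code`, `date`, `suspected`, `dpc_field`, `discharge_date` |
#' | drugs | `source`, `drug_code`, `date` |
#' | labs | `analyte` (`"BNP"`/`"NTPROBNP"`), `value`, `date` |
#' | procedures | `source`, `procedure_code`, `date` |
#'
#' Construction validates the cross-field invariants: `dpc_field` present
#' exactly on DPC diagnosis rows, `discharge_date >= date`, non-negative lab
#' values, no SS-MIX2 procedures.
#'
#' @param diagnoses,drugs,labs,procedures Data frames following the schemas
#'   above; any may be omitted for an empty table.
#' @return An object of class `hf_records`: a named list of four tibbles.
#' @examples
#' recs <- hf_records(diagnoses = tibble::tibble(
#'   patient_id = "p1", hospital_id = "A", source = "DPC",
#'   icd10_code = "I500", date = as.Date("2021-03-10"), suspected = NA,
#'   dpc_field = "MAIN", discharge_date = as.Date("2021-03-20")
#' ))
#' recs
#' @export
hf_records <- function(diagnoses = NULL, drugs = NULL, labs = NULL,
                       procedures = NULL) {
  recs <- structure(
    list(
      diagnoses = validate_diagnoses(coerce_table(diagnoses, empty_diagnoses())),
      drugs = validate_drugs(coerce_table(drugs, empty_drugs())),
      labs = validate_labs(coerce_table(labs, empty_labs())),
      procedures = validate_procedures(coerce_table(procedures, empty_procedures()))
    ),
    class = "hf_records"
  )
  recs
}

empty_diagnoses <- function() {
  tibble::tibble(patient_id = character(), hospital_id = character(),
                 source = character(), icd10_code = character(),
                 date = as.Date(character()), suspected = logical(),
                 dpc_field = character(),
                 discharge_date = as.Date(character()))
}
empty_drugs <- function() {
  tibble::tibble(patient_id = character(), hospital_id = character(),
                 source = character(), drug_code = character(),
                 date = as.Date(character()))
}
empty_labs <- function() {
  tibble::tibble(patient_id = character(), hospital_id = character(),
                 analyte = character(), value = double(),
                 date = as.Date(character()))
}
empty_procedures <- function() {
  tibble::tibble(patient_id = character(), hospital_id = character(),
                 source = character(), procedure_code = character(),
                 date = as.Date(character()))
}

coerce_table <- function(x, template) {
  if (is.null(x)) return(template)
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(template), names(x))
  # optional diagnosis columns may be absent entirely
  optional <- c("suspected", "dpc_field", "discharge_date")
  for (col in intersect(missing, optional)) {
    x[[col]] <- switch(col,
      suspected = rep(NA, nrow(x)),
      dpc_field = rep(NA_character_, nrow(x)),
      discharge_date = rep(as.Date(NA), nrow(x))
    )
  }
  missing <- setdiff(names(template), names(x))
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x[names(template)]
}

check_source <- function(source, allowed = source_tags, what = "source") {
  bad <- !is.na(source) & !(source %in% allowed)
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s (row %s)", what,
                  paste(unique(source[bad]), collapse = ", "),
                  paste(which(bad), collapse = ", ")))
  }
}

validate_diagnoses <- function(x) {
  check_source(x$source)
  if (any(is.na(x$icd10_code) | x$icd10_code == "")) {
    abort("diagnoses: icd10_code must be non-empty")
  }
  is_dpc <- x$source == "DPC"
  if (any(is_dpc & is.na(x$dpc_field))) {
    abort(sprintf("diagnoses: DPC rows must carry dpc_field (row %s)",
                  paste(which(is_dpc & is.na(x$dpc_field)), collapse = ", ")))
  }
  if (any(!is_dpc & !is.na(x$dpc_field))) {
    abort(sprintf("diagnoses: dpc_field set on non-DPC row(s) %s",
                  paste(which(!is_dpc & !is.na(x$dpc_field)), collapse = ", ")))
  }
  check_source(x$dpc_field, dpc_fields, what = "dpc_field")
  if (any(!is_dpc & !is.na(x$discharge_date))) {
    abort("diagnoses: discharge_date is a DPC-only column")
  }
  bad_stay <- !is.na(x$discharge_date) & x$discharge_date < x$date
  if (any(bad_stay)) {
    abort(sprintf("diagnoses: discharge_date earlier than admission date (row %s)",
                  paste(which(bad_stay), collapse = ", ")))
  }
  x
}

validate_drugs <- function(x) {
  check_source(x$source)
  if (any(is.na(x$drug_code) | x$drug_code == "")) {
    abort("drugs: drug_code must be non-empty")
  }
  x
}

validate_labs <- function(x) {
  bad <- !(x$analyte %in% c("BNP", "NTPROBNP"))
  if (any(bad)) {
    abort(sprintf("labs: analyte must be BNP or NTPROBNP (row %s)",
                  paste(which(bad), collapse = ", ")))
  }
  if (any(is.na(x$value) | x$value < 0)) {
    abort("labs: value must be a non-negative concentration in pg/ml")
  }
  x
}

validate_procedures <- function(x) {
  check_source(x$source, c("DPC", "CLAIMS"))
  if (any(is.na(x$procedure_code) | x$procedure_code == "")) {
    abort("procedures: procedure_code must be non-empty")
  }
  x
}

#' @export
print.hf_records <- function(x, ...) {
  n_pat <- nrow(dplyr::distinct(
    dplyr::bind_rows(lapply(x, function(t) t[c("patient_id", "hospital_id")]))
  ))
  cat("<hf_records>", n_pat, "patient(s)\n")
  for (nm in names(x)) cat(sprintf("  %-10s %d row(s)\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Count or list the patients present in a record set
#'
#' @param records An [hf_records()] object.
#' @return A tibble with one row per distinct (`hospital_id`, `patient_id`).
#' @export
hf_patients <- function(records) {
  stopifnot(inherits(records, "hf_records"))
  dplyr::bind_rows(lapply(records, function(t) t[c("hospital_id", "patient_id")])) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$hospital_id, .data$patient_id)
}

# IO ---------------------------------------------------------------------

record_files <- c(diagnoses = "diagnoses.csv", drugs = "drugs.csv",
                  labs = "labs.csv", procedures = "procedures.csv")

parse_date_col <- function(x, col, file) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)))
  nonblank <- !is.na(x) & x != ""
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonblank)[is.na(parsed)]
    abort(sprintf("%s: unparseable date in column `%s` at row %s",
                  file, col, paste(bad, collapse = ", ")))
  }
  out[nonblank] <- parsed
  out
}

read_record_csv <- function(path, template, date_cols, logical_cols = character()) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(setdiff(names(template), c("suspected", "dpc_field", "discharge_date")),
                     names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing mandatory column(s): %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  for (col in date_cols) {
    if (col %in% names(x)) x[[col]] <- parse_date_col(x[[col]], col, basename(path))
  }
  for (col in logical_cols) {
    if (col %in% names(x)) x[[col]] <- as.logical(x[[col]])
  }
  if ("value" %in% names(template) && "value" %in% names(x)) {
    x$value <- as.numeric(x$value)
  }
  if ("dpc_field" %in% names(x)) {
    x$dpc_field[!is.na(x$dpc_field) & x$dpc_field == ""] <- NA_character_
  }
  x
}

#' Read and write record tables as CSV
#'
#' One UTF-8, comma-separated file per record type (`diagnoses.csv`,
#' `drugs.csv`, `labs.csv`, `procedures.csv`), header row, ISO-8601 dates.
#' `read_hf_records()` validates everything [hf_records()] validates; a
#' missing file yields an empty table of that type. The pair round-trips:
#' reading written tables reproduces the record set exactly.
#'
#' @param dir Directory containing (or to receive) the four CSV files.
#' @return `read_hf_records()` returns an [hf_records()] object;
#'   `write_hf_records()` returns `dir` invisibly.
#' @export
read_hf_records <- function(dir) {
  paths <- file.path(dir, record_files)
  names(paths) <- names(record_files)
  get <- function(nm, template, date_cols, logical_cols = character()) {
    if (!file.exists(paths[[nm]])) return(template)
    read_record_csv(paths[[nm]], template, date_cols, logical_cols)
  }
  hf_records(
    diagnoses = get("diagnoses", empty_diagnoses(),
                    c("date", "discharge_date"), "suspected"),
    drugs = get("drugs", empty_drugs(), "date"),
    labs = get("labs", empty_labs(), "date"),
    procedures = get("procedures", empty_procedures(), "date")
  )
}

#' @rdname read_hf_records
#' @param records An [hf_records()] object.
#' @export
write_hf_records <- function(records, dir) {
  stopifnot(inherits(records, "hf_records"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(record_files)) {
    readr::write_csv(records[[nm]], file.path(dir, record_files[[nm]]),
                     na = "", progress = FALSE)
  }
  invisible(dir)
}
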