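#' Code-set configuration
#'
#' Every diagnosis, drug and procedure condition is grounded in a configurable
#' code list rather than hard-coded strings: hospitals differ in local drug and
#' procedure codes, and the exact lists used in the original multi-hospital
#' validation are not public. The shipped defaults ([default_code_config()])
#' are documented placeholders in the standard dialects (ICD-10 prefixes,
#' WHO-ATC-style drug classes) and should be replaced with site lists for any
#' real extraction.
#'
#' ICD-10 disease matching is by code *prefix*: `"I50"` matches `"I500"`,
#' `"I501"`, and so on, the usual way ICD-10 families are specified.
#'
#' Two structural invariants are enforced at construction time because the
#' drug-class hierarchy demands them: loop diuretics (`DRUG6`) and
#' potassium-sparing diuretics (`DRUG3`) are kinds of diuretic, so their code
#' sets must be subsets of the diuretics class (`DRUG5`).
#'
#' @param hf_disease_codes Character vector of ICD-10 code prefixes naming
#'   acute-heart-failure-related diagnoses.
#' @param drug_class_codes Named list `DRUG1`..`DRUG8`, each a character vector
#'   of drug codes: 1 carperitide (human atrial natriuretic peptide),
#'   2 catecholamines/pimobendan, 3 potassium-sparing diuretics, 4 digitalis,
#'   5 diuretics (any), 6 loop diuretics, 7 tolvaptan,
#'   8 phosphodiesterase inhibitors.
#' @param tte_procedure_codes Character vector of transthoracic
#'   echocardiography procedure codes.
#' @param bnp_analyte_ids,ntprobnp_analyte_ids Character vectors of laboratory
#'   test identifiers mapped to serum BNP and NT-proBNP (pg/ml).
#'
#' @return An object of class `hf_code_config`.
#' @examples
#' cfg <- default_code_config()
#' cfg$hf_disease_codes
#' @export
hf_code_config <- function(hf_disease_codes,
                           drug_class_codes,
                           tte_procedure_codes,
                           bnp_analyte_ids,
                           ntprobnp_analyte_ids) {
  if (!is.character(hf_disease_codes) || length(hf_disease_codes) == 0) {
    abort("`hf_disease_codes` must be a non-empty character vector")
  }
  if (!is.list(drug_class_codes) ||
      !setequal(names(drug_class_codes), drug_ids)) {
    abort(sprintf("`drug_class_codes` must be a named list with exactly the keys %s",
                  paste(drug_ids, collapse = ", ")))
  }
  drug_class_codes <- drug_class_codes[drug_ids]
  empty <- vapply(drug_class_codes, function(x) length(x) == 0, logical(1))
  if (any(empty)) {
    abort(sprintf("empty drug code set(s): %s",
                  paste(drug_ids[empty], collapse = ", ")))
  }
  if (!all(drug_class_codes$DRUG6 %in% drug_class_codes$DRUG5)) {
    abort("loop-diuretic codes (DRUG6) must be a subset of diuretic codes (DRUG5)")
  }
  if (!all(drug_class_codes$DRUG3 %in% drug_class_codes$DRUG5)) {
    abort("potassium-sparing-diuretic codes (DRUG3) must be a subset of diuretic codes (DRUG5)")
  }
  structure(
    list(
      hf_disease_codes = as.character(hf_disease_codes),
      drug_class_codes = lapply(drug_class_codes, as.character),
      tte_procedure_codes = as.character(tte_procedure_codes),
      bnp_analyte_ids = as.character(bnp_analyte_ids),
      ntprobnp_analyte_ids = as.character(ntprobnp_analyte_ids)
    ),
    class = "hf_code_config"
  )
}

#' @rdname hf_code_config
#' @export
default_code_config <- function() {
  hf_code_config(
    # ICD-10 families conventionally used for (acute) heart failure;
    # placeholder for a site-specific list.
    hf_disease_codes = c("I110", "I130", "I132", "I50"),
    drug_class_codes = list(
      DRUG1 = c("CARPERITIDE"),
      DRUG2 = c("C01CA04", "C01CA24", "C01CE90"),        # dobutamine, adrenaline, pimobendan
      DRUG3 = c("C03DA01", "C03DA04", "C03DB01"),        # K-sparing diuretics
      DRUG4 = c("C01AA05", "C01AA08"),                   # digitalis
      DRUG5 = c("C03CA01", "C03CA04", "C03CC01",         # all diuretics (incl. loop + K-sparing)
                "C03DA01", "C03DA04", "C03DB01",
                "C03AA03", "C03BA11"),
      DRUG6 = c("C03CA01", "C03CA04", "C03CC01"),        # loop diuretics
      DRUG7 = c("TOLVAPTAN"),
      DRUG8 = c("C01CE02", "C01CE03")                    # PDE inhibitors
    ),
    tte_procedure_codes = c("TTE001"),
    bnp_analyte_ids = c("BNP"),
    ntprobnp_analyte_ids = c("NTPROBNP")
  )
}

#' @export
print.hf_code_config <- function(x, ...) {
  cat("<hf_code_config>\n")
  cat("  HF disease code prefixes:", paste(x$hf_disease_codes, collapse = ", "), "\n")
  cat("  drug classes:",
      paste(sprintf("%s(%d)", names(x$drug_class_codes),
                    lengths(x$drug_class_codes)), collapse = " "), "\n")
  cat("  TTE procedure codes:", paste(x$tte_procedure_codes, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a code-set configuration as YAML
#'
#' @param path File path of the YAML document.
#' @return `read_code_config()` returns a validated [hf_code_config()];
#'   `write_code_config()` returns `path` invisibly.
#' @export
read_code_config <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("hf_disease_codes", "drug_class_codes", "tte_procedure_codes",
              "bnp_analyte_ids", "ntprobnp_analyte_ids")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("code config is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  hf_code_config(
    hf_disease_codes = raw$hf_disease_codes,
    drug_class_codes = raw$drug_class_codes,
    tte_procedure_codes = raw$tte_procedure_codes,
    bnp_analyte_ids = raw$bnp_analyte_ids,
    ntprobnp_analyte_ids = raw$ntprobnp_analyte_ids
  )
}

#' @rdname read_code_config
#' @param config An [hf_code_config()] object.
#' @export
write_code_config <- function(config, path) {
  stopifnot(inherits(config, "hf_code_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
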