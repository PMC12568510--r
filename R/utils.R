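# Internal helpers shared across the package.

#' @importFrom rlang abort %||%
#' @importFrom dplyr %>%
NULL

# Round half away from zero (SAS-style presentation rounding); base round()
# rounds half to even, which disagrees with printed tables at .5 boundaries.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Condition identifier vocabularies --------------------------------------

disease_ids <- paste0("DISEASE", 1:6)
drug_ids <- paste0("DRUG", 1:8)
blood_ids <- paste0("BLOOD", 1:6)
practice_ids <- "MEDPRACTICE1"
all_condition_ids <- c(disease_ids, drug_ids, blood_ids, practice_ids)

source_tags <- c("SSMIX2", "DPC", "CLAIMS")
dpc_fields <- c("MAIN", "ADMISSION_PRECIPITATING", "MOST_RESOURCE",
                "SECOND_MOST_RESOURCE", "COMORBIDITY_ON_ADMISSION",
                "COMPLICATION_DURING_ADMISSION")
# the "three-field" subset used by Disease 2
dpc_three_fields <- c("MAIN", "ADMISSION_PRECIPITATING", "MOST_RESOURCE")

case_categories <- c("TRUE_A", "TRUE_B", "SUSPECTED", "OTHER")

stopifnot_scalar_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}
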