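#' Chart-review case classification
#'
#' Each sampled case is adjudicated by a three-step judgement scheme and
#' mapped to one of four ordered categories:
#'
#' * **Judgement 1** — the Framingham diagnostic criteria for heart failure:
#'   `POSITIVE` or `INCONCLUSIVE`.
#' * **Judgement 2** — comprehensive clinical assessment (natriuretic
#'   peptides, chest imaging, echocardiography): `POSITIVE` or
#'   `INCONCLUSIVE`.
#' * **Judgement 3** — whether treatment for acute heart failure was given:
#'   `POSITIVE` or `NEGATIVE`.
#'
#' The mapping (a total function over the eight judgement combinations):
#' Judgement 3 negative always yields `OTHER`; otherwise Judgement 1 positive
#' yields `TRUE_A`; Judgement 1 inconclusive with Judgement 2 positive yields
#' `TRUE_B`; both inconclusive yields `SUSPECTED`. The categories are ordinal
#' (`TRUE_A` > `TRUE_B` > `SUSPECTED` > `OTHER`), which is what the weighted
#' kappa's quadratic disagreement weights act on.
#'
#' The clinical content of the judgements (applying the Framingham criteria,
#' reading images) is outside this package: judgements arrive as data.
#'
#' @param j1,j2,j3 Character vectors (recycled to a common length):
#'   `j1`, `j2` in `{"POSITIVE","INCONCLUSIVE"}`,
#'   `j3` in `{"POSITIVE","NEGATIVE"}`.
#' @return `classify_case()` returns an ordered factor with levels
#'   `TRUE_A`, `TRUE_B`, `SUSPECTED`, `OTHER` (highest to lowest).
#' @examples
#' classify_case("POSITIVE", "INCONCLUSIVE", "POSITIVE")   # TRUE_A
#' classify_case("INCONCLUSIVE", "POSITIVE", "POSITIVE")   # TRUE_B
#' classify_case("POSITIVE", "POSITIVE", "NEGATIVE")       # OTHER
#' @export
classify_case <- function(j1, j2, j3) {
  n <- max(length(j1), length(j2), length(j3))
  j1 <- rep_len(j1, n); j2 <- rep_len(j2, n); j3 <- rep_len(j3, n)
  if (!all(j1 %in% c("POSITIVE", "INCONCLUSIVE"))) {
    abort("`j1` must be POSITIVE or INCONCLUSIVE")
  }
  if (!all(j2 %in% c("POSITIVE", "INCONCLUSIVE"))) {
    abort("`j2` must be POSITIVE or INCONCLUSIVE")
  }
  if (!all(j3 %in% c("POSITIVE", "NEGATIVE"))) {
    abort("`j3` must be POSITIVE or NEGATIVE")
  }
  out <- rep("OTHER", n)
  treated <- j3 == "POSITIVE"
  out[treated & j1 == "POSITIVE"] <- "TRUE_A"
  out[treated & j1 == "INCONCLUSIVE" & j2 == "POSITIVE"] <- "TRUE_B"
  out[treated & j1 == "INCONCLUSIVE" & j2 == "INCONCLUSIVE"] <- "SUSPECTED"
  factor(out, levels = case_categories, ordered = TRUE)
}

#' Is a category counted as a true case?
#'
#' The primary analysis counts `TRUE_A` and `TRUE_B` as true; the sensitivity
#' analysis additionally counts `SUSPECTED` as true. `OTHER` is never true.
#' By construction every case that is true under the primary rule is true
#' under the sensitivity rule.
#'
#' @param category Character vector or factor of case categories.
#' @param mode `"primary"` or `"sensitivity"`.
#' @return Logical vector.
#' @examples
#' is_true_case("SUSPECTED", "primary")      # FALSE
#' is_true_case("SUSPECTED", "sensitivity")  # TRUE
#' @export
is_true_case <- function(category, mode = c("primary", "sensitivity")) {
  mode <- match.arg(mode)
  category <- as.character(category)
  bad <- !category %in% case_categories
  if (any(bad)) {
    abort(sprintf("unknown case category: %s",
                  paste(unique(category[bad]), collapse = ", ")))
  }
  true_set <- if (mode == "primary") c("TRUE_A", "TRUE_B")
              else c("TRUE_A", "TRUE_B", "SUSPECTED")
  category %in% true_set
}

#' Read an adjudication table
#'
#' CSV with columns `patient_id`, `hospital_id`, `reviewer_a`, `reviewer_b`,
#' `final` — the two independent reviewer categories and the final category
#' after disagreements were resolved by discussion. Categories must be one of
#' `TRUE_A`, `TRUE_B`, `SUSPECTED`, `OTHER`.
#'
#' @param path CSV file path.
#' @return A tibble with category columns as ordered factors.
#' @export
read_adjudications <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  needed <- c("patient_id", "hospital_id", "reviewer_a", "reviewer_b", "final")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("adjudications: missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (col in c("reviewer_a", "reviewer_b", "final")) {
    bad <- !x[[col]] %in% case_categories
    if (any(bad)) {
      abort(sprintf("adjudications: invalid %s value(s): %s", col,
                    paste(unique(x[[col]][bad]), collapse = ", ")))
    }
    x[[col]] <- factor(x[[col]], levels = case_categories, ordered = TRUE)
  }
  x
}
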