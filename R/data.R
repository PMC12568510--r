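#' Reference results of the three-hospital chart-review validation
#'
#' Summary results of the multi-hospital chart-review validation in which the
#' bundled algorithms were originally assessed (348 adjudicated cases sampled
#' from the APC screen across three hospitals, March 2021). They serve as
#' worked-example inputs and as regression targets for the statistics in this
#' package; the underlying patient-level data are not public.
#'
#' * `ahf_agreement()` — the pooled 4×4 cross-tabulation of the two
#'   independent reviewers' case categories (rows = reviewer A, columns =
#'   reviewer B, ordered `TRUE_A`, `TRUE_B`, `SUSPECTED`, `OTHER`).
#' * `ahf_reported_validity()` — per-algorithm possible cases, confusion
#'   counts and the published PPV / sensitivity percentages with exact 95%
#'   intervals, for both analysis modes (`"primary"`: Suspected counted as
#'   other; `"sensitivity"`: Suspected counted as true).
#'
#' @return `ahf_agreement()` returns a 4×4 integer matrix;
#'   `ahf_reported_validity()` a tibble with one row per algorithm and mode.
#' @examples
#' hf_weighted_kappa(ahf_agreement())
#' ahf_reported_validity() |> dplyr::filter(mode == "primary")
#' @export
ahf_agreement <- function() {
  m <- matrix(c(57, 4, 1, 3,
                3, 16, 2, 1,
                0, 1, 6, 1,
                0, 3, 2, 248),
              nrow = 4, byrow = TRUE,
              dimnames = list(reviewer_a = case_categories,
                              reviewer_b = case_categories))
  storage.mode(m) <- "integer"
  m
}

#' @rdname ahf_agreement
#' @export
ahf_reported_validity <- function() {
  path <- system.file("extdata", "reported_validity.csv", package = "ahfid",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    algorithm_id = readr::col_character(),
    mode = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
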