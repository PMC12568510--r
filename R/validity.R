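#' Exact binomial (Clopper–Pearson) confidence interval
#'
#' Central exact interval obtained from beta quantiles (equivalently, by
#' inverting the binomial tails): for `k` successes in `n` trials at level
#' `1 - alpha`, the lower bound is the `alpha/2` quantile of
#' `Beta(k, n - k + 1)` (0 when `k = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials (vectorised).
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `low`, `high` in percent.
#' @examples
#' clopper_pearson(21, 27)   # 57.74 .. 91.38
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  m <- max(length(k), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m)
  if (any(n < 1) || any(k < 0) || any(k > n) ||
      any(k != floor(k)) || any(n != floor(n))) {
    abort("require integer 0 <= k <= n and n >= 1")
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single value in (0, 1)")
  }
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(low = 100 * low, high = 100 * high)
}

#' Confusion counts for each algorithm
#'
#' Under the APC-anchored validation design the adjudicated study population
#' (the sampled APC cases) is treated as containing every true case — the
#' screen is assumed 100% sensitive. For one algorithm:
#' true positives are matched cases adjudicated true, false positives are
#' matched cases adjudicated other, false negatives are *unmatched* true
#' cases within the study population, and true negatives — defined only when
#' the total patient count of the hospitals over the study period is
#' supplied — are obtained by subtraction
#' `tn = total_population - tp - fp - fn`.
#'
#' @param matches Match tibble (`algorithm_id`, `patient_id`, `hospital_id`,
#'   `matched`), e.g. the `matches` element of [hf_run_panel()]; every case
#'   must be adjudicated.
#' @param adjudications Adjudication tibble with a `final` category column
#'   (see [read_adjudications()]).
#' @param mode `"primary"` (Suspected counts as other) or `"sensitivity"`
#'   (Suspected counts as true).
#' @param total_population Total number of patients at the hospitals over the
#'   study period, or `NULL` to leave `tn` (hence NPV/specificity) undefined.
#' @return Tibble with one row per algorithm: `algorithm_id`, `mode`,
#'   `possible_cases`, `tp`, `fp`, `fn`, `tn` (`NA` without
#'   `total_population`).
#' @export
hf_confusion <- function(matches, adjudications,
                         mode = c("primary", "sensitivity"),
                         total_population = NULL) {
  mode <- match.arg(mode)
  keys <- c("hospital_id", "patient_id")
  adj <- tibble::as_tibble(adjudications)
  missing_adj <- dplyr::anti_join(dplyr::distinct(matches[keys]), adj, by = keys)
  if (nrow(missing_adj) > 0) {
    abort(sprintf("case(s) without adjudication: %s",
                  paste(paste(missing_adj$hospital_id, missing_adj$patient_id,
                              sep = "/"), collapse = ", ")))
  }
  joined <- matches %>%
    dplyr::inner_join(adj[c(keys, "final")], by = keys) %>%
    dplyr::mutate(true = is_true_case(.data$final, mode))
  counts <- joined %>%
    dplyr::summarise(
      possible_cases = sum(.data$matched),
      tp = sum(.data$matched & .data$true),
      fp = sum(.data$matched & !.data$true),
      fn = sum(!.data$matched & .data$true),
      .by = "algorithm_id"
    ) %>%
    dplyr::mutate(mode = mode, .after = "algorithm_id")
  if (is.null(total_population)) {
    counts$tn <- NA_integer_
  } else {
    total_population <- stopifnot_scalar_int(total_population, "total_population")
    counts$tn <- total_population - counts$tp - counts$fp - counts$fn
    if (any(counts$tn < 0)) {
      abort("`total_population` smaller than tp + fp + fn: true negatives would be negative")
    }
  }
  counts
}

#' Validity measures with exact confidence intervals
#'
#' PPV, sensitivity and — when true negatives are defined — NPV and
#' specificity, each as a percentage with a Clopper–Pearson 95% interval:
#' `PPV = tp / (tp + fp)`, `sensitivity = tp / (tp + fn)` (the denominator
#' being the number of true cases in the APC study population, i.e. the
#' 100%-sensitive-screen assumption), `NPV = tn / (fn + tn)`,
#' `specificity = tn / (fp + tn)`. A zero denominator yields an `NA` point
#' estimate flagged `undefined`, never a silent zero.
#'
#' @param counts Confusion-count tibble from [hf_confusion()] (columns
#'   `algorithm_id`, `mode`, `tp`, `fp`, `fn`, `tn`).
#' @param level Confidence level for the exact intervals.
#' @return A tidy tibble: one row per algorithm, mode and measure with
#'   `numerator`, `denominator`, `point`, `ci_low`, `ci_high` (percent) and
#'   `undefined`.
#' @examples
#' counts <- tibble::tibble(algorithm_id = "ALG9", mode = "primary",
#'                          tp = 77, fp = 112, fn = 9, tn = NA)
#' validity_measures(counts)
#' @export
validity_measures <- function(counts, level = 0.95) {
  long <- counts %>%
    dplyr::mutate(
      PPV_num = .data$tp, PPV_den = .data$tp + .data$fp,
      SENSITIVITY_num = .data$tp, SENSITIVITY_den = .data$tp + .data$fn,
      NPV_num = .data$tn, NPV_den = .data$fn + .data$tn,
      SPECIFICITY_num = .data$tn, SPECIFICITY_den = .data$fp + .data$tn
    ) %>%
    dplyr::select(dplyr::all_of(c("algorithm_id", "mode")),
                  dplyr::matches("_(num|den)$")) %>%
    tidyr::pivot_longer(-dplyr::all_of(c("algorithm_id", "mode")),
                        names_to = c("measure", ".value"),
                        names_pattern = "(.*)_(num|den)") %>%
    dplyr::rename(numerator = "num", denominator = "den") %>%
    dplyr::filter(!is.na(.data$denominator))
  long <- long %>%
    dplyr::mutate(undefined = .data$denominator == 0,
                  point = ifelse(.data$undefined, NA_real_,
                                 100 * .data$numerator / .data$denominator))
  ci <- clopper_pearson(pmax(long$numerator, 0)[!long$undefined],
                        long$denominator[!long$undefined], level)
  long$ci_low <- long$ci_high <- NA_real_
  long$ci_low[!long$undefined] <- ci$low
  long$ci_high[!long$undefined] <- ci$high
  long
}

#' Per-algorithm validity report
#'
#' One row per algorithm per analysis mode, mirroring the layout of the
#' published validation tables: possible cases, confusion counts, PPV and
#' sensitivity as percentages with exact 95% intervals. The APC screen row is
#' included with its sensitivity fixed at 100 (it *defines* the denominator,
#' so no interval is attached). Values are kept at full precision; use
#' [format_validity_report()] for the 2-decimal presentation.
#'
#' @param panel An [hf_run_panel()] result (or a bare `matches` tibble).
#' @param adjudications Adjudication tibble covering every sampled case.
#' @param modes Character vector of analysis modes to include.
#' @param total_population Optional total patient count enabling
#'   NPV/specificity columns.
#' @param level Confidence level.
#' @return A tibble of class `hf_validity_report`.
#' @export
hf_validity_report <- function(panel, adjudications,
                               modes = c("primary", "sensitivity"),
                               total_population = NULL, level = 0.95) {
  matches <- if (inherits(panel, "hf_panel")) panel$matches else panel
  rows <- purrr::map(modes, function(mode) {
    counts <- hf_confusion(matches, adjudications, mode, total_population)
    meas <- validity_measures(counts, level)
    wide <- meas %>%
      dplyr::filter(.data$measure %in% c("PPV", "SENSITIVITY", "NPV", "SPECIFICITY")) %>%
      dplyr::select(dplyr::all_of(c("algorithm_id", "mode", "measure",
                                    "point", "ci_low", "ci_high"))) %>%
      tidyr::pivot_wider(names_from = "measure",
                         values_from = c("point", "ci_low", "ci_high"),
                         names_glue = "{tolower(measure)}_{.value}") %>%
      dplyr::rename_with(~ sub("_point$", "", .x))
    counts %>%
      dplyr::left_join(wide, by = c("algorithm_id", "mode"))
  })
  out <- dplyr::bind_rows(rows)
  measure_order <- unlist(lapply(c("ppv", "sensitivity", "npv", "specificity"),
                                 function(m) paste0(m, c("", "_ci_low", "_ci_high"))))
  out <- dplyr::relocate(out, dplyr::any_of(measure_order),
                         .after = dplyr::last_col())
  # The screen anchors the denominator: its sensitivity is 100 by definition.
  apc <- out$algorithm_id == "APC"
  out$sensitivity[apc] <- 100
  out$sensitivity_ci_low[apc] <- NA_real_
  out$sensitivity_ci_high[apc] <- NA_real_
  # stable row order: APC first, then algorithm number
  ord <- order(match(out$mode, modes),
               !apc, suppressWarnings(as.integer(sub("ALG", "", out$algorithm_id))))
  out <- out[ord, , drop = FALSE]
  class(out) <- c("hf_validity_report", class(out))
  out
}

#' @rdname hf_validity_report
#' @param report An `hf_validity_report`.
#' @param digits Decimal places for percentages (round-half-up, applied only
#'   at presentation).
#' @export
format_validity_report <- function(report, digits = 2) {
  pct_cols <- intersect(c("ppv", "ppv_ci_low", "ppv_ci_high",
                          "sensitivity", "sensitivity_ci_low", "sensitivity_ci_high",
                          "npv", "npv_ci_low", "npv_ci_high",
                          "specificity", "specificity_ci_low", "specificity_ci_high"),
                        names(report))
  out <- tibble::as_tibble(report)
  out[pct_cols] <- lapply(out[pct_cols], round_half_up, digits = digits)
  out
}
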