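#' Cross-tabulate the two reviewers' categories
#'
#' @param adjudications Adjudication tibble with `reviewer_a`, `reviewer_b`
#'   columns of case categories.
#' @return A 4×4 integer matrix over the ordered categories
#'   (`TRUE_A`, `TRUE_B`, `SUSPECTED`, `OTHER`), rows = reviewer A.
#' @export
hf_agreement_table <- function(adjudications) {
  a <- factor(as.character(adjudications$reviewer_a), levels = case_categories)
  b <- factor(as.character(adjudications$reviewer_b), levels = case_categories)
  if (anyNA(a) || anyNA(b)) abort("reviewer categories must be TRUE_A/TRUE_B/SUSPECTED/OTHER")
  unclass(table(reviewer_a = a, reviewer_b = b))
}

#' Quadratic-weighted (Fleiss–Cohen) kappa
#'
#' Chance-corrected inter-reviewer agreement over the `k = 4` ordered case
#' categories with quadratic disagreement weights
#' `w_ij = 1 - ((i - j) / (k - 1))^2`, so adjacent-category disagreements
#' (True A vs True B) cost far less than distant ones (True A vs Other):
#' `kappa = (Po_w - Pe_w) / (1 - Pe_w)` where `Po_w` is the weighted observed
#' agreement and `Pe_w` the weighted agreement expected from the marginals.
#'
#' The standard error is the Fleiss–Cohen–Everitt large-sample formula for
#' weighted kappa, and the reported interval is the normal approximation
#' `kappa ± z * SE` truncated to `[-1, 1]`.
#'
#' A degenerate table with all mass in a single cell leaves chance agreement
#' at 1 and kappa undefined; this is reported as `NA` rather than an error so
#' that calling code can flag it.
#'
#' @param x A square contingency matrix over the ordered categories (e.g.
#'   from [hf_agreement_table()]), or an adjudication tibble with
#'   `reviewer_a` / `reviewer_b` columns.
#' @param level Confidence level for the normal-approximation interval.
#' @return An object of class `hf_kappa` with elements `estimate`, `se`,
#'   `ci_low`, `ci_high`, `po`, `pe`, `n`, `table`, `weights`. [tidy()] and
#'   [glance()] methods return it as a one-row tibble.
#' @examples
#' m <- matrix(c(57, 4, 1, 3,
#'               3, 16, 2, 1,
#'               0, 1, 6, 1,
#'               0, 3, 2, 248), 4, 4, byrow = TRUE)
#' hf_weighted_kappa(m)
#' @export
hf_weighted_kappa <- function(x, level = 0.95) {
  if (is.data.frame(x)) x <- hf_agreement_table(x)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("`x` must be a square contingency matrix or an adjudication table")
  }
  if (any(x < 0)) abort("negative cell count")
  n <- sum(x)
  if (n < 2) abort("need at least two adjudicated cases")
  k <- nrow(x)
  w <- outer(seq_len(k), seq_len(k),
             function(i, j) 1 - ((i - j) / (k - 1))^2)
  p <- x / n
  r <- rowSums(p)
  cl <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cl))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    kappa <- NA_real_
    se <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    # Fleiss, Cohen & Everitt large-sample variance of weighted kappa
    wbar_i <- as.vector(w %*% cl)     # row-wise expected weight
    wbar_j <- as.vector(t(w) %*% r)   # column-wise expected weight
    term <- sum(p * (w - outer(wbar_i, wbar_j, "+") * (1 - kappa))^2)
    v <- (term - (kappa - pe * (1 - kappa))^2) / ((1 - pe)^2 * n)
    se <- sqrt(max(v, 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(
      estimate = kappa, se = se,
      ci_low = if (is.na(kappa)) NA_real_ else max(kappa - z * se, -1),
      ci_high = if (is.na(kappa)) NA_real_ else min(kappa + z * se, 1),
      po = po, pe = pe, n = n, level = level,
      table = x, weights = w
    ),
    class = "hf_kappa"
  )
}

#' @export
print.hf_kappa <- function(x, ...) {
  cat("Quadratic-weighted (Fleiss-Cohen) kappa\n")
  cat(sprintf("  kappa = %.4f  (SE %.4f, %g%% CI %.4f-%.4f), n = %d\n",
              x$estimate, x$se, 100 * x$level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname hf_weighted_kappa
#' @param ... Unused.
#' @method tidy hf_kappa
#' @export
tidy.hf_kappa <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname hf_weighted_kappa
#' @method glance hf_kappa
#' @export
glance.hf_kappa <- function(x, ...) {
  tibble::tibble(kappa = x$estimate, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 p.observed = x$po, p.expected = x$pe, n = x$n)
}
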