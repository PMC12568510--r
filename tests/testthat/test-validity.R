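test_that("exact binomial intervals match hand-checked values", {
  expect_equal(unlist(clopper_pearson(21, 27)), c(low = 57.74, high = 91.38),
               tolerance = 1e-4)
  expect_equal(unlist(clopper_pearson(86, 348)), c(low = 20.27, high = 29.59),
               tolerance = 1e-4)
  expect_equal(clopper_pearson(0, 10)$low, 0)
  expect_equal(clopper_pearson(10, 10)$high, 100)
  expect_error(clopper_pearson(5, 4), "k")
  expect_error(clopper_pearson(-1, 4), "k")
})

test_that("beta-quantile intervals agree with direct tail inversion", {
  # independent oracle: bisection on the binomial CDF
  invert_low <- function(k, n, alpha) {
    if (k == 0) return(0)
    f <- function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  invert_high <- function(k, n, alpha) {
    if (k == n) return(1)
    f <- function(p) stats::pbinom(k, n, p) - alpha / 2
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_equal(ci$low / 100, invert_low(k, n, 0.05), tolerance = 1e-7)
    expect_equal(ci$high / 100, invert_high(k, n, 0.05), tolerance = 1e-7)
  }
})

test_that("intervals contain the point estimate and tighten with n", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_true(ci$low <= 100 * k / n + 1e-9)
    expect_true(ci$high >= 100 * k / n - 1e-9)
    wider <- clopper_pearson(k, n)
    narrower <- clopper_pearson(4 * k, 4 * n)
    expect_true(narrower$high - narrower$low <= wider$high - wider$low + 1e-9)
  }
})

make_matches <- function(n_matched_true, n_matched_other, n_unmatched_true,
                         n_unmatched_other = 0, algorithm_id = "ALG") {
  n <- n_matched_true + n_matched_other + n_unmatched_true + n_unmatched_other
  tibble::tibble(
    algorithm_id = algorithm_id,
    hospital_id = "A",
    patient_id = sprintf("p%04d", seq_len(n)),
    matched = rep(c(TRUE, TRUE, FALSE, FALSE),
                  c(n_matched_true, n_matched_other, n_unmatched_true,
                    n_unmatched_other)),
    truecase = rep(c(TRUE, FALSE, TRUE, FALSE),
                   c(n_matched_true, n_matched_other, n_unmatched_true,
                     n_unmatched_other)))
}

adj_of <- function(matches) {
  tibble::tibble(
    patient_id = matches$patient_id, hospital_id = matches$hospital_id,
    reviewer_a = ifelse(matches$truecase, "TRUE_A", "OTHER"),
    reviewer_b = ifelse(matches$truecase, "TRUE_A", "OTHER"),
    final = ifelse(matches$truecase, "TRUE_A", "OTHER"))
}

test_that("confusion counts follow the screen-anchored design", {
  m <- make_matches(77, 112, 9)
  counts <- hf_confusion(m, adj_of(m), "primary")
  expect_equal(counts$tp, 77L)
  expect_equal(counts$fp, 112L)
  expect_equal(counts$fn, 9L)
  expect_equal(counts$possible_cases, 189L)
  expect_true(is.na(counts$tn))

  # an algorithm matching nobody leaves every true case as a false negative
  m <- make_matches(0, 0, 86, 262)
  counts <- hf_confusion(m, adj_of(m), "primary")
  expect_equal(c(counts$tp, counts$fp, counts$fn), c(0L, 0L, 86L))

  # subtraction identity for true negatives
  m <- make_matches(10, 5, 3)
  counts <- hf_confusion(m, adj_of(m), "primary", total_population = 18)
  expect_equal(counts$tn, 0L)
  expect_error(hf_confusion(m, adj_of(m), "primary", total_population = 17),
               "negative")

  # every matched case must be adjudicated
  adj <- adj_of(m)[-1, ]
  expect_error(hf_confusion(m, adj, "primary"), "without adjudication")
})

test_that("suspected cases flip from other to true across analysis modes", {
  m <- make_matches(5, 3, 2)
  adj <- adj_of(m)
  adj$final[m$matched & !m$truecase][1] <- "SUSPECTED"
  p <- hf_confusion(m, adj, "primary")
  s <- hf_confusion(m, adj, "sensitivity")
  expect_equal(s$tp - p$tp, 1L)
  expect_equal(p$fp - s$fp, 1L)
})

test_that("validity measures are the definitional ratios with exact CIs", {
  counts <- tibble::tibble(algorithm_id = "ALG9", mode = "primary",
                           tp = 77L, fp = 112L, fn = 9L, tn = NA_integer_)
  meas <- validity_measures(counts)
  ppv <- meas[meas$measure == "PPV", ]
  expect_equal(ppv$point, 100 * 77 / 189)
  expect_equal(rh2(ppv$point), 40.74)
  sens <- meas[meas$measure == "SENSITIVITY", ]
  expect_equal(sens$point, 100 * 77 / 86)
  expect_equal(rh2(sens$point), 89.53)
  expect_setequal(meas$measure, c("PPV", "SENSITIVITY"))

  # with a total population, NPV and specificity appear
  counts$tn <- 10000L
  meas <- validity_measures(counts)
  expect_setequal(meas$measure, c("PPV", "SENSITIVITY", "NPV", "SPECIFICITY"))
  npv <- meas[meas$measure == "NPV", ]
  expect_equal(npv$point, 100 * 10000 / 10009)

  # zero denominators are flagged undefined, not reported as zero
  counts <- tibble::tibble(algorithm_id = "X", mode = "primary",
                           tp = 0L, fp = 0L, fn = 5L, tn = NA_integer_)
  meas <- validity_measures(counts)
  expect_true(meas$undefined[meas$measure == "PPV"])
  expect_true(is.na(meas$point[meas$measure == "PPV"]))
  # PPV of 0 out of 5 is a defined zero with a one-sided interval
  counts <- tibble::tibble(algorithm_id = "X", mode = "primary",
                           tp = 0L, fp = 5L, fn = 5L, tn = NA_integer_)
  ppv <- validity_measures(counts) %>% dplyr::filter(measure == "PPV")
  expect_equal(ppv$point, 0)
  expect_equal(ppv$ci_low, 0)
})

test_that("weighted kappa reproduces the hand-derived pooled-review value", {
  k <- hf_weighted_kappa(ahf_agreement())
  # Po = 341.33../348 and Pe from marginals (65,22,8,253) x (60,24,11,253)
  expect_equal(k$estimate, 0.9393, tolerance = 1e-4)
  expect_equal(k$n, 348L)
  expect_equal(round(k$ci_low, 2), 0.90)
  expect_equal(round(k$ci_high, 2), 0.98)

  td <- tidy(k)
  expect_equal(td$estimate, k$estimate)
  expect_equal(names(glance(k)),
               c("kappa", "std.error", "conf.low", "conf.high",
                 "p.observed", "p.expected", "n"))
})

test_that("weighted kappa agrees with an independent cell-by-cell computation", {
  # loop-based oracle over random tables
  oracle_kappa <- function(m) {
    n <- sum(m); k <- nrow(m)
    po <- 0; pe <- 0
    for (i in 1:k) for (j in 1:k) {
      w <- 1 - ((i - j) / (k - 1))^2
      po <- po + w * m[i, j] / n
      pe <- pe + w * sum(m[i, ]) * sum(m[, j]) / n^2
    }
    (po - pe) / (1 - pe)
  }
  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(stats::rpois(16, lambda = sample(1:30, 1)), 4, 4)
    diag(m) <- diag(m) + sample(5:50, 4, replace = TRUE)
    k <- hf_weighted_kappa(m)
    expect_equal(k$estimate, oracle_kappa(m), tolerance = 1e-12)
    expect_true(k$estimate >= -1 && k$estimate <= 1)
  }
})

test_that("kappa is 1 exactly for perfect agreement and NA when degenerate", {
  perfect <- diag(c(10, 20, 5, 40))
  expect_equal(hf_weighted_kappa(perfect)$estimate, 1)

  off <- perfect; off[1, 2] <- 1
  expect_lt(hf_weighted_kappa(off)$estimate, 1)

  degenerate <- matrix(0, 4, 4); degenerate[1, 1] <- 50
  expect_true(is.na(hf_weighted_kappa(degenerate)$estimate))
  expect_error(hf_weighted_kappa(matrix(1, 2, 3)), "square")
})

test_that("the agreement table cross-tabulates the ordered categories", {
  adj <- tibble::tibble(reviewer_a = c("TRUE_A", "TRUE_A", "OTHER"),
                        reviewer_b = c("TRUE_A", "TRUE_B", "OTHER"))
  tab <- hf_agreement_table(adj)
  expect_equal(dim(tab), c(4L, 4L))
  expect_equal(tab["TRUE_A", "TRUE_A"], 1L, ignore_attr = TRUE)
  expect_equal(tab["TRUE_A", "TRUE_B"], 1L, ignore_attr = TRUE)
  expect_equal(sum(tab), 3L)
})

test_that("the validity report mirrors the published table layout", {
  coh <- generate_cohort(n_patients = 500, seed = 17)
  panel <- hf_run_panel(coh$records, seed = 17, min_per_hospital = 80)
  rep <- hf_validity_report(panel, coh$adjudications)

  expect_equal(nrow(rep), 38L)  # 19 designs x 2 modes
  expect_equal(rep$algorithm_id[1], "APC")
  expect_equal(rep$possible_cases, rep$tp + rep$fp)
  apc <- rep[rep$algorithm_id == "APC", ]
  expect_equal(apc$sensitivity, c(100, 100))
  expect_true(all(is.na(apc$sensitivity_ci_low)))
  expect_true(all(rep$fn[rep$algorithm_id == "APC"] == 0))

  fmt <- format_validity_report(rep)
  expect_equal(fmt$ppv, rh2(rep$ppv))

  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_agreement(ahf_agreement()), "ggplot")
})
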