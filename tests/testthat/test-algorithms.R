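test_that("the built-in registry encodes the published designs", {
  reg <- hf_algorithms()
  expect_length(reg, 19L)
  expect_setequal(names(reg), c("APC", paste0("ALG", 1:18)))

  # wide-window single-branch design anchored on confirmed diagnoses
  expect_equal(reg$ALG9$half_window_days, 30L)
  expect_equal(reg$ALG9$branches,
               list(list(c("DISEASE1", "DISEASE4", "DISEASE5"),
                         "BLOOD1",
                         c("DRUG1", "DRUG6", "DRUG7", "DRUG8"))))

  # the 14-day variant differs from its parent only in the window
  expect_equal(reg$ALG3$branches, reg$ALG2$branches)
  expect_equal(reg$ALG2$half_window_days, 14L)
  expect_equal(reg$ALG3$half_window_days, 7L)
  expect_equal(reg$ALG11$branches, reg$ALG10$branches)
  expect_equal(reg$ALG11$half_window_days, 7L)

  # echo variants append one conjunct to every branch of the parent
  strip_last <- function(br) lapply(br, function(g) g[-length(g)])
  expect_equal(strip_last(reg$ALG4$branches), reg$ALG2$branches)
  expect_equal(strip_last(reg$ALG12$branches), reg$ALG10$branches)
  expect_true(all(vapply(reg$ALG4$branches,
                         function(g) identical(g[[length(g)]], "MEDPRACTICE1"),
                         logical(1))))

  # loop-diuretic-only restriction
  expect_equal(reg$ALG13$branches,
               list(list(c("DISEASE1", "DISEASE3", "DISEASE5"),
                         c("BLOOD1", "BLOOD4"), "DRUG6")))

  # every branch has exactly one disease group and windows are legal
  for (spec in reg) {
    expect_true(spec$half_window_days %in% c(7L, 14L, 30L))
    for (br in spec$branches) {
      expect_equal(sum(vapply(br, function(g) all(grepl("^DISEASE", g)),
                              logical(1))), 1L)
    }
  }
})

test_that("spec construction rejects malformed designs", {
  expect_error(hf_algorithm_spec("X", list(list("DISEASE1", "BLOOD1")), 10),
               "half_window_days")
  expect_error(
    hf_algorithm_spec("X", list(list("BLOOD1")), 14), "disease group")
  expect_error(
    hf_algorithm_spec("X", list(list(c("DISEASE1", "BLOOD1"))), 14), "mixes")
  expect_error(hf_algorithm("ALG99"), "unknown algorithm")
})

test_that("the index date is the first qualifying diagnosis date", {
  recs <- hf_records(diagnoses = dplyr::bind_rows(
    dx_row(date = as.Date("2021-03-15")),
    dx_row(date = as.Date("2021-03-10"), dpc_field = "MOST_RESOURCE"),
    dx_row(source = "CLAIMS", date = as.Date("2021-03-10"),
           dpc_field = NA_character_)))
  ev <- hf_condition_events(recs)
  idx <- hf_index_dates(ev, hf_algorithm("ALG2"))
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$index_date, as.Date("2021-03-10"))
  expect_false(idx$index_fallback)

  # no qualifying diagnosis -> no index row
  idx <- hf_index_dates(ev[0, ], hf_algorithm("ALG2"))
  expect_equal(nrow(idx), 0L)
})

test_that("windowed evaluation matches worked examples", {
  # DPC main diagnosis day 0 + high BNP day +5: matched via the first branch
  recs <- hf_records(diagnoses = dx_row(date = day0),
                     labs = lab_row(value = 450, date = day0 + 5))
  ev <- hf_condition_events(recs)
  res <- hf_evaluate(ev, "ALG8")
  expect_true(res$matched)
  expect_equal(res$satisfied_branch, 1L)
  expect_equal(res$index_date, day0)

  # the same lab one day beyond the inclusive 14-day window: no match
  recs <- hf_records(diagnoses = dx_row(date = day0),
                     labs = lab_row(value = 450, date = day0 + 15))
  expect_false(hf_evaluate(hf_condition_events(recs), "ALG8")$matched)
  # exactly on the boundary: match
  recs <- hf_records(diagnoses = dx_row(date = day0),
                     labs = lab_row(value = 450, date = day0 + 14))
  expect_true(hf_evaluate(hf_condition_events(recs), "ALG8")$matched)
})

test_that("moderate BNP with only a loop diuretic separates the designs", {
  # confirmed SS-MIX2 diagnosis day 0, BNP 150 day +3, loop diuretic day -2
  recs <- hf_records(
    diagnoses = dx_row(source = "SSMIX2", suspected = FALSE,
                       dpc_field = NA_character_, date = day0),
    labs = lab_row(value = 150, date = day0 + 3),
    drugs = drug_row(code = "C03CA01", date = day0 - 2))
  ev <- hf_condition_events(recs)
  # abnormal-BNP + loop-diuretic design matches
  expect_true(hf_evaluate(ev, "ALG10")$matched)
  # the moderate-band design needs carperitide/catecholamines/K-sparing or
  # digitalis plus a diuretic; a loop diuretic alone is insufficient
  expect_false(hf_evaluate(ev, "ALG1")$matched)
})

test_that("conjunction groups may be satisfied on different dates", {
  recs <- hf_records(
    diagnoses = dx_row(date = day0),
    labs = lab_row(value = 150, date = day0 + 3),
    drugs = dplyr::bind_rows(
      drug_row(code = "C01AA05", date = day0 - 10),   # digitalis
      drug_row(code = "C03AA03", date = day0 + 10)))  # diuretic
  ev <- hf_condition_events(recs)
  res <- hf_evaluate(ev, "ALG1")
  expect_true(res$matched)
  expect_equal(res$satisfied_branch, 3L)
})

test_that("the APC screen applies its definition and claims-only fallback", {
  # suspected SS-MIX2 diagnosis + BNP 120 twenty-nine days earlier
  recs <- hf_records(
    diagnoses = dx_row(source = "SSMIX2", suspected = TRUE,
                       dpc_field = NA_character_, date = day0),
    labs = lab_row(value = 120, date = day0 - 29))
  res <- hf_evaluate_apc(hf_condition_events(recs))
  expect_true(res$matched)
  expect_false(res$index_fallback)

  # claims-only diagnosis anchors via the documented fallback
  recs <- hf_records(
    diagnoses = dx_row(source = "CLAIMS", dpc_field = NA_character_,
                       date = day0),
    labs = lab_row(analyte = "NTPROBNP", value = 500, date = day0 + 20))
  res <- hf_evaluate_apc(hf_condition_events(recs))
  expect_true(res$matched)
  expect_true(res$index_fallback)

  # BNP below every screen threshold: not matched
  recs <- hf_records(
    diagnoses = dx_row(source = "CLAIMS", dpc_field = NA_character_),
    labs = lab_row(value = 99))
  expect_false(hf_evaluate_apc(hf_condition_events(recs))$matched)
})

test_that("reported evidence lies inside the window, one event per group", {
  recs <- hf_records(
    diagnoses = dx_row(date = day0),
    labs = dplyr::bind_rows(lab_row(value = 450, date = day0 + 5),
                            lab_row(value = 500, date = day0 + 20)))
  res <- hf_evaluate(hf_condition_events(recs), "ALG8", evidence = TRUE)
  evd <- res$evidence[[1]]
  expect_equal(nrow(evd), 2L)   # one per group of branch 1
  expect_equal(evd$group, c(1L, 2L))
  expect_true(all(abs(as.integer(evd$date - res$index_date)) <= 14))
})

test_that("study-population sampling is seeded, uniform and bounded", {
  apc <- tibble::tibble(
    algorithm_id = "APC",
    hospital_id = rep(c("A", "B", "C"), c(150, 120, 80)),
    patient_id = sprintf("p%04d", 1:350),
    matched = TRUE, index_date = day0, index_fallback = FALSE,
    satisfied_branch = 1L)
  s1 <- hf_sample_population(apc, min_per_hospital = 100, seed = 9)
  s2 <- hf_sample_population(apc, min_per_hospital = 100, seed = 9)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$hospital_id)[c("A", "B", "C")]),
               c(100, 100, 80), ignore_attr = TRUE)
  expect_false(identical(
    s1$patient_id,
    hf_sample_population(apc, min_per_hospital = 100, seed = 10)$patient_id))

  # requesting more than any hospital holds returns the full population
  all_in <- hf_sample_population(apc, min_per_hospital = 500, seed = 1)
  expect_equal(nrow(all_in), 350L)
  expect_error(hf_sample_population(apc, min_per_hospital = 100), "seed")
})

test_that("the panel restricts algorithms to the sampled APC population", {
  coh <- generate_cohort(n_patients = 400, seed = 5)
  panel <- hf_run_panel(coh$records, seed = 5, min_per_hospital = 60)
  pop_key <- paste(panel$population$hospital_id, panel$population$patient_id)

  matches <- panel$matches
  expect_setequal(unique(matches$algorithm_id), c("APC", paste0("ALG", 1:18)))
  for (alg in unique(matches$algorithm_id)) {
    m <- matches[matches$algorithm_id == alg & matches$matched, ]
    expect_true(all(paste(m$hospital_id, m$patient_id) %in% pop_key))
  }

  key_of <- function(alg) {
    m <- matches[matches$algorithm_id == alg & matches$matched, ]
    paste(m$hospital_id, m$patient_id)
  }
  # tightening the window or adding a conjunct can only lose matches
  expect_true(all(key_of("ALG3") %in% key_of("ALG2")))
  expect_true(all(key_of("ALG12") %in% key_of("ALG10")))
  expect_identical(tidy(panel), matches)
})

test_that("a registry round-trips through YAML", {
  reg <- hf_algorithms()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unname(reg), unclass), path)
  back <- read_algorithms(path)
  expect_setequal(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(back[[nm]]$branches, reg[[nm]]$branches, info = nm)
    expect_equal(back[[nm]]$half_window_days, reg[[nm]]$half_window_days)
  }
})
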