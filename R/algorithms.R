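#' Declarative identification-algorithm specifications
#'
#' An algorithm is a disjunction of *branches*; a branch is a conjunction of
#' condition *groups*; a group is satisfied when at least one of its member
#' conditions has a qualifying event inside the algorithm's day window around
#' the index date. Exactly one group per branch holds disease conditions; the
#' union of disease conditions across branches defines which diagnosis dates
#' can anchor the index date. A conjunction such as "digitalis *and* a
#' diuretic" is encoded as two singleton groups, and its two conditions may be
#' satisfied on different dates, each independently in-window.
#'
#' The window is symmetric and inclusive: an event qualifies when its date
#' lies in `[index - half_window_days, index + half_window_days]` counted in
#' whole days. "Within 28 days of the index date" therefore corresponds to
#' `half_window_days = 14`.
#'
#' @param algorithm_id Identifier string, e.g. `"ALG9"` or `"APC"`.
#' @param branches List of branches; each branch is a list of character
#'   vectors of condition identifiers (the groups).
#' @param half_window_days Half-width of the symmetric day window: 7, 14
#'   or 30.
#' @param index_group Conditions whose earliest event date defines the index
#'   date; defaults to the union of disease conditions across branches.
#' @param index_fallback_group Optional conditions used to anchor the index
#'   only when no `index_group` event exists (used by the APC screen, whose
#'   written definition anchors on Disease 1–3 yet admits claims-only
#'   patients via Disease 5; such matches are flagged `index_fallback`).
#' @return An object of class `hf_algorithm_spec`.
#' @seealso [hf_algorithms()] for the built-in registry.
#' @export
hf_algorithm_spec <- function(algorithm_id, branches, half_window_days,
                              index_group = NULL, index_fallback_group = NULL) {
  if (!half_window_days %in% c(7L, 14L, 30L)) {
    abort("`half_window_days` must be 7, 14 or 30")
  }
  if (!is.list(branches) || length(branches) == 0) {
    abort("`branches` must be a non-empty list")
  }
  disease_union <- character()
  for (b in seq_along(branches)) {
    groups <- branches[[b]]
    if (!is.list(groups) || length(groups) == 0) {
      abort(sprintf("branch %d must be a non-empty list of groups", b))
    }
    unknown <- setdiff(unlist(groups), all_condition_ids)
    if (length(unknown) > 0) {
      abort(sprintf("branch %d references unknown condition(s): %s", b,
                    paste(unknown, collapse = ", ")))
    }
    is_disease_group <- vapply(groups, function(g) all(g %in% disease_ids),
                               logical(1))
    mixed <- vapply(groups, function(g) any(g %in% disease_ids) && !all(g %in% disease_ids),
                    logical(1))
    if (any(mixed)) {
      abort(sprintf("branch %d mixes disease and non-disease conditions in one group", b))
    }
    if (sum(is_disease_group) != 1L) {
      abort(sprintf("branch %d must contain exactly one disease group", b))
    }
    disease_union <- union(disease_union, unlist(groups[is_disease_group]))
  }
  structure(
    list(
      algorithm_id = algorithm_id,
      branches = branches,
      half_window_days = as.integer(half_window_days),
      disease_group = disease_union,
      index_group = index_group %||% disease_union,
      index_fallback_group = index_fallback_group
    ),
    class = "hf_algorithm_spec"
  )
}

#' @export
print.hf_algorithm_spec <- function(x, ...) {
  cat(sprintf("<hf_algorithm_spec> %s  (half-window %d days)\n",
              x$algorithm_id, x$half_window_days))
  for (b in seq_along(x$branches)) {
    cat(sprintf("  branch %d: %s\n", b,
                paste(vapply(x$branches[[b]],
                             function(g) paste0("[", paste(g, collapse = "|"), "]"),
                             character(1)),
                      collapse = " & ")))
  }
  invisible(x)
}

#' Built-in algorithm registry
#'
#' The All-Possible-Cases (APC) screen plus the eighteen identification
#' algorithms. The APC screen requires an HF diagnosis in any source
#' (`DISEASE1`, `3` or `5`) together with BNP ≥ 100 or NT-proBNP ≥ 400 pg/ml
#' (`BLOOD1` or `4`) within ±30 days of the first diagnosis date; it anchors
#' the sensitivity denominator of every validity analysis under the working
#' assumption that it captures every true acute-HF case.
#'
#' Algorithms 1–8 are three-branch designs: high-band natriuretic peptide
#' alone, or moderate-band peptide plus acute-HF medications (carperitide,
#' catecholamines/pimobendan, or potassium-sparing diuretics; alternatively
#' digitalis *and* a diuretic). Algorithms 9–18 are single-branch designs
#' combining a diagnosis, any abnormal peptide value and one of the acute-HF
#' drug classes (carperitide, loop diuretics, tolvaptan, PDE inhibitors).
#' Variants tighten the window (3, 11), add echocardiography (4, 12), or
#' restrict the diagnosis source or DPC field (5–8, 15–18) or the drug class
#' (13, 14).
#'
#' @return `hf_algorithms()` returns a named list of [hf_algorithm_spec()]
#'   objects (`APC`, `ALG1` .. `ALG18`); `hf_algorithm(id)` returns one of
#'   them.
#' @examples
#' hf_algorithm("ALG9")
#' names(hf_algorithms())
#' @export
hf_algorithms <- function() {
  D145 <- c("DISEASE1", "DISEASE4", "DISEASE5")
  D135 <- c("DISEASE1", "DISEASE3", "DISEASE5")
  D24 <- c("DISEASE2", "DISEASE4")
  B25 <- c("BLOOD2", "BLOOD5")
  B36 <- c("BLOOD3", "BLOOD6")
  B14 <- c("BLOOD1", "BLOOD4")
  Dr123 <- c("DRUG1", "DRUG2", "DRUG3")
  Dr1678 <- c("DRUG1", "DRUG6", "DRUG7", "DRUG8")
  MP <- "MEDPRACTICE1"

  # the common three-branch body of Algorithms 2-8, parameterised by the
  # disease group (and optionally an extra conjunct appended to every branch)
  three_branch <- function(dz, extra = NULL) {
    add <- function(groups) c(groups, if (!is.null(extra)) list(extra))
    list(add(list(dz, B25)),
         add(list(dz, B36, Dr123)),
         add(list(dz, B36, "DRUG4", "DRUG5")))
  }
  one_branch <- function(dz, blood, drugs, extra = NULL) {
    list(c(list(dz, blood, drugs), if (!is.null(extra)) list(extra)))
  }

  specs <- list(
    hf_algorithm_spec("APC",
      branches = list(list(D135, B14)),
      half_window_days = 30L,
      index_group = c("DISEASE1", "DISEASE2", "DISEASE3"),
      index_fallback_group = "DISEASE5"),
    hf_algorithm_spec("ALG1", list(
      list(D145, "BLOOD2"),
      list(D145, "BLOOD3", Dr123),
      list(D145, "BLOOD3", "DRUG4", "DRUG5")), 14L),
    hf_algorithm_spec("ALG2", three_branch(D135), 14L),
    hf_algorithm_spec("ALG3", three_branch(D135), 7L),
    hf_algorithm_spec("ALG4", three_branch(D135, extra = MP), 14L),
    hf_algorithm_spec("ALG5", three_branch("DISEASE1"), 14L),
    hf_algorithm_spec("ALG6", three_branch("DISEASE6"), 14L),
    hf_algorithm_spec("ALG7", three_branch(D24), 14L),
    hf_algorithm_spec("ALG8", three_branch("DISEASE2"), 14L),
    hf_algorithm_spec("ALG9", one_branch(D145, "BLOOD1", Dr1678), 30L),
    hf_algorithm_spec("ALG10", one_branch(D135, B14, Dr1678), 14L),
    hf_algorithm_spec("ALG11", one_branch(D135, B14, Dr1678), 7L),
    hf_algorithm_spec("ALG12", one_branch(D135, B14, Dr1678, extra = MP), 14L),
    hf_algorithm_spec("ALG13", one_branch(D135, B14, "DRUG6"), 14L),
    hf_algorithm_spec("ALG14", one_branch(D135, B14, "DRUG1"), 14L),
    hf_algorithm_spec("ALG15", one_branch("DISEASE1", B14, Dr1678), 14L),
    hf_algorithm_spec("ALG16", one_branch("DISEASE6", B14, Dr1678), 14L),
    hf_algorithm_spec("ALG17", one_branch(D24, B14, Dr1678), 14L),
    hf_algorithm_spec("ALG18", one_branch("DISEASE2", B14, Dr1678), 14L)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "algorithm_id"))
}

#' @rdname hf_algorithms
#' @param id Algorithm identifier (`"APC"`, `"ALG1"` .. `"ALG18"`).
#' @export
hf_algorithm <- function(id) {
  reg <- hf_algorithms()
  if (!id %in% names(reg)) {
    abort(sprintf("unknown algorithm id `%s`; available: %s", id,
                  paste(names(reg), collapse = ", ")))
  }
  reg[[id]]
}

#' Read an algorithm registry from YAML
#'
#' A YAML document mirroring the [hf_algorithm_spec()] structure: a sequence
#' of mappings with keys `algorithm_id`, `half_window_days`, `branches` (a
#' sequence of branches, each a sequence of condition-id groups) and optional
#' `index_group` / `index_fallback_group`.
#'
#' @param path YAML file path.
#' @return Named list of [hf_algorithm_spec()] objects.
#' @export
read_algorithms <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(a) {
    hf_algorithm_spec(
      algorithm_id = a$algorithm_id,
      branches = lapply(a$branches, function(br) lapply(br, unlist)),
      half_window_days = a$half_window_days,
      index_group = unlist(a$index_group),
      index_fallback_group = unlist(a$index_fallback_group)
    )
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "algorithm_id"))
}

# Index dates ------------------------------------------------------------

#' Per-patient index dates for an algorithm
#'
#' The index date is the first (earliest) date among the patient's qualifying
#' diagnosis events for the algorithm's disease conditions; every other
#' condition must then fall within the algorithm's window around it. Patients
#' with no qualifying diagnosis have no index date and can never match. For
#' the APC screen the index is anchored on Disease 1–3 with a documented
#' fallback to the earliest claims diagnosis (Disease 5) when no other
#' anchor exists; fallback-anchored patients are flagged.
#'
#' @param events Condition-event tibble from [hf_condition_events()].
#' @param spec An [hf_algorithm_spec()].
#' @return Tibble with `patient_id`, `hospital_id`, `index_date`,
#'   `index_fallback`.
#' @export
hf_index_dates <- function(events, spec) {
  min_date <- function(x) if (length(x) == 0) as.Date(NA) else min(x)
  idx <- events %>%
    dplyr::filter(.data$condition %in% spec$index_group) %>%
    dplyr::summarise(index_date = min_date(.data$date), index_fallback = FALSE,
                     .by = c("hospital_id", "patient_id"))
  if (!is.null(spec$index_fallback_group)) {
    fb <- events %>%
      dplyr::filter(.data$condition %in% spec$index_fallback_group) %>%
      dplyr::summarise(index_date = min_date(.data$date), index_fallback = TRUE,
                       .by = c("hospital_id", "patient_id")) %>%
      dplyr::anti_join(idx, by = c("hospital_id", "patient_id"))
    idx <- dplyr::bind_rows(idx, fb)
  }
  idx
}

# Evaluation -------------------------------------------------------------

#' Evaluate an algorithm over condition events
#'
#' Determines each patient's index date ([hf_index_dates()]), restricts
#' events to the inclusive window `index ± half_window_days`, and declares a
#' match when some branch has every group satisfied by at least one in-window
#' event. Disease groups may be satisfied by the index-defining event itself
#' (which is in-window by construction, at distance zero). Branches are tried
#' in their printed order and the first satisfied branch is reported;
#' matching itself is order-independent.
#'
#' @param events Condition-event tibble from [hf_condition_events()].
#' @param spec An [hf_algorithm_spec()] (or an id string resolved via
#'   [hf_algorithm()]).
#' @param patients Optional tibble of `patient_id`, `hospital_id` defining
#'   the evaluation population (one result row each); defaults to the
#'   patients present in `events`.
#' @param evidence If `TRUE`, attach an `evidence` list-column holding, for
#'   each matched patient, one qualifying event per group of the satisfied
#'   branch (earliest in-window event, ties broken by the group's condition
#'   order).
#' @return Tibble with one row per patient: `algorithm_id`, `patient_id`,
#'   `hospital_id`, `matched`, `index_date`, `index_fallback`,
#'   `satisfied_branch` and optionally `evidence`.
#' @examples
#' recs <- hf_records(
#'   diagnoses = tibble::tibble(
#'     patient_id = "p1", hospital_id = "A", source = "DPC",
#'     icd10_code = "I500", date = as.Date("2021-03-10"), suspected = NA,
#'     dpc_field = "MAIN", discharge_date = as.Date(NA)),
#'   labs = tibble::tibble(
#'     patient_id = "p1", hospital_id = "A", analyte = "BNP",
#'     value = 450, date = as.Date("2021-03-15"))
#' )
#' ev <- hf_condition_events(recs)
#' hf_evaluate(ev, "ALG8")
#' @export
hf_evaluate <- function(events, spec, patients = NULL, evidence = TRUE) {
  if (is.character(spec)) spec <- hf_algorithm(spec)
  stopifnot(inherits(spec, "hf_algorithm_spec"))
  if (is.null(patients)) {
    patients <- dplyr::distinct(events, .data$hospital_id, .data$patient_id)
  }
  patients <- dplyr::arrange(tibble::as_tibble(patients)[c("hospital_id", "patient_id")],
                             .data$hospital_id, .data$patient_id)

  idx <- hf_index_dates(events, spec)
  out <- patients %>%
    dplyr::left_join(idx, by = c("hospital_id", "patient_id")) %>%
    dplyr::mutate(index_fallback = dplyr::coalesce(.data$index_fallback, FALSE))

  all_conds <- unique(unlist(spec$branches))
  win <- events %>%
    dplyr::inner_join(out[c("hospital_id", "patient_id", "index_date")],
                      by = c("hospital_id", "patient_id")) %>%
    dplyr::filter(.data$condition %in% all_conds,
                  abs(as.integer(.data$date - .data$index_date)) <= spec$half_window_days)

  key <- function(d) paste(d$hospital_id, d$patient_id, sep = "\r")
  pkey <- key(out)
  have <- dplyr::distinct(win, .data$hospital_id, .data$patient_id, .data$condition)
  hkey <- key(have)

  satisfied_branch <- rep(NA_integer_, nrow(out))
  for (b in seq_along(spec$branches)) {
    branch_ok <- rep(TRUE, nrow(out))
    for (g in spec$branches[[b]]) {
      gk <- unique(hkey[have$condition %in% g])
      branch_ok <- branch_ok & (pkey %in% gk)
    }
    satisfied_branch[is.na(satisfied_branch) & branch_ok] <- b
  }
  out$matched <- !is.na(satisfied_branch)
  out$satisfied_branch <- satisfied_branch
  out <- dplyr::mutate(out, algorithm_id = spec$algorithm_id, .before = 1)

  if (evidence) out$evidence <- extract_evidence(out, win, spec, pkey)
  out
}

# one qualifying event per group of the satisfied branch, matched patients only
extract_evidence <- function(out, win, spec, pkey) {
  ev <- vector("list", nrow(out))
  if (!any(out$matched)) return(ev)
  wkey <- paste(win$hospital_id, win$patient_id, sep = "\r")
  for (i in which(out$matched)) {
    rows <- win[wkey == pkey[i], , drop = FALSE]
    groups <- spec$branches[[out$satisfied_branch[i]]]
    picks <- lapply(seq_along(groups), function(j) {
      g <- groups[[j]]
      cand <- rows[rows$condition %in% g, , drop = FALSE]
      cand <- cand[order(cand$date, match(cand$condition, g), cand$record_row), ,
                   drop = FALSE]
      cbind(group = j, cand[1, c("condition", "date", "source", "record_type",
                                 "record_row")])
    })
    ev[[i]] <- dplyr::bind_rows(picks)
  }
  ev
}

#' @rdname hf_evaluate
#' @export
hf_evaluate_apc <- function(events, patients = NULL, evidence = TRUE) {
  hf_evaluate(events, hf_algorithm("APC"), patients = patients,
              evidence = evidence)
}

# Sampling ---------------------------------------------------------------

#' Sample the study population from the APC screen
#'
#' Chart review cannot cover every screened patient, so a fixed number of
#' cases is drawn uniformly without replacement within each hospital from the
#' APC-matched population. Hospitals with at most `min_per_hospital` matches
#' contribute all of them. The draw is fully determined by `seed`; there is
#' no silent default.
#'
#' @param apc_results Result tibble from [hf_evaluate_apc()].
#' @param min_per_hospital Number of cases to draw per hospital.
#' @param seed Integer random seed (required).
#' @return Tibble of sampled cases (subset of the matched rows).
#' @export
hf_sample_population <- function(apc_results, min_per_hospital = 100, seed) {
  if (missing(seed)) abort("`seed` is required for study-population sampling")
  min_per_hospital <- stopifnot_scalar_int(min_per_hospital, "min_per_hospital")
  if (min_per_hospital < 1) abort("`min_per_hospital` must be >= 1")
  matched <- apc_results %>%
    dplyr::filter(.data$matched) %>%
    dplyr::arrange(.data$hospital_id, .data$patient_id)
  with_preserved_seed({
    set.seed(seed)
    matched %>%
      dplyr::group_by(.data$hospital_id) %>%
      dplyr::group_modify(function(d, key) {
        if (nrow(d) <= min_per_hospital) d
        else d[sort(sample.int(nrow(d), min_per_hospital)), , drop = FALSE]
      }) %>%
      dplyr::ungroup()
  })
}

# evaluate an expression with the caller's RNG state untouched
with_preserved_seed <- function(expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Panel ------------------------------------------------------------------

#' Run the full identification panel
#'
#' Evaluates the APC screen over all patients, samples the study population
#' within each hospital, and evaluates every identification algorithm on the
#' sampled cases. An algorithm's *possible cases* are the sampled cases it
#' matches. The APC screen itself is carried through as a row-per-case match
#' (every sampled case matches it by construction), so downstream reports can
#' include the APC row.
#'
#' @param records An [hf_records()] object.
#' @param config An [hf_code_config()].
#' @param seed Integer seed for the sampling step (required).
#' @param min_per_hospital Cases to sample per hospital (default 100).
#' @param algorithms Named list of [hf_algorithm_spec()]s; must contain
#'   `"APC"`. Defaults to [hf_algorithms()].
#' @return An object of class `hf_panel`: a list with `apc` (screen results,
#'   all patients), `population` (sampled cases) and `matches` (one row per
#'   sampled case per algorithm, including `"APC"`).
#' @export
hf_run_panel <- function(records, config = default_code_config(), seed,
                         min_per_hospital = 100, algorithms = hf_algorithms()) {
  if (missing(seed)) abort("`seed` is required (study-population sampling)")
  if (!"APC" %in% names(algorithms)) abort("`algorithms` must include \"APC\"")
  events <- hf_condition_events(records, config)
  apc <- hf_evaluate(events, algorithms$APC, patients = hf_patients(records),
                     evidence = FALSE)
  population <- hf_sample_population(apc, min_per_hospital, seed)
  pop_keys <- population[c("hospital_id", "patient_id")]
  matches <- purrr::map(algorithms, function(spec) {
    if (spec$algorithm_id == "APC") {
      dplyr::select(population, -dplyr::any_of("evidence"))
    } else {
      hf_evaluate(events, spec, patients = pop_keys, evidence = FALSE)
    }
  }) %>%
    dplyr::bind_rows()
  structure(list(apc = apc, population = population, matches = matches),
            class = "hf_panel")
}

#' @export
print.hf_panel <- function(x, ...) {
  cat("<hf_panel>\n")
  cat("  APC screen:", sum(x$apc$matched), "of", nrow(x$apc), "patients matched\n")
  cat("  study population:", nrow(x$population), "sampled case(s)\n")
  counts <- x$matches %>%
    dplyr::filter(.data$algorithm_id != "APC", .data$matched) %>%
    dplyr::count(.data$algorithm_id)
  cat("  possible cases per algorithm:",
      paste(sprintf("%s=%d", counts$algorithm_id, counts$n), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy hf_panel
#' @export
tidy.hf_panel <- function(x, ...) {
  x$matches
}
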