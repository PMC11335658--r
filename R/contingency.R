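#' Count drug-event pairs
#'
#' The counting unit is the distinct (report, term) pair: a report
#' mentioning the same PT twice contributes once. For each term, `a` is the
#' number of distinct target-primary-suspect reports mentioning it; the drug
#' margin `a + b` is the total number of distinct (target report, term)
#' pairs; the event margin `a + c` counts the term over all reports; `n` is
#' the total number of distinct (report, term) pairs in the database.
#'
#' @param cases A deduplicated `faers_cases` collection (the full database,
#'   not pre-filtered to the target drug).
#' @param target_synonyms Drug-name patterns defining the target drug (see
#'   [filter_primary_suspect()]).
#' @param match `"substring"` or `"exact"` synonym matching.
#' @return An object of class `pair_counts` with elements `counts` (tibble:
#'   `term`, `a`, `event_margin`), `drug_margin`, `n`, `level` (`"PT"`),
#'   `subgroup`, and the underlying distinct pair list.
#' @seealso [aggregate_soc()], [build_contingency()]
#' @export
count_pairs <- function(cases, target_synonyms, match = "substring") {
  pairs <- dplyr::distinct(cases$reactions, .data$primaryid, .data$pt)
  names(pairs) <- c("primaryid", "term")
  target_ids <- target_primaryids(cases, target_synonyms, match)
  pairs$is_target <- pairs$primaryid %in% target_ids
  counts_from_pairs(pairs, level = "PT", subgroup = "all")
}

counts_from_pairs <- function(pairs, level, subgroup) {
  ev <- pairs %>%
    dplyr::count(.data$term, name = "event_margin")
  a_tb <- pairs %>%
    dplyr::filter(.data$is_target) %>%
    dplyr::count(.data$term, name = "a")
  counts <- ev %>%
    dplyr::left_join(a_tb, by = "term") %>%
    dplyr::mutate(a = ifelse(is.na(.data$a), 0L, .data$a)) %>%
    dplyr::arrange(.data$term)
  structure(list(
    counts = counts[, c("term", "a", "event_margin")],
    drug_margin = sum(counts$a),
    n = nrow(pairs),
    level = level,
    subgroup = subgroup,
    pairs = pairs
  ), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> level=", x$level, " subgroup=", x$subgroup,
      ": ", nrow(x$counts), " terms, drug margin ", x$drug_margin,
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Aggregate pair counts to the system organ class level
#'
#' Maps each PT-level pair to its SOC and re-counts distinct (report, SOC)
#' pairs: a report mentioning two PTs of the same SOC contributes once to
#' that SOC. All margins and `n` are recomputed at the SOC-pair level so the
#' SOC tables are internally consistent.
#'
#' @param counts A PT-level `pair_counts` from [count_pairs()].
#' @param map A `pt_soc_map`.
#' @return A SOC-level `pair_counts`.
#' @export
aggregate_soc <- function(counts, map) {
  stopifnot(inherits(counts, "pair_counts"), counts$level == "PT")
  pairs <- counts$pairs
  pairs$term <- map_pt(map, pairs$term)
  pairs <- dplyr::distinct(pairs, .data$primaryid, .data$term,
                           .keep_all = TRUE)
  counts_from_pairs(pairs, level = "SOC", subgroup = counts$subgroup)
}

#' Build 2x2 contingency tables from pair counts
#'
#' For each term, the four cells of the drug-by-event table are
#' `a` (target drug, this event), `b` (target drug, other events),
#' `c` (other drugs, this event), `d` (neither), with
#' `b = drug margin - a`, `c = event margin - a`, `d = n - a - b - c`.
#'
#' @param counts A `pair_counts` object.
#' @return A tibble with columns `term`, `level`, `subgroup`, `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
build_contingency <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  tb <- counts$counts
  out <- tibble::tibble(
    term = tb$term,
    level = counts$level,
    subgroup = counts$subgroup,
    a = as.numeric(tb$a),
    b = counts$drug_margin - as.numeric(tb$a),
    c = as.numeric(tb$event_margin) - as.numeric(tb$a),
    n = as.numeric(counts$n)
  )
  out$d <- out$n - out$a - out$b - out$c
  if (any(out$b < 0 | out$c < 0 | out$d < 0)) {
    stop("Internal consistency error: negative contingency cell ",
         "(margins inconsistent with counts)", call. = FALSE)
  }
  out[, c("term", "level", "subgroup", "a", "b", "c", "d", "n")]
}

#' Define a report subgroup
#'
#' A composable predicate over case reports: reporter-occupation set, sex,
#' and/or an age lower bound. Reports with missing age fail an age-restricted
#' predicate (they are excluded from age subgroups). A custom `predicate`
#' function on the `demo` tibble may be supplied instead.
#'
#' @param name Subgroup name, stamped into downstream outputs.
#' @param occupations Optional character vector of reporter occupations
#'   (e.g. `"PHYSICIAN"`).
#' @param sex Optional `"F"` or `"M"`.
#' @param age_min Optional minimum age in years (inclusive).
#' @param predicate Optional function `demo -> logical vector`.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, occupations = NULL, sex = NULL,
                          age_min = NULL, predicate = NULL) {
  structure(list(name = name, occupations = occupations, sex = sex,
                 age_min = age_min, predicate = predicate),
            class = "subgroup_spec")
}

#' Built-in subgroup specifications
#'
#' The three standard subset analyses: reports from healthcare professionals
#' (physician, pharmacist, other health professional, registered nurse),
#' female patients, and patients aged 45 and older.
#'
#' @return Named list of `subgroup_spec` objects.
#' @export
subgroup_presets <- function() {
  list(
    health_professional = subgroup_spec(
      "health_professional",
      occupations = c("PHYSICIAN", "PHARMACIST",
                      "OTHER_HEALTH_PROFESSIONAL", "REGISTERED_NURSE")),
    female = subgroup_spec("female", sex = "F"),
    age45plus = subgroup_spec("age45plus", age_min = 45)
  )
}

#' Restrict case reports to a subgroup
#'
#' Returns exactly the reports satisfying the predicate; downstream pair
#' counts then use the subgroup's own totals (the comparator is the
#' same-subgroup non-target pairs).
#'
#' @param cases A `faers_cases` object.
#' @param spec A `subgroup_spec`.
#' @return A filtered `faers_cases` object.
#' @export
apply_subgroup <- function(cases, spec) {
  stopifnot(inherits(spec, "subgroup_spec"))
  demo <- cases$demo
  keep <- rep(TRUE, nrow(demo))
  if (!is.null(spec$occupations)) {
    keep <- keep & demo$reporter_occupation %in% spec$occupations
  }
  if (!is.null(spec$sex)) {
    keep <- keep & !is.na(demo$sex) & demo$sex == spec$sex
  }
  if (!is.null(spec$age_min)) {
    keep <- keep & !is.na(demo$age_years) & demo$age_years >= spec$age_min
  }
  if (!is.null(spec$predicate)) {
    p <- spec$predicate(demo)
    stopifnot(is.logical(p), length(p) == nrow(demo))
    keep <- keep & !is.na(p) & p
  }
  subset_cases(cases, demo$primaryid[keep])
}

#' Drug-by-event cell counts for empirical-Bayes prior fitting
#'
#' Builds the full cross-product of primary-suspect drugs and event terms
#' with observed counts `a` and baseline expectations
#' `E = (drug margin)(event margin) / n`, including `a = 0` cells. This is
#' the input the MGPS hyperparameter fit operates on.
#'
#' @param cases A deduplicated `faers_cases` collection.
#' @param map Optional `pt_soc_map`; when given, cells are built at SOC
#'   level.
#' @return Tibble with columns `drug`, `term`, `a`, `E`.
#' @seealso [fit_mgps_prior()]
#' @export
mgps_cells <- function(cases, map = NULL) {
  ps <- cases$drugs[!is.na(cases$drugs$role) & cases$drugs$role == "PS", ]
  ps <- dplyr::distinct(
    tibble::tibble(primaryid = ps$primaryid,
                   drug = normalize_name(ps$drug_name)))
  pairs <- dplyr::distinct(cases$reactions, .data$primaryid, .data$pt)
  names(pairs) <- c("primaryid", "term")
  if (!is.null(map)) {
    pairs$term <- map_pt(map, pairs$term)
    pairs <- dplyr::distinct(pairs)
  }
  n <- nrow(pairs)
  obs <- dplyr::inner_join(ps, pairs, by = "primaryid",
                           relationship = "many-to-many") %>%
    dplyr::distinct(.data$drug, .data$term, .data$primaryid) %>%
    dplyr::count(.data$drug, .data$term, name = "a")
  drug_margin <- obs %>%
    dplyr::summarise(drug_n = sum(.data$a), .by = "drug")
  event_margin <- pairs %>% dplyr::count(.data$term, name = "event_n")
  grid <- tidyr::expand_grid(drug = drug_margin$drug,
                             term = event_margin$term)
  grid %>%
    dplyr::left_join(obs, by = c("drug", "term")) %>%
    dplyr::mutate(a = ifelse(is.na(.data$a), 0, as.numeric(.data$a))) %>%
    dplyr::left_join(drug_margin, by = "drug") %>%
    dplyr::left_join(event_margin, by = "term") %>%
    dplyr::mutate(E = .data$drug_n * .data$event_n / n) %>%
    dplyr::select("drug", "term", "a", "E")
}
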