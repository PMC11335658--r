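.outcome_labels <- c(
  DE = "Death", LT = "Life threatening", HO = "Hospitalization",
  DS = "Disability", CA = "Congenital anomaly",
  RI = "Required intervention to Prevent Permanent Impairment/Damage",
  OT = "Other serious")

.occupation_labels <- c(
  CONSUMER = "Consumer", PHYSICIAN = "Physician", PHARMACIST = "Pharmacist",
  OTHER_HEALTH_PROFESSIONAL = "Other health-professional",
  REGISTERED_NURSE = "Registered Nurse", LAWYER = "Lawyer",
  UNK = "Unknown")

.age_band_levels <- c("<18", "18-45", "45-65", "65-75", ">=75", "Unknown")
.onset_band_levels <- c("<7", "7-28", "28-60", ">=60", "Unknown")

age_band <- function(age_years) {
  band <- cut(age_years, breaks = c(0, 18, 45, 65, 75, Inf),
              labels = .age_band_levels[1:5], right = FALSE)
  out <- as.character(band)
  out[is.na(out)] <- "Unknown"
  out
}

onset_band <- function(days) {
  out <- as.character(cut(days, breaks = c(0, 7, 28, 60, Inf),
                          labels = .onset_band_levels[1:4], right = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Time from therapy start to event onset
#'
#' Days between the earliest therapy start date among the target
#' primary-suspect drug entries and the event date, per report. Negative
#' gaps, missing dates and dates of reduced precision (year-month or year
#' only) yield an unknown onset. Reports are "in section" for the
#' time-to-onset summary when they carry at least one therapy-start or
#' event date record (at any precision); otherwise the report is excluded
#' from the section denominator entirely.
#'
#' @param cases A `faers_cases` collection.
#' @param target_synonyms Target drug synonyms.
#' @param match Synonym matching mode.
#' @return Tibble with columns `primaryid`, `days` (whole days or `NA`),
#'   `band` (`"<7"`, `"7-28"`, `"28-60"`, `">=60"`, `"Unknown"`) and
#'   `in_section`.
#' @export
time_to_onset <- function(cases, target_synonyms, match = "substring") {
  demo <- cases$demo
  target_ids <- target_primaryids(cases, target_synonyms, match)
  dr <- cases$drugs
  hit <- dr$primaryid %in% target_ids & !is.na(dr$role) & dr$role == "PS"
  syn <- normalize_name(target_synonyms)
  nm <- normalize_name(dr$drug_name)
  ai <- normalize_name(dr$active_ingredient)
  is_syn <- rep(FALSE, nrow(dr))
  for (s in syn) {
    if (match == "substring") {
      is_syn <- is_syn | grepl(s, nm, fixed = TRUE) |
        (!is.na(ai) & grepl(s, ai, fixed = TRUE))
    } else {
      is_syn <- is_syn | nm == s | (!is.na(ai) & ai == s)
    }
  }
  tgt <- dr[hit & is_syn, ]
  # earliest therapy start per report; among ties, a day-precision record
  # makes the start usable for onset arithmetic
  starts <- tgt %>%
    dplyr::filter(!is.na(.data$therapy_start_date)) %>%
    dplyr::arrange(.data$primaryid, .data$therapy_start_date,
                   dplyr::desc(.data$therapy_start_precision == "day")) %>%
    dplyr::distinct(.data$primaryid, .keep_all = TRUE) %>%
    dplyr::transmute(.data$primaryid, start = .data$therapy_start_date,
                     start_precise = .data$therapy_start_precision == "day")
  has_start_record <- unique(tgt$primaryid[!is.na(tgt$therapy_start_date)])

  out <- tibble::tibble(primaryid = demo$primaryid) %>%
    dplyr::left_join(starts, by = "primaryid")
  ev_ok <- !is.na(demo$event_date)
  precise <- ev_ok & demo$event_date_precision == "day" &
    !is.na(out$start) & out$start_precise
  days <- as.numeric(demo$event_date - out$start)
  days[!precise | days < 0] <- NA_real_
  tibble::tibble(
    primaryid = demo$primaryid,
    days = days,
    band = ifelse(is.na(days), "Unknown", onset_band(days)),
    in_section = ev_ok | demo$primaryid %in% has_start_record
  )
}

#' Most frequently reported indications
#'
#' Indications are counted once per report (duplicate mentions within one
#' report collapse); percentages are of the total report count. Ties in
#' count order alphabetically.
#'
#' @param cases A `faers_cases` collection.
#' @param k Number of top indications to return (all, if fewer exist).
#' @return Tibble with columns `indication`, `count`, `percent`.
#' @export
top_indications <- function(cases, k = 6) {
  stopifnot(k >= 1)
  total <- n_reports(cases)
  cases$indications %>%
    dplyr::distinct(.data$primaryid, .data$indication) %>%
    dplyr::count(.data$indication, name = "count") %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$indication) %>%
    utils::head(k) %>%
    dplyr::mutate(percent = percent_of(.data$count, total))
}

section_tbl <- function(section, category, count, denominator) {
  tibble::tibble(section = section, category = as.character(category),
                 count = as.numeric(count),
                 denominator = as.numeric(denominator),
                 percent = percent_of(as.numeric(count), denominator))
}

#' Clinical characteristics summary of target-drug reports
#'
#' The standard descriptive table for a primary-suspect-filtered report
#' set: year of report, gender, age bands, reporter occupation, top
#' reporting countries, administration route, outcomes, time-to-onset bands
#' and top indications, each with count and percentage.
#'
#' Denominator conventions: demographic sections (year, gender, age,
#' reporter, country, route, indications) use the total report count;
#' outcomes use the total number of outcome records (a multi-outcome report
#' contributes one record per outcome); time-to-onset uses the reports with
#' any therapy/event date record, with an in-section `Unknown` bucket for
#' undeterminable onsets. Percentages are rounded half-up to 2 decimals.
#' The route reported is that of the target primary-suspect drug entry,
#' with unknown routes folded into `Other`.
#'
#' @param cases A deduplicated, primary-suspect-filtered `faers_cases`.
#' @param target_synonyms Target drug synonyms (for route and onset
#'   attribution).
#' @param top_countries Number of named countries (default 5); the rest
#'   fold into `Other`, missing countries are excluded from the listing.
#' @param top_k_indications Number of indications (default 6).
#' @param match Synonym matching mode.
#' @return An object of class `faers_characteristics`: a tibble with
#'   columns `section`, `category`, `count`, `denominator`, `percent`.
#' @export
summarize_characteristics <- function(cases, target_synonyms,
                                      top_countries = 5,
                                      top_k_indications = 6,
                                      match = "substring") {
  demo <- cases$demo
  total <- nrow(demo)
  if (total == 0L) {
    return(structure(section_tbl(character(0), character(0), numeric(0),
                                 numeric(0)),
                     class = c("faers_characteristics", "tbl_df", "tbl",
                               "data.frame")))
  }
  sections <- list()

  yr <- format(demo$receipt_date, "%Y")
  yr[is.na(yr)] <- "Unknown"
  yc <- sort(table(yr))
  yc <- yc[order(names(yc))]
  sections$year <- section_tbl("Year of report", names(yc), as.integer(yc),
                               total)

  sex_lab <- c(F = "Female", M = "Male", UNK = "Unknown")
  gc <- table(factor(sex_lab[demo$sex], levels = sex_lab))
  gc <- sort(gc, decreasing = TRUE)
  sections$gender <- section_tbl("Gender", names(gc), as.integer(gc), total)

  ac <- table(factor(age_band(demo$age_years), levels = .age_band_levels))
  sections$age <- section_tbl("Age", names(ac), as.integer(ac), total)

  tto <- time_to_onset(cases, target_synonyms, match)
  tto <- tto[tto$in_section, ]
  oc <- table(factor(tto$band, levels = .onset_band_levels))
  sections$onset <- section_tbl("Time to event onset (days)", names(oc),
                                as.integer(oc), sum(oc))

  rp <- table(factor(.occupation_labels[demo$reporter_occupation],
                     levels = .occupation_labels))
  rp <- sort(rp, decreasing = TRUE)
  sections$reporter <- section_tbl("Reporter", names(rp), as.integer(rp),
                                   total)

  ctry <- demo$country[!is.na(demo$country)]
  cc <- sort(table(ctry), decreasing = TRUE)
  top <- utils::head(cc, top_countries)
  other <- sum(cc) - sum(top)
  ct <- c(as.integer(top), Other = other)
  names(ct) <- c(names(top), "Other")
  ct <- sort(ct, decreasing = TRUE)
  sections$country <- section_tbl(
    sprintf("Reported countries (top %d)", top_countries),
    names(ct), ct, total)

  # route of the target PS drug entry (first by drug_seq); UNK -> Other
  target_ids <- target_primaryids(cases, target_synonyms, match)
  ps <- cases$drugs[!is.na(cases$drugs$role) & cases$drugs$role == "PS" &
                      cases$drugs$primaryid %in% target_ids, ]
  ps <- ps[order(ps$primaryid, ps$drug_seq), ]
  ps <- ps[!duplicated(ps$primaryid), ]
  route <- ifelse(ps$route == "UNK", "OTHER", ps$route)
  route_lab <- c(SUBCUTANEOUS = "Subcutaneous", ORAL = "Oral",
                 INTRAMUSCULAR = "Intramuscular", INTRAVENOUS = "Intravenous",
                 OTHER = "Other")
  rc <- sort(table(factor(route_lab[route], levels = route_lab)),
             decreasing = TRUE)
  sections$route <- section_tbl("Route", names(rc), as.integer(rc), total)

  ou <- table(factor(.outcome_labels[cases$outcomes$outcome],
                     levels = .outcome_labels))
  ou <- sort(ou, decreasing = TRUE)
  sections$outcomes <- section_tbl("Outcomes", names(ou), as.integer(ou),
                                   sum(ou))

  ti <- top_indications(cases, top_k_indications)
  sections$indications <- section_tbl(
    sprintf("Indications (top %d)", top_k_indications),
    ti$indication, ti$count, total)

  out <- dplyr::bind_rows(sections)
  class(out) <- c("faers_characteristics", class(out))
  out
}
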