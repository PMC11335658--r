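# In-code fixture builders: tiny case collections and raw FAERS files.

# One case report as a list; mk_cases() assembles a faers_cases object.
mk_report <- function(primaryid, caseid = primaryid %/% 10,
                      caseversion = primaryid %% 10,
                      sex = "F", age = 70, country = "US",
                      occupation = "CONSUMER",
                      event = NA, event_precision = "day",
                      receipt = NA,
                      drugs = list(list(name = "TERIPARATIDE",
                                        role = "PS")),
                      pts = "PT_A",
                      outcomes = character(0),
                      indications = character(0)) {
  list(primaryid = primaryid, caseid = caseid, caseversion = caseversion,
       sex = sex, age = age, country = country, occupation = occupation,
       event = event, event_precision = event_precision, receipt = receipt,
       drugs = drugs, pts = pts, outcomes = outcomes,
       indications = indications)
}

mk_cases <- function(reports) {
  demo <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(
      primaryid = r$primaryid, caseid = r$caseid,
      caseversion = as.integer(r$caseversion), sex = r$sex,
      age_years = if (is.null(r$age)) NA_real_ else as.numeric(r$age),
      age_code_raw = "YR", weight_kg = NA_real_, country = r$country,
      reporter_occupation = r$occupation,
      event_date = as.Date(r$event),
      event_date_precision = if (is.na(r$event)) NA_character_ else
        r$event_precision,
      receipt_date = as.Date(r$receipt),
      receipt_date_precision = if (is.na(r$receipt)) NA_character_ else
        "day")
  }))
  drugs <- dplyr::bind_rows(lapply(reports, function(r) {
    dplyr::bind_rows(lapply(seq_along(r$drugs), function(i) {
      d <- r$drugs[[i]]
      tibble::tibble(
        primaryid = r$primaryid, drug_seq = i, drug_name = d$name,
        active_ingredient = if (is.null(d$ai)) NA_character_ else d$ai,
        role = d$role,
        route = if (is.null(d$route)) "UNK" else d$route,
        therapy_start_date = if (is.null(d$start)) as.Date(NA) else
          as.Date(d$start),
        therapy_start_precision = if (is.null(d$start)) NA_character_ else
          if (is.null(d$start_precision)) "day" else d$start_precision)
    }))
  }))
  reactions <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(primaryid = r$primaryid, pt = r$pts)
  }))
  outcomes <- dplyr::bind_rows(lapply(reports, function(r) {
    if (length(r$outcomes) == 0) return(NULL)
    tibble::tibble(primaryid = r$primaryid, outcome = r$outcomes)
  }))
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    outcomes <- tibble::tibble(primaryid = numeric(0),
                               outcome = character(0))
  }
  indications <- dplyr::bind_rows(lapply(reports, function(r) {
    if (length(r$indications) == 0) return(NULL)
    tibble::tibble(primaryid = r$primaryid, indication = r$indications)
  }))
  if (is.null(indications) || nrow(indications) == 0) {
    indications <- tibble::tibble(primaryid = numeric(0),
                                  indication = character(0))
  }
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, indications = indications,
                 issues = c(none = 0L)),
            class = "faers_cases")
}

# Write a minimal raw FAERS quarter from per-table line vectors.
write_raw_quarter <- function(dir,
                              demo = character(0),
                              drug = character(0),
                              reac = character(0),
                              outc = character(0),
                              indi = character(0),
                              ther = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  headers <- list(
    DEMO = "primaryid$caseid$caseversion$event_dt$fda_dt$age$age_cod$sex$wt$wt_cod$occp_cod$reporter_country",
    DRUG = "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$route",
    REAC = "primaryid$caseid$pt",
    OUTC = "primaryid$caseid$outc_cod",
    INDI = "primaryid$caseid$indi_drug_seq$indi_pt",
    THER = "primaryid$caseid$dsg_drug_seq$start_dt")
  lines <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                INDI = indi, THER = ther)
  for (tb in names(headers)) {
    writeLines(c(headers[[tb]], lines[[tb]]),
               file.path(dir, paste0(tb, "23Q3.txt")))
  }
  dir
}

# small synthetic universe used by most pipeline-level tests (fast fits)
small_synth <- function(n_reports = 1500, seed = 101, ...) {
  synth_config(n_reports = n_reports, n_drugs = 12, n_pts = 30, n_socs = 6,
               target_drug_share = 0.12,
               planted = data.frame(drug = 1, pt = c(3, 25), rr = 10),
               seed = seed, ...)
}
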