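#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Column requirements per table for the supported (post-2012Q4) schema.
.faers_required_cols <- list(
  demo = c("primaryid", "caseid", "caseversion"),
  drug = c("primaryid", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt")
)

# Read one "$"-delimited FAERS ASCII table. FAERS files are unquoted, so a
# simple split is exact; rows whose field count differs from the header are
# counted as parse issues and excluded (never silently dropped).
read_faers_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("FAERS file is empty (no header): ", path, call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  body <- lines[-1L]
  fields <- strsplit(body, "$", fixed = TRUE)
  # trailing empty field is dropped by strsplit; pad rows one short where the
  # final column is empty
  nf <- lengths(fields)
  pad <- nf == length(header) - 1L & endsWith(body, "$")
  fields[pad] <- lapply(fields[pad], function(f) c(f, ""))
  nf[pad] <- length(header)
  bad <- nf != length(header)
  n_malformed <- sum(bad)
  fields <- fields[!bad]
  if (length(fields) > 0L) {
    mat <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  } else {
    mat <- matrix(character(0), ncol = length(header))
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- header
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Parse one FAERS quarterly data extract
#'
#' Reads the six `$`-delimited ASCII tables of a FAERS Quarterly Data Extract
#' (DEMO, DRUG, REAC, OUTC, INDI, THER) in the post-2012Q4 schema
#' (`primaryid`/`caseid`/`caseversion` keys). Column names are normalized to
#' lower case; malformed rows (wrong field count) and child rows whose
#' `primaryid` has no DEMO record are excluded and counted in the parse-issue
#' log, never silently dropped.
#'
#' @param dir Directory containing the quarterly files, named like
#'   `DEMO23Q3.txt`, `DRUG23Q3.txt`, ... Ignored when `paths` is given.
#' @param paths Optional named list/vector with elements `demo`, `drug`,
#'   `reac`, `outc`, `indi`, `ther` giving explicit file locations.
#' @param quarter_label Quarter label such as `"2023Q3"`; inferred from the
#'   DEMO file name when `NULL`.
#' @param schema Schema dialect identifier; only `"faers_2012q4"` (the
#'   current extract layout) is supported.
#' @return An object of class `faers_raw_quarter`: a list with one tibble per
#'   table (all columns character), `quarter_label`, and `issues` (named
#'   integer vector of excluded-row counts).
#' @seealso [build_cases()] to link the tables into case reports.
#' @export
parse_quarter <- function(dir = NULL, paths = NULL, quarter_label = NULL,
                          schema = "faers_2012q4") {
  if (!identical(schema, "faers_2012q4")) {
    stop("Unknown schema dialect: '", schema,
         "' (supported: 'faers_2012q4')", call. = FALSE)
  }
  tables <- names(.faers_required_cols)
  if (is.null(paths)) {
    if (is.null(dir)) stop("Provide either `dir` or `paths`", call. = FALSE)
    paths <- lapply(tables, function(tb) {
      hits <- list.files(dir, pattern = paste0("^", toupper(tb),
                                               ".*\\.[Tt][Xx][Tt]$"),
                         full.names = TRUE)
      if (length(hits) == 0L) {
        stop("No ", toupper(tb), " file found in ", dir, call. = FALSE)
      }
      sort(hits)[[1]]
    })
    names(paths) <- tables
  }
  paths <- as.list(paths)
  missing_tb <- setdiff(tables, names(paths))
  if (length(missing_tb)) {
    stop("Missing table paths: ", paste(missing_tb, collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(tables, function(tb) read_faers_table(paths[[tb]]))
  names(parsed) <- tables
  issues <- vapply(parsed, function(x) attr(x, "n_malformed"), integer(1))
  names(issues) <- paste0(tables, "_malformed")

  for (tb in tables) {
    need <- setdiff(.faers_required_cols[[tb]], names(parsed[[tb]]))
    if (length(need)) {
      stop("Schema error in ", toupper(tb), " table: missing column(s) ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }

  if (is.null(quarter_label)) {
    m <- regmatches(basename(paths$demo),
                    regexpr("([0-9]{2})[Qq]([1-4])", basename(paths$demo)))
    quarter_label <- if (length(m)) {
      paste0("20", substr(m, 1, 2), "Q", substr(m, 4, 4))
    } else {
      "UNKNOWN"
    }
  }
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", quarter_label) ||
              quarter_label == "UNKNOWN")

  # enforce the referential invariant: child rows must have a DEMO parent
  demo_ids <- unique(parsed$demo$primaryid)
  for (tb in setdiff(tables, "demo")) {
    orphan <- !(parsed[[tb]]$primaryid %in% demo_ids)
    issues[[paste0(tb, "_orphan")]] <- sum(orphan)
    parsed[[tb]] <- parsed[[tb]][!orphan, , drop = FALSE]
  }

  structure(c(parsed,
              list(quarter_label = quarter_label, issues = issues)),
            class = "faers_raw_quarter")
}

#' @export
print.faers_raw_quarter <- function(x, ...) {
  cat("<faers_raw_quarter> ", x$quarter_label, "\n", sep = "")
  for (tb in names(.faers_required_cols)) {
    cat(sprintf("  %-4s rows: %d\n", toupper(tb), nrow(x[[tb]])))
  }
  if (any(x$issues > 0)) {
    bad <- x$issues[x$issues > 0]
    cat("  parse issues:",
        paste(names(bad), bad, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert reported age to years
#'
#' FAERS ages carry a unit code: `DEC` (decades), `YR` (years), `MON`
#' (months), `WK` (weeks), `DY` (days), `HR` (hours). An empty code with a
#' value present is treated as years. Results outside `[0, 150]` years and
#' non-numeric values become missing.
#'
#' @param value Numeric (or character) age values.
#' @param code Character unit codes, recycled against `value`.
#' @return Numeric vector of ages in years, `NA` where undeterminable.
#' @export
#' @examples
#' normalize_age(c(720, 7.2, 2000), c("MON", "DEC", "YR")) # 60, 72, NA
normalize_age <- function(value, code) {
  value <- suppressWarnings(as.numeric(value))
  code <- toupper(trimws(as.character(code)))
  code[is.na(code) | code == ""] <- "YR"
  factor_tbl <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  mult <- unname(factor_tbl[code])
  out <- value * mult
  out[is.na(mult)] <- NA_real_
  out[!is.na(out) & (out < 0 | out > 150)] <- NA_real_
  out
}

.occp_map <- c(CN = "CONSUMER", MD = "PHYSICIAN", PH = "PHARMACIST",
               OT = "OTHER_HEALTH_PROFESSIONAL", RN = "REGISTERED_NURSE",
               LW = "LAWYER")

.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

.route_levels <- c("SUBCUTANEOUS", "ORAL", "INTRAMUSCULAR", "INTRAVENOUS",
                   "OTHER", "UNK")

map_route <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("OTHER", length(x))
  out[x == "" | is.na(x) | x %in% c("UNKNOWN", "UNK")] <- "UNK"
  out[grepl("SUBCUTANEOUS", x)] <- "SUBCUTANEOUS"
  out[grepl("^ORAL", x)] <- "ORAL"
  out[grepl("INTRAMUSCULAR", x)] <- "INTRAMUSCULAR"
  out[grepl("INTRAVENOUS", x)] <- "INTRAVENOUS"
  out
}

#' Link a parsed quarter into normalized case reports
#'
#' Joins the six raw tables into a `faers_cases` collection: a per-report
#' `demo` tibble (demographics, reporter, dates) plus child tibbles `drugs`
#' (with therapy start dates joined from THER), `reactions`, `outcomes` and
#' `indications`, all keyed by `primaryid`. Reports with no drug or no
#' reaction rows are excluded and counted in the issue log. Ages are
#' converted to years ([normalize_age()]), dates parsed with precision flags
#' ([parse_faers_date()]), reporter occupation and route codes mapped to
#' their categorical forms.
#'
#' @param raw A `faers_raw_quarter` from [parse_quarter()], or a list of
#'   several to be combined.
#' @return An object of class `faers_cases`.
#' @export
build_cases <- function(raw) {
  if (inherits(raw, "faers_raw_quarter")) raw <- list(raw)
  stopifnot(all(vapply(raw, inherits, logical(1), "faers_raw_quarter")))
  tabs <- lapply(names(.faers_required_cols), function(tb) {
    dplyr::bind_rows(lapply(raw, `[[`, tb))
  })
  names(tabs) <- names(.faers_required_cols)
  issues <- Reduce(`+`, lapply(raw, function(q) q$issues[order(names(q$issues))]))

  dm <- tabs$demo
  getcol <- function(df, nm) {
    if (nm %in% names(df)) df[[nm]] else rep(NA_character_, nrow(df))
  }
  ev <- parse_faers_date(getcol(dm, "event_dt"))
  receipt_raw <- getcol(dm, "fda_dt")
  alt <- getcol(dm, "rept_dt")
  receipt_raw[is.na(receipt_raw) | receipt_raw == ""] <-
    alt[is.na(receipt_raw) | receipt_raw == ""]
  rc <- parse_faers_date(receipt_raw)
  occp <- toupper(trimws(getcol(dm, "occp_cod")))
  wt <- suppressWarnings(as.numeric(getcol(dm, "wt")))
  wt_cod <- toupper(trimws(getcol(dm, "wt_cod")))
  wt_kg <- ifelse(wt_cod == "LBS", wt * 0.453592,
                  ifelse(wt_cod == "GMS", wt / 1000, wt))
  sex <- toupper(trimws(getcol(dm, "sex")))
  sex[!(sex %in% c("F", "M"))] <- "UNK"
  country <- trimws(getcol(dm, "reporter_country"))
  country[country == ""] <- NA_character_

  demo <- tibble::tibble(
    primaryid = as.numeric(dm$primaryid),
    caseid = as.numeric(dm$caseid),
    caseversion = suppressWarnings(as.integer(dm$caseversion)),
    sex = sex,
    age_years = normalize_age(getcol(dm, "age"), getcol(dm, "age_cod")),
    age_code_raw = {
      ac <- getcol(dm, "age_cod")
      ac[is.na(ac) | ac == ""] <- NA_character_
      ac
    },
    weight_kg = ifelse(!is.na(wt_kg) & wt_kg >= 0, wt_kg, NA_real_),
    country = country,
    reporter_occupation = unname(
      ifelse(occp %in% names(.occp_map), .occp_map[occp], "UNK")),
    event_date = ev$date,
    event_date_precision = ev$precision,
    receipt_date = rc$date,
    receipt_date_precision = rc$precision
  )
  demo$caseversion[is.na(demo$caseversion)] <- 0L

  dr <- tabs$drug
  ther <- tabs$ther
  ther_start <- parse_faers_date(ther$start_dt)
  ther_tb <- tibble::tibble(
    primaryid = as.numeric(ther$primaryid),
    drug_seq = suppressWarnings(as.integer(ther$dsg_drug_seq)),
    therapy_start_date = ther_start$date,
    therapy_start_precision = ther_start$precision
  )
  # a drug can have several therapy episodes; keep the earliest start
  ther_tb <- ther_tb %>%
    dplyr::filter(!is.na(.data$therapy_start_date)) %>%
    dplyr::arrange(.data$primaryid, .data$drug_seq,
                   .data$therapy_start_date) %>%
    dplyr::distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)

  role <- toupper(trimws(getcol(dr, "role_cod")))
  bad_role <- !(role %in% c("PS", "SS", "C", "I"))
  issues[["drug_bad_role"]] <- sum(bad_role)
  drugs <- tibble::tibble(
    primaryid = as.numeric(dr$primaryid),
    drug_seq = suppressWarnings(as.integer(getcol(dr, "drug_seq"))),
    drug_name = trimws(getcol(dr, "drugname")),
    active_ingredient = {
      ai <- trimws(getcol(dr, "prod_ai"))
      ai[ai == ""] <- NA_character_
      ai
    },
    role = ifelse(bad_role, NA_character_, role),
    route = map_route(getcol(dr, "route"))
  ) %>%
    dplyr::left_join(ther_tb, by = c("primaryid", "drug_seq"))

  rx <- tabs$reac
  reactions <- tibble::tibble(
    primaryid = as.numeric(rx$primaryid),
    pt = trimws(rx$pt)
  ) %>% dplyr::filter(.data$pt != "")

  oc <- tabs$outc
  out_code <- toupper(trimws(oc$outc_cod))
  bad_outc <- !(out_code %in% .outcome_codes)
  issues[["outc_bad_code"]] <- sum(bad_outc)
  outcomes <- tibble::tibble(
    primaryid = as.numeric(oc$primaryid),
    outcome = out_code
  )[!bad_outc, ]

  ind <- tabs$indi
  indications <- tibble::tibble(
    primaryid = as.numeric(ind$primaryid),
    indication = trimws(ind$indi_pt)
  ) %>% dplyr::filter(.data$indication != "")

  # invariant: a case report has at least one drug and one reaction
  ok_ids <- intersect(unique(drugs$primaryid), unique(reactions$primaryid))
  issues[["demo_no_drug_or_reac"]] <- sum(!(demo$primaryid %in% ok_ids))
  demo <- demo[demo$primaryid %in% ok_ids, ]
  keep <- demo$primaryid
  structure(list(
    demo = dplyr::arrange(demo, .data$caseid, .data$primaryid),
    drugs = drugs[drugs$primaryid %in% keep, ],
    reactions = reactions[reactions$primaryid %in% keep, ],
    outcomes = outcomes[outcomes$primaryid %in% keep, ],
    indications = indications[indications$primaryid %in% keep, ],
    issues = issues
  ), class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " case reports\n", sep = "")
  cat("  drug rows:       ", nrow(x$drugs), "\n", sep = "")
  cat("  reaction rows:   ", nrow(x$reactions), "\n", sep = "")
  cat("  outcome rows:    ", nrow(x$outcomes), "\n", sep = "")
  cat("  indication rows: ", nrow(x$indications), "\n", sep = "")
  invisible(x)
}

#' Number of case reports in a collection
#' @param cases A `faers_cases` object.
#' @return Integer count of reports.
#' @export
n_reports <- function(cases) nrow(cases$demo)

# restrict all child tables to a set of surviving primaryids
subset_cases <- function(cases, keep_ids) {
  out <- cases
  out$demo <- cases$demo[cases$demo$primaryid %in% keep_ids, ]
  for (tb in c("drugs", "reactions", "outcomes", "indications")) {
    out[[tb]] <- cases[[tb]][cases[[tb]]$primaryid %in% keep_ids, ]
  }
  out
}

#' Deduplicate case versions
#'
#' FAERS follow-up reports share a `caseid` with an incremented
#' `caseversion`. Exactly one report per `caseid` survives: the highest
#' `caseversion`, ties broken by latest `receipt_date` (missing dates sort
#' last) then largest `primaryid`. Case ids on the deleted list are removed
#' entirely. The operation is idempotent and the output ordering (by
#' `caseid`) is deterministic.
#'
#' @param cases A `faers_cases` object.
#' @param deleted_caseids Optional vector of case ids to drop (FDA deleted
#'   case lists).
#' @return A deduplicated `faers_cases` object.
#' @export
deduplicate <- function(cases, deleted_caseids = NULL) {
  demo <- cases$demo
  if (!is.null(deleted_caseids) && length(deleted_caseids)) {
    demo <- demo[!(demo$caseid %in% as.numeric(deleted_caseids)), ]
  }
  if (nrow(demo) == 0L) return(subset_cases(cases, numeric(0)))
  ord <- order(demo$caseid,
               -demo$caseversion,
               -ifelse(is.na(as.numeric(demo$receipt_date)), -Inf,
                       as.numeric(demo$receipt_date)),
               -demo$primaryid)
  demo <- demo[ord, ]
  demo <- demo[!duplicated(demo$caseid), ]
  subset_cases(cases, demo$primaryid)
}

#' Filter to reports with the target drug as primary suspect
#'
#' Retains exactly the reports containing at least one drug entry with role
#' `PS` whose `drug_name` or `active_ingredient` matches any synonym,
#' case-insensitively after trimming and collapsing whitespace. Matching is
#' substring by default (FAERS verbatim drug names are noisy, e.g.
#' `"FORTEO (TERIPARATIDE)"`), or exact.
#'
#' @param cases A `faers_cases` object (deduplicate first).
#' @param synonyms Non-empty character vector of drug-name patterns, e.g.
#'   `c("TERIPARATIDE", "FORTEO", "FORSTEO", "BONSITY")`.
#' @param match `"substring"` (default) or `"exact"`.
#' @return A `faers_cases` object restricted to matching reports.
#' @export
filter_primary_suspect <- function(cases, synonyms,
                                   match = c("substring", "exact")) {
  match <- match.arg(match)
  if (length(synonyms) == 0L) stop("`synonyms` must be non-empty",
                                   call. = FALSE)
  subset_cases(cases, target_primaryids(cases, synonyms, match))
}

# primaryids of reports with a PS drug matching any synonym
target_primaryids <- function(cases, synonyms, match = "substring") {
  syn <- normalize_name(synonyms)
  ps <- cases$drugs[!is.na(cases$drugs$role) & cases$drugs$role == "PS", ]
  nm <- normalize_name(ps$drug_name)
  ai <- normalize_name(ps$active_ingredient)
  ai[is.na(ps$active_ingredient)] <- NA_character_
  hit <- rep(FALSE, nrow(ps))
  for (s in syn) {
    if (match == "substring") {
      hit <- hit | grepl(s, nm, fixed = TRUE) |
        (!is.na(ai) & grepl(s, ai, fixed = TRUE))
    } else {
      hit <- hit | nm == s | (!is.na(ai) & ai == s)
    }
  }
  unique(ps$primaryid[hit])
}

#' Serialize case reports to CSV
#'
#' Writes the five component tables of a `faers_cases` object as plain CSV
#' files (`demo.csv`, `drugs.csv`, `reactions.csv`, `outcomes.csv`,
#' `indications.csv`) in `dir`, plus `parse_issues.csv` recording the issue
#' log. [cases_from_csv()] restores an identical collection.
#'
#' @param cases A `faers_cases` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cases_to_csv <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("demo", "drugs", "reactions", "outcomes", "indications")) {
    utils::write.csv(cases[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(
    data.frame(issue = names(cases$issues), n = as.integer(cases$issues)),
    file.path(dir, "parse_issues.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read case reports back from CSV
#' @param dir Directory written by [cases_to_csv()].
#' @return A `faers_cases` object.
#' @export
cases_from_csv <- function(dir) {
  rd <- function(nm) {
    tibble::as_tibble(utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                      stringsAsFactors = FALSE,
                                      na.strings = ""))
  }
  demo <- rd("demo")
  for (cl in c("event_date", "receipt_date")) {
    demo[[cl]] <- as.Date(demo[[cl]])
  }
  demo$caseversion <- as.integer(demo$caseversion)
  drugs <- rd("drugs")
  drugs$therapy_start_date <- as.Date(drugs$therapy_start_date)
  drugs$drug_seq <- as.integer(drugs$drug_seq)
  iss <- utils::read.csv(file.path(dir, "parse_issues.csv"),
                         stringsAsFactors = FALSE)
  issues <- stats::setNames(as.integer(iss$n), iss$issue)
  structure(list(demo = demo, drugs = drugs, reactions = rd("reactions"),
                 outcomes = rd("outcomes"), indications = rd("indications"),
                 issues = issues),
            class = "faers_cases")
}
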