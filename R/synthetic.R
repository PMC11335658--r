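#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a FAERS-like database: background drug and event reporting
#' frequencies, a designated target drug, planted drug-event signals with
#' known relative reporting rates, duplicate case versions, a deleted-case
#' list, and missingness. Drug 1 is the target drug (named
#' `target_drug_name`); remaining drugs get synthetic names. Event terms
#' (`PT_001`, ...) map round-robin onto synthetic organ classes
#' (`SOC_01`, ...).
#'
#' @param n_reports Number of base case reports.
#' @param n_drugs,n_pts,n_socs Universe sizes.
#' @param target_drug_share Probability that a report's primary suspect is
#'   the target drug.
#' @param planted Data frame with columns `drug`, `pt` (1-based indices)
#'   and `rr` (relative reporting rate multiplier, `>= 1`) for planted
#'   signals; the named PT's selection probability is multiplied by `rr`
#'   (then renormalized) in reports whose primary suspect is that drug.
#'   The default plants three ten-fold pairs on the target drug, at a
#'   common, a mid-frequency and a rare event term (scaled to `n_pts`).
#' @param drugs_per_report_mean,pts_per_report_mean Mean number of drug /
#'   reaction entries per report (1 plus a Poisson excess).
#' @param duplicate_rate Fraction of cases re-emitted as a follow-up
#'   version (`caseversion = 2`).
#' @param deleted_rate Fraction of caseids put on the deleted-case list.
#' @param missing_sex_rate,missing_age_rate,missing_date_rate Missingness.
#' @param imprecise_date_rate Fraction of dates degraded to year-month
#'   precision (exercises the imprecise-date path).
#' @param onset_gap_meanlog,onset_gap_sdlog Log-normal therapy-to-event gap
#'   (days).
#' @param target_drug_name Verbatim name of drug 1.
#' @param quarter Quarter label, e.g. `"2023Q3"`.
#' @param seed Integer seed; a given (config, seed) is byte-reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_reports = 50000,
                         n_drugs = 40, n_pts = 120, n_socs = 12,
                         target_drug_share = 0.05,
                         planted = NULL,
                         drugs_per_report_mean = 2,
                         pts_per_report_mean = 3,
                         duplicate_rate = 0.02,
                         deleted_rate = 0.01,
                         missing_sex_rate = 0.02,
                         missing_age_rate = 0.15,
                         missing_date_rate = 0.2,
                         imprecise_date_rate = 0.05,
                         onset_gap_meanlog = 3,
                         onset_gap_sdlog = 1.2,
                         target_drug_name = "TERIPARATIDE",
                         quarter = "2023Q3",
                         seed = 20240101) {
  if (is.null(planted)) {
    planted <- data.frame(
      drug = 1,
      pt = unique(pmax(1, ceiling(n_pts * c(0.05, 0.2, 0.8)))),
      rr = 10)
  }
  cfg <- as.list(environment())
  stopifnot(n_reports >= 1, n_drugs >= 2, n_pts >= 2, n_socs >= 1,
            target_drug_share > 0, target_drug_share < 1,
            drugs_per_report_mean >= 1, pts_per_report_mean >= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            deleted_rate >= 0, deleted_rate < 1)
  if (nrow(planted) > 0) {
    if (any(planted$pt < 1 | planted$pt > n_pts) ||
        any(planted$drug < 1 | planted$drug > n_drugs)) {
      stop("Planted pair indices out of range for the configured universe",
           call. = FALSE)
    }
    if (any(planted$rr < 1)) {
      stop("Planted relative reporting rates must be >= 1", call. = FALSE)
    }
  }
  structure(cfg, class = "synth_config")
}

synth_drug_names <- function(cfg) {
  c(cfg$target_drug_name,
    sprintf("DRUG_%03d", seq_len(cfg$n_drugs - 1)))
}

synth_pt_names <- function(cfg) sprintf("PT_%03d", seq_len(cfg$n_pts))

synth_pt_soc_table <- function(cfg) {
  data.frame(
    pt = synth_pt_names(cfg),
    soc = sprintf("SOC_%02d", ((seq_len(cfg$n_pts) - 1) %% cfg$n_socs) + 1),
    stringsAsFactors = FALSE)
}

#' Write the synthetic PT to SOC map
#'
#' Every synthetic PT maps to exactly one synthetic SOC, round-robin, so no
#' licensed dictionary content is needed to run the pipeline end to end.
#'
#' @param config A `synth_config`.
#' @param path Output CSV path (columns `pt`, `soc`).
#' @return `path`, invisibly.
#' @export
emit_pt_soc_map <- function(config, path) {
  utils::write.csv(synth_pt_soc_table(config), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

fmt_date <- function(d, precision) {
  out <- format(d, "%Y%m%d")
  out[precision == "month"] <- format(d[precision == "month"], "%Y%m")
  out[is.na(d)] <- ""
  out
}

#' Generate a synthetic FAERS quarter with known ground truth
#'
#' Emits a full `$`-delimited quarterly file set (DEMO/DRUG/REAC/OUTC/INDI/
#' THER), a deleted-case list, a toy PT-to-SOC map, and a ground-truth
#' manifest (JSON) recording the planted signals, their realized exposure
#' counts among surviving target reports, duplicate/deleted bookkeeping and
#' the expected post-deduplication report count.
#'
#' Reports are drawn independently. Each report gets one primary-suspect
#' drug (the target with probability `target_drug_share`) plus background
#' co-medications, and reaction terms from a background frequency simplex;
#' for reports whose primary suspect participates in a planted pair, that
#' PT's selection probability is multiplied by `rr` and renormalized —
#' planting the signal multiplicatively on the same relative reporting rate
#' that the disproportionality statistics estimate. Duplicates are emitted
#' as extra case versions of sampled caseids. All randomness derives from
#' `config$seed`: identical (config, seed) yields byte-identical files.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the emitted `paths` and the `manifest`
#'   (also written as `manifest.json`).
#' @export
generate_quarter <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_reports
  drug_names <- synth_drug_names(cfg)
  pt_names <- synth_pt_names(cfg)

  # background frequency simplices (power-law, realistic skew)
  w_drug <- 1 / seq_len(cfg$n_drugs - 1)^0.6
  ps_prob <- c(cfg$target_drug_share,
               (1 - cfg$target_drug_share) * w_drug / sum(w_drug))
  w_pt <- 1 / seq_len(cfg$n_pts)^0.5
  w_pt <- w_pt / sum(w_pt)

  caseid <- 1000000 + seq_len(n)
  primaryid <- caseid * 10 + 1

  ps_drug <- sample.int(cfg$n_drugs, n, replace = TRUE, prob = ps_prob)

  # reactions: grouped by whether the PS drug carries planted signals
  npts <- 1L + stats::rpois(n, cfg$pts_per_report_mean - 1)
  pt_of_report <- vector("list", n)
  planted_drugs <- unique(cfg$planted$drug)
  grp_plain <- !(ps_drug %in% planted_drugs)
  draw_group <- function(idx, w) {
    if (!length(idx)) return()
    k <- npts[idx]
    draws <- sample.int(cfg$n_pts, sum(k), replace = TRUE, prob = w)
    pt_of_report[idx] <<- split(draws, rep(seq_along(idx), k))
  }
  draw_group(which(grp_plain), w_pt)
  for (dg in planted_drugs) {
    w <- w_pt
    rows <- cfg$planted[cfg$planted$drug == dg, ]
    w[rows$pt] <- w[rows$pt] * rows$rr
    draw_group(which(ps_drug == dg), w / sum(w))
  }

  # co-medications with non-PS roles
  n_extra <- stats::rpois(n, cfg$drugs_per_report_mean - 1)
  extra_drug <- sample.int(cfg$n_drugs, sum(n_extra), replace = TRUE,
                           prob = ps_prob)
  extra_role <- sample(c("SS", "C", "I"), sum(n_extra), replace = TRUE,
                       prob = c(0.5, 0.4, 0.1))

  # demographics
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.88, 0.12))
  sex[stats::runif(n) < cfg$missing_sex_rate] <- ""
  age_years <- round(pmin(pmax(stats::rnorm(n, 71, 12), 18), 100))
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.93, 0.05, 0.02))
  age_val <- ifelse(age_cod == "DEC", age_years / 10,
                    ifelse(age_cod == "MON", age_years * 12, age_years))
  miss_age <- stats::runif(n) < cfg$missing_age_rate
  age_val[miss_age] <- NA
  age_cod[miss_age] <- ""
  wt <- round(stats::rnorm(n, 62, 10), 1)
  miss_wt <- stats::runif(n) < 0.6
  occp <- sample(c("CN", "MD", "OT", "PH", "RN", "LW", ""), n,
                 replace = TRUE,
                 prob = c(0.55, 0.15, 0.08, 0.05, 0.01, 0.002, 0.158))
  country <- sample(c("US", "JP", "ES", "DE", "GB", "FR", "CA", "IT"), n,
                    replace = TRUE,
                    prob = c(0.55, 0.12, 0.08, 0.07, 0.06, 0.05, 0.04,
                             0.03))

  # therapy start / event / receipt dates
  start <- as.Date("2015-01-01") + sample.int(3000, n, replace = TRUE)
  gap <- round(stats::rlnorm(n, cfg$onset_gap_meanlog, cfg$onset_gap_sdlog))
  event <- start + gap
  miss_start <- stats::runif(n) < cfg$missing_date_rate
  miss_event <- stats::runif(n) < cfg$missing_date_rate
  start_prec <- ifelse(stats::runif(n) < cfg$imprecise_date_rate,
                       "month", "day")
  event_prec <- ifelse(stats::runif(n) < cfg$imprecise_date_rate,
                       "month", "day")
  start[miss_start] <- NA
  event[miss_event] <- NA
  receipt <- pmax(event, start, na.rm = TRUE)
  receipt[is.na(receipt)] <- as.Date("2023-06-30")
  receipt <- receipt + sample.int(60, n, replace = TRUE)

  # outcomes (0-2 records per report)
  n_outc <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  outc_cod <- sample(c("HO", "OT", "DE", "LT", "DS", "RI", "CA"),
                     sum(n_outc), replace = TRUE,
                     prob = c(0.35, 0.40, 0.08, 0.05, 0.06, 0.04, 0.02))

  # one indication per report, attached to the PS drug
  indi <- sample(c("Osteoporosis", "Senile osteoporosis",
                   "Osteoporosis postmenopausal", "Osteopenia",
                   "Bone disorder", "Product used for unknown indication"),
                 n, replace = TRUE,
                 prob = c(0.62, 0.08, 0.06, 0.05, 0.04, 0.15))

  # duplicates: follow-up versions of sampled caseids
  n_dup <- floor(cfg$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  # deleted-case list (kept disjoint from nothing; may overlap duplicates)
  n_del <- floor(cfg$deleted_rate * n)
  del_idx <- if (n_del > 0) sort(sample.int(n, n_del)) else integer(0)
  deleted_caseids <- caseid[del_idx]

  route_target <- function(m) {
    sample(c("Subcutaneous", "Unknown", "Oral"), m, replace = TRUE,
           prob = c(0.7, 0.25, 0.05))
  }
  route_other <- function(m) {
    sample(c("Oral", "Intravenous", "Subcutaneous", "Unknown",
             "Intramuscular"), m, replace = TRUE,
           prob = c(0.5, 0.1, 0.1, 0.25, 0.05))
  }

  # assemble row blocks for the base version of every report
  ps_route <- ifelse(ps_drug == 1, route_target(n), route_other(n))
  drug_rows <- data.frame(
    idx = c(seq_len(n), rep(seq_len(n), n_extra)),
    drug_seq = c(rep(1L, n),
                 unlist(lapply(n_extra, function(k) seq_len(k) + 1L),
                        use.names = FALSE)),
    role = c(rep("PS", n), extra_role),
    drug = drug_names[c(ps_drug, extra_drug)],
    route = c(ps_route, route_other(sum(n_extra))),
    stringsAsFactors = FALSE)
  drug_rows <- drug_rows[order(drug_rows$idx, drug_rows$drug_seq), ]

  reac_rows <- data.frame(
    idx = rep(seq_len(n), npts),
    pt = pt_names[unlist(pt_of_report, use.names = FALSE)],
    stringsAsFactors = FALSE)

  outc_rows <- data.frame(idx = rep(seq_len(n), n_outc), outc = outc_cod,
                          stringsAsFactors = FALSE)

  # emit a report's rows under a given (primaryid, caseversion)
  version_of <- rep(1L, n)
  emit_ids <- seq_len(n)
  emit_pid <- primaryid
  emit_ver <- version_of
  emit_receipt <- receipt
  if (n_dup > 0) {
    emit_ids <- c(emit_ids, dup_idx)
    emit_pid <- c(emit_pid, caseid[dup_idx] * 10 + 2)
    emit_ver <- c(emit_ver, rep(2L, n_dup))
    emit_receipt <- c(emit_receipt, receipt[dup_idx] + 7)
  }
  ord <- order(emit_pid)
  emit_ids <- emit_ids[ord]
  emit_pid <- emit_pid[ord]
  emit_ver <- emit_ver[ord]
  emit_receipt <- emit_receipt[ord]

  demo_lines <- paste(
    emit_pid, caseid[emit_ids], emit_ver,
    fmt_date(event[emit_ids], event_prec[emit_ids]),
    format(emit_receipt, "%Y%m%d"),
    ifelse(is.na(age_val[emit_ids]), "", age_val[emit_ids]),
    age_cod[emit_ids], sex[emit_ids],
    ifelse(miss_wt[emit_ids], "", wt[emit_ids]),
    ifelse(miss_wt[emit_ids], "", "KG"),
    occp[emit_ids], country[emit_ids],
    sep = "$")

  expand <- function(rows) {
    m <- match(rows$idx, emit_ids)  # first occurrence; need all versions
    # build mapping idx -> all emitted (pid, version) rows
    reps <- split(seq_along(emit_ids), emit_ids)
    take <- reps[as.character(rows$idx)]
    k <- lengths(take)
    data.frame(row = rep(seq_len(nrow(rows)), k),
               emit = unlist(take, use.names = FALSE))
  }
  ex_drug <- expand(drug_rows)
  drug_lines <- paste(
    emit_pid[ex_drug$emit], caseid[emit_ids[ex_drug$emit]],
    drug_rows$drug_seq[ex_drug$row], drug_rows$role[ex_drug$row],
    drug_rows$drug[ex_drug$row], drug_rows$drug[ex_drug$row],
    drug_rows$route[ex_drug$row],
    sep = "$")
  ex_reac <- expand(reac_rows)
  reac_lines <- paste(emit_pid[ex_reac$emit],
                      caseid[emit_ids[ex_reac$emit]],
                      reac_rows$pt[ex_reac$row], sep = "$")
  ex_outc <- if (nrow(outc_rows)) expand(outc_rows) else
    data.frame(row = integer(0), emit = integer(0))
  outc_lines <- paste(emit_pid[ex_outc$emit],
                      caseid[emit_ids[ex_outc$emit]],
                      outc_rows$outc[ex_outc$row], sep = "$")
  indi_lines <- paste(emit_pid, caseid[emit_ids], 1L, indi[emit_ids],
                      sep = "$")
  ther_keep <- !is.na(start[emit_ids])
  ther_lines <- paste(emit_pid[ther_keep], caseid[emit_ids[ther_keep]], 1L,
                      fmt_date(start[emit_ids[ther_keep]],
                               start_prec[emit_ids[ther_keep]]),
                      sep = "$")

  qq <- sub("^20([0-9]{2})Q([1-4])$", "\\1Q\\2", cfg$quarter)
  wf <- function(stem, header, lines) {
    p <- file.path(dir, paste0(stem, qq, ".txt"))
    writeLines(c(header, lines), p)
    p
  }
  paths <- list(
    demo = wf("DEMO",
              "primaryid$caseid$caseversion$event_dt$fda_dt$age$age_cod$sex$wt$wt_cod$occp_cod$reporter_country",
              demo_lines),
    drug = wf("DRUG", "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$route",
              drug_lines),
    reac = wf("REAC", "primaryid$caseid$pt", reac_lines),
    outc = wf("OUTC", "primaryid$caseid$outc_cod", outc_lines),
    indi = wf("INDI", "primaryid$caseid$indi_drug_seq$indi_pt", indi_lines),
    ther = wf("THER", "primaryid$caseid$dsg_drug_seq$start_dt", ther_lines)
  )
  deleted_path <- file.path(dir, "deleted_cases.txt")
  writeLines(as.character(deleted_caseids), deleted_path)
  map_path <- file.path(dir, "pt_soc_map.csv")
  emit_pt_soc_map(cfg, map_path)

  # ground truth: realized counts among surviving (post-dedup, non-deleted)
  # reports; duplicates carry identical content so survivors are the base
  # reports of non-deleted caseids
  surviving <- setdiff(seq_len(n), del_idx)
  target_ps_ids <- surviving[ps_drug[surviving] == 1]
  realized <- lapply(seq_len(nrow(cfg$planted)), function(i) {
    dg <- cfg$planted$drug[i]; pt <- cfg$planted$pt[i]
    ids <- surviving[ps_drug[surviving] == dg]
    a <- sum(vapply(pt_of_report[ids], function(p) pt %in% p, logical(1)))
    list(drug = drug_names[dg], pt = pt_names[pt],
         rr = cfg$planted$rr[i], realized_a = a)
  })
  manifest <- list(
    quarter = cfg$quarter,
    seed = cfg$seed,
    n_reports = n,
    n_duplicates = n_dup,
    n_deleted = length(unique(deleted_caseids)),
    expected_survivors = length(surviving),
    expected_target_ps_reports = length(target_ps_ids),
    target_drug = cfg$target_drug_name,
    planted = realized,
    deleted_caseids = deleted_caseids,
    pt_soc_map = basename(map_path)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, deleted = deleted_path,
                 pt_soc = map_path, manifest_path = manifest_path,
                 manifest = manifest))
}
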