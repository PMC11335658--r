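#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis needs: input location (a
#' directory of FAERS quarterly files, or a [synth_config()] to generate
#' one), target drug synonyms, the PT-SOC map, thresholds, subgroup
#' specifications, counting options and output directory.
#'
#' @param input_dir Directory with quarterly files (and optionally
#'   `deleted_cases.txt`, `pt_soc_map.csv`); `NULL` when `synth` is given.
#' @param synth Optional [synth_config()]; the corpus is generated under
#'   `out_dir/input`.
#' @param target_synonyms Drug-name synonyms of the target drug. Default:
#'   the teriparatide brand/generic set.
#' @param pt_soc_map Path to the PT-SOC CSV; defaults to
#'   `pt_soc_map.csv` in the input directory.
#' @param deleted_cases Path to a deleted-case list (one caseid per line),
#'   `NULL` to skip, or `"auto"` to use `deleted_cases.txt` when present.
#' @param thresholds A [signal_thresholds()].
#' @param subgroups Named list of [subgroup_spec()]s (default:
#'   [subgroup_presets()]).
#' @param zero_policy,yates Statistic options (see [ror()],
#'   [chi_square()]).
#' @param match Synonym matching mode.
#' @param top_k Size of the EBGM-ranked top table (default 30).
#' @param out_dir Output directory.
#' @param seed Integer seed for the stochastic components (MGPS restart
#'   jitter; synthetic generation keeps its own seed).
#' @return An object of class `pv_run_config`.
#' @export
run_config <- function(input_dir = NULL, synth = NULL,
                       target_synonyms = c("TERIPARATIDE", "FORTEO",
                                           "FORSTEO", "BONSITY"),
                       pt_soc_map = NULL, deleted_cases = "auto",
                       thresholds = signal_thresholds(),
                       subgroups = subgroup_presets(),
                       zero_policy = "haldane", yates = TRUE,
                       match = "substring", top_k = 30,
                       out_dir = "pvsignal_out", seed = 1) {
  if (is.null(input_dir) && is.null(synth)) {
    stop("Provide `input_dir` or `synth`", call. = FALSE)
  }
  structure(as.list(environment()), class = "pv_run_config")
}

# score one level for one report set; returns classified signal table
signal_table <- function(cases, synonyms, map, level, thresholds,
                         zero_policy, yates, match, subgroup = "all") {
  counts <- count_pairs(cases, synonyms, match)
  if (level == "SOC") counts <- aggregate_soc(counts, map)
  counts$subgroup <- subgroup
  tables <- build_contingency(counts)
  hyper <- NULL
  if (nrow(tables) > 0 && counts$n > 0) {
    cells <- mgps_cells(cases, map = if (level == "SOC") map else NULL)
    cells <- cells[cells$E > 0, ]
    if (sum(cells$a > 0) >= 2) {
      hyper <- fit_mgps_prior(cells$a, cells$E)
    }
  }
  scored <- compute_signal_stats(tables, hyper = hyper,
                                 thresholds = thresholds,
                                 zero_policy = zero_policy, yates = yates)
  attr(scored, "hyper") <- hyper
  scored
}

write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- signif(df[[cl]], 10)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full signal-detection pipeline
#'
#' Executes parse, deduplication, primary-suspect filtering, the
#' clinical-characteristics summary (overall and per subgroup), PT- and
#' SOC-level contingency tables, the four disproportionality statistics and
#' signal classification, writing all output tables to
#' `config$out_dir`:
#'
#' * `characteristics.csv` — descriptive summary (all subgroups stacked)
#' * `pt_signals.csv`, `soc_signals.csv` — full score tables
#' * `waterfall.csv` — PT terms sorted by EBGM descending (all statistics)
#' * `top30_pt.csv` — the EBGM-ranked top `top_k` PT table
#' * `subgroup_<name>_signals.csv` — per-subgroup PT+SOC score tables
#' * `run_metadata.json` — versions, options and decisions in effect
#'
#' Outputs are deterministic given (config, seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  input_dir <- cfg$input_dir
  if (!is.null(cfg$synth)) {
    input_dir <- file.path(cfg$out_dir, "input")
    generate_quarter(cfg$synth, input_dir)
  }

  raw <- parse_quarter(input_dir)
  cases_all <- build_cases(raw)

  deleted <- NULL
  del_path <- cfg$deleted_cases
  if (identical(del_path, "auto")) {
    del_path <- file.path(input_dir, "deleted_cases.txt")
    if (!file.exists(del_path)) del_path <- NULL
  }
  if (!is.null(del_path)) {
    deleted <- as.numeric(readLines(del_path, warn = FALSE))
    deleted <- deleted[!is.na(deleted)]
  }
  cases_all <- deduplicate(cases_all, deleted)

  map_path <- cfg$pt_soc_map
  if (is.null(map_path)) map_path <- file.path(input_dir, "pt_soc_map.csv")
  map <- load_pt_soc_map(map_path)

  target_cases <- filter_primary_suspect(cases_all, cfg$target_synonyms,
                                         cfg$match)

  # descriptive characteristics: overall + per subgroup
  char_all <- summarize_characteristics(target_cases, cfg$target_synonyms,
                                        match = cfg$match)
  char_all$subgroup <- "all"
  char_list <- list(char_all)
  for (nm in names(cfg$subgroups)) {
    sub_cases <- apply_subgroup(target_cases, cfg$subgroups[[nm]])
    ch <- summarize_characteristics(sub_cases, cfg$target_synonyms,
                                    match = cfg$match)
    if (nrow(ch) > 0) ch$subgroup <- nm
    char_list[[nm]] <- ch
  }
  characteristics <- dplyr::bind_rows(char_list)

  set.seed(cfg$seed)
  pt_signals <- signal_table(cases_all, cfg$target_synonyms, map, "PT",
                             cfg$thresholds, cfg$zero_policy, cfg$yates,
                             cfg$match)
  set.seed(cfg$seed + 1)
  soc_signals <- signal_table(cases_all, cfg$target_synonyms, map, "SOC",
                              cfg$thresholds, cfg$zero_policy, cfg$yates,
                              cfg$match)

  sub_signals <- subgroup_runs(cases_all, cfg, map)

  waterfall <- pt_signals %>%
    dplyr::arrange(dplyr::desc(.data$ebgm), .data$term)
  top_pt <- utils::head(waterfall, cfg$top_k)

  paths <- list(
    characteristics = write_csv_plain(
      characteristics, file.path(cfg$out_dir, "characteristics.csv")),
    pt_signals = write_csv_plain(
      pt_signals, file.path(cfg$out_dir, "pt_signals.csv")),
    soc_signals = write_csv_plain(
      soc_signals, file.path(cfg$out_dir, "soc_signals.csv")),
    waterfall = write_csv_plain(
      waterfall, file.path(cfg$out_dir, "waterfall.csv")),
    top30_pt = write_csv_plain(
      top_pt, file.path(cfg$out_dir, "top30_pt.csv"))
  )
  for (nm in names(sub_signals)) {
    paths[[paste0("subgroup_", nm)]] <- write_csv_plain(
      sub_signals[[nm]],
      file.path(cfg$out_dir, sprintf("subgroup_%s_signals.csv", nm)))
  }

  hyper <- attr(pt_signals, "hyper")
  metadata <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    seed = cfg$seed,
    quarters = raw$quarter_label,
    n_reports_parsed = n_reports(build_cases(raw)),
    n_reports_deduplicated = n_reports(cases_all),
    n_target_ps_reports = n_reports(target_cases),
    parse_issues = as.list(cases_all$issues),
    target_synonyms = cfg$target_synonyms,
    match_mode = cfg$match,
    counting_unit = "distinct (report, term) pair",
    dedup_rule = "max caseversion, then latest receipt date, then max primaryid; deleted-case list applied when present",
    zero_policy = cfg$zero_policy,
    yates = cfg$yates,
    thresholds = unclass(cfg$thresholds),
    bcpnn_moments = "approx (closed-form moment approximation)",
    mgps_prior = if (!is.null(hyper)) {
      unclass(hyper)
    } else {
      "not fitted (too few nonzero cells)"
    }
  )
  meta_path <- file.path(cfg$out_dir, "run_metadata.json")
  jsonlite::write_json(metadata, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$run_metadata <- meta_path

  invisible(list(characteristics = characteristics,
                 pt_signals = pt_signals, soc_signals = soc_signals,
                 subgroup_signals = sub_signals,
                 waterfall = waterfall, top_pt = top_pt,
                 cases = cases_all, target_cases = target_cases,
                 paths = paths))
}

#' Per-subgroup signal tables
#'
#' Recomputes the PT- and SOC-level score tables within each configured
#' subgroup, using the subgroup's own margins and totals (the comparator is
#' the same-subgroup non-target pairs). The subgroup name is stamped in
#' every row. An empty subgroup yields a zero-row table with a warning.
#'
#' @param cases The deduplicated full database (`faers_cases`).
#' @param config A [run_config()].
#' @param map A `pt_soc_map` (loaded from `config` when `NULL`).
#' @return Named list of score tibbles, one per subgroup.
#' @export
subgroup_runs <- function(cases, config, map = NULL) {
  cfg <- config
  if (is.null(map)) map <- load_pt_soc_map(cfg$pt_soc_map)
  out <- list()
  i <- 0L
  for (nm in names(cfg$subgroups)) {
    i <- i + 1L
    sub_cases <- apply_subgroup(cases, cfg$subgroups[[nm]])
    if (n_reports(sub_cases) == 0L) {
      warning("Subgroup '", nm, "' is empty; emitting zero-row table",
              call. = FALSE)
      out[[nm]] <- compute_signal_stats(
        tibble::tibble(term = character(0), level = character(0),
                       subgroup = character(0), a = numeric(0),
                       b = numeric(0), c = numeric(0), d = numeric(0),
                       n = numeric(0)),
        thresholds = cfg$thresholds)
      next
    }
    set.seed(cfg$seed + 100 + i)
    pt <- signal_table(sub_cases, cfg$target_synonyms, map, "PT",
                       cfg$thresholds, cfg$zero_policy, cfg$yates,
                       cfg$match, subgroup = nm)
    set.seed(cfg$seed + 200 + i)
    soc <- signal_table(sub_cases, cfg$target_synonyms, map, "SOC",
                        cfg$thresholds, cfg$zero_policy, cfg$yates,
                        cfg$match, subgroup = nm)
    out[[nm]] <- dplyr::bind_rows(pt, soc)
  }
  out
}
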