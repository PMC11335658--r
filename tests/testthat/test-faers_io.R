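test_that("a DEMO file with header and two records parses to two rows", {
  d <- write_raw_quarter(
    withr::local_tempdir(),
    demo = c("11$1$1$20230101$20230201$70$YR$F$60$KG$MD$US",
             "21$2$1$20230102$20230202$65$YR$M$$$CN$JP"),
    drug = c("11$1$1$PS$TERIPARATIDE$TERIPARATIDE$Subcutaneous",
             "21$2$1$SS$DRUG_001$DRUG_001$Oral",
             "21$2$2$C$DRUG_002$$Unknown",
             "11$1$2$I$DRUG_003$$Oral"),
    reac = c("11$1$PT_A", "21$2$PT_B"))
  raw <- parse_quarter(d)
  expect_s3_class(raw, "faers_raw_quarter")
  expect_equal(nrow(raw$demo), 2L)
  expect_equal(raw$quarter_label, "2023Q3")
  expect_true(all(names(raw$demo) == tolower(names(raw$demo))))

  cases <- build_cases(raw)
  expect_equal(n_reports(cases), 2L)
  # the four FAERS role codes map onto the role enum
  expect_setequal(cases$drugs$role, c("PS", "SS", "C", "I"))
  expect_equal(cases$drugs$route[cases$drugs$role == "PS"], "SUBCUTANEOUS")
})

test_that("a row with the wrong field count is excluded and counted", {
  d <- write_raw_quarter(
    withr::local_tempdir(),
    demo = c("11$1$1$20230101$20230201$70$YR$F$60$KG$MD$US",
             "21$2$1$20230102",  # too few fields
             "31$3$1$20230103$20230203$71$YR$F$$$CN$US"),
    drug = c("11$1$1$PS$TERIPARATIDE$$",
             "31$3$1$PS$TERIPARATIDE$$"),
    reac = c("11$1$PT_A", "31$3$PT_A"))
  raw <- parse_quarter(d)
  expect_equal(nrow(raw$demo), 2L)
  expect_equal(unname(raw$issues[["demo_malformed"]]), 1L)
})

test_that("schema violations are explicit errors", {
  d <- withr::local_tempdir()
  write_raw_quarter(d)
  # clobber DEMO with a file lacking caseversion
  writeLines(c("primaryid$caseid$sex", "11$1$F"),
             file.path(d, "DEMO23Q3.txt"))
  expect_error(parse_quarter(d), "caseversion")
  expect_error(parse_quarter(d, schema = "laers_legacy"), "schema")
})

test_that("child rows without a DEMO parent are excluded and counted", {
  d <- write_raw_quarter(
    withr::local_tempdir(),
    demo = "11$1$1$20230101$20230201$70$YR$F$$$MD$US",
    drug = c("11$1$1$PS$TERIPARATIDE$$", "99$9$1$PS$TERIPARATIDE$$"),
    reac = c("11$1$PT_A", "99$9$PT_B"))
  raw <- parse_quarter(d)
  expect_equal(unname(raw$issues[["drug_orphan"]]), 1L)
  expect_equal(unname(raw$issues[["reac_orphan"]]), 1L)
  expect_equal(nrow(raw$drug), 1L)
})

test_that("age normalization converts units and rejects out-of-range", {
  expect_equal(normalize_age(720, "MON"), 60)
  expect_equal(normalize_age(7.2, "DEC"), 72)
  expect_true(is.na(normalize_age(2000, "YR")))
  expect_equal(normalize_age(73, ""), 73)      # empty code = years
  expect_true(is.na(normalize_age("abc", "YR")))
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_true(is.na(normalize_age(-5, "YR")))
})

test_that("FAERS dates parse at day, month and year precision", {
  p <- parse_faers_date(c("20230105", "202301", "2023", "", "1cat"))
  expect_equal(p$date[1:3],
               as.Date(c("2023-01-05", "2023-01-01", "2023-01-01")))
  expect_equal(p$precision, c("day", "month", "year", NA, NA))
})

test_that("deduplication keeps the highest caseversion with fixed ties", {
  cases <- mk_cases(list(
    mk_report(11, caseid = 1, caseversion = 1),
    mk_report(12, caseid = 1, caseversion = 2),
    # caseid 2: same version, receipt date decides
    mk_report(21, caseid = 2, caseversion = 1, receipt = "2023-01-01"),
    mk_report(22, caseid = 2, caseversion = 1, receipt = "2023-06-01"),
    # caseid 3: same version and date, largest primaryid decides
    mk_report(31, caseid = 3, caseversion = 1, receipt = "2023-01-01"),
    mk_report(32, caseid = 3, caseversion = 1, receipt = "2023-01-01")))
  dd <- deduplicate(cases)
  expect_equal(sort(dd$demo$primaryid), c(12, 22, 32))
  # deletion removes the whole case
  dd2 <- deduplicate(cases, deleted_caseids = c(1))
  expect_false(1 %in% dd2$demo$caseid)
  # idempotent, never increases the report count
  expect_identical(deduplicate(dd)$demo, dd$demo)
  expect_lte(n_reports(dd), n_reports(cases))
  # empty input is fine
  empty <- deduplicate(cases, deleted_caseids = unique(cases$demo$caseid))
  expect_equal(n_reports(deduplicate(empty)), 0L)
})

test_that("generator-scale deduplication matches the manifest and is idempotent", {
  cfg <- synth_config(n_reports = 1000, n_drugs = 8, n_pts = 20, n_socs = 4,
                      duplicate_rate = 0.1, deleted_rate = 0.02, seed = 31)
  d <- withr::local_tempdir()
  g <- generate_quarter(cfg, d)
  cases <- build_cases(parse_quarter(d))
  expect_equal(n_reports(cases), 1000 + g$manifest$n_duplicates)
  dd <- deduplicate(cases, g$manifest$deleted_caseids)
  expect_equal(n_reports(dd), g$manifest$expected_survivors)
  expect_identical(deduplicate(dd, g$manifest$deleted_caseids)$demo,
                   dd$demo)
  # surviving versions are the max caseversion per caseid
  expect_true(all(tapply(cases$demo$caseversion, cases$demo$caseid, max)[
    as.character(dd$demo$caseid)] == dd$demo$caseversion))
})

test_that("primary-suspect filtering honours role and synonym matching", {
  cases <- mk_cases(list(
    mk_report(11, drugs = list(list(name = "TERIPARATIDE", role = "SS"),
                               list(name = "OTHER", role = "PS"))),
    mk_report(21, drugs = list(list(name = "FORTEO (TERIPARATIDE)",
                                    role = "PS"))),
    mk_report(31, drugs = list(list(name = "forteo  injection",
                                    role = "PS"))),
    mk_report(41, drugs = list(list(name = "UNRELATED", role = "PS",
                                    ai = "TERIPARATIDE")))))
  got <- filter_primary_suspect(cases, c("TERIPARATIDE", "FORTEO"))
  expect_setequal(got$demo$primaryid, c(21, 31, 41))  # SS-only excluded
  # exact mode requires full-name equality after normalization
  got2 <- filter_primary_suspect(cases, "TERIPARATIDE", match = "exact")
  expect_setequal(got2$demo$primaryid, 41)  # via active ingredient
  expect_error(filter_primary_suspect(cases, character(0)), "non-empty")
})

test_that("the generator's target-marked reports are exactly recovered", {
  cfg <- small_synth(n_reports = 800, seed = 77)
  d <- withr::local_tempdir()
  g <- generate_quarter(cfg, d)
  dd <- deduplicate(build_cases(parse_quarter(d)),
                    g$manifest$deleted_caseids)
  tg <- filter_primary_suspect(dd, "TERIPARATIDE")
  expect_equal(n_reports(tg), g$manifest$expected_target_ps_reports)
})

test_that("CSV round trip preserves the case collection", {
  cfg <- small_synth(n_reports = 300, seed = 5)
  d <- withr::local_tempdir()
  generate_quarter(cfg, d)
  cases <- deduplicate(build_cases(parse_quarter(d)))
  out <- withr::local_tempdir()
  cases_to_csv(cases, out)
  back <- cases_from_csv(out)
  for (tb in c("demo", "drugs", "reactions", "outcomes", "indications")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(cases[[tb]]),
                 ignore_attr = TRUE)
  }
  expect_equal(back$issues, cases$issues)
})

test_that("reaction rows are conserved from file to case collection", {
  cfg <- small_synth(n_reports = 400, seed = 9)
  d <- withr::local_tempdir()
  generate_quarter(cfg, d)
  raw <- parse_quarter(d)
  cases <- build_cases(raw)
  # every reaction PT traces to exactly one accepted REAC row
  expect_equal(nrow(cases$reactions),
               sum(raw$reac$primaryid %in% cases$demo$primaryid))
})
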