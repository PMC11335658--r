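test_that("pair counting uses distinct (report, term) pairs", {
  cases <- mk_cases(list(
    mk_report(11, pts = c("X", "X")),
    mk_report(21, pts = c("X", "X"))))
  counts <- count_pairs(cases, "TERIPARATIDE")
  expect_equal(counts$counts$a[counts$counts$term == "X"], 2L)
})

test_that("hand-enumerated pair counts and the 2x2 cells agree", {
  cases <- mk_cases(list(
    mk_report(11, pts = c("X", "Y")),
    mk_report(21, pts = "X"),
    mk_report(31, pts = "X",
              drugs = list(list(name = "OTHER", role = "PS")))))
  counts <- count_pairs(cases, "TERIPARATIDE")
  cx <- counts$counts[counts$counts$term == "X", ]
  expect_equal(cx$a, 2L)
  expect_equal(counts$drug_margin, 3)       # a+b
  expect_equal(cx$event_margin, 3L)         # a+c
  expect_equal(counts$n, 4)
  tab <- build_contingency(counts)
  tx <- tab[tab$term == "X", ]
  expect_equal(unlist(tx[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 1, 1, 0))
  # conservation on every built row
  expect_true(all(tab$a + tab$b + tab$c + tab$d == tab$n))
  expect_true(all(tab[, c("a", "b", "c", "d")] >= 0))
})

test_that("a single-term database yields the degenerate table (a,0,0,0)", {
  cases <- mk_cases(list(mk_report(11, pts = "X")))
  tab <- build_contingency(count_pairs(cases, "TERIPARATIDE"))
  expect_equal(unlist(tab[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 0, 0, 0))
})

test_that("SOC aggregation counts distinct (report, SOC) pairs", {
  m <- pt_soc_map(c("X", "Y", "Z"), c("S", "S", "T"))
  cases <- mk_cases(list(mk_report(11, pts = c("X", "Y", "Z"))))
  soc <- aggregate_soc(count_pairs(cases, "TERIPARATIDE"), m)
  expect_equal(soc$counts$a[soc$counts$term == "S"], 1L)  # X,Y collapse
  expect_equal(soc$n, 2)

  # all PTs in distinct SOCs: SOC counts equal PT counts
  m2 <- pt_soc_map(c("X", "Y", "Z"), c("S1", "S2", "S3"))
  ptc <- count_pairs(cases, "TERIPARATIDE")
  soc2 <- aggregate_soc(ptc, m2)
  expect_equal(sort(soc2$counts$a), sort(ptc$counts$a))
  expect_equal(soc2$n, ptc$n)
})

test_that("SOC totals never exceed PT totals on synthetic corpora", {
  d <- withr::local_tempdir()
  g <- generate_quarter(small_synth(n_reports = 500, seed = 13), d)
  cases <- deduplicate(build_cases(parse_quarter(d)),
                       g$manifest$deleted_caseids)
  m <- load_pt_soc_map(g$pt_soc)
  ptc <- count_pairs(cases, "TERIPARATIDE")
  socc <- aggregate_soc(ptc, m)
  expect_lte(sum(socc$counts$a), sum(ptc$counts$a))
  expect_lte(socc$n, ptc$n)
})

test_that("planted exposure counts match the generator manifest", {
  d <- withr::local_tempdir()
  g <- generate_quarter(small_synth(n_reports = 1200, seed = 23), d)
  cases <- deduplicate(build_cases(parse_quarter(d)),
                       g$manifest$deleted_caseids)
  counts <- count_pairs(cases, "TERIPARATIDE")
  for (pl in g$manifest$planted) {
    expect_equal(counts$counts$a[counts$counts$term == pl$pt],
                 pl$realized_a)
  }
})

test_that("subgroup predicates select exactly the matching reports", {
  cases <- mk_cases(list(
    mk_report(11, occupation = "PHYSICIAN", sex = "M", age = 50),
    mk_report(21, occupation = "CONSUMER", sex = "F", age = 80),
    mk_report(31, occupation = "REGISTERED_NURSE", sex = "F", age = NA),
    mk_report(41, occupation = "PHARMACIST", sex = "M", age = 30)))
  hp <- apply_subgroup(cases, subgroup_presets()$health_professional)
  expect_setequal(hp$demo$primaryid, c(11, 31, 41))
  fem <- apply_subgroup(cases, subgroup_presets()$female)
  expect_setequal(fem$demo$primaryid, c(21, 31))
  # age >= 45 excludes age-missing reports
  older <- apply_subgroup(cases, subgroup_presets()$age45plus)
  expect_setequal(older$demo$primaryid, c(11, 21))
  # female spec on an all-male corpus -> empty
  males <- mk_cases(list(mk_report(51, sex = "M")))
  expect_equal(n_reports(apply_subgroup(males, subgroup_presets()$female)),
               0L)
})

test_that("subgrouping commutes with pair counting", {
  d <- withr::local_tempdir()
  g <- generate_quarter(small_synth(n_reports = 600, seed = 3), d)
  cases <- deduplicate(build_cases(parse_quarter(d)))
  spec <- subgroup_presets()$female
  # route 1: filter reports then count
  c1 <- count_pairs(apply_subgroup(cases, spec), "TERIPARATIDE")
  # route 2: count, then restrict the pair list to subgroup reports
  ids <- apply_subgroup(cases, spec)$demo$primaryid
  c0 <- count_pairs(cases, "TERIPARATIDE")
  pairs <- c0$pairs[c0$pairs$primaryid %in% ids, ]
  a2 <- table(pairs$term[pairs$is_target])
  expect_equal(c1$n, nrow(pairs))
  for (tm in names(a2)) {
    expect_equal(c1$counts$a[c1$counts$term == tm], unname(a2[[tm]]))
  }
})

test_that("inconsistent margins raise an internal-consistency error", {
  counts <- structure(list(
    counts = tibble::tibble(term = "X", a = 5L, event_margin = 3L),
    drug_margin = 10, n = 8, level = "PT", subgroup = "all",
    pairs = NULL), class = "pair_counts")
  expect_error(build_contingency(counts), "consistency")
})

test_that("MGPS cell grid includes zeros and conserves margins", {
  d <- withr::local_tempdir()
  generate_quarter(small_synth(n_reports = 500, seed = 41), d)
  cases <- deduplicate(build_cases(parse_quarter(d)))
  cells <- mgps_cells(cases)
  # full cross product of observed PS drugs and terms
  expect_equal(nrow(cells),
               length(unique(cells$drug)) * length(unique(cells$term)))
  expect_true(any(cells$a == 0))
  # per drug, sum of E equals the drug margin (expectations conserve)
  agg <- stats::aggregate(cbind(E, a) ~ drug, data = cells, FUN = sum)
  expect_equal(agg$E, agg$a, tolerance = 1e-9)
})
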