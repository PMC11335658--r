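test_that("ROR matches the closed form on reference tables", {
  r <- ror(10, 20, 30, 240)
  expect_equal(r$ror, 4)
  # ln 4 +/- 1.96 * sqrt(0.1875)
  expect_equal(r$ror_lo95, exp(log(4) - qnorm(0.975) * sqrt(0.1875)))
  expect_equal(r$ror_hi95, exp(log(4) + qnorm(0.975) * sqrt(0.1875)))
  expect_equal(round(r$ror_lo95, 2), 1.71)
  expect_equal(round(r$ror_hi95, 2), 9.35)
  expect_equal(ror(5, 5, 5, 5)$ror, 1)
})

test_that("the zero-cell policy adds 0.5 to every cell, or refuses", {
  r <- ror(4, 0, 3, 100)
  expect_equal(r$ror, (4.5 * 100.5) / (0.5 * 3.5))
  expect_true(is.na(ror(4, 0, 3, 100, zero_policy = "none")$ror))
  # an all-zero table is undefined, not a number
  expect_true(is.na(ror(0, 0, 0, 0)$ror))
  expect_true(is.na(prr(0, 0, 0, 0)$prr))
})

test_that("PRR matches the closed form and equals 1 on independence", {
  expect_equal(prr(10, 20, 30, 240)$prr, 3)
  expect_equal(prr(1, 9, 9, 81)$prr, 1)
  p <- prr(10, 20, 30, 240)
  se <- sqrt(1 / 10 - 1 / 30 + 1 / 30 - 1 / 270)
  expect_equal(p$prr_lo95, exp(log(3) - qnorm(0.975) * se))
})

test_that("chi-squared matches Yates and Pearson closed forms", {
  expect_equal(chi_square(10, 20, 30, 240),
               300 * (abs(10 * 240 - 20 * 30) - 150)^2 /
                 (30 * 270 * 40 * 260))
  expect_equal(round(chi_square(10, 20, 30, 240), 2), 9.70)
  expect_equal(round(chi_square(10, 20, 30, 240, yates = FALSE), 2), 11.54)
  expect_equal(chi_square(1, 9, 9, 81, yates = FALSE), 0)
  # Yates floors at zero when |ad - bc| <= n/2
  expect_equal(chi_square(2, 18, 18, 162), 0)
})

test_that("chi-squared agrees with stats::chisq.test", {
  set.seed(4)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(chi_square(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2],
                            yates = FALSE),
                 unname(chisq.test(tb, correct = FALSE)$statistic))
    expect_equal(chi_square(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 unname(chisq.test(tb, correct = TRUE)$statistic))
  }
})

test_that("BCPNN IC matches its closed form, centred on independence", {
  ic <- ic_bcpnn(10, 20, 30, 240)
  # direct arithmetic from the stated formula
  g <- 1 * 302 * 302 / (31 * 41)
  e_ref <- log2(11 * 302 * 302 / ((300 + g) * 31 * 41))
  v_ref <- (1 / log(2))^2 *
    ((300 - 10 + g - 1) / (11 * (301 + g)) +
       (300 - 30 + 1) / (31 * 303) + (300 - 40 + 1) / (41 * 303))
  expect_equal(ic$ic, e_ref)
  expect_equal(ic$ic025, e_ref - 2 * sqrt(v_ref))
  expect_equal(round(ic$ic, 2), 1.09)
  # large independence table: prior centred on independence
  big <- ic_bcpnn(100, 900, 9900, 89100)
  expect_lt(abs(big$ic), 0.05)
  # a = 0 stays finite and negative
  z <- ic_bcpnn(0, 30, 40, 230)
  expect_true(is.finite(z$ic))
  expect_lt(z$ic, 0)
  expect_error(ic_bcpnn(1, 1, 1, 1, prior = bcpnn_prior(alpha1 = -1)),
               "positive")
})

test_that("exact BCPNN moments reduce the approximation bias", {
  # exact digamma moments sit below the log-of-means approximation by
  # ~1/(2 ln2 (a + 1)) for small a
  ap <- ic_bcpnn(10, 20, 30, 240)
  ex <- ic_bcpnn(10, 20, 30, 240, moments = "exact")
  expect_lt(ex$ic, ap$ic)
  expect_lt(abs(ap$ic - ex$ic), 1 / (2 * log(2) * 11) + 0.01)
})

test_that("signs agree across ROR, PRR and the cross-product", {
  set.seed(11)
  for (i in 1:200) {
    a <- rpois(1, 8) + 1; b <- rpois(1, 50) + 1
    c <- rpois(1, 30) + 1; d <- rpois(1, 800) + 1
    r <- ror(a, b, c, d)$ror
    p <- prr(a, b, c, d)$prr
    expect_equal(r >= 1, p >= 1)
    expect_equal(r >= 1, a * d >= b * c)
  }
})

test_that("statistics are nondecreasing in a with fixed margins", {
  nx <- 40; ny <- 60; n <- 1000
  a <- 1:30
  b <- nx - a; c <- ny - a; d <- n - a - b - c
  h <- mgps_hyperparams(2, 2, 20, 2, 0.9)
  vals <- list(ror = ror(a, b, c, d)$ror,
               prr = prr(a, b, c, d)$prr,
               ic = ic_bcpnn(a, b, c, d)$ic,
               ebgm = ebgm_scores(a, nx * ny / n, h)$ebgm)
  for (v in vals) expect_true(all(diff(v) > -1e-12))
})

test_that("interval ordering holds on every computed pair", {
  set.seed(21)
  a <- rpois(60, 5); b <- rpois(60, 100) + 1
  c <- rpois(60, 50) + 1; d <- rpois(60, 2000) + 1
  h <- mgps_hyperparams(1.2, 1.1, 8, 2, 0.7)
  s <- compute_signal_stats(tibble::tibble(a = a, b = b, c = c, d = d),
                            hyper = h)
  expect_true(all(s$ror_lo95 <= s$ror & s$ror <= s$ror_hi95))
  expect_true(all(s$prr_lo95 <= s$prr & s$prr <= s$prr_hi95))
  expect_true(all(s$ic025 <= s$ic))
  expect_true(all(s$ebgm05 <= s$ebgm + 1e-12))
  expect_true(all(s$ebgm <= s$ebgm95 + 1e-12))
})

test_that("ROR and PRR agree for rare-exposure rare-event tables", {
  # the published pattern: ROR 552.96 vs PRR 552.95 on FAERS-scale margins
  tabs <- list(c(4, 342686, 400, 50526617),
               c(17, 342673, 120, 50526897),
               c(1988, 340702, 37000, 50489917))
  for (tb in tabs) {
    r <- ror(tb[1], tb[2], tb[3], tb[4])$ror
    p <- prr(tb[1], tb[2], tb[3], tb[4])$prr
    expect_lt(abs(r - p) / p, 0.01)
  }
})

test_that("classification applies thresholds, min_a and NA rules", {
  sc <- tibble::tibble(a = 5, ror_lo95 = 1.2, prr = 2.5, chi2 = 5,
                       ic025 = 0.1, ebgm05 = 2.2)
  got <- classify_signals(sc)
  expect_true(all(unlist(
    got[, c("flag_ror", "flag_prr", "flag_bcpnn", "flag_mgps", "signal")])))
  # a = 2 with huge ROR: case-count rule
  got2 <- classify_signals(dplyr::mutate(sc, a = 2, ror_lo95 = 50))
  expect_false(got2$flag_ror)
  expect_false(got2$flag_prr)
  expect_false(got2$signal)
  # ic025 = 0 exactly fails the strict inequality
  got3 <- classify_signals(dplyr::mutate(sc, ic025 = 0))
  expect_false(got3$flag_bcpnn)
  # undefined statistic -> flag false, not NA
  got4 <- classify_signals(dplyr::mutate(sc, ror_lo95 = NA_real_))
  expect_false(got4$flag_ror)
  # ANY combination mode
  got5 <- classify_signals(dplyr::mutate(sc, ic025 = 0),
                           signal_thresholds(combine = "ANY"))
  expect_true(got5$signal)
})

test_that("the single-table battery reproduces the reference arithmetic", {
  s <- stats_2x2(10, 20, 30, 240)
  expect_equal(s$ror, 4)
  expect_equal(s$prr, 3)
  expect_equal(round(s$chi2, 2), 9.70)
  expect_equal(round(s$ic, 2), 1.09)
})
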