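# Apply the zero-cell policy: Haldane-Anscombe continuity correction adds
# 0.5 to all four cells of any table with a zero cell. Applies to ROR, PRR
# and chi-squared only; the Bayesian statistics handle zeros natively.
apply_zero_policy <- function(a, b, c, d, zero_policy) {
  if (zero_policy == "haldane") {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  list(a = a, b = b, c = c, d = d)
}

#' Reporting odds ratio
#'
#' `ROR = (a d) / (b c)` with Wald 95% interval
#' `exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. With the default
#' `zero_policy = "haldane"`, 0.5 is added to all four cells of any table
#' containing a zero before computing. An all-zero table yields `NA`
#' (undefined statistic), as does a table still containing a zero cell under
#' `zero_policy = "none"`.
#'
#' @param a,b,c,d Vectors of 2x2 cell counts (target drug & event, target
#'   drug & other events, other drugs & event, neither).
#' @param zero_policy `"haldane"` (default) or `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with columns `ror`, `ror_lo95`, `ror_hi95`.
#' @export
#' @examples
#' ror(10, 20, 30, 240) # 4.00 (1.71, 9.35)
ror <- function(a, b, c, d, zero_policy = c("haldane", "none"),
                conf_level = 0.95) {
  zero_policy <- match.arg(zero_policy)
  undef <- (a + b + c + d) == 0
  z <- apply_zero_policy(a, b, c, d, zero_policy)
  bad <- undef | z$a == 0 | z$b == 0 | z$c == 0 | z$d == 0
  est <- (z$a * z$d) / (z$b * z$c)
  se <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    ror = est,
    ror_lo95 = exp(log(est) - q * se),
    ror_hi95 = exp(log(est) + q * se)
  )
  out[bad, ] <- NA_real_
  out
}

#' Proportional reporting ratio
#'
#' `PRR = [a / (a + b)] / [c / (c + d)]` with interval
#' `exp(ln PRR +/- z sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' Zero-cell handling as in [ror()].
#'
#' @inheritParams ror
#' @return Tibble with columns `prr`, `prr_lo95`, `prr_hi95`.
#' @export
#' @examples
#' prr(10, 20, 30, 240) # 3.00
prr <- function(a, b, c, d, zero_policy = c("haldane", "none"),
                conf_level = 0.95) {
  zero_policy <- match.arg(zero_policy)
  undef <- (a + b + c + d) == 0
  z <- apply_zero_policy(a, b, c, d, zero_policy)
  bad <- undef | z$a == 0 | z$c == 0 | (z$a + z$b) == 0 | (z$c + z$d) == 0
  est <- (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  se <- sqrt(1 / z$a - 1 / (z$a + z$b) + 1 / z$c - 1 / (z$c + z$d))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    prr = est,
    prr_lo95 = exp(log(est) - q * se),
    prr_hi95 = exp(log(est) + q * se)
  )
  out[bad, ] <- NA_real_
  out
}

#' Chi-squared statistic for a 2x2 table
#'
#' Pearson `chi^2 = n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with the Yates
#' continuity correction (default) `|ad - bc|` is reduced by `n / 2` and
#' floored at zero. A zero margin yields `NA`. The zero-cell policy is
#' applied as in [ror()] (cells, not margins, are corrected).
#'
#' @inheritParams ror
#' @param yates Apply the Yates continuity correction (default `TRUE`).
#' @return Numeric vector of chi-squared values.
#' @export
#' @examples
#' chi_square(10, 20, 30, 240)               # ~9.70
#' chi_square(10, 20, 30, 240, yates = FALSE) # ~11.54
chi_square <- function(a, b, c, d, yates = TRUE,
                       zero_policy = c("haldane", "none")) {
  zero_policy <- match.arg(zero_policy)
  z <- apply_zero_policy(a, b, c, d, zero_policy)
  a <- z$a; b <- z$b; c <- z$c; d <- z$d
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  bad <- denom == 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  out <- n * dev^2 / denom
  out[bad] <- NA_real_
  out
}

#' BCPNN prior specification
#'
#' Hyperparameters of the Beta priors underlying the information component:
#' marginal priors `Beta(alpha1, alpha - alpha1)` and
#' `Beta(beta1, beta - beta1)` for the drug and event reporting
#' probabilities, and joint prior parameter `gamma11`; the joint prior total
#' `gamma` is chosen per table so the prior IC is centred on independence.
#' Defaults (`alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2`) are the
#' standard uniform-margin choice.
#'
#' @param alpha1,beta1 Marginal prior successes (default 1).
#' @param alpha,beta Marginal prior totals (default 2).
#' @param gamma11 Joint prior successes (default 1).
#' @return An object of class `bcpnn_prior`.
#' @export
bcpnn_prior <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                        gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("BCPNN prior parameters must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "bcpnn_prior")
}

#' BCPNN information component
#'
#' The information component `IC = log2 p(drug, event) / (p(drug) p(event))`
#' under independent Beta posteriors for the joint and marginal reporting
#' probabilities. `moments = "approx"` (default) returns the standard
#' closed-form moment approximation: `E(IC)` as the log of the ratio of
#' posterior means and `V(IC)` from the delta method; `ic025 / ic975` are
#' `E(IC) -/+ 2 sqrt(V(IC))`. `moments = "exact"` returns the exact moments
#' of the same Beta model via digamma/trigamma (`E log Beta(u, v) =
#' psi(u) - psi(u + v)`), useful for calibration checks; the credibility
#' bounds are then exact-moment two-sigma bounds.
#'
#' Handles `a = 0` natively (no zero-cell correction is applied).
#'
#' @inheritParams ror
#' @param prior A [bcpnn_prior()].
#' @param moments `"approx"` or `"exact"`.
#' @return Tibble with columns `ic`, `ic_var`, `ic025`, `ic975`.
#' @export
#' @examples
#' ic_bcpnn(10, 20, 30, 240) # E(IC) ~ 1.09, ic025 ~ 0.02
ic_bcpnn <- function(a, b, c, d, prior = bcpnn_prior(),
                     moments = c("approx", "exact")) {
  stopifnot(inherits(prior, "bcpnn_prior"))
  moments <- match.arg(moments)
  nxy <- a
  nx <- a + b
  ny <- a + c
  n <- a + b + c + d
  a1 <- prior$alpha1; b1 <- prior$beta1
  al <- prior$alpha; be <- prior$beta; g11 <- prior$gamma11
  g <- g11 * (n + al) * (n + be) / ((nx + a1) * (ny + b1))
  if (moments == "approx") {
    e_ic <- log2((nxy + g11) * (n + al) * (n + be) /
                   ((n + g) * (nx + a1) * (ny + b1)))
    v_ic <- (1 / log(2))^2 * (
      (n - nxy + g - g11) / ((nxy + g11) * (1 + n + g)) +
      (n - nx + al - a1) / ((nx + a1) * (1 + n + al)) +
      (n - ny + be - b1) / ((ny + b1) * (1 + n + be)))
  } else {
    e_ic <- (digamma(nxy + g11) - digamma(n + g) -
               (digamma(nx + a1) - digamma(n + al)) -
               (digamma(ny + b1) - digamma(n + be))) / log(2)
    v_ic <- (trigamma(nxy + g11) - trigamma(n + g) +
               trigamma(nx + a1) - trigamma(n + al) +
               trigamma(ny + b1) - trigamma(n + be)) / log(2)^2
  }
  tibble::tibble(ic = e_ic, ic_var = v_ic,
                 ic025 = e_ic - 2 * sqrt(v_ic),
                 ic975 = e_ic + 2 * sqrt(v_ic))
}

#' Signal classification thresholds
#'
#' The standard per-algorithm criteria: ROR lower 95% bound > 1; PRR >= 2
#' with chi-squared >= 4; BCPNN IC025 > 0 (strict); MGPS EBGM05 >= 2. A
#' minimum case count `min_a` (default 3) gates every algorithm's flag. The
#' combined flag is `ALL` (all four criteria met, default), `ANY`, or
#' `PER_ALGORITHM` (no combination).
#'
#' @param min_a Minimum case count (default 3).
#' @param ror_lo Threshold for the ROR lower bound (default 1, strict >).
#' @param prr_min,chi2_min PRR criterion components (defaults 2 and 4, >=).
#' @param ic025_min BCPNN threshold (default 0, strict >).
#' @param ebgm05_min MGPS threshold (default 2, >=).
#' @param combine `"ALL"`, `"ANY"`, or `"PER_ALGORITHM"`.
#' @return An object of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo = 1, prr_min = 2,
                              chi2_min = 4, ic025_min = 0, ebgm05_min = 2,
                              combine = c("ALL", "ANY", "PER_ALGORITHM")) {
  stopifnot(min_a >= 0)
  structure(list(min_a = min_a, ror_lo = ror_lo, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, combine = match.arg(combine)),
            class = "signal_thresholds")
}

#' Classify signal scores against thresholds
#'
#' Applies the per-algorithm rules of [signal_thresholds()] to a score table.
#' An undefined (`NA`) statistic makes that algorithm's flag `FALSE`.
#'
#' @param scores Data frame with columns `a`, `ror_lo95`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (extra columns are carried through).
#' @param thresholds A `signal_thresholds` object.
#' @return `scores` with added logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps` and (unless `combine = "PER_ALGORITHM"`)
#'   `signal`.
#' @export
classify_signals <- function(scores, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  th <- thresholds
  ok_a <- !is.na(scores$a) & scores$a >= th$min_a
  flag <- function(x, test) ok_a & !is.na(x) & test
  scores$flag_ror <- flag(scores$ror_lo95, scores$ror_lo95 > th$ror_lo)
  scores$flag_prr <- ok_a & !is.na(scores$prr) & !is.na(scores$chi2) &
    scores$prr >= th$prr_min & scores$chi2 >= th$chi2_min
  scores$flag_bcpnn <- flag(scores$ic025, scores$ic025 > th$ic025_min)
  scores$flag_mgps <- flag(scores$ebgm05, scores$ebgm05 >= th$ebgm05_min)
  if (th$combine == "ALL") {
    scores$signal <- scores$flag_ror & scores$flag_prr &
      scores$flag_bcpnn & scores$flag_mgps
  } else if (th$combine == "ANY") {
    scores$signal <- scores$flag_ror | scores$flag_prr |
      scores$flag_bcpnn | scores$flag_mgps
  }
  scores
}

#' Compute the full disproportionality battery for contingency tables
#'
#' Runs ROR, PRR, chi-squared, BCPNN IC and (when hyperparameters are
#' supplied) MGPS EBGM on each row of a contingency table, then classifies
#' signals. This is the per-pair score table behind the PT- and SOC-level
#' output tables.
#'
#' @param tables Data frame with columns `a`, `b`, `c`, `d` (and typically
#'   `term`, `level`, `subgroup`, `n` from [build_contingency()]).
#' @param hyper Optional `mgps_hyperparams` from [fit_mgps_prior()]; when
#'   `NULL`, EBGM columns are `NA`.
#' @param thresholds A [signal_thresholds()] specification.
#' @param zero_policy Passed to [ror()], [prr()] and [chi_square()].
#' @param yates Passed to [chi_square()].
#' @param bcpnn The [bcpnn_prior()].
#' @return `tables` augmented with all statistic, bound and flag columns.
#' @export
compute_signal_stats <- function(tables, hyper = NULL,
                                 thresholds = signal_thresholds(),
                                 zero_policy = "haldane", yates = TRUE,
                                 bcpnn = bcpnn_prior()) {
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  out <- dplyr::bind_cols(
    tibble::as_tibble(tables),
    ror(a, b, c, d, zero_policy = zero_policy),
    prr(a, b, c, d, zero_policy = zero_policy),
    tibble::tibble(chi2 = chi_square(a, b, c, d, yates = yates,
                                     zero_policy = zero_policy)),
    ic_bcpnn(a, b, c, d, prior = bcpnn)[, c("ic", "ic025", "ic975")]
  )
  if (!is.null(hyper)) {
    eb <- ebgm_scores(a, (a + b) * (a + c) / (a + b + c + d), hyper)
    out <- dplyr::bind_cols(out, eb)
  } else {
    out$ebgm <- NA_real_
    out$ebgm05 <- NA_real_
    out$ebgm95 <- NA_real_
  }
  classify_signals(out, thresholds)
}

#' Disproportionality battery for one literal 2x2 table
#'
#' Convenience wrapper for spot-checking a published table: supply the four
#' cells, get all statistics. EBGM uses a supplied prior or, by default, a
#' vague single-component prior centred on independence
#' (`Gamma(1, 1)` both components), which is only indicative for a single
#' table — fit the prior on a full database for real use.
#'
#' @param a,b,c,d Single 2x2 cell counts.
#' @param hyper Optional `mgps_hyperparams`.
#' @param yates Yates correction for chi-squared.
#' @inheritParams compute_signal_stats
#' @return One-row tibble of statistics and flags.
#' @export
#' @examples
#' stats_2x2(10, 20, 30, 240)
stats_2x2 <- function(a, b, c, d, hyper = NULL,
                      thresholds = signal_thresholds(),
                      zero_policy = "haldane", yates = TRUE) {
  if (is.null(hyper)) {
    hyper <- mgps_hyperparams(1, 1, 1, 1, 0.5)
  }
  compute_signal_stats(
    tibble::tibble(term = "(manual)", level = "PT", subgroup = "all",
                   a = a, b = b, c = c, d = d, n = a + b + c + d),
    hyper = hyper, thresholds = thresholds,
    zero_policy = zero_policy, yates = yates)
}
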