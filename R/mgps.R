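#' MGPS hyperparameters
#'
#' The five parameters of the two-component gamma mixture prior on the
#' relative reporting rate `lambda`:
#' `lambda ~ p_mix Gamma(alpha1, beta1) + (1 - p_mix) Gamma(alpha2, beta2)`
#' (shape/rate), with observed cell counts `a ~ Poisson(lambda E)`.
#'
#' @param alpha1,beta1 Shape and rate of the first component.
#' @param alpha2,beta2 Shape and rate of the second component.
#' @param p_mix Mixing weight of the first component, in (0, 1).
#' @param loglik Marginal log-likelihood at these values (optional).
#' @param converged Optimizer convergence flag (optional).
#' @return An object of class `mgps_hyperparams`.
#' @export
mgps_hyperparams <- function(alpha1, beta1, alpha2, beta2, p_mix,
                             loglik = NA_real_, converged = NA) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("MGPS hyperparameters must be positive", call. = FALSE)
  }
  if (!is.finite(p_mix) || p_mix <= 0 || p_mix >= 1) {
    stop("p_mix must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, p_mix = p_mix, loglik = loglik,
                 converged = converged),
            class = "mgps_hyperparams")
}

#' @export
print.mgps_hyperparams <- function(x, ...) {
  cat("<mgps_hyperparams>\n")
  cat(sprintf("  component 1: Gamma(shape %.4g, rate %.4g), mean %.3g\n",
              x$alpha1, x$beta1, x$alpha1 / x$beta1))
  cat(sprintf("  component 2: Gamma(shape %.4g, rate %.4g), mean %.3g\n",
              x$alpha2, x$beta2, x$alpha2 / x$beta2))
  cat(sprintf("  p_mix = %.4f; loglik = %.4f; converged = %s\n",
              x$p_mix, x$loglik, x$converged))
  invisible(x)
}

# Marginal log-density of counts under the gamma-Poisson mixture: each
# component induces a negative binomial with size alpha and prob
# beta / (beta + E).
mgps_marginal_ll <- function(a, E, a1, b1, a2, b2, p, weights = NULL,
                             truncated = FALSE) {
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  ll <- log_add(log(p) + l1, log(1 - p) + l2)
  if (truncated) {
    # condition on a >= 1
    p0 <- exp(log_add(log(p) + a1 * log(b1 / (b1 + E)),
                      log(1 - p) + a2 * log(b2 / (b2 + E))))
    ll <- ll - log1p(-pmin(p0, 1 - 1e-12))
  }
  if (is.null(weights)) sum(ll) else sum(weights * ll)
}

#' Fit the MGPS gamma-mixture prior by maximum marginal likelihood
#'
#' Maximizes the negative-binomial mixture marginal likelihood of all
#' drug-event cell counts `a` given baseline expectations
#' `E = (a+b)(a+c)/n`. Optimization runs on transformed parameters (log for
#' the gamma parameters, logit for `p_mix`) from the classical starting
#' point `(0.2, 0.1, 2, 4, 1/3)` plus `n_restarts` jittered restarts (drawn
#' from the current RNG stream); the best log-likelihood wins.
#'
#' @param a Nonnegative integer cell counts (include `a = 0` cells).
#' @param E Positive baseline expected counts, same length.
#' @param weights Optional cell weights (for count-stratified "squashing" of
#'   large databases: collapse identical `(a, E)` strata and weight by
#'   stratum size).
#' @param start Numeric length-5 starting value
#'   `(alpha1, beta1, alpha2, beta2, p_mix)`.
#' @param n_restarts Number of jittered restarts (default 4).
#' @param truncated If `TRUE`, maximize the `a >= 1` conditional
#'   (zero-truncated) likelihood.
#' @return An `mgps_hyperparams` object with `loglik` and `converged` set.
#' @seealso [ebgm_scores()], [mgps_cells()], [squash_cells()]
#' @export
fit_mgps_prior <- function(a, E, weights = NULL,
                           start = c(0.2, 0.1, 2, 4, 1 / 3),
                           n_restarts = 4, truncated = FALSE) {
  stopifnot(length(a) == length(E))
  if (length(a) < 2) stop("Need at least 2 cells to fit the prior",
                          call. = FALSE)
  if (any(E <= 0)) stop("All baseline expectations E must be positive",
                        call. = FALSE)
  if (all(a == 0)) {
    stop("Degenerate input: all cell counts are zero; ",
         "the mixture prior is not identifiable", call. = FALSE)
  }
  negll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    v <- -mgps_marginal_ll(a, E, a1, b1, a2, b2, p, weights, truncated)
    if (!is.finite(v)) 1e12 else v
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  starts <- c(list(theta0),
              lapply(seq_len(n_restarts), function(i) {
                theta0 + stats::rnorm(5, sd = 0.75)
              }))
  # box bounds on the transformed scale keep the gamma parameters inside
  # (e-12, e12); a variance-zero component is represented at the boundary
  fits <- lapply(starts, function(th) {
    tryCatch(stats::optim(pmin(pmax(th, -11), 11), negll,
                          method = "L-BFGS-B", lower = -12, upper = 12,
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("MGPS prior optimization failed on every restart", call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  th <- best$par
  mgps_hyperparams(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]),
                   stats::plogis(th[5]),
                   loglik = -best$value,
                   converged = best$convergence == 0)
}

#' Collapse cells into count strata for large databases
#'
#' Optional pre-processing ("squashing") for [fit_mgps_prior()]: cells with
#' the same count `a` and similar `E` (binned on a log grid) are collapsed
#' to one representative cell weighted by stratum size, preserving the
#' likelihood to binning precision while shrinking the problem.
#'
#' @param a,E Cell counts and expectations.
#' @param e_bins Number of logarithmic `E` bins (default 100).
#' @return Tibble with columns `a`, `E` (stratum mean) and `weight`.
#' @export
squash_cells <- function(a, E, e_bins = 100) {
  bin <- cut(log(E), breaks = e_bins, labels = FALSE)
  tibble::tibble(a = a, E = E, bin = bin) %>%
    dplyr::summarise(E = mean(.data$E), weight = dplyr::n(),
                     .by = c("a", "bin")) %>%
    dplyr::select("a", "E", "weight")
}

# Posterior mixture weight of component 1 given count a and expectation E
mgps_posterior_q <- function(a, E, h) {
  l1 <- log(h$p_mix) +
    stats::dnbinom(a, size = h$alpha1, prob = h$beta1 / (h$beta1 + E),
                   log = TRUE)
  l2 <- log(1 - h$p_mix) +
    stats::dnbinom(a, size = h$alpha2, prob = h$beta2 / (h$beta2 + E),
                   log = TRUE)
  1 / (1 + exp(l2 - l1))
}

# Mixture-gamma posterior CDF of lambda | a
mgps_posterior_cdf <- function(x, a, E, q, h) {
  q * stats::pgamma(x, shape = h$alpha1 + a, rate = h$beta1 + E) +
    (1 - q) * stats::pgamma(x, shape = h$alpha2 + a, rate = h$beta2 + E)
}

#' Empirical-Bayes geometric mean and posterior quantiles
#'
#' Under the fitted prior, the posterior of the relative reporting rate is
#' the gamma mixture
#' `Q Gamma(alpha1 + a, beta1 + E) + (1 - Q) Gamma(alpha2 + a, beta2 + E)`
#' with `Q` the posterior weight of component 1. `EBGM = exp(E[log lambda])`
#' is computed in closed form via the digamma function; `ebgm05` / `ebgm95`
#' are the posterior 5th / 95th percentiles obtained by monotone
#' root-finding on the mixture CDF (tolerance 1e-9). The arithmetic
#' posterior mean is also returned for diagnostics.
#'
#' @param a Nonnegative counts.
#' @param E Positive baseline expectations.
#' @param hyper An `mgps_hyperparams` object.
#' @return Tibble with columns `ebgm`, `ebgm05`, `ebgm95`, `eb_mean`,
#'   `q_weight`.
#' @export
#' @examples
#' h <- mgps_hyperparams(1, 1, 1, 1, 0.5)
#' ebgm_scores(10, 2, h) # exp(digamma(11) - log(3)) ~ 3.50
ebgm_scores <- function(a, E, hyper) {
  stopifnot(inherits(hyper, "mgps_hyperparams"))
  if (any(E <= 0)) stop("All expectations E must be positive", call. = FALSE)
  h <- hyper
  q <- mgps_posterior_q(a, E, h)
  elog <- q * (digamma(h$alpha1 + a) - log(h$beta1 + E)) +
    (1 - q) * (digamma(h$alpha2 + a) - log(h$beta2 + E))
  mean_post <- q * (h$alpha1 + a) / (h$beta1 + E) +
    (1 - q) * (h$alpha2 + a) / (h$beta2 + E)
  quant <- function(p, ai, Ei, qi) {
    lo <- min(stats::qgamma(p, shape = h$alpha1 + ai, rate = h$beta1 + Ei),
              stats::qgamma(p, shape = h$alpha2 + ai, rate = h$beta2 + Ei))
    hi <- max(stats::qgamma(p, shape = h$alpha1 + ai, rate = h$beta1 + Ei),
              stats::qgamma(p, shape = h$alpha2 + ai, rate = h$beta2 + Ei))
    if (hi - lo < 1e-12) return(lo)
    stats::uniroot(function(x) mgps_posterior_cdf(x, ai, Ei, qi, h) - p,
                   lower = lo, upper = hi, tol = 1e-9,
                   extendInt = "upX")$root
  }
  ebgm05 <- mapply(quant, p = 0.05, ai = a, Ei = E, qi = q)
  ebgm95 <- mapply(quant, p = 0.95, ai = a, Ei = E, qi = q)
  tibble::tibble(ebgm = exp(elog), ebgm05 = ebgm05, ebgm95 = ebgm95,
                 eb_mean = mean_post, q_weight = q)
}
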