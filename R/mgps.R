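# Multi-item gamma-Poisson shrinker (DuMouchel empirical Bayes).
#
# Model: observed count a ~ Poisson(lambda * E) with expected count
# E = (a+b)(a+c)/N under independence; the reporting-rate ratio lambda has
# a two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2)
# so the marginal of a is a mixture of negative binomials.  The posterior
# is again a two-gamma mixture, from which EBGM (geometric mean) and EB05
# (5th percentile) follow.

.mgps_nll <- function(theta, a, e) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  d1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + e))
  d2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + e))
  -sum(log(pmax(w * d1 + (1 - w) * d2, 1e-300)))
}

#' DuMouchel default gamma-mixture prior
#'
#' The canonical starting values of the shrinkage literature
#' (`alpha1 = 0.2`, `beta1 = 0.1`, `alpha2 = 2`, `beta2 = 4`,
#' `w = 1/3`), used as optimizer start and as fallback prior for
#' degenerate inputs.
#'
#' @return An object of class `mgps_prior`.
#' @export
default_mgps_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                 w = 1 / 3, converged = NA, loglik = NA_real_,
                 fitted = FALSE),
            class = "mgps_prior")
}

#' Fit the gamma-mixture hyperprior to all drug-event pairs
#'
#' Maximizes the negative-binomial mixture marginal likelihood of the
#' observed counts given their independence-expected counts over the five
#' hyperparameters, using the derivative-free Nelder-Mead simplex on a
#' log/logit-transformed scale from the canonical starting point.  The
#' optimizer is deterministic, so a fixed dataset yields identical fitted
#' parameters.
#'
#' @param a Integer vector of observed counts, one per drug-event pair
#'   (at least 2 pairs; 100 or more recommended).
#' @param expected Numeric vector of expected counts `E = (a+b)(a+c)/N`
#'   (pairs with `E = 0` are dropped).
#' @return An object of class `mgps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `w`, plus `converged`, `loglik`, `fitted`.
#' @section Errors: non-convergence raises a condition of class
#'   `mgps_convergence_error` whose `fit` field carries the best-found
#'   parameters and optimizer status.
#' @export
fit_mgps_prior <- function(a, expected) {
  keep <- !is.na(a) & !is.na(expected) & expected > 0
  a <- a[keep]; expected <- expected[keep]
  if (length(a) < 2L)
    stop_config("need at least 2 drug-event pairs with positive expected counts")
  start <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  opt <- stats::optim(start, .mgps_nll, a = a, e = expected,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  prior <- structure(list(alpha1 = exp(opt$par[1]), beta1 = exp(opt$par[2]),
                          alpha2 = exp(opt$par[3]), beta2 = exp(opt$par[4]),
                          w = stats::plogis(opt$par[5]),
                          converged = opt$convergence == 0,
                          loglik = -opt$value, fitted = TRUE),
                     class = "mgps_prior")
  if (opt$convergence != 0) {
    cond <- structure(
      class = c("mgps_convergence_error", "error", "condition"),
      list(message = sprintf(
        "gamma-mixture optimizer did not converge (status %d)",
        opt$convergence),
        call = sys.call(-1), fit = prior, status = opt$convergence))
    stop(cond)
  }
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior>%s w=%.3f  Gamma(%.3g, %.3g) / ",
                     "Gamma(%.3g, %.3g)\n"),
              if (isTRUE(x$fitted)) " fitted:" else " default:",
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2))
  invisible(x)
}

# posterior mixture for one vector of (a, E): weights and gamma components
.mgps_posterior <- function(a, e, prior) {
  d1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + e))
  d2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + e))
  qn <- prior$w * d1 / pmax(prior$w * d1 + (1 - prior$w) * d2, 1e-300)
  list(qn = qn, shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical-Bayes geometric mean and its posterior 5th percentile
#'
#' For each drug-event pair the posterior of the reporting-rate ratio is a
#' two-component gamma mixture; `EBGM = exp(E[log lambda])` (the posterior
#' geometric mean) and `EB05` is the posterior 5th percentile, located by
#' bisection on the mixture distribution function to an absolute tolerance
#' of 1e-6.
#'
#' @param table A `contingency` object, or a list with elements `a`
#'   (counts) and `expected` (expected counts) for vectorized use.
#' @param prior An `mgps_prior` (fitted or default).
#' @return List with numeric vectors `ebgm` and `eb05`.
#' @export
#' @examples
#' ebgm(list(a = 50, expected = 10), default_mgps_prior())
ebgm <- function(table, prior) {
  if (!inherits(prior, "mgps_prior")) stop_config("prior must be an mgps_prior")
  if (inherits(table, "contingency")) {
    n <- table$a + table$b + table$c + table$d
    a <- table$a
    e <- (table$a + table$b) * (table$a + table$c) / n
  } else if (is.list(table) && all(c("a", "expected") %in% names(table))) {
    a <- table$a; e <- table$expected
  } else {
    stop_config("table must be a contingency or list(a, expected)")
  }
  bad <- is.na(a) | is.na(e) | e <= 0
  po <- .mgps_posterior(a, e, prior)
  mean_log <- po$qn * (digamma(po$shape1) - log(po$rate1)) +
    (1 - po$qn) * (digamma(po$shape2) - log(po$rate2))
  ebgm_v <- exp(mean_log)

  eb05_v <- vapply(seq_along(a), function(i) {
    if (bad[i]) return(NA_real_)
    cdf <- function(x)
      po$qn[i] * stats::pgamma(x, po$shape1[i], rate = po$rate1[i]) +
      (1 - po$qn[i]) * stats::pgamma(x, po$shape2[i], rate = po$rate2[i])
    lo <- 0
    hi <- max(stats::qgamma(0.999, po$shape1[i], rate = po$rate1[i]),
              stats::qgamma(0.999, po$shape2[i], rate = po$rate2[i]), 1)
    if (cdf(hi) < 0.05) {  # pathological; widen until bracketed
      for (k in 1:60) { hi <- hi * 2; if (cdf(hi) >= 0.05) break }
      if (cdf(hi) < 0.05)
        stop_config("EB05 root-finding failed: cdf(%g) = %g < 0.05",
                    hi, cdf(hi))
    }
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < 0.05) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))

  ebgm_v[bad] <- NA_real_
  list(ebgm = ebgm_v, eb05 = eb05_v)
}
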