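# Time-to-onset: sample collection, description, Weibull hazard model.

#' Collect the time-to-onset sample from assembled reports
#'
#' Gathers the per-report onset intervals (days from therapy start to
#' event) computed at assembly; reports with missing or logically
#' inconsistent dates contribute to the unknown count rather than the
#' sample.
#'
#' @param fd A `faers_data` (usually [subject_reports()] of the dataset).
#' @return An object of class `tto_sample`: list with `values`
#'   (non-negative integer days) and `n_unknown`.
#' @export
collect_tto <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  t <- fd$reports$tto_days
  ok <- !is.na(t) & t >= 0
  structure(list(values = as.integer(t[ok]), n_unknown = sum(!ok)),
            class = "tto_sample")
}

#' @export
print.tto_sample <- function(x, ...) {
  cat(sprintf("<tto_sample> n=%d (unknown %d), median %s days\n",
              length(x$values), x$n_unknown,
              if (length(x$values)) format(stats::median(x$values)) else "NA"))
  invisible(x)
}

#' Describe a time-to-onset sample
#'
#' Median and quartiles (order-statistic quantiles with linear
#' interpolation, [stats::quantile()] type 7) plus the standard onset bins
#' `<2`, `2-5`, `5-7`, `7-14`, `14-28`, `>=28` days (half-open
#' `[lower, upper)`) and the unknown count; bin percentages use the block
#' sum (known bins + unknown) as denominator.
#'
#' @param sample A `tto_sample` (or bare numeric vector of days).
#' @return List with `median`, `q1`, `q3`, `n`, `n_unknown` and `bins`
#'   (data frame `level`, `count`, `pct`).  An empty sample yields `NA`
#'   summaries.
#' @export
describe_tto <- function(sample) {
  if (!inherits(sample, "tto_sample"))
    sample <- structure(list(values = as.numeric(sample), n_unknown = 0L),
                        class = "tto_sample")
  v <- sample$values
  bins <- .count_block("TTO, days",
                       c(as.character(.bin_tto(v)),
                         rep(NA, sample$n_unknown)),
                       c("<2", "2-5", "5-7", "7-14", "14-28", ">=28",
                         "Unknown"))
  if (length(v)) {
    q <- unname(stats::quantile(v, c(0.5, 0.25, 0.75)))
  } else {
    q <- rep(NA_real_, 3)
  }
  list(median = q[1], q1 = q[2], q3 = q[3], n = length(v),
       n_unknown = sample$n_unknown, bins = bins[, -1, drop = FALSE])
}

#' Weibull maximum-likelihood fit of onset times
#'
#' Fits shape and scale by maximizing the Weibull log-likelihood over the
#' log-transformed parameters (deterministic quasi-Newton from a
#' moment-style start).  The shape confidence interval is the Wald
#' interval on `log(shape)` from the observed information, back-
#' transformed — so it is always positive and the hazard classification of
#' [classify_hazard()] is well-defined.  Zero-day onsets (event on the
#' start date) fall outside the positive Weibull support and are shifted
#' to `zero_shift` days before fitting.
#'
#' @param sample A `tto_sample` or numeric vector of non-negative days.
#' @param min_n Smallest sample size accepted (default 10).
#' @param zero_shift Replacement value for zero-day onsets (default 0.5).
#' @param conf_level Confidence level of the shape interval (default 0.95).
#' @return An object of class `weibull_fit`: `shape`, `scale`,
#'   `shape_ci` (lower, upper), `scale_ci`, `loglik`, `n`,
#'   `hazard_class`.
#' @export
#' @examples
#' set.seed(1)
#' weibull_mle(rweibull(500, shape = 0.8, scale = 30))
weibull_mle <- function(sample, min_n = 10, zero_shift = 0.5,
                        conf_level = 0.95) {
  x <- if (inherits(sample, "tto_sample")) sample$values else
    as.numeric(sample)
  x <- x[!is.na(x)]
  if (any(x < 0)) stop_config("onset times must be non-negative")
  if (length(x) < min_n)
    stop_config("need at least %d onset values to fit (got %d)", min_n,
                length(x))
  x[x == 0] <- zero_shift
  if (length(unique(x)) == 1L)
    stop_config("degenerate sample: all onset values identical after zero shift")

  nll <- function(th) {
    v <- suppressWarnings(
      -sum(stats::dweibull(x, shape = exp(th[1]), scale = exp(th[2]),
                           log = TRUE)))
    if (!is.finite(v)) return(1e10)   # keeps line searches in-bounds
    v
  }
  # moment-style start: shape from the dispersion of log(x)
  s0 <- max(1.2 / stats::sd(log(x)), 0.05)
  sc0 <- exp(mean(log(x)) + 0.5772 / s0)
  opt <- stats::optim(c(log(s0), log(sc0)), nll, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop_config("Weibull likelihood optimization failed to converge (status %d)",
                opt$convergence)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0))
    stop_config("observed information is singular; cannot form confidence interval")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(diag(vc))
  shape <- exp(opt$par[1]); scale <- exp(opt$par[2])
  shape_ci <- exp(opt$par[1] + c(-1, 1) * z * se_log[1])
  scale_ci <- exp(opt$par[2] + c(-1, 1) * z * se_log[2])
  fit <- structure(list(shape = shape, scale = scale,
                        shape_ci = shape_ci, scale_ci = scale_ci,
                        se_log_shape = se_log[1],
                        loglik = -opt$value, n = length(x),
                        conf_level = conf_level),
                   class = "weibull_fit")
  fit$hazard_class <- classify_hazard(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d  shape %.3f (%.0f%% CI %.3f-%.3f)  scale %.2f\n",
    x$n, x$shape, 100 * x$conf_level, x$shape_ci[1], x$shape_ci[2],
    x$scale))
  cat(sprintf("  hazard: %s over time\n", x$hazard_class))
  invisible(x)
}

#' Classify the hazard pattern from the shape confidence interval
#'
#' A Weibull shape below 1 means a hazard that falls with time on therapy
#' (early-risk concentration), above 1 a rising hazard.  The class is
#' decided by the whole confidence interval: `"decreasing"` when the upper
#' bound is below 1, `"increasing"` when the lower bound is above 1, and
#' `"constant"` when the interval contains 1.
#'
#' @param fit A `weibull_fit`, or a length-2 numeric `c(low, high)`
#'   confidence interval for the shape.
#' @return `"decreasing"`, `"constant"` or `"increasing"`.
#' @export
#' @examples
#' classify_hazard(c(0.719, 0.850))  # "decreasing"
classify_hazard <- function(fit) {
  ci <- if (inherits(fit, "weibull_fit")) fit$shape_ci else as.numeric(fit)
  if (length(ci) != 2L || any(is.na(ci)) || ci[1] > ci[2])
    stop_config("need a valid (low, high) shape confidence interval")
  if (ci[2] < 1) "decreasing" else if (ci[1] > 1) "increasing" else "constant"
}
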