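# Disproportionality statistics on 2x2 drug-event contingency tables.
#
# The 2x2 for a term:            event   not event
#   subject drug reports            a        b
#   all other reports               c        d
# Counting is report-level: a report counts once per term regardless of
# repeated PT rows, and once per SOC however many of its PTs map there.

#' Build a drug-event 2x2 contingency table
#'
#' Counts reports at the preferred-term or system-organ-class level,
#' splitting the dataset into subject-drug reports (`is_subject`) versus
#' all other reports — the comparator is the complement of the subject
#' reports within the supplied dataset.
#'
#' @param fd A `faers_data` containing both subject and background reports.
#' @param term The PT (or SOC when `level = "soc"`) to count.
#' @param level `"pt"` or `"soc"`.
#' @param soc_map Data frame with columns `pt`, `soc`; required for SOC
#'   level.
#' @return An object of class `contingency`: list with counts `a`, `b`,
#'   `c`, `d`, the `term`, `level` and `n` (= `a`).  A term absent from the
#'   dataset gives `a = c = 0`, not an error.
#' @export
build_contingency <- function(fd, term, level = c("pt", "soc"),
                              soc_map = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(fd, "faers_data"))
  re <- fd$reactions
  if (level == "soc") {
    if (is.null(soc_map) || !all(c("pt", "soc") %in% names(soc_map)))
      stop_config("soc_map with columns pt, soc is required at SOC level")
    re$termval <- soc_map$soc[match(re$pt, soc_map$pt)]
  } else {
    re$termval <- re$pt
  }
  subj <- fd$reports$primaryid[fd$reports$is_subject]
  n_subj <- length(subj)
  n_tot <- nrow(fd$reports)
  with_term <- unique(re$primaryid[!is.na(re$termval) & re$termval == term])
  a <- sum(with_term %in% subj)
  c_ <- length(with_term) - a
  structure(list(a = a, b = n_subj - a, c = c_,
                 d = n_tot - n_subj - c_, term = term, level = level,
                 n = a),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %s (%s): a=%d b=%d c=%d d=%d\n",
              x$term, x$level, x$a, x$b, x$c, x$d))
  invisible(x)
}

# Haldane-Anscombe: add 0.5 to every cell, only when some cell is zero.
# Applied to ROR / PRR / chi-square; the Bayesian statistics have their own
# priors and use raw counts.
.correct_cells <- function(a, b, c, d) {
  z <- (a == 0 | b == 0 | c == 0 | d == 0)
  list(a = a + 0.5 * z, b = b + 0.5 * z, c = c + 0.5 * z, d = d + 0.5 * z)
}

.ror_vec <- function(a, b, c, d) {
  undef <- (a + b == 0) | (c + d == 0)
  cc <- .correct_cells(a, b, c, d)
  est <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  out <- data.frame(ror = est, ror_low = exp(log(est) - 1.96 * se),
                    ror_high = exp(log(est) + 1.96 * se))
  out[undef, ] <- NA_real_
  out
}

.chi2_vec <- function(a, b, c, d, variant = c("yates", "pearson")) {
  variant <- match.arg(variant)
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (variant == "yates") num <- pmax(num - n / 2, 0)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

.prr_vec <- function(a, b, c, d, variant = "yates") {
  undef <- (a + b == 0) | (c + d == 0)
  cc <- .correct_cells(a, b, c, d)
  prr <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  chi2 <- .chi2_vec(cc$a, cc$b, cc$c, cc$d, variant)
  out <- data.frame(prr = prr, chi2 = chi2)
  out[undef, ] <- NA_real_
  out
}

# Bayesian confidence propagation moment approximation (information
# component).  Prior parameters are the customary defaults: gamma11 = 1,
# alpha1 = beta1 = 1, alpha = beta = 2, with gamma tied so E(IC) = 0 under
# independence.
.bcpnn_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + g) * (a + b + a1) * (a + c + b1)))
  v_ic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
             (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
             (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  data.frame(ic = e_ic, ic_var = v_ic,
             ic_minus_2sd = e_ic - 2 * sqrt(v_ic))
}

.as_cells <- function(table) {
  if (inherits(table, "contingency")) table
  else if (is.list(table) && all(c("a", "b", "c", "d") %in% names(table)))
    table
  else stop_config("expected a contingency table (a, b, c, d)")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a d) / (b c)`; the interval is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to all four cells) is
#' applied first.  An empty margin (`a + b = 0` or `c + d = 0`) yields an
#' undefined statistic (`NA`).
#'
#' @param table A `contingency` object (or list with `a`, `b`, `c`, `d`).
#' @return List with `ror`, `ror_low`, `ror_high`.
#' @export
#' @examples
#' ror(list(a = 20, b = 80, c = 100, d = 9800))$ror  # 24.5
ror <- function(table) {
  t <- .as_cells(table)
  as.list(.ror_vec(t$a, t$b, t$c, t$d))
}

#' Proportional reporting ratio with chi-square statistic
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`, with the Yates continuity-corrected
#' Pearson chi-square on the 2x2 (the uncorrected Pearson statistic is
#' available via `variant = "pearson"`).  Zero cells are Haldane-corrected
#' as for [ror()].
#'
#' @param table A `contingency` object (or list with `a`, `b`, `c`, `d`).
#' @param variant `"yates"` (default) or `"pearson"`.
#' @return List with `prr` and `chi2`.
#' @export
prr <- function(table, variant = c("yates", "pearson")) {
  variant <- match.arg(variant)
  t <- .as_cells(table)
  as.list(.prr_vec(t$a, t$b, t$c, t$d, variant))
}

#' Information component (Bayesian confidence propagation)
#'
#' Moment approximation of the information component
#' `IC = log2` of the observed-to-expected reporting probability ratio
#' under Dirichlet/Beta priors with the customary defaults, together with
#' its variance.  The signal criterion is `IC - 2 SD > 0`, computed
#' literally as `E[IC] - 2 sqrt(Var[IC])`.
#'
#' @param table A `contingency` object (or list with `a`, `b`, `c`, `d`).
#' @return List with `ic` (the posterior expectation, in bits), `ic_var`,
#'   and `ic_minus_2sd`.
#' @export
bcpnn_ic <- function(table) {
  t <- .as_cells(table)
  as.list(.bcpnn_vec(t$a, t$b, t$c, t$d))
}

#' Apply the per-algorithm signal criteria
#'
#' Flags: ROR positive when the 95% CI lower bound exceeds 1 (strictly)
#' with at least `min_n` reports; PRR positive when `PRR >= 2`, `chi2 >= 4`
#' (non-strict) and at least `min_n` reports; information component
#' positive when `IC - 2 SD > 0`; empirical-Bayes positive when
#' `EB05 > 2`.  The composite "positive safety signal" is any algorithm
#' positive.
#'
#' @param stats Data frame with columns `n`, `ror_low`, `prr`, `chi2`,
#'   `ic_minus_2sd`, `eb05` (e.g. from [signal_table()]).
#' @param min_n Minimum case count applied to the ROR and PRR criteria
#'   (default 3).
#' @return `stats` with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_ebgm`, `signal` appended (recomputed if present).
#' @export
evaluate_criteria <- function(stats, min_n = 3) {
  req <- c("n", "ror_low", "prr", "chi2", "ic_minus_2sd", "eb05")
  if (!all(req %in% names(stats)))
    stop_config("stats must have columns %s", paste(req, collapse = ", "))
  isT <- function(x) !is.na(x) & x
  stats$flag_ror <- isT(stats$ror_low > 1) & stats$n >= min_n
  stats$flag_prr <- isT(stats$prr >= 2) & isT(stats$chi2 >= 4) &
    stats$n >= min_n
  stats$flag_bcpnn <- isT(stats$ic_minus_2sd > 0)
  stats$flag_ebgm <- isT(stats$eb05 > 2)
  stats$signal <- stats$flag_ror | stats$flag_prr | stats$flag_bcpnn |
    stats$flag_ebgm
  stats
}

#' Full disproportionality table for every term
#'
#' Builds the 2x2 for every term observed at the requested level and
#' computes all four algorithms: reporting odds ratio, proportional
#' reporting ratio with chi-square, information component, and the
#' empirical-Bayes geometric mean under a gamma-mixture prior fitted to
#' the whole table set (see [fit_mgps_prior()]; a supplied `prior`
#' overrides the fit, and the DuMouchel default prior is used as a fallback
#' when fewer than two terms are available).
#'
#' @param fd A `faers_data` with subject flags set.
#' @param level `"pt"` or `"soc"`.
#' @param soc_map PT-to-SOC map (required at SOC level).
#' @param min_n Case-count floor for the ROR/PRR criteria.
#' @param prior Optional `mgps_prior` to use instead of fitting.
#' @param chi2_variant `"yates"` (default) or `"pearson"`.
#' @return Data frame, one row per term: counts, all statistics and
#'   bounds, per-algorithm flags and the composite `signal`, ordered by
#'   decreasing case count.  The fitted prior is attached as attribute
#'   `mgps_prior`.
#' @export
signal_table <- function(fd, level = c("pt", "soc"), soc_map = NULL,
                         min_n = 3, prior = NULL,
                         chi2_variant = c("yates", "pearson")) {
  level <- match.arg(level)
  chi2_variant <- match.arg(chi2_variant)
  stopifnot(inherits(fd, "faers_data"))
  re <- fd$reactions
  if (level == "soc") {
    if (is.null(soc_map) || !all(c("pt", "soc") %in% names(soc_map)))
      stop_config("soc_map with columns pt, soc is required at SOC level")
    re$termval <- soc_map$soc[match(re$pt, soc_map$pt)]
    re <- re[!is.na(re$termval), , drop = FALSE]
  } else {
    re$termval <- re$pt
  }
  pairs <- unique(re[, c("primaryid", "termval")])
  is_subj <- fd$reports$is_subject[match(pairs$primaryid,
                                         fd$reports$primaryid)]
  terms <- sort(unique(pairs$termval))
  a <- as.integer(table(factor(pairs$termval[is_subj], levels = terms)))
  ac <- as.integer(table(factor(pairs$termval, levels = terms)))
  n_subj <- sum(fd$reports$is_subject)
  n_tot <- nrow(fd$reports)
  b <- n_subj - a
  c_ <- ac - a
  d <- n_tot - n_subj - c_

  res <- data.frame(term = terms, n = a, a = a, b = b, c = c_, d = d,
                    stringsAsFactors = FALSE)
  res <- cbind(res, .ror_vec(a, b, c_, d), .prr_vec(a, b, c_, d,
                                                    chi2_variant),
               .bcpnn_vec(a, b, c_, d))

  expected <- (a + b) * (a + c_) / n_tot
  if (is.null(prior)) {
    prior <- if (length(a) >= 2 && any(expected > 0))
      tryCatch(fit_mgps_prior(a, expected),
               mgps_convergence_error = function(e) default_mgps_prior())
    else default_mgps_prior()
  }
  eb <- ebgm(list(a = a, expected = expected), prior)
  res$ebgm <- eb$ebgm
  res$eb05 <- eb$eb05

  res <- evaluate_criteria(res, min_n = min_n)
  res <- res[order(-res$n, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "mgps_prior") <- prior
  res
}
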