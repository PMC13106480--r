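# Case/non-case risk-factor analysis: strict case labelling, univariate
# screen, LASSO selection (10-fold CV, one-standard-error rule),
# multivariable logistic estimation.

#' Label reports as cases of the target event
#'
#' A report is a case if and only if it contains the exact target
#' preferred term; reports with related but different terms (neutropenia,
#' anemia, ...) are non-cases, keeping the case definition unambiguous.
#'
#' @param fd A `faers_data`.
#' @param case_pt The case-defining PT string or code (exact,
#'   case-insensitive match).
#' @return Data frame with `primaryid` and logical `case`, one row per
#'   report in the dataset.
#' @export
define_cases <- function(fd, case_pt) {
  stopifnot(inherits(fd, "faers_data"))
  hit <- unique(fd$reactions$primaryid[
    tolower(trimws(fd$reactions$pt)) == tolower(trimws(case_pt))])
  data.frame(primaryid = fd$reports$primaryid,
             case = fd$reports$primaryid %in% hit)
}

# Association test between a single variable and a binary grouping.
# Categorical: Yates chi-square on 2x2 / Pearson chi-square on r x c,
# switching to Fisher's exact test when any expected cell is below 5.
# Continuous: Wilcoxon rank-sum.  Returns list(test, p, note).
.assoc_test <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (length(unique(g)) < 2L)
    return(list(test = "none", p = NA_real_, note = "single group"))
  is_cont <- is.numeric(x) && length(unique(x)) > 6L
  if (is_cont) {
    p <- stats::wilcox.test(x ~ factor(g), exact = FALSE)$p.value
    return(list(test = "wilcoxon", p = p, note = ""))
  }
  tab <- table(factor(x), factor(g))
  if (nrow(tab) < 2L)
    return(list(test = "none", p = NA_real_, note = "constant variable"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab, workspace = 2e6)$p.value
    return(list(test = "fisher", p = p, note = "expected cell < 5"))
  }
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    p <- stats::chisq.test(tab, correct = TRUE)$p.value
    list(test = "chisq_yates", p = p, note = "")
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    list(test = "chisq", p = p, note = "")
  }
}

#' Univariate screen of candidate risk factors
#'
#' Tests each candidate variable against the case label: Yates-corrected
#' chi-square for binary factors (Pearson for multi-level), Fisher's exact
#' test whenever any expected cell is below 5, and the Wilcoxon rank-sum
#' test for continuous variables.  Variables pass at `p < alpha`
#' (strictly); constant variables are excluded with a reason.
#'
#' @param features Data frame of candidate variables (binary/ordinal
#'   columns as numeric or factor, continuous as numeric).
#' @param labels Logical or 0/1 vector of case labels, `nrow(features)`
#'   long.
#' @param alpha Screening threshold (default 0.10).
#' @return Data frame: `variable`, `test`, `p`, `pass`, `note`.
#' @export
univariate_screen <- function(features, labels, alpha = 0.10) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  g <- as.integer(as.logical(labels))
  rows <- lapply(names(features), function(nm) {
    r <- .assoc_test(features[[nm]], g)
    data.frame(variable = nm, test = r$test, p = r$p,
               pass = !is.na(r$p) && r$p < alpha, note = r$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# complete-case model matrix for the penalized / logistic stages;
# factors are expanded to treatment-contrast indicators
.design_matrix <- function(features, labels) {
  df <- as.data.frame(features)
  cc <- stats::complete.cases(df) & !is.na(labels)
  df <- df[cc, , drop = FALSE]
  x <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  list(x = x, y = as.integer(as.logical(labels))[cc],
       n_dropped = sum(!cc))
}

#' LASSO variable selection with cross-validated penalty
#'
#' Penalized logistic regression (glmnet binomial deviance path) with the
#' penalty chosen by k-fold cross-validation; the default is the
#' one-standard-error rule (the largest penalty whose CV deviance is
#' within one standard error of the minimum), favouring the sparser
#' model.  Fold assignment is stratified by outcome and derived from
#' `seed`, so the whole selection is reproducible.  Predictors are
#' standardized to unit variance inside the penalty (coefficients are
#' reported on the original scale).  Complete cases only; dropped rows
#' are counted.
#'
#' @param features Data frame of candidate predictors (2 or more columns).
#' @param labels Case labels (logical or 0/1).
#' @param folds Number of CV folds (default 10).
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `lasso_result`: `lambda_grid`,
#'   `cv_deviance`, `cv_se`, `lambda_min`, `lambda_1se`, `lambda_used`,
#'   `selected` (names with non-zero coefficients at the chosen penalty),
#'   `coefs`, `n_used`, `n_dropped`, `seed`.
#' @export
lasso_select <- function(features, labels, folds = 10, rule = c("1se", "min"),
                         seed = 1L) {
  rule <- match.arg(rule)
  if (ncol(features) < 2L)
    stop_config("need at least 2 candidate variables for selection")
  dm <- .design_matrix(features, labels)
  n_events <- sum(dm$y == 1L)
  n_non <- sum(dm$y == 0L)
  if (min(n_events, n_non) < folds)
    stop_config(paste0("only %d observations in the smaller outcome class; ",
                       "use fewer than %d folds"),
                min(n_events, n_non), folds)
  set.seed(seed)
  foldid <- integer(length(dm$y))
  for (cls in c(0L, 1L)) {
    idx <- which(dm$y == cls)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(dm$x, dm$y, family = "binomial",
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  lambda_used <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(stats::coef(cv, s = lambda_used))[, 1]
  selected <- setdiff(names(beta)[beta != 0], "(Intercept)")
  structure(list(lambda_grid = cv$lambda, cv_deviance = cv$cvm,
                 cv_se = cv$cvsd, lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se, lambda_used = lambda_used,
                 rule = rule, selected = selected, coefs = beta,
                 n_used = length(dm$y), n_dropped = dm$n_dropped,
                 seed = seed),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> lambda.min=%.4g lambda.1se=%.4g (%s rule)\n",
              x$lambda_min, x$lambda_1se, x$rule))
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Multivariable logistic regression with separation-aware reporting
#'
#' Maximum-likelihood logistic fit of the case label on the selected
#' variables, reporting adjusted odds ratios with Wald 95% intervals on
#' the log scale.  Complete separation is detected (diverging coefficient
#' with an exploding standard error) and reported as an odds ratio of 0 or
#' infinity with an unbounded interval and the (non-significant) Wald
#' p-value — not as an exception.  A rank-deficient design is an error
#' naming the aliased columns.
#'
#' @param features Data frame containing at least the selected variables.
#' @param labels Case labels (logical or 0/1).
#' @param selected Character vector of variable names to adjust for
#'   (non-empty).
#' @return Data frame of class `effect_estimates`: `variable`, `or`,
#'   `ci_low`, `ci_high`, `p`, `converged`, `separation`; attributes
#'   `n_used`, `n_dropped`, `fit` (the `glm` object).
#' @export
fit_logistic <- function(features, labels, selected) {
  if (length(selected) == 0L)
    stop_config("'selected' must name at least one variable")
  missing_vars <- setdiff(selected, names(features))
  if (length(missing_vars))
    stop_config("variables not in features: %s",
                paste(missing_vars, collapse = ", "))
  df <- as.data.frame(features)[, selected, drop = FALSE]
  cc <- stats::complete.cases(df) & !is.na(labels)
  df <- df[cc, , drop = FALSE]
  df$.y <- as.integer(as.logical(labels))[cc]
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = df))
  if (any(is.na(stats::coef(fit))))
    stop_config("singular design; aliased column(s): %s",
                paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                      collapse = ", "))
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  b <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; p <- sm[, 4]
  sep <- se > 50 | abs(b) > 15
  or <- exp(b); lo <- exp(b - 1.96 * se); hi <- exp(b + 1.96 * se)
  or[sep] <- ifelse(b[sep] < 0, 0, Inf)
  lo[sep] <- 0
  hi[sep] <- Inf
  out <- data.frame(variable = rownames(sm), or = or, ci_low = lo,
                    ci_high = hi, p = p,
                    converged = fit$converged & !sep, separation = sep,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_used") <- nrow(df)
  attr(out, "n_dropped") <- sum(!cc)
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Report-level feature table for the case/non-case analysis
#'
#' Derives candidate predictors from an assembled dataset: sex (female
#' indicator, unknown sex as missing), age in years, one binary indicator
#' per indication (non-mutually exclusive, since one report may list
#' several cancer types), and one binary indicator per co-reported
#' (non-subject) drug among the `max_drugs` most frequent ones.
#'
#' @param fd A `faers_data` (typically [subject_reports()]).
#' @param max_drugs Number of most frequent concomitant drugs to encode
#'   (default 10).
#' @return List with `features` (data frame) and `primaryid`.
#' @export
report_features <- function(fd, max_drugs = 10) {
  stopifnot(inherits(fd, "faers_data"))
  r <- fd$reports
  feats <- data.frame(row.names = seq_len(nrow(r)))
  feats$sex_female <- ifelse(r$sex %in% c("F", "M"),
                             as.integer(r$sex == "F"), NA_integer_)
  feats$age <- r$age_years
  if (!is.null(fd$indications) && nrow(fd$indications)) {
    for (ind in sort(unique(fd$indications$indi_pt))) {
      ids <- unique(fd$indications$primaryid[fd$indications$indi_pt == ind])
      nm <- paste0("indi_", gsub("[^A-Za-z0-9]+", "_", tolower(ind)))
      feats[[nm]] <- as.integer(r$primaryid %in% ids)
    }
  }
  if (!is.null(fd$drugs) && nrow(fd$drugs)) {
    con <- fd$drugs[!(toupper(fd$drugs$role_cod) == "PS" & r$is_subject[
      match(fd$drugs$primaryid, r$primaryid)]), , drop = FALSE]
    top <- names(sort(table(con$drugname), decreasing = TRUE))
    top <- utils::head(top, max_drugs)
    for (dn in top) {
      ids <- unique(con$primaryid[con$drugname == dn])
      nm <- paste0("drug_", gsub("[^A-Za-z0-9]+", "_", tolower(dn)))
      feats[[nm]] <- as.integer(r$primaryid %in% ids)
    }
  }
  list(features = feats, primaryid = r$primaryid)
}
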