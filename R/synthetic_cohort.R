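#' Configuration for the clinical-cohort simulator
#'
#' Describes a synthetic patient cohort whose binary outcome
#' (myelosuppression) follows a logistic model with user-specified covariate
#' effects, and whose severity grade, assigned only to patients with the
#' outcome, is multinomial over CTCAE grades I-IV.
#'
#' The default configuration emulates a single-centre checkpoint-inhibitor
#' cohort of 170 thoracic-oncology patients: almost exclusively male,
#' esophageal or lung cancer, platinum-based combination chemotherapy, an
#' ordinal metastasis (M) stage with an "unknown" top level, a true
#' cisplatin odds ratio of 2.24 and a per-increment M-stage odds ratio of
#' 0.871, an intercept giving roughly two-thirds outcome prevalence, and a
#' conditional grade distribution concentrated on grades I-II.
#'
#' @param n_patients Number of patients (0 allowed; yields an empty table).
#' @param covariate_spec Named list; each element is a list with fields
#'   `type` (`"binary"`, `"ordinal"` or `"continuous"`) and marginal
#'   parameters: `p` (success probability) for binary, `probs` (level
#'   probabilities for integer levels `0, 1, ...`) for ordinal, `mean` and
#'   `sd` for continuous.
#' @param log_odds Named numeric vector of true log odds ratios per unit of
#'   the named covariates; covariates not named get effect 0.
#' @param intercept True intercept of the logistic outcome model.
#' @param grade_probs Length-4 probability vector (grades I-IV, summing to 1
#'   within 1e-12) for the grade assigned when the outcome occurs.
#' @param seed Integer seed (Mersenne-Twister via [set.seed()]).
#' @return An object of class `cohort_sim_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_sim_config <- function(n_patients = 170,
                              covariate_spec = NULL,
                              log_odds = c(cisplatin = log(2.240),
                                           m_stage = log(0.871)),
                              intercept = 0.3,
                              grade_probs = c(69, 32, 7, 6) / 114,
                              seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0 || n_patients != as.integer(n_patients))
    stop_config("'n_patients' must be a non-negative integer")
  n_patients <- as.integer(n_patients)
  if (is.null(covariate_spec)) {
    covariate_spec <- list(
      sex_female = list(type = "binary", p = 0.035),
      age = list(type = "continuous", mean = 63.5, sd = 7),
      lung_cancer = list(type = "binary", p = 0.32),
      esophageal_cancer = list(type = "binary", p = 0.68),
      m_stage = list(type = "ordinal", probs = c(0.53, 0.30, 0.17)),
      carboplatin = list(type = "binary", p = 0.16),
      nedaplatin = list(type = "binary", p = 0.135),
      cisplatin = list(type = "binary", p = 0.62),
      bevacizumab = list(type = "binary", p = 0.035)
    )
  }
  nms <- names(covariate_spec)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop_config("covariate_spec must be a named list with unique names")
  for (nm in nms) {
    sp <- covariate_spec[[nm]]
    if (!is.list(sp) || is.null(sp$type) ||
        !sp$type %in% c("binary", "ordinal", "continuous"))
      stop_config("covariate '%s' needs type binary, ordinal or continuous", nm)
    switch(sp$type,
      binary = assert_prob(sp$p, paste0(nm, "$p")),
      ordinal = {
        if (is.null(sp$probs) || any(sp$probs < 0) ||
            abs(sum(sp$probs) - 1) > 1e-8)
          stop_config("covariate '%s' needs probs summing to 1", nm)
      },
      continuous = {
        if (is.null(sp$mean) || is.null(sp$sd) || sp$sd <= 0)
          stop_config("covariate '%s' needs mean and positive sd", nm)
      })
  }
  if (length(log_odds) && (is.null(names(log_odds)) ||
      !all(names(log_odds) %in% nms)))
    stop_config("log_odds names must be a subset of covariate names")
  if (length(grade_probs) != 4L || any(grade_probs < 0) ||
      abs(sum(grade_probs) - 1) > 1e-12)
    stop_config("grade_probs must be 4 probabilities summing to 1 (within 1e-12)")
  seed <- assert_count(seed, "seed", min = 0L)

  structure(list(n_patients = n_patients, covariate_spec = covariate_spec,
                 log_odds = log_odds, intercept = intercept,
                 grade_probs = grade_probs, seed = seed),
            class = "cohort_sim_config")
}

#' Generate a synthetic clinical cohort
#'
#' Draws covariates from their marginal distributions (independently), the
#' binary outcome from the logistic model
#' `logit P(outcome) = intercept + sum(log_odds * x)`, and, for patients
#' with the outcome, a CTCAE grade (`"I"`-`"IV"`) from `grade_probs`.
#'
#' @param config A [cohort_sim_config()].
#' @return A data frame with one row per patient: `patient_id`, one column
#'   per covariate, `myelosuppression` (0/1) and `grade` (factor, `NA` for
#'   patients without the outcome).  The true linear predictor is not
#'   included; ground truth lives in `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n_patients = 50, seed = 3))
#' table(coh$myelosuppression)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    stop_config("config must be a cohort_sim_config")
  set.seed(config$seed)
  n <- config$n_patients
  nms <- names(config$covariate_spec)
  cols <- lapply(nms, function(nm) {
    sp <- config$covariate_spec[[nm]]
    if (n == 0L) return(numeric(0))
    switch(sp$type,
      binary = stats::rbinom(n, 1L, sp$p),
      ordinal = sample(seq_along(sp$probs) - 1L, n, replace = TRUE,
                       prob = sp$probs),
      continuous = stats::rnorm(n, sp$mean, sp$sd))
  })
  names(cols) <- nms
  x <- as.data.frame(cols)
  lp <- rep(config$intercept, n)
  for (nm in names(config$log_odds))
    lp <- lp + config$log_odds[[nm]] * x[[nm]]
  y <- if (n) stats::rbinom(n, 1L, stats::plogis(lp)) else integer(0)
  grade <- factor(rep(NA_character_, n), levels = c("I", "II", "III", "IV"))
  if (any(y == 1L))
    grade[y == 1L] <- sample(c("I", "II", "III", "IV"), sum(y == 1L),
                             replace = TRUE, prob = config$grade_probs)
  out <- cbind(data.frame(patient_id = seq_len(n)), x,
               data.frame(myelosuppression = y, grade = grade))
  rownames(out) <- NULL
  out
}
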