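test_that("case labelling is strict: only the exact target term counts", {
  fd <- toy_faers_data(list(c("Neutropenia", "Rash"),
                            "Myelosuppression",
                            c("Anaemia", "Myelosuppression"),
                            "Thrombocytopenia"),
                       is_subject = rep(TRUE, 4))
  lab <- define_cases(fd, "Myelosuppression")
  expect_equal(lab$case, c(FALSE, TRUE, TRUE, FALSE))
  empty <- define_cases(toy_faers_data(list(), logical(0)), "X")
  expect_equal(nrow(empty), 0L)
})

test_that("the univariate screen reproduces printed two-group p-values", {
  # sex split across non-cases/cases: F 37/34, M 104/42
  sex <- expand_table(matrix(c(37, 104, 34, 42), 2,
                             dimnames = list(c("F", "M"), c("0", "1"))))
  scr <- univariate_screen(data.frame(sex = sex$x),
                           labels = sex$g == "1")
  expect_equal(scr$test, "chisq_yates")
  expect_equal(round_half_up(scr$p, 3), 0.009)
  expect_true(scr$pass)
  # carboplatin: no 130/71, yes 11/5 -> p = 0.955, fails the 0.10 screen
  cb <- expand_table(matrix(c(130, 11, 71, 5), 2,
                            dimnames = list(c("no", "yes"), c("0", "1"))))
  scr2 <- univariate_screen(data.frame(carboplatin = cb$x), cb$g == "1")
  expect_equal(round_half_up(scr2$p, 3), 0.955)
  expect_false(scr2$pass)
})

test_that("screen handles balanced, constant and continuous variables", {
  y <- rep(c(FALSE, TRUE), each = 50)
  bal <- rep(c(0, 1), 50)                       # identical in both groups
  scr <- univariate_screen(
    data.frame(balanced = bal, constant = 1,
               cont = c(rnorm(50), rnorm(50, 2))), y)
  expect_equal(scr$p[scr$variable == "balanced"], 1)
  expect_false(scr$pass[scr$variable == "balanced"])
  expect_true(is.na(scr$p[scr$variable == "constant"]))
  expect_equal(scr$note[scr$variable == "constant"], "constant variable")
  expect_equal(scr$test[scr$variable == "cont"], "wilcoxon")
  expect_true(scr$pass[scr$variable == "cont"])
})

test_that("null predictors are mostly dropped; a strong one is always kept", {
  n <- 1000
  picks_null <- integer(0)
  picks_strong <- logical(0)
  for (s in 1:10) {
    set.seed(s)
    x <- as.data.frame(matrix(rbinom(n * 8, 1, 0.3), n))
    names(x) <- paste0("v", 1:8)
    y_null <- rbinom(n, 1, 0.3)
    sel <- lasso_select(x, y_null, seed = s)$selected
    picks_null <- c(picks_null, length(sel))
    x$strong <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, plogis(-1 + log(4) * x$strong))
    sel2 <- lasso_select(x, y, seed = s)$selected
    picks_strong <- c(picks_strong, "strong" %in% sel2)
  }
  expect_gte(mean(picks_null <= 1), 0.8)
  expect_gte(mean(picks_strong), 0.95)
})

test_that("selection is deterministic given the seed", {
  set.seed(99)
  x <- as.data.frame(matrix(rbinom(3000, 1, 0.4), 500))
  y <- rbinom(500, 1, 0.4)
  r1 <- lasso_select(x, y, seed = 42)
  r2 <- lasso_select(x, y, seed = 42)
  expect_identical(r1$lambda_used, r2$lambda_used)
  expect_identical(r1$selected, r2$selected)
  expect_gte(r1$lambda_1se, r1$lambda_min)
})

test_that("too few events for the fold count is a clear error", {
  x <- data.frame(a = rbinom(50, 1, 0.5), b = rbinom(50, 1, 0.5))
  y <- c(rep(TRUE, 4), rep(FALSE, 46))
  expect_error(lasso_select(x, y, folds = 10), "fewer")
  expect_error(lasso_select(x[, 1, drop = FALSE], y), "2 candidate")
})

test_that("complete separation is reported, not thrown", {
  n <- 80
  x <- data.frame(sep = rep(c(0, 1), each = n / 2),
                  ok = rbinom(n, 1, 0.5))
  y <- c(rbinom(n / 2, 1, 0.4), rep(0, n / 2))  # no events where sep = 1
  eff <- fit_logistic(x, y, c("sep", "ok"))
  row <- eff[eff$variable == "sep", ]
  expect_true(row$separation)
  expect_false(row$converged)
  expect_equal(row$or, 0)
  expect_equal(row$ci_low, 0)
  expect_equal(row$ci_high, Inf)
  expect_gt(row$p, 0.5)
})

test_that("the adjusted odds ratio recovers a planted fourfold effect", {
  cfg <- cohort_sim_config(
    n_patients = 5000,
    covariate_spec = list(
      paclitaxel = list(type = "binary", p = 0.11),
      sex_female = list(type = "binary", p = 0.33),
      age = list(type = "continuous", mean = 60, sd = 10)),
    log_odds = c(paclitaxel = log(4.129), sex_female = log(0.457)),
    intercept = -0.8, seed = 61)
  coh <- generate_cohort(cfg)
  eff <- fit_logistic(coh[, c("paclitaxel", "sex_female", "age")],
                      coh$myelosuppression,
                      c("paclitaxel", "sex_female", "age"))
  or <- eff$or[eff$variable == "paclitaxel"]
  expect_gt(or, 3.3)
  expect_lt(or, 5.2)
})

test_that("affine recoding of an ordinal rescales its per-unit effect", {
  set.seed(71)
  m <- sample(0:2, 600, replace = TRUE)
  y <- rbinom(600, 1, plogis(0.3 - 0.2 * m))
  e1 <- fit_logistic(data.frame(m = m), y, "m")
  e2 <- fit_logistic(data.frame(m = 2 * m), y, "m")
  expect_equal(log(e1$or), 2 * log(e2$or), tolerance = 1e-8)
})

test_that("a singular design names the aliased column", {
  x <- data.frame(a = rbinom(100, 1, 0.5))
  x$b <- x$a
  y <- rbinom(100, 1, 0.5)
  expect_error(fit_logistic(x, y, c("a", "b")), "aliased.*b")
})

test_that("screen, selection and fit compose deterministically", {
  cfg <- cohort_sim_config(n_patients = 800, seed = 19)
  coh <- generate_cohort(cfg)
  feats <- coh[, c("sex_female", "age", "lung_cancer", "m_stage",
                   "carboplatin", "cisplatin")]
  run_once <- function() {
    scr <- univariate_screen(feats, coh$myelosuppression, alpha = 0.5)
    cand <- scr$variable[scr$pass]
    las <- lasso_select(feats[, cand], coh$myelosuppression, seed = 7)
    sel <- if (length(las$selected)) las$selected else cand[1]
    fit_logistic(feats, coh$myelosuppression, intersect(sel, names(feats)))
  }
  expect_identical(run_once(), run_once())
})
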