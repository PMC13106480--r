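test_that("a fixed seed reproduces the table set exactly, on disk too", {
  cfg <- faers_sim_config(n_reports = 300, seed = 123)
  s1 <- generate_faers_tables(cfg)
  s2 <- generate_faers_tables(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_faers_tables(s1, d1)
  write_faers_tables(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("without planted effects every drug-event odds ratio sits near 1", {
  res <- sim_to_data(faers_sim_config(n_reports = 10000, seed = 21))
  st <- signal_table(res$fd)
  expect_true(all(st$ror > 0.5 & st$ror < 2, na.rm = TRUE))
  # composite criterion fires rarely under the null
  expect_lt(mean(st$signal), 0.10)
})

test_that("a planted relative risk of 5 yields an empirical odds ratio in [4, 6]", {
  cfg <- faers_sim_config(
    n_reports = 50000, seed = 7,
    planted_effects = data.frame(drug = "DRUG_0001", term = "TERM_0007",
                                 rr = 5))
  res <- sim_to_data(cfg)
  # independent tally straight from the long tables, no signal-engine code
  reps <- res$fd$reports
  subj <- reps$primaryid[reps$is_subject]
  with_term <- unique(res$fd$reactions$primaryid[
    res$fd$reactions$pt == "TERM_0007"])
  a <- sum(with_term %in% subj)
  b <- length(subj) - a
  c_ <- length(with_term) - a
  d <- nrow(reps) - length(subj) - c_
  or_hand <- (a * d) / (b * c_)
  expect_gt(or_hand, 4)
  expect_lt(or_hand, 6)
  # the signal engine must agree with the direct tally exactly
  st <- signal_table(res$fd)
  expect_equal(st$ror[st$term == "TERM_0007"], or_hand, tolerance = 1e-12)
})

test_that("duplicate injection matches the ground-truth registry", {
  sim <- generate_faers_tables(faers_sim_config(n_reports = 500, seed = 5,
                                                duplicate_fraction = 0.2))
  dd <- deduplicate_reports(sim$tables$demo)
  expect_equal(dd$n_removed, nrow(sim$truth$duplicates))
  expect_setequal(dd$demo$primaryid, sim$truth$reports$primaryid_kept)
  # duplicates mutate only PRIMARYID and FDA_DT
  dup <- sim$tables$demo[match(sim$truth$duplicates$primaryid_dup,
                               sim$tables$demo$primaryid), ]
  orig <- sim$tables$demo[match(sim$truth$duplicates$primaryid_original,
                                sim$tables$demo$primaryid), ]
  same_cols <- setdiff(names(dup), c("primaryid", "fda_dt"))
  for (cn in same_cols)
    expect_identical(unname(dup[[cn]]), unname(orig[[cn]]), label = cn)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(faers_sim_config(n_reports = 0), "n_reports")
  expect_error(faers_sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(faers_sim_config(duplicate_fraction = 1.2),
               "duplicate_fraction")
  expect_error(faers_sim_config(
    planted_effects = data.frame(drug = "DRUG_9999", term = "TERM_0001",
                                 rr = 2)), "vocabulary")
  expect_error(cohort_sim_config(grade_probs = c(0.5, 0.5, 0.1, 0)),
               "grade_probs")
  expect_error(cohort_sim_config(n_patients = -1), "n_patients")
  expect_error(cohort_sim_config(log_odds = c(nosuch = 1)), "log_odds")
})

test_that("zero-effect cohort has one-half outcome prevalence", {
  cfg <- cohort_sim_config(
    n_patients = 20000,
    covariate_spec = list(x1 = list(type = "binary", p = 0.5),
                          x2 = list(type = "continuous", mean = 0, sd = 1)),
    log_odds = c(x1 = 0), intercept = 0, seed = 31)
  coh <- generate_cohort(cfg)
  expect_gt(mean(coh$myelosuppression), 0.48)
  expect_lt(mean(coh$myelosuppression), 0.52)
})

test_that("a logistic refit recovers the planted cisplatin odds ratio", {
  coh <- generate_cohort(cohort_sim_config(n_patients = 5000, seed = 17))
  fit <- glm(myelosuppression ~ cisplatin + m_stage, binomial(), coh)
  or <- exp(coef(fit)["cisplatin"])
  expect_gt(or, 1.8)
  expect_lt(or, 2.8)
})

test_that("degenerate cohort size yields an empty, well-formed table", {
  coh <- generate_cohort(cohort_sim_config(n_patients = 0))
  expect_equal(nrow(coh), 0)
  expect_true(all(c("patient_id", "cisplatin", "myelosuppression",
                    "grade") %in% names(coh)))
})

test_that("grades are assigned exactly to patients with the outcome", {
  coh <- generate_cohort(cohort_sim_config(n_patients = 400, seed = 9))
  expect_true(all(is.na(coh$grade[coh$myelosuppression == 0])))
  expect_true(all(!is.na(coh$grade[coh$myelosuppression == 1])))
})
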