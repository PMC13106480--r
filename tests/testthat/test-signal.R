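# Hand-checkable dataset: 6 reports, first three from the subject drug.
# term X: subject 2 of 3, background 1 of 3 -> a=2 b=1 c=1 d=2
toy_six <- function() {
  toy_faers_data(list(c("X", "Y"), "X", "Y", "X", "Y", "Z"),
                 is_subject = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
}

test_that("contingency counts equal a manual tally, report-level", {
  tab <- build_contingency(toy_six(), "X")
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 2, b = 1, c = 1, d = 2))
  # a report with repeated PT rows still counts once
  fd <- toy_six()
  fd$reactions <- rbind(fd$reactions,
                        data.frame(primaryid = 1001L, caseid = 1001L,
                                   pt = "X"))
  expect_equal(build_contingency(fd, "X")$a, 2)
  # unreported term and saturated term
  none <- build_contingency(toy_six(), "NOPE")
  expect_equal(c(none$a, none$c), c(0, 0))
  all_fd <- toy_faers_data(list("X", "X"), c(TRUE, FALSE))
  sat <- build_contingency(all_fd, "X")
  expect_equal(c(sat$b, sat$d), c(0, 0))
})

test_that("SOC-level counting deduplicates PTs within an organ class", {
  fd <- toy_faers_data(list(c("pt1", "pt2", "pt3"), "pt4"),
                       is_subject = c(TRUE, FALSE))
  map <- data.frame(pt = c("pt1", "pt2", "pt3", "pt4"),
                    soc = c("SOC_A", "SOC_A", "SOC_A", "SOC_B"))
  tab <- build_contingency(fd, "SOC_A", level = "soc", soc_map = map)
  expect_equal(tab$a, 1)      # three PTs, one report, one count
  expect_error(build_contingency(fd, "SOC_A", level = "soc"), "soc_map")
})

test_that("reporting odds ratio matches its closed form", {
  ind <- ror(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(ind$ror, 1)
  expect_equal(log(ind$ror_high) + log(ind$ror_low), 0, tolerance = 1e-12)
  expect_equal(ror(list(a = 20, b = 80, c = 100, d = 9800))$ror, 24.5)
  # zero cell: Haldane correction keeps everything finite
  z <- ror(list(a = 0, b = 10, c = 5, d = 85))
  expect_equal(z$ror, (0.5 * 85.5) / (10.5 * 5.5))
  expect_lt(z$ror, 1)
  expect_lt(z$ror_low, 1)
  # empty margin is undefined, not an error
  expect_true(is.na(ror(list(a = 0, b = 0, c = 5, d = 5))$ror))
})

test_that("proportional reporting ratio and chi-square match closed forms", {
  flat <- prr(list(a = 10, b = 90, c = 20, d = 180))
  expect_equal(flat$prr, 1)
  expect_lt(flat$chi2, 0.1)
  expect_equal(prr(list(a = 20, b = 80, c = 100, d = 9800))$prr, 19.8)
  # swapping the two rows inverts the ratio
  t1 <- prr(list(a = 7, b = 13, c = 4, d = 76))
  t2 <- prr(list(a = 4, b = 76, c = 7, d = 13))
  expect_equal(t1$prr, 1 / t2$prr, tolerance = 1e-12)
})

test_that("both chi-square variants agree with stats::chisq.test", {
  set.seed(8)
  for (i in 1:20) {
    cells <- sample(1:60, 4, replace = TRUE)
    tab <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(prr(tab, variant = "yates")$chi2,
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
    expect_equal(prr(tab, variant = "pearson")$chi2,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("information component is near zero at independence, negative at a = 0", {
  # margins chosen so a equals its expectation exactly
  ind <- bcpnn_ic(list(a = 50, b = 450, c = 950, d = 8550))
  expect_lt(abs(ind$ic), 0.05)
  expect_lt(bcpnn_ic(list(a = 0, b = 100, c = 200, d = 9700))$ic, 0)
})

test_that("signal criteria apply the case floor and strict/non-strict bounds", {
  base <- data.frame(n = c(2, 10, 3, 3), ror_low = c(5, 1.0, 0.5, 2),
                     prr = c(3, 1, 2.0, 1), chi2 = c(10, 1, 4.0, 1),
                     ic_minus_2sd = c(-1, -1, -1, -1),
                     eb05 = c(1, 1, 1, 1))
  out <- evaluate_criteria(base)
  expect_equal(out$flag_ror, c(FALSE, FALSE, FALSE, TRUE))  # n floor; =1 strict
  expect_equal(out$flag_prr, c(FALSE, FALSE, TRUE, FALSE))  # >= bounds
  expect_equal(out$signal, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("ROR approximates PRR when the event is rare in both arms", {
  set.seed(15)
  for (i in 1:20) {
    a <- sample(1:20, 1); b <- sample(500:2000, 1)
    c_ <- sample(1:100, 1); d <- sample(5000:50000, 1)
    r <- ror(list(a = a, b = b, c = c_, d = d))$ror
    p <- prr(list(a = a, b = b, c = c_, d = d))$prr
    expect_lt(abs(r - p) / p, 0.05)
  }
})

test_that("the batch table equals per-term evaluation and ignores row order", {
  res <- sim_to_data(faers_sim_config(n_reports = 1500, seed = 3))
  st <- signal_table(res$fd)
  for (tm in st$term[1:5]) {
    tab <- build_contingency(res$fd, tm)
    expect_equal(st$ror[st$term == tm], ror(tab)$ror)
    expect_equal(st$prr[st$term == tm], prr(tab)$prr)
    expect_equal(st$ic[st$term == tm], bcpnn_ic(tab)$ic)
  }
  fd2 <- res$fd
  set.seed(1)
  fd2$reactions <- fd2$reactions[sample(nrow(fd2$reactions)), ]
  fd2$reports <- fd2$reports[sample(nrow(fd2$reports)), ]
  st2 <- signal_table(fd2, prior = attr(st, "mgps_prior"))
  st1 <- signal_table(res$fd, prior = attr(st, "mgps_prior"))
  expect_equal(st1, st2, ignore_attr = TRUE)
})

test_that("a planted signal clears the Bayesian criterion at realistic size", {
  cfg <- faers_sim_config(
    n_reports = 10000, seed = 25,
    planted_effects = data.frame(drug = "DRUG_0001", term = "TERM_0003",
                                 rr = 5))
  st <- signal_table(sim_to_data(cfg)$fd)
  row <- st[st$term == "TERM_0003", ]
  expect_gt(row$ic_minus_2sd, 0)
  expect_gt(row$eb05, 2)
})
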