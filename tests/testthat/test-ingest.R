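test_that("written tables round-trip through the ASCII reader", {
  sim <- generate_faers_tables(faers_sim_config(n_reports = 50, seed = 2))
  dir <- withr::local_tempdir()
  write_faers_tables(sim, dir)
  for (kind in names(sim$tables)) {
    got <- read_ascii_table(file.path(dir, paste0(toupper(kind), ".txt")),
                            kind)
    want <- sim$tables[[kind]]
    expect_equal(nrow(got), nrow(want), label = kind)
    expect_equal(got$primaryid, want$primaryid, label = kind)
    expect_equal(attr(got, "parse_warnings"), 0L, label = kind)
  }
  demo <- read_ascii_table(file.path(dir, "DEMO.txt"), "demo")
  expect_identical(demo$fda_dt, sim$tables$demo$fda_dt)
  expect_identical(demo$sex, sim$tables$demo$sex)
  expect_equal(demo$wt, sim$tables$demo$wt)
})

test_that("malformed rows are counted and skipped, not silently dropped", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$pt",
               "1$10$TERM_0001",
               "2$20$TERM_0002$EXTRA$FIELDS",
               "3$30$TERM_0003"), p)
  expect_warning(tab <- read_ascii_table(p, "reac"), "1 malformed")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "parse_warnings"), 1L)
})

test_that("header-only files, bad kinds and missing files behave per contract", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$pt", p)
  tab <- read_ascii_table(p, "reac")
  expect_equal(nrow(tab), 0L)
  expect_error(read_ascii_table(p, "nonsense"), "unknown table_kind")
  expect_error(read_ascii_table(file.path(tempdir(), "nope.txt"), "demo"),
               "no such file")
  writeLines("foo$bar", p)
  expect_error(read_ascii_table(p, "reac"), "lacks required")
})

test_that("deduplication keeps the most recent FDA date, then highest id", {
  d <- data.frame(primaryid = c(90012L, 90013L), caseid = c(9L, 9L),
                  fda_dt = c(20240101L, 20240301L))
  expect_equal(deduplicate_reports(d)$demo$primaryid, 90013L)
  d2 <- data.frame(primaryid = c(90012L, 90055L), caseid = c(9L, 9L),
                   fda_dt = c(20240101L, 20240101L))
  expect_equal(deduplicate_reports(d2)$demo$primaryid, 90055L)
  # an undated record is never preferred over a dated one
  d3 <- data.frame(primaryid = c(99999L, 90001L), caseid = c(9L, 9L),
                   fda_dt = c(NA, 20200101L))
  expect_equal(deduplicate_reports(d3)$demo$primaryid, 90001L)
})

test_that("deduplication is idempotent, order-independent and size-consistent", {
  set.seed(4)
  d <- data.frame(primaryid = sample(1:500), caseid = sample(1:120, 500,
                                                             replace = TRUE),
                  fda_dt = 20200000L + sample(101:1231, 500, replace = TRUE))
  ref <- deduplicate_reports(d)
  expect_equal(nrow(d), nrow(ref$demo) + ref$n_removed)
  expect_equal(deduplicate_reports(ref$demo)$n_removed, 0L)
  expect_identical(deduplicate_reports(ref$demo)$demo, ref$demo)
  for (i in 1:5) {
    perm <- d[sample(nrow(d)), ]
    expect_identical(deduplicate_reports(perm)$demo, ref$demo)
  }
  # distinct caseids pass through untouched
  u <- data.frame(primaryid = 1:10, caseid = 1:10, fda_dt = 20240101L)
  expect_equal(deduplicate_reports(u)$n_removed, 0L)
})

test_that("primary-suspect filtering honours role codes and name variants", {
  drug <- data.frame(primaryid = c(1L, 2L, 3L, 4L),
                     drugname = c("Sintilimab", "SINTILIMAB ", "sintilimab",
                                  "otherdrug"),
                     role_cod = c("PS", "C", "I", "PS"))
  expect_equal(filter_primary_suspect(drug, c("sintilimab")), 1L)
  expect_equal(filter_primary_suspect(drug, "nomatch"), integer(0))
  expect_error(filter_primary_suspect(drug, character(0)), "subject_names")
})

test_that("assembly matches the generator's ground truth", {
  res <- sim_to_data(faers_sim_config(n_reports = 400, seed = 13,
                                      duplicate_fraction = 0.15))
  truth <- res$sim$truth$reports
  expect_setequal(res$fd$reports$primaryid, truth$primaryid_kept)
  m <- merge(res$fd$reports, truth, by = "caseid")
  expect_equal(m$is_subject, m$has_subject)
  # onset days equal the generator's Weibull draws wherever dates were kept
  known <- !m$event_date_missing
  expect_equal(m$tto_days.x[known], m$tto_days.y[known])
  expect_true(all(is.na(m$tto_days.x[!known])))
})

test_that("an event dated before therapy start loses its onset with a reason", {
  demo <- data.frame(primaryid = 1:2, caseid = 1:2,
                     fda_dt = 20240401L, event_dt = c(20240110L, 20240120L),
                     sex = "F", age = 50, age_cod = "YR", wt = NA_real_,
                     wt_cod = "", occp_cod = "MD", occr_country = "CN")
  drug <- data.frame(primaryid = 1:2, caseid = 1:2, drug_seq = 1L,
                     role_cod = "PS", drugname = "x", route = "Other")
  reac <- data.frame(primaryid = 1:2, caseid = 1:2, pt = "TERM_0001")
  ther <- data.frame(primaryid = 1:2, caseid = 1:2, dsg_drug_seq = 1L,
                     start_dt = c(20240201L, 20240101L))
  fd <- assemble_reports(demo, drug, reac, ther = ther, subject_ids = 1:2)
  expect_true(is.na(fd$reports$tto_days[1]))
  expect_equal(fd$reports$tto_days[2], 19L)
  expect_equal(fd$exclusions$reason[fd$exclusions$primaryid == 1],
               "inconsistent dates")
  # the report itself is retained
  expect_equal(nrow(fd$reports), 2L)
})

test_that("reports without any reaction term are excluded and orphans logged", {
  demo <- data.frame(primaryid = 1:3, caseid = 1:3, fda_dt = 20240101L,
                     event_dt = NA_integer_, sex = "M", age = 60,
                     age_cod = "YR", wt = NA_real_, wt_cod = "",
                     occp_cod = "MD", occr_country = "CN")
  drug <- data.frame(primaryid = c(1:3, 99L), caseid = c(1:3, 99L),
                     drug_seq = 1L, role_cod = "PS", drugname = "x",
                     route = "Other")
  reac <- data.frame(primaryid = c(1L, 2L, 98L), caseid = c(1L, 2L, 98L),
                     pt = "TERM_0001")
  fd <- assemble_reports(demo, drug, reac, subject_ids = 1:3)
  expect_equal(nrow(fd$reports), 2L)
  expect_equal(fd$exclusions$reason, "no reaction PT")
  expect_equal(fd$log$orphan_drug_rows, 1L)
  expect_equal(fd$log$orphan_reac_rows, 1L)
  expect_equal(fd$log$n_excluded, 1L)
})

test_that("age is harmonized to years through the unit codes", {
  demo <- data.frame(primaryid = 1:4, caseid = 1:4, fda_dt = 20240101L,
                     event_dt = NA_integer_, sex = "M",
                     age = c(60, 720, 5, 40), age_cod = c("YR", "MON",
                                                          "DEC", "???"),
                     wt = NA_real_, wt_cod = "", occp_cod = "MD",
                     occr_country = "CN")
  reac <- data.frame(primaryid = 1:4, caseid = 1:4, pt = "T1")
  drug <- data.frame(primaryid = 1:4, caseid = 1:4, drug_seq = 1L,
                     role_cod = "PS", drugname = "x", route = "Other")
  fd <- assemble_reports(demo, drug, reac)
  expect_equal(fd$reports$age_years, c(60, 60, 50, NA))
})
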