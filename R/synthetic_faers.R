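#' Configuration for the FAERS-like report simulator
#'
#' Describes a synthetic spontaneous-report database with known ground truth:
#' a designated subject drug, a background of co-reported drugs, per-term
#' baseline reporting rates, optional planted drug-event relative risks,
#' Weibull-distributed onset times, injected duplicate cases, and missing
#' event dates.  The generator emits the same "$"-delimited tables the ingest
#' stage reads, so the full pipeline can be exercised and validated against
#' the returned ground truth without any database download.
#'
#' Defaults mirror the reporting structure the package is designed around:
#' onset times with Weibull shape 0.785 and scale 30 days (median about 19
#' days), about a third of reports without a usable event date, and a
#' duplicate-case rate of 15 percent, comparable to the share of duplicate
#' records removed from real FAERS demographic tables.
#'
#' @param n_reports Number of base reports (before duplicate injection).
#' @param n_drugs Size of the drug vocabulary (`DRUG_0001` is the subject
#'   drug and is always reported with role code `PS`).
#' @param n_terms Size of the event vocabulary (`TERM_0001`...); a synthetic
#'   PT-to-SOC map is generated alongside.
#' @param baseline_rate Per-(report, term) probability of the event under no
#'   planted association.  Every report carries at least one event term
#'   (rows are redrawn conditional on one or more terms), as in real
#'   spontaneous reports.
#' @param planted_effects `NULL`, or a data frame with columns `drug`,
#'   `term`, `rr` giving multiplicative relative risks (>= 0) applied to the
#'   term's rate in reports that contain the drug.
#' @param duplicate_fraction Proportion of base reports that are emitted a
#'   second time with the same `CASEID` but a new `PRIMARYID` and a shifted
#'   or equal `FDA_DT` (all other fields identical), so deduplication can be
#'   checked against ground truth.
#' @param subject_prob Probability that a report contains the subject drug.
#' @param tto_shape,tto_scale Weibull shape and scale (days) of the true
#'   time from therapy start to event; onsets are rounded to whole days.
#' @param missing_date_fraction Proportion of reports whose event date is
#'   withheld from the demographic table.
#' @param seed Integer seed; generation uses R's default Mersenne-Twister
#'   RNG via [set.seed()], so a fixed seed gives identical tables across
#'   runs and platforms.
#' @return An object of class `faers_sim_config` (a validated list).
#' @seealso [generate_faers_tables()]
#' @export
faers_sim_config <- function(n_reports = 10000, n_drugs = 20, n_terms = 30,
                             baseline_rate = 0.02, planted_effects = NULL,
                             duplicate_fraction = 0.15, subject_prob = 0.1,
                             tto_shape = 0.785, tto_scale = 30,
                             missing_date_fraction = 0.33, seed = 1L) {
  n_reports <- assert_count(n_reports, "n_reports")
  n_drugs <- assert_count(n_drugs, "n_drugs", min = 2L)
  n_terms <- assert_count(n_terms, "n_terms")
  assert_pos(baseline_rate, "baseline_rate")
  assert_prob(baseline_rate, "baseline_rate")
  assert_prob(duplicate_fraction, "duplicate_fraction")
  assert_prob(subject_prob, "subject_prob")
  assert_pos(tto_shape, "tto_shape")
  assert_pos(tto_scale, "tto_scale")
  assert_prob(missing_date_fraction, "missing_date_fraction")
  seed <- assert_count(seed, "seed", min = 0L)

  drugs <- sprintf("DRUG_%04d", seq_len(n_drugs))
  terms <- sprintf("TERM_%04d", seq_len(n_terms))
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    need <- c("drug", "term", "rr")
    if (!all(need %in% names(planted_effects)))
      stop_config("planted_effects needs columns drug, term, rr")
    if (is.numeric(planted_effects$drug))
      planted_effects$drug <- drugs[planted_effects$drug]
    if (is.numeric(planted_effects$term))
      planted_effects$term <- terms[planted_effects$term]
    if (!all(planted_effects$drug %in% drugs) ||
        !all(planted_effects$term %in% terms))
      stop_config("planted_effects reference drugs/terms outside the vocabulary")
    if (any(planted_effects$rr < 0) || any(is.na(planted_effects$rr)))
      stop_config("planted relative risks must be >= 0")
  }

  structure(list(
    n_reports = n_reports, n_drugs = n_drugs, n_terms = n_terms,
    baseline_rate = baseline_rate, planted_effects = planted_effects,
    duplicate_fraction = duplicate_fraction, subject_prob = subject_prob,
    tto_shape = tto_shape, tto_scale = tto_scale,
    missing_date_fraction = missing_date_fraction, seed = seed,
    drugs = drugs, terms = terms, subject_drug = drugs[1L]
  ), class = "faers_sim_config")
}

#' Generate a synthetic FAERS-like table set with ground truth
#'
#' Simulates a spontaneous-report database under a
#' [faers_sim_config()]: demographic (DEMO), drug (DRUG), reaction (REAC),
#' therapy-date (THER), outcome (OUTC) and indication (INDI) tables in the
#' "$"-delimited FAERS dialect (dates as `YYYYMMDD` integers), plus a
#' ground-truth sidecar recording the planted effects, true onset days,
#' injected duplicates and which record deduplication should retain.
#'
#' Event terms are drawn independently per (report, term) at
#' `baseline_rate`, multiplied by the planted relative risk of every planted
#' drug present in the report; reports are conditioned on carrying at least
#' one term.  The subject drug always has role code `PS`; co-reported drugs
#' receive roles `SS`, `C` or `I`.  Duplicate cases copy every table row of
#' the original report under a new `PRIMARYID`, altering only `FDA_DT`
#' and `PRIMARYID`.
#'
#' @param config A [faers_sim_config()].
#' @return An object of class `faers_sim`: a list with elements
#'   `tables` (named list of data frames: `demo`, `drug`, `reac`, `ther`,
#'   `outc`, `indi`), `pt_soc` (synthetic PT-to-SOC map), `truth`
#'   (per-report ground truth, duplicate registry, planted effects) and
#'   `config`.
#' @seealso [write_faers_tables()], [read_ascii_table()]
#' @export
#' @examples
#' cfg <- faers_sim_config(n_reports = 200, seed = 7)
#' sim <- generate_faers_tables(cfg)
#' head(sim$tables$demo)
generate_faers_tables <- function(config) {
  if (!inherits(config, "faers_sim_config"))
    stop_config("config must be a faers_sim_config")
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drugs
  terms <- config$terms
  n_terms <- config$n_terms

  primaryid <- 100000000L + seq_len(n)
  caseid <- 20000000L + seq_len(n)

  ## drug sets: subject drug + 1-3 co-reported background drugs
  has_subject <- stats::runif(n) < config$subject_prob
  n_other <- sample(1:3, n, replace = TRUE)
  om <- matrix(sample(2:config$n_drugs, 3L * n, replace = TRUE), nrow = n)

  ## per-(report, term) event probabilities
  rate <- matrix(config$baseline_rate, nrow = n, ncol = n_terms)
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (k in seq_len(nrow(pe))) {
      di <- match(pe$drug[k], drugs)
      ti <- match(pe$term[k], terms)
      present <- if (di == 1L) has_subject else {
        (om[, 1] == di) | (n_other >= 2 & om[, 2] == di) |
          (n_other >= 3 & om[, 3] == di)
      }
      rate[present, ti] <- rate[present, ti] * pe$rr[k]
    }
    rate <- pmin(rate, 1)
  }

  ## draw terms, conditioning each report on >= 1 term
  y <- matrix(stats::runif(n * n_terms), nrow = n) < rate
  empty <- which(rowSums(y) == 0L)
  iter <- 0L
  while (length(empty)) {
    iter <- iter + 1L
    if (iter > 10000L)
      stop_config("event rates too low to place a term in every report")
    y[empty, ] <- matrix(stats::runif(length(empty) * n_terms),
                         nrow = length(empty)) < rate[empty, , drop = FALSE]
    empty <- empty[rowSums(y[empty, , drop = FALSE]) == 0L]
  }

  ## dates: therapy start, whole-day Weibull onset, receipt with lag
  start_date <- as.Date("2020-01-01") +
    sample.int(as.integer(as.Date("2025-03-31") - as.Date("2020-01-01")) + 1L,
               n, replace = TRUE) - 1L
  tto_true <- as.integer(round(stats::rweibull(n, config$tto_shape,
                                               config$tto_scale)))
  event_date <- start_date + tto_true
  fda_date <- event_date + sample(3:60, n, replace = TRUE)
  event_missing <- stats::runif(n) < config$missing_date_fraction

  ## demographics
  sex <- sample(c("F", "M", "UNK"), n, replace = TRUE,
                prob = c(0.27, 0.49, 0.24))
  age <- pmin(pmax(round(stats::rnorm(n, 59, 12)), 1), 95)
  age[stats::runif(n) < 0.24] <- NA
  age_cod <- ifelse(is.na(age), "", "YR")
  in_months <- !is.na(age) & stats::runif(n) < 0.02
  age[in_months] <- age[in_months] * 12L
  age_cod[in_months] <- "MON"
  wt <- round(stats::rnorm(n, 60, 10), 1)
  wt[stats::runif(n) < 0.6] <- NA
  occp <- sample(c("PH", "MD", "CN", ""), n, replace = TRUE,
                 prob = c(0.69, 0.22, 0.075, 0.015))
  country <- sample(c("CN", "DE", "IN", "NL", "US", "FR"), n, replace = TRUE,
                    prob = c(0.97, 0.008, 0.006, 0.006, 0.006, 0.004))

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_to_yyyymmdd(fda_date),
    event_dt = ifelse(event_missing, NA_integer_,
                      date_to_yyyymmdd(event_date)),
    sex = sex, age = age, age_cod = age_cod, wt = wt,
    wt_cod = ifelse(is.na(wt), "", "KG"), occp_cod = occp,
    occr_country = country, stringsAsFactors = FALSE
  )

  ## long DRUG table: subject rows (role PS) then co-reported rows
  sub_idx <- which(has_subject)
  oth_rep <- rep(seq_len(n), n_other)
  oth_col <- sequence(n_other)
  oth_drug <- om[cbind(oth_rep, oth_col)]
  keep <- !duplicated(cbind(oth_rep, oth_drug))          # unique drug per report
  oth_rep <- oth_rep[keep]; oth_drug <- oth_drug[keep]
  drug <- data.frame(
    primaryid = c(primaryid[sub_idx], primaryid[oth_rep]),
    caseid = c(caseid[sub_idx], caseid[oth_rep]),
    drug_seq = c(rep(1L, length(sub_idx)), 1L + ave(oth_rep, oth_rep,
                                                    FUN = seq_along)),
    role_cod = c(rep("PS", length(sub_idx)),
                 sample(c("SS", "C", "I"), length(oth_rep), replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))),
    drugname = c(rep(drugs[1L], length(sub_idx)), drugs[oth_drug]),
    route = c(sample(c("Intravenous drip", "Intravenous", "Other"),
                     length(sub_idx), replace = TRUE,
                     prob = c(0.4, 0.3, 0.3)),
              rep("Other", length(oth_rep))),
    stringsAsFactors = FALSE
  )
  drug <- drug[order(drug$primaryid, drug$drug_seq), , drop = FALSE]
  rownames(drug) <- NULL

  ## REAC: one row per (report, drawn term)
  hit <- which(y, arr.ind = TRUE)
  reac <- data.frame(primaryid = primaryid[hit[, 1]],
                     caseid = caseid[hit[, 1]],
                     pt = terms[hit[, 2]], stringsAsFactors = FALSE)
  reac <- reac[order(reac$primaryid, reac$pt), , drop = FALSE]
  rownames(reac) <- NULL

  ## THER: therapy start for drug_seq 1 of every report
  ther <- data.frame(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = 1L,
                     start_dt = date_to_yyyymmdd(start_date),
                     stringsAsFactors = FALSE)

  ## OUTC: one or two outcome codes per report
  oc <- c("OT", "HO", "DE", "LT", "DS", "CA")
  out1 <- sample(oc, n, replace = TRUE,
                 prob = c(0.54, 0.27, 0.08, 0.08, 0.025, 0.005))
  two <- which(stats::runif(n) < 0.3)
  out2 <- sample(oc, length(two), replace = TRUE)
  keep2 <- out2 != out1[two]
  outc <- data.frame(
    primaryid = c(primaryid, primaryid[two[keep2]]),
    caseid = c(caseid, caseid[two[keep2]]),
    outc_cod = c(out1, out2[keep2]), stringsAsFactors = FALSE
  )
  outc <- outc[order(outc$primaryid, outc$outc_cod), , drop = FALSE]
  rownames(outc) <- NULL

  ## INDI: one indication per report
  ind_vocab <- c("Lung cancer", "Hepatic cancer", "Gastric cancer",
                 "Colorectal cancer", "Esophageal cancer", "Other")
  indi <- data.frame(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = 1L,
    indi_pt = sample(ind_vocab, n, replace = TRUE,
                     prob = c(0.20, 0.17, 0.15, 0.07, 0.03, 0.38)),
    stringsAsFactors = FALSE
  )

  ## synthetic PT -> SOC map
  n_soc <- max(3L, ceiling(n_terms / 10))
  pt_soc <- data.frame(pt = terms,
                       soc = sprintf("SOC_%02d", rep_len(seq_len(n_soc),
                                                         n_terms)),
                       stringsAsFactors = FALSE)

  ## duplicate injection: copy all rows of a case under a new PRIMARYID,
  ## mutating only PRIMARYID and FDA_DT
  n_dup <- floor(config$duplicate_fraction * n)
  dup_reg <- data.frame(caseid = integer(0), primaryid_original = integer(0),
                        primaryid_dup = integer(0), primaryid_kept = integer(0))
  if (n_dup > 0) {
    dup_idx <- sort(sample.int(n, n_dup))
    dup_pid <- 900000000L + seq_len(n_dup)
    u <- stats::runif(n_dup)
    shift <- integer(n_dup)
    shift[u < 0.5] <- sample(1:90, sum(u < 0.5), replace = TRUE)    # dup later
    shift[u >= 0.75] <- -sample(1:90, sum(u >= 0.75), replace = TRUE) # dup earlier
    dup_fda <- fda_date[dup_idx] + shift
    # retained under "max FDA_DT then max PRIMARYID": dup wins unless earlier
    kept <- ifelse(shift < 0, primaryid[dup_idx], dup_pid)
    dup_reg <- data.frame(caseid = caseid[dup_idx],
                          primaryid_original = primaryid[dup_idx],
                          primaryid_dup = dup_pid, primaryid_kept = kept)
    copy_rows <- function(tab) {
      m <- match(tab$primaryid, primaryid[dup_idx])
      cp <- tab[!is.na(m), , drop = FALSE]
      cp$primaryid <- dup_pid[m[!is.na(m)]]
      rbind(tab, cp)
    }
    d2 <- demo[dup_idx, , drop = FALSE]
    d2$primaryid <- dup_pid
    d2$fda_dt <- date_to_yyyymmdd(dup_fda)
    demo <- rbind(demo, d2)
    drug <- copy_rows(drug); reac <- copy_rows(reac); ther <- copy_rows(ther)
    outc <- copy_rows(outc); indi <- copy_rows(indi)
  }
  rownames(demo) <- NULL

  truth_reports <- data.frame(
    caseid = caseid, primaryid = primaryid,
    has_subject = has_subject, tto_days = tto_true,
    event_date_missing = event_missing, stringsAsFactors = FALSE
  )
  truth_reports$primaryid_kept <- truth_reports$primaryid
  if (nrow(dup_reg)) {
    m <- match(dup_reg$caseid, truth_reports$caseid)
    truth_reports$primaryid_kept[m] <- dup_reg$primaryid_kept
  }

  structure(list(
    tables = list(demo = demo, drug = drug, reac = reac, ther = ther,
                  outc = outc, indi = indi),
    pt_soc = pt_soc,
    truth = list(reports = truth_reports, duplicates = dup_reg,
                 planted_effects = config$planted_effects,
                 subject_drug = config$subject_drug),
    config = config
  ), class = "faers_sim")
}

#' Write simulated FAERS tables to disk
#'
#' Writes each table of a [generate_faers_tables()] result as a
#' "$"-delimited ASCII file (`DEMO.txt`, `DRUG.txt`, ...), the synthetic
#' PT-to-SOC map as `pt_soc.csv`, and the ground truth as
#' `ground_truth.json`.
#'
#' @param sim A `faers_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_faers_tables <- function(sim, dir) {
  if (!inherits(sim, "faers_sim")) stop_config("sim must be a faers_sim")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(sim$tables)) {
    p <- file.path(dir, paste0(toupper(nm), ".txt"))
    utils::write.table(sim$tables[[nm]], p, sep = "$", quote = FALSE,
                       row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "pt_soc.csv")
  utils::write.csv(sim$pt_soc, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, p, dataframe = "columns", na = "null")
  invisible(c(paths, p))
}
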