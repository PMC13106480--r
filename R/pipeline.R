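# End-to-end orchestration of the analysis stages behind one declarative
# configuration, with seeded reproducibility and a machine-readable run
# manifest.

#' Pipeline run configuration
#'
#' Declares one full analysis run: where the report tables come from
#' (a directory of "$"-delimited quarterly tables, or a
#' [faers_sim_config()] for a synthetic run), the subject drug's name
#' variants, the case-defining PT for the risk-factor stage, the signal
#' thresholds, and the output directory.  All randomness downstream flows
#' from the single `seed`.
#'
#' @param subject_names Character vector of subject-drug name variants.
#' @param input_dir Directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`
#'   (optionally `THER.txt`, `OUTC.txt`, `INDI.txt`, `pt_soc.csv`), or
#'   `NULL` when `sim_config` is given.
#' @param sim_config Optional [faers_sim_config()]; the tables are then
#'   generated in memory instead of read from `input_dir`.
#' @param case_pt Case-defining PT for the risk-factor stage, or `NULL`
#'   to skip that stage.
#' @param cohort Optional clinical-cohort data frame (or
#'   [cohort_sim_config()]) for the cohort stage.
#' @param soc_map Optional PT-to-SOC map (data frame `pt`, `soc`).
#' @param min_n Case-count floor of the ROR/PRR signal criteria
#'   (default 3).
#' @param screen_alpha Univariate screening threshold (default 0.10).
#' @param folds LASSO cross-validation folds (default 10).
#' @param seed Root seed for the run.
#' @param out_dir Output directory for the artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(subject_names, input_dir = NULL, sim_config = NULL,
                       case_pt = NULL, cohort = NULL, soc_map = NULL,
                       min_n = 3, screen_alpha = 0.10, folds = 10,
                       seed = 1L, out_dir = tempfile("pvmine_run_")) {
  if (is.null(input_dir) && is.null(sim_config))
    stop_config("provide either input_dir or sim_config")
  if (length(subject_names) == 0L)
    stop_config("subject_names must be non-empty")
  assert_count(min_n, "min_n", min = 0L)
  assert_prob(screen_alpha, "screen_alpha")
  assert_count(folds, "folds", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(subject_names = subject_names, input_dir = input_dir,
                 sim_config = sim_config, case_pt = case_pt,
                 cohort = cohort, soc_map = soc_map, min_n = min_n,
                 screen_alpha = screen_alpha, folds = folds, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.load_tables <- function(config) {
  if (!is.null(config$sim_config)) {
    sim <- generate_faers_tables(config$sim_config)
    list(tables = sim$tables, soc_map = config$soc_map %||% sim$pt_soc,
         truth = sim$truth)
  } else {
    dir <- config$input_dir
    rd <- function(kind) {
      p <- file.path(dir, paste0(toupper(kind), ".txt"))
      if (file.exists(p)) read_ascii_table(p, kind) else NULL
    }
    tables <- list(demo = rd("demo"), drug = rd("drug"), reac = rd("reac"),
                   ther = rd("ther"), outc = rd("outc"), indi = rd("indi"))
    if (is.null(tables$demo) || is.null(tables$drug) || is.null(tables$reac))
      stop_config("input_dir must contain DEMO.txt, DRUG.txt and REAC.txt")
    sm <- config$soc_map
    p <- file.path(dir, "pt_soc.csv")
    if (is.null(sm) && file.exists(p))
      sm <- utils::read.csv(p, stringsAsFactors = FALSE)
    list(tables = tables, soc_map = sm, truth = NULL)
  }
}

#' Run the full pipeline and write its artifact directory
#'
#' Executes, in order: table loading (or seeded simulation), case
#' deduplication, primary-suspect selection, report assembly,
#' characteristics summary, PT-level (and, with a map, SOC-level) signal
#' tables, time-to-onset description and Weibull fit, the case/non-case
#' risk-factor stage (screen, LASSO, logistic) when `case_pt` is set, and
#' the clinical-cohort stage when cohort input is given.  Every artifact
#' is a CSV or JSON file under `out_dir`; a `manifest.json` records the
#' package version, seed, configuration hash and the files written, and
#' (on failure) the stage that failed.  Given the same inputs and seed the
#' artifact set is byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the assembled dataset (`data`), the
#'   stage results, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null", pretty = TRUE)
    files <<- c(files, name)
  }
  stage <- "load"
  manifest <- list(package = "pvmine",
                   version = as.character(utils::packageVersion("pvmine")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed, status = "failed", failed_stage = NA)
  write_manifest <- function() {
    cfg_json <- jsonlite::toJSON(list(
      subject_names = config$subject_names, case_pt = config$case_pt,
      min_n = config$min_n, screen_alpha = config$screen_alpha,
      folds = config$folds, seed = config$seed,
      synthetic = !is.null(config$sim_config)), auto_unbox = TRUE)
    tmp <- file.path(config$out_dir, "config.json")
    writeLines(cfg_json, tmp)
    manifest$config_hash <<- unname(tools::md5sum(tmp))
    manifest$files <<- c("config.json", files)
    p <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  }
  on.exit({
    if (manifest$status == "failed") {
      manifest$failed_stage <- stage
      try(write_manifest(), silent = TRUE)
    }
  })

  loaded <- .load_tables(config)
  tb <- loaded$tables

  stage <- "dedup"
  dd <- deduplicate_reports(tb$demo)

  stage <- "primary_suspect"
  subj_ids <- filter_primary_suspect(tb$drug, config$subject_names)

  stage <- "assemble"
  fd <- assemble_reports(dd$demo, tb$drug, tb$reac, ther = tb$ther,
                         outc = tb$outc, indi = tb$indi,
                         subject_ids = subj_ids)
  emit_csv(fd$reports, "reports.csv")
  emit_csv(fd$exclusions, "exclusion_log.csv")

  stage <- "characteristics"
  subj <- subject_reports(fd)
  chars <- summarize_characteristics(subj)
  emit_csv(chars$table, "characteristics.csv")

  stage <- "signals"
  sig_pt <- signal_table(fd, level = "pt", min_n = config$min_n)
  emit_csv(sig_pt, "signals_pt.csv")
  sig_soc <- NULL
  if (!is.null(loaded$soc_map)) {
    sig_soc <- signal_table(fd, level = "soc", soc_map = loaded$soc_map,
                            min_n = config$min_n)
    emit_csv(sig_soc, "signals_soc.csv")
  }

  stage <- "tto"
  tto <- collect_tto(subj)
  tto_desc <- describe_tto(tto)
  emit_csv(tto_desc$bins, "tto_bins.csv")
  tto_fit <- NULL
  if (length(tto$values) >= 10) {
    tto_fit <- weibull_mle(tto)
    emit_json(list(shape = tto_fit$shape, scale = tto_fit$scale,
                   shape_ci = tto_fit$shape_ci, n = tto_fit$n,
                   n_unknown = tto$n_unknown,
                   hazard_class = tto_fit$hazard_class),
              "tto_weibull.json")
  }

  stage <- "riskfactors"
  risk <- NULL
  if (!is.null(config$case_pt)) {
    labels <- define_cases(subj, config$case_pt)
    feats <- report_features(subj)
    if (sum(labels$case) >= config$folds &&
        sum(!labels$case) >= config$folds) {
      screen <- univariate_screen(feats$features, labels$case,
                                  alpha = config$screen_alpha)
      emit_csv(screen, "riskfactor_screen.csv")
      cand <- screen$variable[screen$pass]
      risk <- list(screen = screen)
      if (length(cand) >= 2) {
        las <- lasso_select(feats$features[, cand, drop = FALSE],
                            labels$case, folds = config$folds,
                            seed = config$seed)
        emit_csv(data.frame(lambda = las$lambda_grid,
                            cv_deviance = las$cv_deviance,
                            cv_se = las$cv_se), "lasso_path.csv")
        risk$lasso <- las
        sel <- intersect(las$selected, names(feats$features))
        if (length(sel)) {
          eff <- fit_logistic(feats$features, labels$case, sel)
          emit_csv(eff, "riskfactor_effects.csv")
          risk$effects <- eff
        }
      }
    } else {
      message("risk-factor stage skipped: too few cases for ",
              config$folds, "-fold cross-validation")
    }
  } else {
    message("risk-factor stage skipped: no case PT configured")
  }

  stage <- "cohort"
  cohort_res <- NULL
  coh <- config$cohort
  if (!is.null(coh)) {
    if (inherits(coh, "cohort_sim_config")) coh <- generate_cohort(coh)
    baseline <- compare_baseline(coh)
    emit_csv(baseline, "cohort_baseline.csv")
    inc <- incidence_and_grades(coh)
    emit_json(inc, "cohort_incidence.json")
    cohort_res <- list(baseline = baseline, incidence = inc)
  }

  stage <- "manifest"
  manifest$status <- "ok"
  write_manifest()

  invisible(list(data = fd, characteristics = chars,
                 signals = list(pt = sig_pt, soc = sig_soc),
                 tto = list(sample = tto, description = tto_desc,
                            fit = tto_fit),
                 riskfactors = risk, cohort = cohort_res,
                 truth = loaded$truth, out_dir = config$out_dir))
}
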