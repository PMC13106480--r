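# Reading, deduplicating and assembling "$"-delimited FAERS-style tables.

# expected columns per table kind; primaryid/caseid/date columns are
# converted to integer after parsing
.faers_schema <- list(
  demo = list(cols = c("primaryid", "caseid", "fda_dt", "event_dt", "sex",
                       "age", "age_cod", "wt", "wt_cod", "occp_cod",
                       "occr_country"),
              int = c("primaryid", "caseid", "fda_dt", "event_dt"),
              num = c("age", "wt")),
  drug = list(cols = c("primaryid", "caseid", "drug_seq", "role_cod",
                       "drugname", "route"),
              int = c("primaryid", "caseid", "drug_seq"), num = character(0)),
  reac = list(cols = c("primaryid", "caseid", "pt"),
              int = c("primaryid", "caseid"), num = character(0)),
  ther = list(cols = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
              int = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
              num = character(0)),
  outc = list(cols = c("primaryid", "caseid", "outc_cod"),
              int = c("primaryid", "caseid"), num = character(0)),
  indi = list(cols = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
              int = c("primaryid", "caseid", "indi_drug_seq"),
              num = character(0))
)

#' Read one FAERS-style "$"-delimited ASCII table
#'
#' Parses a quarterly-extract style text file with a header row and
#' "$"-separated fields.  Rows whose field count disagrees with the header
#' are counted and skipped with a warning, never silently dropped; the
#' count is returned in the `parse_warnings` attribute.
#'
#' @param path Path to the file.
#' @param table_kind One of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"outc"`, `"indi"` (case-insensitive).
#' @return A data frame with the table's columns (ids and dates as
#'   integers), with attributes `parse_warnings` (number of malformed data
#'   rows skipped) and `table_kind`.
#' @seealso [write_faers_tables()] for the writing side of the dialect.
#' @export
read_ascii_table <- function(path, table_kind) {
  table_kind <- tolower(table_kind)
  if (!table_kind %in% names(.faers_schema))
    stop_config("unknown table_kind '%s' (use one of %s)", table_kind,
                paste(names(.faers_schema), collapse = ", "))
  if (!file.exists(path)) stop_config("cannot read '%s': no such file", path)
  schema <- .faers_schema[[table_kind]]

  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_config("'%s' is empty (no header row)", path)
  header <- strsplit(lines[1L], "$", fixed = TRUE)[[1L]]
  header <- tolower(trimws(header))
  missing_cols <- setdiff(schema$cols, header)
  if (length(missing_cols))
    stop_config("'%s' lacks required %s column(s): %s", path, table_kind,
                paste(missing_cols, collapse = ", "))

  body <- lines[-1L]
  body <- body[nzchar(body)]
  n_bad <- 0L
  if (length(body)) {
    parts <- strsplit(body, "$", fixed = TRUE)
    # trailing empty field is dropped by strsplit; pad rows one short
    nf <- lengths(parts)
    pad <- nf == length(header) - 1L
    parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
    nf[pad] <- length(header)
    ok <- nf == length(header)
    n_bad <- sum(!ok)
    if (n_bad > 0)
      warning(sprintf("%s: skipped %d malformed row(s) in '%s'",
                      table_kind, n_bad, path), call. = FALSE)
    parts <- parts[ok]
  } else {
    parts <- list()
  }

  if (length(parts)) {
    m <- matrix(unlist(parts, use.names = FALSE), ncol = length(header),
                byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- header
  } else {
    df <- as.data.frame(matrix(character(0), nrow = 0,
                               ncol = length(header)),
                        stringsAsFactors = FALSE)
    names(df) <- header
  }
  df <- df[, schema$cols, drop = FALSE]
  for (cn in schema$int) df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
  for (cn in schema$num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  structure(df, parse_warnings = n_bad, table_kind = table_kind)
}

#' Deduplicate demographic rows by case identifier
#'
#' FAERS cases accrue follow-up versions; for each `caseid` the record with
#' the most recent `fda_dt` is retained, ties broken by the highest
#' `primaryid`.  A missing `fda_dt` sorts as the earliest possible date, so
#' an undated record is never preferred over a dated one.  The operation is
#' idempotent and independent of input row order.
#'
#' @param demo A demographic data frame with `caseid`, `fda_dt`,
#'   `primaryid` columns (e.g. from [read_ascii_table()]).
#' @return A list with `demo` (the retained rows, in `caseid` order) and
#'   `n_removed` (`nrow(input) - nrow(output)`).
#' @export
#' @examples
#' d <- data.frame(primaryid = c(90012, 90055), caseid = c(9, 9),
#'                 fda_dt = c(20240101L, 20240101L))
#' deduplicate_reports(d)$demo$primaryid  # 90055: equal dates, higher id
deduplicate_reports <- function(demo) {
  need <- c("caseid", "fda_dt", "primaryid")
  if (!all(need %in% names(demo)))
    stop_config("demo must have columns %s", paste(need, collapse = ", "))
  n_in <- nrow(demo)
  if (n_in == 0L) return(list(demo = demo, n_removed = 0L))
  fda <- demo$fda_dt
  fda[is.na(fda)] <- -1L                      # undated sorts lowest
  ord <- order(demo$caseid, fda, demo$primaryid)
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(demo = out, n_removed = n_in - nrow(out))
}

#' Select reports where the subject drug is the primary suspect
#'
#' Returns the report ids in which any of the subject drug's name variants
#' appears with role code `PS`.  Matching is case-insensitive exact match
#' after trimming; reports where the subject drug appears only as
#' concomitant (`C`) or interacting (`I`) — or as secondary suspect — are
#' not selected.
#'
#' @param drug A drug table with `primaryid`, `drugname`, `role_cod`.
#' @param subject_names Character vector of name variants (non-empty).
#' @return Sorted vector of unique `primaryid`s.
#' @export
filter_primary_suspect <- function(drug, subject_names) {
  if (length(subject_names) == 0L || all(!nzchar(subject_names)))
    stop_config("subject_names must contain at least one drug name variant")
  need <- c("primaryid", "drugname", "role_cod")
  if (!all(need %in% names(drug)))
    stop_config("drug must have columns %s", paste(need, collapse = ", "))
  nm <- tolower(trimws(drug$drugname))
  hit <- nm %in% tolower(trimws(subject_names)) &
    toupper(trimws(drug$role_cod)) == "PS"
  sort(unique(drug$primaryid[hit]))
}

# FAERS age-unit codes -> years
.age_to_years <- function(age, age_cod) {
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143, DY = 1 / 365.25,
         HR = 1 / 8766)
  mult <- f[toupper(trimws(age_cod))]
  mult[is.na(mult) & !is.na(age)] <- NA    # unparseable unit -> unknown
  unname(age * mult)
}

#' Assemble linked report records
#'
#' Joins deduplicated demographics with the drug, reaction and (optionally)
#' therapy, outcome and indication tables into one cleaned dataset keyed by
#' `primaryid`.  Reports with no reaction term (and, if
#' `require_outcome = TRUE`, no outcome code) are excluded with a logged
#' reason.  Time-to-onset in days is computed as event date minus the
#' earliest therapy start date; an event dated before therapy start is
#' logically inconsistent, so its interval is withheld and logged.  Drug or
#' reaction rows whose `primaryid` has no demographic row are counted as
#' orphans and skipped.
#'
#' @param demo Deduplicated demographic rows (see [deduplicate_reports()]).
#' @param drug,reac Drug and reaction tables.
#' @param ther,outc,indi Optional therapy-date, outcome and indication
#'   tables.
#' @param subject_ids Report ids flagged as subject-drug primary-suspect
#'   reports (from [filter_primary_suspect()]); used to set the
#'   `is_subject` column that downstream signal statistics condition on.
#' @param require_outcome Exclude reports with no outcome code (default
#'   `FALSE`).
#' @return An object of class `faers_data`: a list of data frames
#'   `reports` (one row per retained report with demographics, `age_years`,
#'   report `year`, `tto_days`, `is_subject`), `reactions`, `drugs`,
#'   `outcomes`, `indications` (long tables restricted to retained
#'   reports), `exclusions` (primaryid, reason) and `log` (orphan and
#'   exclusion counts).
#' @export
assemble_reports <- function(demo, drug, reac, ther = NULL, outc = NULL,
                             indi = NULL, subject_ids = integer(0),
                             require_outcome = FALSE) {
  ids <- demo$primaryid
  if (anyDuplicated(ids))
    stop_config("demo has duplicated primaryid; deduplicate first")

  orphan_drug <- sum(!drug$primaryid %in% ids)
  orphan_reac <- sum(!reac$primaryid %in% ids)
  drug <- drug[drug$primaryid %in% ids, , drop = FALSE]
  reac <- reac[reac$primaryid %in% ids, , drop = FALSE]

  exclusions <- data.frame(primaryid = integer(0), reason = character(0))
  no_pt <- setdiff(ids, unique(reac$primaryid))
  if (length(no_pt))
    exclusions <- rbind(exclusions,
                        data.frame(primaryid = no_pt,
                                   reason = "no reaction PT"))
  if (require_outcome) {
    has_outc <- if (is.null(outc)) integer(0) else unique(outc$primaryid)
    no_outc <- setdiff(setdiff(ids, no_pt), has_outc)
    if (length(no_outc))
      exclusions <- rbind(exclusions,
                          data.frame(primaryid = no_outc,
                                     reason = "no valid outcome"))
  }
  keep_ids <- setdiff(ids, exclusions$primaryid)
  reports <- demo[match(keep_ids, demo$primaryid), , drop = FALSE]
  rownames(reports) <- NULL

  reports$age_years <- .age_to_years(reports$age, reports$age_cod)
  reports$year <- reports$fda_dt %/% 10000L

  ## time to onset: event date minus earliest therapy start
  tto <- rep(NA_integer_, nrow(reports))
  if (!is.null(ther) && nrow(ther)) {
    ther_ok <- ther[!is.na(ther$start_dt) & ther$primaryid %in% keep_ids, ,
                    drop = FALSE]
    if (nrow(ther_ok)) {
      start_min <- tapply(ther_ok$start_dt, ther_ok$primaryid, min)
      sd_int <- as.integer(start_min)[match(reports$primaryid,
                                            as.integer(names(start_min)))]
      ev <- yyyymmdd_to_date(reports$event_dt)
      st <- yyyymmdd_to_date(sd_int)
      diff_days <- as.integer(ev - st)
      inconsistent <- !is.na(diff_days) & diff_days < 0
      if (any(inconsistent))
        exclusions <- rbind(exclusions,
                            data.frame(primaryid =
                                         reports$primaryid[inconsistent],
                                       reason = "inconsistent dates"))
      tto <- ifelse(is.na(diff_days) | inconsistent, NA_integer_, diff_days)
    }
  }
  reports$tto_days <- as.integer(tto)
  reports$is_subject <- reports$primaryid %in% subject_ids

  restrict <- function(tab) {
    if (is.null(tab)) return(NULL)
    out <- tab[tab$primaryid %in% keep_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }

  structure(list(
    reports = reports,
    reactions = restrict(reac),
    drugs = restrict(drug),
    outcomes = restrict(outc),
    indications = restrict(indi),
    exclusions = exclusions,
    log = list(orphan_drug_rows = orphan_drug,
               orphan_reac_rows = orphan_reac,
               n_excluded = length(setdiff(ids, keep_ids)))
  ), class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat(sprintf("<faers_data> %d reports (%d subject-drug), %d reaction rows\n",
              nrow(x$reports), sum(x$reports$is_subject),
              nrow(x$reactions)))
  cat(sprintf("  excluded: %d; orphan drug/reac rows: %d/%d\n",
              x$log$n_excluded, x$log$orphan_drug_rows,
              x$log$orphan_reac_rows))
  invisible(x)
}

#' Restrict a dataset to the subject-drug reports
#'
#' Convenience filter returning a `faers_data` containing only reports
#' flagged `is_subject` (the characteristics and time-to-onset stages
#' operate on this subset, while signal statistics need the full dataset as
#' background).
#'
#' @param fd A `faers_data` object.
#' @return A `faers_data` restricted to subject reports.
#' @export
subject_reports <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  keep <- fd$reports$primaryid[fd$reports$is_subject]
  res <- fd
  res$reports <- fd$reports[fd$reports$is_subject, , drop = FALSE]
  rownames(res$reports) <- NULL
  for (nm in c("reactions", "drugs", "outcomes", "indications")) {
    if (!is.null(fd[[nm]]))
      res[[nm]] <- fd[[nm]][fd[[nm]]$primaryid %in% keep, , drop = FALSE]
  }
  res
}
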