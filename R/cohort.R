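# Clinical-cohort stage: baseline comparison, incidence and CTCAE grade
# distribution, descriptive management summary.

#' Baseline comparison between outcome groups
#'
#' Compares each baseline variable between the two outcome groups:
#' categorical variables by the chi-square test (Yates-corrected on 2x2,
#' Pearson on r x c) switching to Fisher's exact test when any expected
#' cell is below 5, and continuous variables by the Wilcoxon rank-sum
#' test.  "Unknown" stage categories are treated as a level of their own,
#' not as missing data.  P-values are rounded half-up to 3 decimals.
#'
#' @param patients Data frame of patients.
#' @param group Name of the binary grouping column (default
#'   `"myelosuppression"`).
#' @param vars Character vector of variables to compare (default: all
#'   columns except the grouping column, `patient_id` and `grade`).
#' @return An object of class `baseline_table`: data frame with one row
#'   per variable level (`variable`, `level`, per-group `count` and `pct`
#'   columns, `test`, `p`) — continuous variables get a single
#'   `median (Q1, Q3)` row per group — plus attribute `group_sizes`.
#'   Variables with a single observed level are reported untestable
#'   (`test = "none"`, `p = NA`).
#' @export
compare_baseline <- function(patients, group = "myelosuppression",
                             vars = NULL) {
  stopifnot(is.data.frame(patients), group %in% names(patients))
  g <- as.integer(as.logical(patients[[group]]))
  if (length(unique(stats::na.omit(g))) < 2L || min(table(g)) < 2L)
    stop_config("need at least 2 patients in each outcome group")
  if (is.null(vars))
    vars <- setdiff(names(patients), c(group, "patient_id", "grade"))
  glab <- c("group0", "group1")

  rows <- lapply(vars, function(nm) {
    x <- patients[[nm]]
    r <- .assoc_test(x, g)
    p <- round_half_up(r$p, 3)
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 6L) {
      fmt <- vapply(c(0L, 1L), function(k) {
        q <- stats::quantile(x[g == k], c(0.5, 0.25, 0.75), na.rm = TRUE)
        sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
      }, character(1))
      return(data.frame(variable = nm, level = "median (Q1, Q3)",
                        group0 = fmt[1], group1 = fmt[2],
                        pct0 = NA_real_, pct1 = NA_real_,
                        test = r$test, p = p, stringsAsFactors = FALSE))
    }
    tab <- table(factor(x), factor(g, levels = c(0L, 1L)))
    data.frame(variable = nm, level = rownames(tab),
               group0 = as.character(tab[, 1]),
               group1 = as.character(tab[, 2]),
               pct0 = block_pct(as.integer(tab[, 1])),
               pct1 = block_pct(as.integer(tab[, 2])),
               test = r$test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "group0"] <- paste0("n_", glab[1])
  names(out)[names(out) == "group1"] <- paste0("n_", glab[2])
  attr(out, "group_sizes") <- table(g)
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Incidence and severity-grade distribution
#'
#' Overall incidence of the outcome and the CTCAE grade distribution,
#' both as percentages of the full cohort (2-decimal half-up rounding).
#' Grade counts always sum to the event count.
#'
#' @param patients Data frame with a binary `myelosuppression` column and
#'   a `grade` factor (`"I"`-`"IV"`, `NA` without the outcome).
#' @param outcome Name of the outcome column.
#' @return List with `n`, `n_events`, `incidence_pct`, and `grades`
#'   (data frame `grade`, `count`, `pct_of_cohort`).  An empty cohort
#'   yields `NA` incidence.
#' @export
incidence_and_grades <- function(patients, outcome = "myelosuppression") {
  stopifnot(is.data.frame(patients), outcome %in% names(patients))
  n <- nrow(patients)
  y <- as.logical(patients[[outcome]])
  n_ev <- sum(y, na.rm = TRUE)
  if (n == 0L)
    return(list(n = 0L, n_events = 0L, incidence_pct = NA_real_,
                grades = data.frame(grade = character(0),
                                    count = integer(0),
                                    pct_of_cohort = numeric(0))))
  if ("grade" %in% names(patients)) {
    gr <- factor(patients$grade, levels = c("I", "II", "III", "IV"))
    if (any(!is.na(gr) & !y))
      stop_config("grade present for patients without the outcome")
    tab <- table(gr[y])
  } else {
    tab <- table(factor(character(0), levels = c("I", "II", "III", "IV")))
  }
  if (n_ev > 0L && sum(tab) != n_ev)
    warning("grades missing for some patients with the outcome",
            call. = FALSE)
  grades <- data.frame(grade = names(tab), count = as.integer(tab),
                       pct_of_cohort = round_half_up(100 * as.integer(tab) / n,
                                                     2),
                       stringsAsFactors = FALSE)
  if (n_ev == 0L) grades <- grades[0, , drop = FALSE]
  list(n = n, n_events = n_ev,
       incidence_pct = round_half_up(100 * n_ev / n, 2), grades = grades)
}

#' Descriptive summary of myelosuppression management
#'
#' Counts and percentages of management/complication indicator fields
#' among the patients who developed the outcome (event-subgroup
#' denominator, matching clinical-management reporting conventions).
#'
#' @param patients Data frame with the outcome column and logical/0-1
#'   management columns.
#' @param fields Character vector of management columns to summarize;
#'   default: every logical or 0/1 column except the outcome itself.
#' @param outcome Name of the outcome column.
#' @return Data frame `field`, `count`, `pct_of_events`.  With no
#'   management data an empty summary is returned with a warning.
#' @export
management_summary <- function(patients, fields = NULL,
                               outcome = "myelosuppression") {
  stopifnot(is.data.frame(patients), outcome %in% names(patients))
  y <- as.logical(patients[[outcome]])
  ev <- patients[which(y), , drop = FALSE]
  if (is.null(fields)) {
    is01 <- vapply(patients, function(col) {
      is.logical(col) ||
        (is.numeric(col) && all(stats::na.omit(col) %in% 0:1))
    }, logical(1))
    fields <- setdiff(names(patients)[is01],
                      c(outcome, "patient_id", "sex_female"))
  }
  fields <- intersect(fields, names(patients))
  if (!length(fields) || nrow(ev) == 0L) {
    warning("no management data to summarize", call. = FALSE)
    return(data.frame(field = character(0), count = integer(0),
                      pct_of_events = numeric(0)))
  }
  cnt <- vapply(fields, function(f) sum(ev[[f]], na.rm = TRUE), numeric(1))
  data.frame(field = fields, count = as.integer(cnt),
             pct_of_events = round_half_up(100 * cnt / nrow(ev), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
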