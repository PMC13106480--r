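# Descriptive characteristics of an assembled report set.

.bin_age <- function(a) {
  cut(a, breaks = c(-Inf, 19, 44, 60, Inf), right = FALSE,
      labels = c("<19", "19-44", "44-59", ">=60"))
}

.bin_tto <- function(t) {
  cut(t, breaks = c(-Inf, 2, 5, 7, 14, 28, Inf), right = FALSE,
      labels = c("<2", "2-5", "5-7", "7-14", "14-28", ">=28"))
}

.outcome_labels <- c(HO = "Hospitalization", DE = "Death",
                     LT = "Life threatening", DS = "Disability",
                     CA = "Congenital anomaly", OT = "Other serious")

.reporter_labels <- c(PH = "Pharmacist", MD = "Physician", CN = "Consumer",
                      OT = "Other")

.count_block <- function(block, x, order_levels = NULL) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "Unknown"
  tab <- table(x)
  if (length(tab) == 0L)
    return(data.frame(block = character(0), level = character(0),
                      count = integer(0), pct = numeric(0)))
  if (!is.null(order_levels)) {
    lv <- c(intersect(order_levels, names(tab)),
            setdiff(names(tab), order_levels))
    tab <- tab[lv]
  }
  data.frame(block = block, level = names(tab),
             count = as.integer(tab), pct = block_pct(as.integer(tab)),
             stringsAsFactors = FALSE)
}

#' Summarize report characteristics
#'
#' Tabulates the standard descriptive blocks of a spontaneous-report
#' dataset: receipt year, sex, age bins (`<19`, `19-44`, `44-59`, `>=60`
#' years, half-open on the right), weight bins, reporter type, indication,
#' reporting country, administration route of the subject drug,
#' seriousness outcomes, and time-to-onset bins (`<2`, `2-5`, `5-7`,
#' `7-14`, `14-28`, `>=28` days, half-open).
#'
#' Percentages within each block use the sum of that block's tabulated
#' counts as denominator — not the overall report count.  Because outcomes
#' and indications are multi-valued, one report can contribute several
#' entries to those blocks, and their denominators exceed the report count;
#' this is the arithmetic convention of published characteristic tables for
#' this kind of data.
#'
#' @param fd A `faers_data`, usually restricted with [subject_reports()].
#' @return A list with `table` (data frame: `block`, `level`, `count`,
#'   `pct` rounded half-up to 2 decimals) and `medians` (named list of
#'   median and quartiles for age, weight and time-to-onset).
#' @export
summarize_characteristics <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  r <- fd$reports
  blocks <- list()

  blocks$year <- .count_block("Year", r$year)

  sex <- r$sex
  sex[!sex %in% c("F", "M")] <- NA
  sex <- c(F = "Female", M = "Male")[sex]
  blocks$sex <- .count_block("Sex", sex, c("Female", "Male", "Unknown"))

  blocks$age <- .count_block("Age, years", .bin_age(r$age_years),
                             c("<19", "19-44", "44-59", ">=60", "Unknown"))

  wbin <- cut(r$wt, breaks = c(-Inf, 50, 100, Inf), right = FALSE,
              labels = c("<50", "50-100", ">=100"))
  blocks$weight <- .count_block("Weight, kg", wbin,
                                c("<50", "50-100", ">=100", "Unknown"))

  rep_lab <- .reporter_labels[toupper(trimws(r$occp_cod))]
  blocks$reporter <- .count_block("Reporter", rep_lab,
                                  c("Pharmacist", "Physician", "Consumer",
                                    "Other", "Unknown"))

  if (!is.null(fd$indications) && nrow(fd$indications))
    blocks$indication <- .count_block("Indication", fd$indications$indi_pt)

  blocks$country <- .count_block("Reported countries", r$occr_country)

  if (!is.null(fd$drugs) && nrow(fd$drugs)) {
    ps <- fd$drugs[toupper(fd$drugs$role_cod) == "PS", , drop = FALSE]
    route <- ps$route[match(r$primaryid, ps$primaryid)]
    blocks$route <- .count_block("Route", route)
  }

  if (!is.null(fd$outcomes) && nrow(fd$outcomes)) {
    oc <- .outcome_labels[toupper(trimws(fd$outcomes$outc_cod))]
    blocks$outcomes <- .count_block("Outcomes", oc,
                                    unname(.outcome_labels))
  }

  blocks$tto <- .count_block("TTO, days", .bin_tto(r$tto_days),
                             c("<2", "2-5", "5-7", "7-14", "14-28", ">=28",
                               "Unknown"))

  q3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    unname(stats::quantile(x, c(0.5, 0.25, 0.75)))
  }
  med <- list(age_years = q3(r$age_years), weight_kg = q3(r$wt),
              tto_days = q3(r$tto_days))

  list(table = do.call(rbind, c(blocks, list(make.row.names = FALSE))),
       medians = med)
}
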