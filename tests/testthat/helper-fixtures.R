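# Fixture builders shared across the test files.  Everything is generated
# in code; no data files.

# Minimal assembled dataset built directly: `pts` is a list of character
# vectors (reaction PTs per report); `is_subject` flags the subject-drug
# reports; `tto` optional per-report onset days.
toy_faers_data <- function(pts, is_subject, tto = NULL, years = NULL) {
  n <- length(pts)
  pid <- 1000L + seq_len(n)
  yr <- if (is.null(years)) rep(2024L, n) else as.integer(years)
  reports <- data.frame(
    primaryid = pid, caseid = pid, fda_dt = yr * 10000L + 615L,
    event_dt = rep(NA_integer_, n), sex = rep("M", n),
    age = rep(60, n), age_cod = rep("YR", n), wt = rep(NA_real_, n),
    wt_cod = rep("", n), occp_cod = rep("MD", n),
    occr_country = rep("CN", n), age_years = rep(60, n), year = yr,
    tto_days = if (is.null(tto)) rep(NA_integer_, n) else as.integer(tto),
    is_subject = is_subject, stringsAsFactors = FALSE
  )
  reactions <- data.frame(primaryid = rep(pid, lengths(pts)),
                          caseid = rep(pid, lengths(pts)),
                          pt = as.character(unlist(pts)),
                          stringsAsFactors = FALSE)
  structure(list(reports = reports, reactions = reactions, drugs = NULL,
                 outcomes = NULL, indications = NULL,
                 exclusions = data.frame(primaryid = integer(0),
                                         reason = character(0)),
                 log = list(orphan_drug_rows = 0L, orphan_reac_rows = 0L,
                            n_excluded = 0L)),
            class = "faers_data")
}

# Expand a 2 x k contingency matrix (columns = groups) into x/group vectors.
expand_table <- function(tab) {
  tab <- as.matrix(tab)
  x <- rep(rep(rownames(tab) %||% seq_len(nrow(tab)), ncol(tab)), c(tab))
  g <- rep(rep(colnames(tab) %||% seq_len(ncol(tab)), each = nrow(tab)),
           c(tab))
  data.frame(x = x, g = g, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run generator -> dedup -> PS filter -> assembly in one step.
sim_to_data <- function(cfg) {
  sim <- generate_faers_tables(cfg)
  dd <- deduplicate_reports(sim$tables$demo)
  ids <- filter_primary_suspect(sim$tables$drug, cfg$subject_drug)
  fd <- assemble_reports(dd$demo, sim$tables$drug, sim$tables$reac,
                         ther = sim$tables$ther, outc = sim$tables$outc,
                         indi = sim$tables$indi, subject_ids = ids)
  list(sim = sim, fd = fd, dedup = dd)
}

# Patient table reproducing printed two-group baseline counts:
# each entry of `vars` is a 2-column matrix (group0, group1) of level counts.
cohort_from_counts <- function(vars, n0, n1) {
  out <- data.frame(myelosuppression = rep(c(0L, 1L), c(n0, n1)))
  for (nm in names(vars)) {
    tab <- vars[[nm]]
    stopifnot(colSums(tab) == c(n0, n1))
    v <- c(rep(rownames(tab), tab[, 1]), rep(rownames(tab), tab[, 2]))
    out[[nm]] <- v
  }
  out
}
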