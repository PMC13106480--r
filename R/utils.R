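# Shared internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' the printed tables this package reproduces), as opposed to the IEC 60559
#' banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.675), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# YYYYMMDD integer <-> Date. Unparseable values become NA without warning;
# callers count them as missing.
yyyymmdd_to_date <- function(x) {
  x <- suppressWarnings(as.integer(x))
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & x >= 10000101L & x <= 29991231L
  if (any(ok)) {
    d <- as.Date(as.character(x[ok]), format = "%Y%m%d")
    out[ok] <- d
  }
  out
}

date_to_yyyymmdd <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}

# Block percentage used across the summary tables: denominator is the sum of
# the tabulated counts of the block, not the overall record count.
block_pct <- function(counts, digits = 2) {
  round_half_up(100 * counts / sum(counts), digits)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a single proportion in [0, 1]", name)
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_config("'%s' must be a single %s number", name,
                       if (strict) "positive" else "non-negative")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min
  if (!ok) stop_config("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}
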