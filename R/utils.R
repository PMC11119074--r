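# internal helpers shared across modules

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the convention
#' used when percentages are reported in published summary tables
#' (e.g. 19/60 -> 31.67, 46/60 -> 76.67).  Base `round()` uses banker's
#' rounding, which would report 0.125 as 0.12 rather than 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(19 / 60 * 100)  # 31.67
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 nudge guards against values like 31.665 stored as 31.66499...9
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# classed errors so callers can distinguish data problems from bugs
pc_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pharmcat_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pc_stop(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "pharmcat_parse_error"
    )
  }
  invisible(df)
}

# coerce a character column to integer, reporting the first offending row
as_integer_col <- function(x, col, what = "input") {
  x_trim <- trimws(x)
  suppressWarnings(out <- as.numeric(x_trim))
  bad <- is.na(out) & !is.na(x_trim) & nzchar(x_trim)
  bad <- bad | (!is.na(out) & out != floor(out))
  if (any(bad)) {
    pc_stop(
      sprintf("%s: column '%s' has a non-integer value '%s' at row %d",
              what, col, x[which(bad)[1]], which(bad)[1]),
      "pharmcat_parse_error"
    )
  }
  as.integer(out)
}
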