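VALID_TYPES <- c("oncology", "haematology")
VALID_PHASES <- c("I", "II", "III")

check_enum_col <- function(x, valid, col, what) {
  bad <- !x %in% valid
  if (any(bad)) {
    pc_stop(
      sprintf("%s: column '%s' has invalid value '%s' at row %d (allowed: %s)",
              what, col, x[which(bad)[1]], which(bad)[1],
              paste(valid, collapse = ", ")),
      "pharmcat_parse_error"
    )
  }
  invisible(x)
}

#' Read and write assessment CSV files
#'
#' The shared assessment exchange format: UTF-8, comma-separated, header
#' row `trial_id, centre_id, trial_type, phase, rater_id,
#' item_1, ..., item_15` (one `item_<id>` column per instrument item, in
#' instrument order; integer scores).  `trial_type` must be `oncology` or
#' `haematology`, `phase` must be `I`, `II` or `III`.  Malformed files
#' fail with an error naming the offending column and row.  Reading does
#' not validate scores against the instrument's allowed levels -- use
#' [validate_assessments()] for that -- but does enforce column presence
#' and integer scores.
#'
#' @param path file path.
#' @param assessments assessment data frame (see [validate_assessments()]
#'   for the shape).
#' @param instrument a `pharmcat_instrument` defining the expected item
#'   columns.
#' @return `read_assessments()` returns the assessment data frame;
#'   `write_assessments()` returns `path` invisibly.
#' @export
read_assessments <- function(path, instrument = default_instrument()) {
  what <- sprintf("assessment file '%s'", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  meta <- c("trial_id", "centre_id", "trial_type", "phase", "rater_id")
  stopifnot_cols(df, c(meta, item_columns(instrument)), what)
  check_enum_col(df$trial_type, VALID_TYPES, "trial_type", what)
  check_enum_col(df$phase, VALID_PHASES, "phase", what)
  for (col in item_columns(instrument)) {
    df[[col]] <- as_integer_col(df[[col]], col, what)
  }
  df[, c(meta, item_columns(instrument)), drop = FALSE]
}

#' @rdname read_assessments
#' @export
write_assessments <- function(assessments, path,
                              instrument = default_instrument()) {
  meta <- c("trial_id", "centre_id", "trial_type", "phase", "rater_id")
  stopifnot_cols(assessments, c(meta, item_columns(instrument)),
                 "assessment table")
  utils::write.csv(assessments[, c(meta, item_columns(instrument))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write score CSV files
#'
#' Score tables carry one row per (trial, rater): `trial_id, centre_id,
#' trial_type, phase, rater_id, total` plus an optional `category`
#' column.  Totals must be integers; parse failures name the offending
#' column and row.
#'
#' @param path file path.
#' @param scores score data frame (see [total_scores()]).
#' @return `read_scores()` returns the score data frame;
#'   `write_scores()` returns `path` invisibly.
#' @export
read_scores <- function(path) {
  what <- sprintf("score file '%s'", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  stopifnot_cols(df, c("trial_id", "rater_id", "total"), what)
  if ("trial_type" %in% names(df)) {
    check_enum_col(df$trial_type, VALID_TYPES, "trial_type", what)
  }
  if ("phase" %in% names(df)) {
    check_enum_col(df$phase, VALID_PHASES, "phase", what)
  }
  df$total <- as_integer_col(df$total, "total", what)
  df
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  stopifnot_cols(scores, c("trial_id", "rater_id", "total"), "score table")
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
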