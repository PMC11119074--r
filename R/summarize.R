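collapse_per_trial <- function(scores, per_trial_rule) {
  split_idx <- split(seq_len(nrow(scores)), scores$trial_id)
  if (per_trial_rule %in% c("mean_floor", "max")) {
    bad <- names(split_idx)[vapply(split_idx, length, integer(1)) != 2]
    if (length(bad) > 0) {
      pc_stop(sprintf(
        "per-trial rule '%s' needs exactly 2 raters per trial; offending trial(s): %s",
        per_trial_rule, paste(utils::head(bad, 5), collapse = ", ")),
        "pharmcat_data_error")
    }
  }
  trial_order <- unique(scores$trial_id)
  rows <- lapply(trial_order, function(tid) {
    i <- split_idx[[tid]]
    total <- switch(per_trial_rule,
      rater_a = scores$total[i[1]],
      mean_floor = as.integer(floor(mean(scores$total[i]))),
      max = max(scores$total[i])
    )
    data.frame(trial_id = tid,
               centre_id = scores$centre_id[i[1]],
               trial_type = scores$trial_type[i[1]],
               phase = scores$phase[i[1]],
               total = total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stratum_row <- function(stratum, level, df, n_cohort) {
  cats <- df$category
  n <- nrow(df)
  data.frame(
    stratum = stratum,
    level = level,
    n_trials = n,
    percent_of_cohort = round_half_up(100 * n / n_cohort, 2),
    mean_score = round_half_up(mean(df$total), 2),
    n_low = sum(cats == "low"),
    pct_low = round_half_up(100 * sum(cats == "low") / n, 2),
    n_medium = sum(cats == "medium"),
    pct_medium = round_half_up(100 * sum(cats == "medium") / n, 2),
    n_high = sum(cats == "high"),
    pct_high = round_half_up(100 * sum(cats == "high") / n, 2),
    stringsAsFactors = FALSE
  )
}

#' Stratified cohort summary
#'
#' Summarises a scored cohort the way development-cohort results tables
#' are reported: a total row, then one row per centre, trial type
#' (oncology/haematology) and phase (I/II/III), each with the number of
#' trials, its percentage of the cohort, the mean total score, and the
#' within-stratum count and percentage of low-, medium- and
#' high-complexity trials.  Percentages are rounded half away from zero to
#' two decimals.
#'
#' Each trial in the study is assessed by two raters but summarised once;
#' `per_trial_rule` selects how the two totals collapse to one trial-level
#' value:
#' * `"rater_a"` (default) -- the first-listed rater's total,
#' * `"mean_floor"` -- the floor of the two raters' mean,
#' * `"max"` -- the larger total.
#'
#' `mode = "per_score"` skips the collapse and summarises every recorded
#' score as its own unit (so n doubles), for cohorts where the reported
#' mean is taken over all scores rather than over trials.
#'
#' @param scores data frame with columns `trial_id`, `centre_id`,
#'   `trial_type`, `phase`, `rater_id`, `total` (see [total_scores()]).
#' @param cutoffs a `pharmcat_cutoffs`; default [study_cutoffs()].
#' @param per_trial_rule `"rater_a"`, `"mean_floor"` or `"max"`.
#' @param mode `"per_trial"` (default) or `"per_score"`.
#' @return Data frame of class `pharmcat_summary`, one row per stratum.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_config(seed = 3))
#' summarize_cohort(total_scores(cohort$assessments))
summarize_cohort <- function(scores, cutoffs = study_cutoffs(),
                             per_trial_rule = c("rater_a", "mean_floor", "max"),
                             mode = c("per_trial", "per_score")) {
  per_trial_rule <- match.arg(per_trial_rule)
  mode <- match.arg(mode)
  stopifnot_cols(scores,
                 c("trial_id", "centre_id", "trial_type", "phase", "total"),
                 "score table")
  if (nrow(scores) < 1) {
    pc_stop("at least one score is required", "pharmcat_insufficient_data")
  }
  units <- if (mode == "per_trial") {
    stopifnot_cols(scores, "rater_id", "score table")
    collapse_per_trial(scores, per_trial_rule)
  } else {
    scores
  }
  units$category <- categorize(units$total, cutoffs)
  n_cohort <- nrow(units)

  rows <- list(stratum_row("total", "total", units, n_cohort))
  strata <- list(centre = "centre_id", type = "trial_type", phase = "phase")
  for (s in names(strata)) {
    col <- strata[[s]]
    levels_order <- switch(s,
      phase = intersect(c("I", "II", "III"), unique(units[[col]])),
      type = intersect(c("oncology", "haematology"), unique(units[[col]])),
      sort(unique(units[[col]]))
    )
    for (lv in levels_order) {
      rows[[length(rows) + 1]] <-
        stratum_row(s, lv, units[units[[col]] == lv, , drop = FALSE], n_cohort)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pharmcat_summary", "data.frame")
  out
}
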