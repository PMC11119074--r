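#' Pair the two raters' totals per trial
#'
#' Reshapes a long score table (one row per trial and rater) into one row
#' per trial with the two raters' totals side by side.  Rater A is the
#' first-listed rater for each trial, rater B the second; every trial must
#' have exactly two raters.
#'
#' @param scores data frame with columns `trial_id`, `rater_id`, `total`
#'   (as produced by [total_scores()]).
#' @return Data frame with columns `trial_id`, `rater_a`, `rater_b`,
#'   `total_a`, `total_b`.
#' @export
pair_scores <- function(scores) {
  stopifnot_cols(scores, c("trial_id", "rater_id", "total"), "score table")
  split_idx <- split(seq_len(nrow(scores)), scores$trial_id)
  bad <- names(split_idx)[vapply(split_idx, length, integer(1)) != 2]
  if (length(bad) > 0) {
    pc_stop(sprintf(
      "every trial needs exactly 2 raters; offending trial(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")),
      "pharmcat_data_error")
  }
  # preserve first-occurrence trial order
  trial_order <- unique(scores$trial_id)
  rows <- lapply(trial_order, function(tid) {
    i <- split_idx[[tid]]
    data.frame(trial_id = tid,
               rater_a = scores$rater_id[i[1]],
               rater_b = scores$rater_id[i[2]],
               total_a = scores$total[i[1]],
               total_b = scores$total[i[2]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_pairs <- function(pairs) {
  stopifnot_cols(pairs, c("total_a", "total_b"), "paired score table")
  if (nrow(pairs) < 1) {
    pc_stop("at least one scored pair is required", "pharmcat_insufficient_data")
  }
  invisible(pairs)
}

#' Summarise score differences between two raters
#'
#' For paired independent assessments of the same trials, computes the
#' share of trials where the two raters produced the identical total, the
#' histogram of absolute score differences, and the mean absolute score
#' difference.  Values are returned at full precision; rounding to two
#' decimals happens at print time.
#'
#' @param pairs data frame with columns `total_a`, `total_b`
#'   (see [pair_scores()]).
#' @return List with `n`, `n_exact`, `percent_exact`, `diff_histogram`
#'   (named count vector over absolute differences) and `mean_abs_diff`.
#' @export
#' @examples
#' pairs <- data.frame(total_a = c(20, 20, 25), total_b = c(20, 21, 25))
#' score_diff_summary(pairs)
score_diff_summary <- function(pairs) {
  check_pairs(pairs)
  d <- abs(pairs$total_a - pairs$total_b)
  n <- length(d)
  hist <- table(d)
  diff_histogram <- as.integer(hist)
  names(diff_histogram) <- names(hist)
  list(
    n = n,
    n_exact = sum(d == 0),
    percent_exact = 100 * mean(d == 0),
    diff_histogram = diff_histogram,
    mean_abs_diff = mean(d)
  )
}

#' Cross-classify the two raters' complexity categories
#'
#' Builds the 3x3 contingency table of rater A's versus rater B's
#' complexity category over the paired trials, in category order
#' low/medium/high.
#'
#' @inheritParams score_diff_summary
#' @param cutoffs a `pharmcat_cutoffs`; default [study_cutoffs()].
#' @return An object of class `pharmcat_crossclass`: a list with `counts`
#'   (3x3 integer matrix, rows = rater A) and `n`.
#' @export
cross_classification <- function(pairs, cutoffs = study_cutoffs()) {
  check_pairs(pairs)
  cat_a <- categorize(pairs$total_a, cutoffs)
  cat_b <- categorize(pairs$total_b, cutoffs)
  counts <- unclass(table(rater_a = cat_a, rater_b = cat_b))
  structure(list(counts = counts, n = nrow(pairs)),
            class = "pharmcat_crossclass")
}

#' @export
print.pharmcat_crossclass <- function(x, ...) {
  cat(sprintf("<pharmcat_crossclass> %d paired assessments\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Cohen's linear weighted kappa
#'
#' Chance-corrected agreement for ordinal categories with a penalty that
#' grows linearly with the category distance.  With \eqn{k} categories and
#' disagreement weights \eqn{w_{ij} = |i - j| / (k - 1)}, observed cell
#' proportions \eqn{p_{ij}} and chance-expected proportions
#' \eqn{e_{ij} = p_{i\cdot} p_{\cdot j}} from the margins,
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} p_{ij}}
#'                           {\sum_{ij} w_{ij} e_{ij}}.}
#' This disagreement-weight form is algebraically identical to the
#' agreement-weight form \eqn{(p_o - p_e)/(1 - p_e)} with weights
#' \eqn{1 - |i - j|/(k - 1)}.
#'
#' When both raters place every trial in the same single category the
#' denominator vanishes and kappa is undefined; a classed error
#' (`pharmcat_undefined_kappa`) is raised so callers can report the
#' perfect-but-degenerate agreement explicitly.
#'
#' @param x a `pharmcat_crossclass`, or a square integer matrix of counts
#'   with rows = rater A categories in ordinal order.
#' @return Kappa, a real number no larger than 1.
#' @export
#' @examples
#' linear_weighted_kappa(diag(c(20, 20, 20)))  # 1
linear_weighted_kappa <- function(x) {
  counts <- if (inherits(x, "pharmcat_crossclass")) x$counts else as.matrix(x)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2) {
    pc_stop("cross-classification must be a square matrix with >= 2 categories",
            "pharmcat_schema_error")
  }
  if (any(counts < 0)) {
    pc_stop("cross-classification counts must be non-negative",
            "pharmcat_schema_error")
  }
  n <- sum(counts)
  if (n < 1) {
    pc_stop("cross-classification is empty", "pharmcat_insufficient_data")
  }
  k <- nrow(counts)
  idx <- seq_len(k)
  w <- abs(outer(idx, idx, `-`)) / (k - 1)
  p <- counts / n
  rm_ <- rowSums(p)
  cm_ <- colSums(p)
  e <- outer(rm_, cm_)
  denom <- sum(w * e)
  if (denom == 0) {
    pc_stop(paste0(
      "weighted kappa is undefined: both raters used a single category ",
      "for every trial (agreement is perfect but chance-uncorrectable)"),
      "pharmcat_undefined_kappa")
  }
  1 - sum(w * p) / denom
}

#' Inter-rater reproducibility report
#'
#' Assembles the full reproducibility analysis for a two-rater paired
#' cohort: exact-score concordance, the absolute score-difference
#' histogram and mean, the 3x3 category cross-classification, the number
#' of trials placed in the same category by both raters, and Cohen's
#' linear weighted kappa on the cross-classification.
#'
#' Kappa is computed on the three complexity categories by default, since
#' the categories are the instrument's operational output once cut-offs
#' are established.  `kappa_on = "total"` instead treats each observed
#' total score as its own ordinal level (sensitivity analysis).
#'
#' If kappa is undefined because all trials fall in one category for both
#' raters, `weighted_kappa` is `NA` and `perfect_agreement` is `TRUE`.
#'
#' @inheritParams cross_classification
#' @param kappa_on `"category"` (default) or `"total"`.
#' @return An object of class `pharmcat_agreement`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_config(seed = 42))
#' pairs <- pair_scores(total_scores(cohort$assessments))
#' agreement_report(pairs, study_cutoffs())
agreement_report <- function(pairs, cutoffs = study_cutoffs(),
                             kappa_on = c("category", "total")) {
  kappa_on <- match.arg(kappa_on)
  check_pairs(pairs)
  diffs <- score_diff_summary(pairs)
  cc <- cross_classification(pairs, cutoffs)
  if (kappa_on == "category") {
    kappa_table <- cc$counts
  } else {
    lev <- sort(unique(c(pairs$total_a, pairs$total_b)))
    kappa_table <- unclass(table(factor(pairs$total_a, levels = lev),
                                 factor(pairs$total_b, levels = lev)))
  }
  perfect <- FALSE
  kappa <- tryCatch(
    linear_weighted_kappa(kappa_table),
    pharmcat_undefined_kappa = function(e) {
      perfect <<- TRUE
      NA_real_
    },
    pharmcat_schema_error = function(e) {
      # single ordinal level observed (kappa_on = "total" with all totals
      # equal): agreement is perfect but chance-uncorrectable
      perfect <<- TRUE
      NA_real_
    }
  )
  structure(list(
    n_trials = diffs$n,
    n_exact = diffs$n_exact,
    percent_exact = diffs$percent_exact,
    diff_histogram = diffs$diff_histogram,
    mean_abs_diff = diffs$mean_abs_diff,
    cross_class = cc,
    same_category_count = sum(diag(cc$counts)),
    weighted_kappa = kappa,
    perfect_agreement = perfect,
    kappa_on = kappa_on,
    cutoffs = cutoffs
  ), class = "pharmcat_agreement")
}

#' @export
print.pharmcat_agreement <- function(x, ...) {
  cat(sprintf("<pharmcat_agreement> %d trials, two raters\n", x$n_trials))
  cat(sprintf("  identical totals : %d (%s%%; %s%% to 0 dp)\n",
              x$n_exact,
              format(round_half_up(x$percent_exact, 2), nsmall = 2),
              format(round_half_up(x$percent_exact, 0))))
  cat(sprintf("  mean |difference|: %s points\n",
              format(round_half_up(x$mean_abs_diff, 2), nsmall = 2)))
  cat("  |difference| histogram:\n")
  for (d in names(x$diff_histogram)) {
    cat(sprintf("    %s point(s): %d trial(s)\n", d, x$diff_histogram[[d]]))
  }
  cat(sprintf("  same category    : %d of %d\n",
              x$same_category_count, x$n_trials))
  if (x$perfect_agreement) {
    cat(sprintf("  weighted kappa   : undefined (single category, perfect agreement) [on %s]\n",
                x$kappa_on))
  } else {
    cat(sprintf("  weighted kappa   : %s [on %s]\n",
                format(round_half_up(x$weighted_kappa, 2), nsmall = 2),
                x$kappa_on))
  }
  cat("  cross-classification (rows rater A, cols rater B):\n")
  print(x$cross_class$counts)
  invisible(x)
}
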