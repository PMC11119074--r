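#' Complexity category cut-offs
#'
#' A cut-off set holds the two inclusive upper bounds separating the three
#' ordinal complexity categories: totals up to `low_max` are low
#' complexity, totals from `low_max + 1` to `med_max` are medium, and
#' anything above `med_max` is high.
#'
#' @param low_max inclusive upper bound of the low category.
#' @param med_max inclusive upper bound of the medium category; must exceed
#'   `low_max`.
#' @return An object of class `pharmcat_cutoffs`.
#' @export
#' @examples
#' cutoff_set(19, 25)
cutoff_set <- function(low_max, med_max) {
  if (!is_count(low_max) || !is_count(med_max)) {
    pc_stop("cut-offs must be single integers", "pharmcat_schema_error")
  }
  if (!(low_max < med_max)) {
    pc_stop(sprintf("low_max (%d) must be strictly below med_max (%d)",
                    low_max, med_max),
            "pharmcat_schema_error")
  }
  structure(list(low_max = as.integer(low_max), med_max = as.integer(med_max)),
            class = "pharmcat_cutoffs")
}

#' @export
print.pharmcat_cutoffs <- function(x, ...) {
  cat(sprintf("<pharmcat_cutoffs> low <= %d < medium <= %d < high\n",
              x$low_max, x$med_max))
  invisible(x)
}

#' Derive complexity cut-offs from an empirical score distribution
#'
#' Implements the tertile rule: the scores are sorted in ascending order
#' and the cut-offs are the values at the first and third tertiles, i.e.
#' at 33.3% and 66.7% of the score distribution.  Made precise as order
#' statistics: with sorted scores \eqn{s_{(1)} \le \dots \le s_{(n)}}, the
#' low/medium boundary is \eqn{s_{(\lceil n/3 \rceil)}} and the
#' medium/high boundary is \eqn{s_{(\lceil 2n/3 \rceil)}}, each taken as
#' an inclusive upper bound.  This convention is deterministic under ties
#' and always returns boundaries that are observed scores.
#'
#' @param scores integer vector of total scores, `length(scores) >= 3`.
#' @return A `pharmcat_cutoffs` object.
#' @export
#' @examples
#' derive_cutoffs(c(15, 16, 17, 20, 21, 22, 26, 27, 28))  # 17 / 22
derive_cutoffs <- function(scores) {
  scores <- as.integer(scores)
  if (any(is.na(scores))) {
    pc_stop("scores contain missing values", "pharmcat_insufficient_data")
  }
  n <- length(scores)
  if (n < 3) {
    pc_stop(sprintf("need at least 3 scores to derive tertile cut-offs, got %d", n),
            "pharmcat_insufficient_data")
  }
  s <- sort(scores)
  low_max <- s[ceiling(n / 3)]
  med_max <- s[ceiling(2 * n / 3)]
  if (low_max >= med_max) {
    pc_stop(sprintf(
      "degenerate score distribution: tertile boundaries coincide at %d; the distribution is too concentrated to split into three categories",
      low_max), "pharmcat_degenerate_distribution")
  }
  cutoff_set(low_max, med_max)
}

#' Published reference cut-offs
#'
#' The complexity cut-offs established from the original 120-score
#' development cohort: low complexity up to 19 points, medium complexity
#' 20--25 points, high complexity 26 points or more.  Packaged as a
#' constant so that new assessments can be categorised against the
#' published boundaries without re-deriving them.
#'
#' @return A `pharmcat_cutoffs` object with `low_max = 19`, `med_max = 25`.
#' @export
#' @examples
#' categorize(c(19, 20, 25, 26), study_cutoffs())
study_cutoffs <- function() {
  cutoff_set(19L, 25L)
}

#' Assign complexity categories to total scores
#'
#' Maps each total to an ordinal category: `low` if
#' `total <= low_max`, `medium` if `low_max < total <= med_max`, `high`
#' otherwise.  Every non-negative integer maps to exactly one category.
#'
#' @param total integer vector of total scores (non-negative).
#' @param cutoffs a `pharmcat_cutoffs`; default [study_cutoffs()].
#' @return Ordered factor with levels `low < medium < high`.
#' @export
categorize <- function(total, cutoffs = study_cutoffs()) {
  if (!inherits(cutoffs, "pharmcat_cutoffs")) {
    pc_stop("cutoffs must be a pharmcat_cutoffs object", "pharmcat_schema_error")
  }
  total <- as.integer(total)
  if (any(is.na(total))) {
    pc_stop("totals contain missing values", "pharmcat_domain_error")
  }
  if (any(total < 0)) {
    pc_stop(sprintf("negative total score %d is outside the instrument domain",
                    min(total)),
            "pharmcat_domain_error")
  }
  lab <- ifelse(total <= cutoffs$low_max, "low",
                ifelse(total <= cutoffs$med_max, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Read and write cut-offs as JSON
#'
#' Cut-offs travel between tools as a tiny JSON document
#' `{"low_max": 19, "med_max": 25}`.
#'
#' @param path file path.
#' @param cutoffs a `pharmcat_cutoffs`.
#' @return `read_cutoffs()` returns a `pharmcat_cutoffs`;
#'   `write_cutoffs()` returns `path` invisibly.
#' @export
read_cutoffs <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$low_max) || is.null(doc$med_max)) {
    pc_stop("cut-off JSON must contain 'low_max' and 'med_max'",
            "pharmcat_schema_error")
  }
  cutoff_set(doc$low_max, doc$med_max)
}

#' @rdname read_cutoffs
#' @export
write_cutoffs <- function(cutoffs, path) {
  if (!inherits(cutoffs, "pharmcat_cutoffs")) {
    pc_stop("cutoffs must be a pharmcat_cutoffs object", "pharmcat_schema_error")
  }
  jsonlite::write_json(list(low_max = cutoffs$low_max,
                            med_max = cutoffs$med_max),
                       path, auto_unbox = TRUE)
  invisible(path)
}
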