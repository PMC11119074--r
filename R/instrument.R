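#' @section Instrument representation:
#' An instrument is pure data: an ordered list of item definitions, each
#' with an id, a section, a human-readable label, and the set of allowed
#' score levels (integers 0--3, each with a description).  Instruments are
#' loaded from JSON so that a modified instrument -- items added, removed
#' or rescored for a particular pharmacy service -- needs no code change.
#' @name pharmcat-instrument
#' @keywords internal
NULL

VALID_SECTIONS <- c("study_design", "drug_management", "drug_preparation")

new_instrument <- function(name, items) {
  structure(list(name = name, items = items), class = "pharmcat_instrument")
}

validate_item <- function(item, idx) {
  where <- sprintf("items[%d]", idx)
  for (field in c("item_id", "section", "label", "levels")) {
    if (is.null(item[[field]])) {
      pc_stop(sprintf("%s: missing field '%s'", where, field),
              "pharmcat_schema_error")
    }
  }
  if (!is_count(item$item_id) || item$item_id < 1) {
    pc_stop(sprintf("%s: 'item_id' must be a positive integer", where),
            "pharmcat_schema_error")
  }
  if (!item$section %in% VALID_SECTIONS) {
    pc_stop(sprintf("%s (item_id %s): 'section' must be one of %s",
                    where, item$item_id,
                    paste(VALID_SECTIONS, collapse = ", ")),
            "pharmcat_schema_error")
  }
  lv <- item$levels
  if (!is.data.frame(lv) || nrow(lv) == 0) {
    pc_stop(sprintf("%s (item_id %s): 'levels' must be a non-empty list",
                    where, item$item_id),
            "pharmcat_schema_error")
  }
  stopifnot_cols(lv, c("score", "description"),
                 sprintf("%s (item_id %s) levels", where, item$item_id))
  if (any(is.na(lv$score)) || any(lv$score != floor(lv$score)) ||
      any(lv$score < 0) || any(lv$score > 3)) {
    pc_stop(sprintf("%s (item_id %s): level 'score' values must be integers in 0..3",
                    where, item$item_id),
            "pharmcat_schema_error")
  }
  if (anyDuplicated(lv$score)) {
    pc_stop(sprintf("%s (item_id %s): duplicate level score %d",
                    where, item$item_id, lv$score[duplicated(lv$score)][1]),
            "pharmcat_schema_error")
  }
  if (nrow(lv) < 2) {
    pc_stop(sprintf("%s (item_id %s): an item needs at least 2 levels",
                    where, item$item_id),
            "pharmcat_schema_error")
  }
  list(
    item_id = as.integer(item$item_id),
    section = item$section,
    label = item$label,
    levels = data.frame(score = as.integer(lv$score),
                        description = as.character(lv$description),
                        stringsAsFactors = FALSE)
  )
}

#' Load an instrument definition from JSON
#'
#' Reads a structured instrument description (a JSON file or an equivalent
#' already-parsed list) and returns a validated instrument object.  The
#' document must contain a `name` and an `items` array; every item carries
#' `item_id`, `section` (one of `study_design`, `drug_management`,
#' `drug_preparation`), `label`, and a `levels` array of
#' `{score, description}` pairs with distinct integer scores in 0--3 and at
#' least two levels per item.
#'
#' @param source path to a JSON file, or a list with the same structure.
#' @return An object of class `pharmcat_instrument`.
#' @seealso [default_instrument()] for the packaged 15-item instrument.
#' @export
#' @examples
#' cfg <- list(name = "mini", items = list(
#'   list(item_id = 1L, section = "study_design", label = "toy",
#'        levels = data.frame(score = c(0L, 3L), description = c("a", "b")))))
#' load_instrument(cfg)
load_instrument <- function(source) {
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      pc_stop(sprintf("instrument file not found: %s", source),
              "pharmcat_schema_error")
    }
    doc <- jsonlite::fromJSON(source, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  } else if (is.list(source)) {
    doc <- source
  } else {
    pc_stop("instrument source must be a file path or a list",
            "pharmcat_schema_error")
  }
  if (is.null(doc$name) || !nzchar(doc$name)) {
    pc_stop("instrument document: missing field 'name'", "pharmcat_schema_error")
  }
  if (is.null(doc$items) || length(doc$items) == 0) {
    pc_stop("instrument document: missing or empty 'items'",
            "pharmcat_schema_error")
  }
  items_raw <- doc$items
  # jsonlite may deliver items as a data.frame with a list-column of levels
  if (is.data.frame(items_raw)) {
    items_raw <- lapply(seq_len(nrow(items_raw)), function(i) {
      list(item_id = items_raw$item_id[i],
           section = items_raw$section[i],
           label = items_raw$label[i],
           levels = items_raw$levels[[i]])
    })
  }
  items <- lapply(seq_along(items_raw), function(i) {
    it <- items_raw[[i]]
    if (!is.null(it$levels) && !is.data.frame(it$levels)) {
      lv <- it$levels
      if (length(lv) == 0) {
        it$levels <- data.frame(score = integer(), description = character())
      } else {
        it$levels <- data.frame(
          score = vapply(lv, function(l) as.integer(l$score), integer(1)),
          description = vapply(lv, function(l) as.character(l$description),
                               character(1)),
          stringsAsFactors = FALSE
        )
      }
    }
    validate_item(it, i)
  })
  ids <- vapply(items, `[[`, integer(1), "item_id")
  if (anyDuplicated(ids)) {
    pc_stop(sprintf("instrument document: duplicate item_id %d",
                    ids[duplicated(ids)][1]),
            "pharmcat_schema_error")
  }
  new_instrument(doc$name, items)
}

#' The default 15-item pharmacy complexity instrument
#'
#' Returns the standard Pharm-CAT instrument: 15 items in three sections
#' (study design, drug management, drug preparation), each scored at a small
#' set of allowed levels between 0 and 3 points.  Item 1 (study phase)
#' scores 3 points for a phase I trial and 1 point otherwise; summing the
#' 15 item scores yields a trial total between 15 and 44 points.
#'
#' The definition is shipped as a JSON config file
#' (`system.file("extdata", "pharmcat_instrument.json", package = "pharmcat")`)
#' which can serve as a template for modified instruments.
#'
#' @return An object of class `pharmcat_instrument` with 15 items.
#' @export
#' @examples
#' inst <- default_instrument()
#' score_bounds(inst)  # 15 44
default_instrument <- function() {
  path <- system.file("extdata", "pharmcat_instrument.json",
                      package = "pharmcat", mustWork = TRUE)
  load_instrument(path)
}

#' @export
print.pharmcat_instrument <- function(x, ...) {
  cat(sprintf("<pharmcat_instrument> %s: %d items\n", x$name, length(x$items)))
  for (it in x$items) {
    cat(sprintf("  %2d [%s] %s: levels {%s}\n", it$item_id, it$section,
                it$label, paste(sort(it$levels$score), collapse = ",")))
  }
  invisible(x)
}

item_ids <- function(instrument) {
  vapply(instrument$items, `[[`, integer(1), "item_id")
}

#' Names of the per-item score columns for an instrument
#'
#' @param instrument a `pharmcat_instrument`.
#' @return Character vector `item_<id>` in instrument order.
#' @export
item_columns <- function(instrument) {
  paste0("item_", item_ids(instrument))
}

allowed_scores <- function(item) sort(item$levels$score)

# does the instrument carry the phase-determined study-phase item
# (item_id 1 with levels exactly {1, 3})?
has_phase_item <- function(instrument) {
  ids <- item_ids(instrument)
  if (!1L %in% ids) return(FALSE)
  identical(allowed_scores(instrument$items[[match(1L, ids)]]), c(1L, 3L))
}

#' Validate assessments against an instrument
#'
#' Checks a table of assessments (one row per trial and rater, item scores
#' in columns `item_1`, `item_2`, ...) against an instrument definition.
#' Violations are returned as data, not raised as errors, so a batch of
#' forms can be screened in one pass.  Checked per row:
#'
#' * every instrument item has a response (no missing scores),
#' * every response uses one of the item's allowed score levels,
#' * when the instrument carries the phase item (item 1 with levels
#'   \{1, 3\}) and `check_phase = TRUE`, the item-1 score is 3 for a
#'   phase I trial and 1 otherwise.  Phase is objective, so a mismatch is
#'   a recording error; set `check_phase = FALSE` to relax this for
#'   instruments where item 1 has been repurposed.
#'
#' @param assessments data frame with columns `trial_id`, `centre_id`,
#'   `trial_type`, `phase`, `rater_id` and one `item_<id>` column per
#'   instrument item.
#' @param instrument a `pharmcat_instrument`; default [default_instrument()].
#' @param check_phase enforce consistency between `phase` and item 1
#'   (default `TRUE`).
#' @return Data frame of violations with columns `row`, `trial_id`,
#'   `rater_id`, `item_id`, `problem`; zero rows when everything is valid.
#' @export
validate_assessments <- function(assessments,
                                 instrument = default_instrument(),
                                 check_phase = TRUE) {
  stopifnot_cols(assessments,
                 c("trial_id", "centre_id", "trial_type", "phase", "rater_id"),
                 "assessment table")
  n <- nrow(assessments)
  out <- list()
  add <- function(row, item_id, problem) {
    out[[length(out) + 1]] <<- data.frame(
      row = row,
      trial_id = assessments$trial_id[row],
      rater_id = assessments$rater_id[row],
      item_id = item_id,
      problem = problem,
      stringsAsFactors = FALSE
    )
  }
  for (it in instrument$items) {
    col <- paste0("item_", it$item_id)
    allowed <- allowed_scores(it)
    allowed_str <- paste0("{", paste(allowed, collapse = ","), "}")
    if (!col %in% names(assessments)) {
      for (r in seq_len(n)) add(r, it$item_id,
                                sprintf("missing item %d", it$item_id))
      next
    }
    sc <- assessments[[col]]
    for (r in seq_len(n)) {
      if (is.na(sc[r])) {
        add(r, it$item_id, sprintf("missing item %d", it$item_id))
      } else if (!sc[r] %in% allowed) {
        add(r, it$item_id,
            sprintf("score %s not in %s", sc[r], allowed_str))
      }
    }
  }
  if (check_phase && has_phase_item(instrument) &&
      "item_1" %in% names(assessments)) {
    expected <- ifelse(assessments$phase == "I", 3L, 1L)
    sc <- assessments$item_1
    for (r in seq_len(n)) {
      if (!is.na(sc[r]) && sc[r] %in% c(1L, 3L) && sc[r] != expected[r]) {
        add(r, 1L,
            sprintf("item 1 score %d inconsistent with phase %s (expected %d)",
                    sc[r], assessments$phase[r], expected[r]))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(row = integer(), trial_id = character(),
                      rater_id = character(), item_id = integer(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$row, res$item_id), , drop = FALSE]
}

#' Total scores for validated assessments
#'
#' Sums the item scores of each assessment row.  The total of a trial
#' assessment is the plain arithmetic sum of its 15 item scores; for the
#' default instrument it lies between 15 and 44 points.
#'
#' @inheritParams validate_assessments
#' @param check validate before scoring (default `TRUE`); with invalid rows
#'   the call fails and the error message lists the violations.
#' @return Data frame with columns `trial_id`, `centre_id`, `trial_type`,
#'   `phase`, `rater_id`, `total`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_config(seed = 1))
#' head(total_scores(cohort$assessments))
total_scores <- function(assessments, instrument = default_instrument(),
                         check = TRUE, check_phase = TRUE) {
  if (check) {
    v <- validate_assessments(assessments, instrument,
                              check_phase = check_phase)
    if (nrow(v) > 0) {
      shown <- utils::head(v, 5)
      pc_stop(paste0(
        sprintf("%d validation violation(s); first %d:\n", nrow(v), nrow(shown)),
        paste(sprintf("  row %d (trial %s, rater %s): %s",
                      shown$row, shown$trial_id, shown$rater_id, shown$problem),
              collapse = "\n")
      ), "pharmcat_validation_error")
    }
  }
  cols <- item_columns(instrument)
  stopifnot_cols(assessments, cols, "assessment table")
  totals <- as.integer(rowSums(as.matrix(assessments[, cols, drop = FALSE])))
  data.frame(
    trial_id = assessments$trial_id,
    centre_id = assessments$centre_id,
    trial_type = assessments$trial_type,
    phase = assessments$phase,
    rater_id = assessments$rater_id,
    total = totals,
    stringsAsFactors = FALSE
  )
}

#' Minimum and maximum achievable total score
#'
#' The extreme totals over all admissible response combinations: the sum of
#' each item's lowest level and the sum of each item's highest level.  For
#' the default instrument this is 15 and 44 points.
#'
#' @param instrument a `pharmcat_instrument`.
#' @return Named integer vector `c(min_total, max_total)`.
#' @export
score_bounds <- function(instrument = default_instrument()) {
  mins <- vapply(instrument$items, function(it) min(it$levels$score), integer(1))
  maxs <- vapply(instrument$items, function(it) max(it$levels$score), integer(1))
  c(min_total = sum(mins), max_total = sum(maxs))
}

#' All achievable total scores
#'
#' The exact set of totals reachable by some admissible combination of item
#' levels, computed by dynamic programming over items (the set of partial
#' sums is folded with each item's level set in turn).  Useful for checking
#' that a proposed category cut-off corresponds to a score the instrument
#' can actually produce.
#'
#' @param instrument a `pharmcat_instrument`.
#' @return Sorted integer vector of achievable totals.
#' @export
#' @examples
#' tot <- achievable_totals(default_instrument())
#' range(tot)  # 15 44
achievable_totals <- function(instrument = default_instrument()) {
  sums <- 0L
  for (it in instrument$items) {
    sums <- unique(as.vector(outer(sums, unique(it$levels$score), `+`)))
  }
  sort(as.integer(sums))
}
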