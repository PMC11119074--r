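# shared fixtures and independent oracles

# independent textbook form of linear weighted kappa:
# agreement weights 1 - |i-j|/(k-1), kappa = (po - pe) / (1 - pe)
oracle_linear_kappa <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  n <- sum(counts)
  w_agree <- 1 - abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  p <- counts / n
  po <- sum(w_agree * p)
  pe <- sum(w_agree * outer(rowSums(p), colSums(p)))
  (po - pe) / (1 - pe)
}

# exhaustive enumeration of achievable totals (oracle for the DP)
enumerate_totals <- function(instrument) {
  level_sets <- lapply(instrument$items, function(it) it$levels$score)
  grid <- expand.grid(level_sets, KEEP.OUT.ATTRS = FALSE)
  sort(unique(as.integer(rowSums(grid))))
}

# a random instrument with small level sets, for property tests
random_small_instrument <- function(n_items = 4) {
  items <- lapply(seq_len(n_items), function(i) {
    n_lev <- sample(2:4, 1)
    scores <- sort(sample(0:3, n_lev))
    list(item_id = as.integer(i), section = sample(c(
      "study_design", "drug_management", "drug_preparation"), 1),
      label = paste0("random item ", i),
      levels = data.frame(score = scores,
                          description = paste0("level ", scores)))
  })
  load_instrument(list(name = "random", items = items))
}

# one valid assessment row for an instrument: each item at a chosen level
# index (1 = lowest); phase picked consistently with item 1 when present
make_assessment <- function(instrument, level_index = 1,
                            trial_id = "T1", rater_id = "A",
                            phase = NULL) {
  ids <- vapply(instrument$items, `[[`, integer(1), "item_id")
  scores <- vapply(seq_along(ids), function(j) {
    lev <- sort(instrument$items[[j]]$levels$score)
    i <- if (length(level_index) == 1) level_index else level_index[j]
    lev[min(i, length(lev))]
  }, integer(1))
  if (is.null(phase) && 1L %in% ids) {
    phase <- if (scores[match(1L, ids)] == 3L) "I" else "III"
  } else if (is.null(phase)) {
    phase <- "III"
  }
  row <- data.frame(trial_id = trial_id, centre_id = "centre_1",
                    trial_type = "oncology", phase = phase,
                    rater_id = rater_id, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) row[[paste0("item_", ids[j])]] <- scores[j]
  row
}

# n random valid assessments against the default instrument, plus the
# per-row sums recorded at generation time (scoring oracle)
random_valid_assessments <- function(n, instrument = default_instrument()) {
  ids <- vapply(instrument$items, `[[`, integer(1), "item_id")
  rows <- lapply(seq_len(n), function(i) {
    phase <- sample(c("I", "II", "III"), 1)
    scores <- vapply(seq_along(ids), function(j) {
      if (ids[j] == 1L) {
        if (phase == "I") 3L else 1L
      } else {
        sample(instrument$items[[j]]$levels$score, 1)
      }
    }, integer(1))
    row <- data.frame(trial_id = sprintf("T%03d", i),
                      centre_id = sample(c("centre_1", "centre_2"), 1),
                      trial_type = sample(c("oncology", "haematology"), 1),
                      phase = phase, rater_id = "A",
                      stringsAsFactors = FALSE)
    for (j in seq_along(ids)) row[[paste0("item_", ids[j])]] <- scores[j]
    attr(row, "oracle_total") <- sum(scores)
    row
  })
  df <- do.call(rbind, rows)
  attr(df, "oracle_totals") <- vapply(rows, attr, integer(1), "oracle_total")
  df
}

# paired totals replicating the published discrepancy breakdown
# (46 identical, 11 differ by 1, 2 by 2, 1 by 4), constructed so that all
# discrepant pairs stay within one complexity category under (19, 25)
study_like_pairs <- function() {
  base_same <- rep(c(16, 18, 21, 23, 27, 30), length.out = 46)
  data.frame(
    trial_id = sprintf("T%03d", 1:60),
    total_a = c(base_same, rep(21, 11), rep(27, 2), 27),
    total_b = c(base_same, rep(22, 11), rep(29, 2), 31)
  )
}

random_crossclass <- function() {
  m <- matrix(sample(0:30, 9, replace = TRUE), 3, 3)
  if (sum(m) == 0) m[2, 2] <- 1
  # ensure defined denominator: at least two categories used overall
  if (sum(rowSums(m) > 0) == 1 && sum(colSums(m) > 0) == 1) m[1, 2] <- 1
  m
}
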