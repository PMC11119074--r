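#' Default per-item response model
#'
#' Categorical distributions over each item's allowed levels (items 2--15;
#' item 1 is determined by trial phase).  The probabilities are calibrated
#' so that a generated cohort has a mean total of about 22.9 points with
#' totals concentrated in the high teens to low thirties, the profile
#' typical of sponsored oncology/haematology portfolios: mostly injectable
#' drugs, frequent IWRS involvement, occasional deep-freeze storage,
#' blinding in a minority of trials, and rare fully personalised
#' administration.
#'
#' @return Named list `item_2` ... `item_15`, each a list with `scores`
#'   (ascending allowed levels) and `probs`.
#' @export
default_item_model <- function() {
  list(
    item_2  = list(scores = c(2L, 3L),     probs = c(0.40, 0.60)),
    item_3  = list(scores = c(1L, 2L, 3L), probs = c(0.35, 0.40, 0.25)),
    item_4  = list(scores = c(1L, 2L, 3L), probs = c(0.55, 0.30, 0.15)),
    item_5  = list(scores = c(1L, 2L, 3L), probs = c(0.55, 0.25, 0.20)),
    item_6  = list(scores = c(2L, 3L),     probs = c(0.80, 0.20)),
    item_7  = list(scores = c(1L, 2L, 3L), probs = c(0.55, 0.35, 0.10)),
    item_8  = list(scores = c(1L, 2L),     probs = c(0.75, 0.25)),
    item_9  = list(scores = c(1L, 3L),     probs = c(0.85, 0.15)),
    item_10 = list(scores = c(1L, 3L),     probs = c(0.65, 0.35)),
    item_11 = list(scores = c(1L, 3L),     probs = c(0.65, 0.35)),
    item_12 = list(scores = c(1L, 2L, 3L), probs = c(0.65, 0.25, 0.10)),
    item_13 = list(scores = c(1L, 2L, 3L), probs = c(0.45, 0.40, 0.15)),
    item_14 = list(scores = c(0L, 2L, 3L), probs = c(0.70, 0.15, 0.15)),
    item_15 = list(scores = c(0L, 3L),     probs = c(0.90, 0.10))
  )
}

#' Study-like cohort configuration
#'
#' Configuration reproducing the composition of the development cohort:
#' 60 trials split 40/20 between two centres, 39 oncology and 21
#' haematology trials, and 6/18/36 trials in phases I/II/III.  Each trial
#' is assessed by two raters; rater B's item responses are independently
#' perturbed to an adjacent allowed level with probability `p_perturb`,
#' whose default solves \eqn{(1 - p)^{14} = 0.77} so that the expected
#' share of trials with identical totals is 77% (item 1 is never
#' perturbed; the 14 remaining items each have an adjacent level
#' available, so any perturbation changes the total).
#'
#' @param seed integer seed; required, there is no silent global
#'   randomness.
#' @param n_trials number of trials (default 60).
#' @param p_perturb per-item perturbation probability for rater B
#'   (default `1 - 0.77^(1/14)`, about 0.0185).
#' @return A list of class `pharmcat_cohort_config` with fields
#'   `n_trials`, `centre_mix`, `type_mix`, `phase_mix`, `item_model`,
#'   `p_perturb`, `seed`.
#' @export
#' @examples
#' cfg <- default_study_config(seed = 1)
#' cfg$phase_mix  # 0.1 0.3 0.6
default_study_config <- function(seed, n_trials = 60L,
                                 p_perturb = 1 - 0.77^(1 / 14)) {
  if (missing(seed) || !is_count(seed)) {
    pc_stop("a single integer 'seed' is required", "pharmcat_schema_error")
  }
  structure(list(
    n_trials = as.integer(n_trials),
    centre_mix = c(centre_1 = 40 / 60, centre_2 = 20 / 60),
    type_mix = c(oncology = 39 / 60, haematology = 21 / 60),
    phase_mix = c(I = 6 / 60, II = 18 / 60, III = 36 / 60),
    item_model = default_item_model(),
    p_perturb = p_perturb,
    seed = as.integer(seed)
  ), class = "pharmcat_cohort_config")
}

validate_config <- function(config, instrument) {
  for (field in c("n_trials", "centre_mix", "type_mix", "phase_mix",
                  "item_model", "p_perturb", "seed")) {
    if (is.null(config[[field]])) {
      pc_stop(sprintf("cohort config: missing field '%s'", field),
              "pharmcat_schema_error")
    }
  }
  if (!is_count(config$n_trials) || config$n_trials < 1) {
    pc_stop("cohort config: 'n_trials' must be a positive integer",
            "pharmcat_schema_error")
  }
  if (!is_count(config$seed)) {
    pc_stop("cohort config: 'seed' must be a single integer",
            "pharmcat_schema_error")
  }
  for (mix in c("centre_mix", "type_mix", "phase_mix")) {
    m <- config[[mix]]
    if (is.null(names(m)) || any(m < 0) || abs(sum(m) - 1) > 1e-8) {
      pc_stop(sprintf("cohort config: '%s' must be named non-negative proportions summing to 1", mix),
              "pharmcat_schema_error")
    }
  }
  if (!is.numeric(config$p_perturb) || config$p_perturb < 0 ||
      config$p_perturb > 1) {
    pc_stop("cohort config: 'p_perturb' must be in [0, 1]",
            "pharmcat_schema_error")
  }
  ids <- item_ids(instrument)
  model_ids <- if (has_phase_item(instrument)) setdiff(ids, 1L) else ids
  for (id in model_ids) {
    key <- paste0("item_", id)
    m <- config$item_model[[key]]
    if (is.null(m)) {
      pc_stop(sprintf("cohort config: item model missing '%s'", key),
              "pharmcat_schema_error")
    }
    allowed <- allowed_scores(instrument$items[[match(id, ids)]])
    if (!all(m$scores %in% allowed)) {
      pc_stop(sprintf("cohort config: '%s' model puts mass on disallowed score(s) %s",
                      key, paste(setdiff(m$scores, allowed), collapse = ",")),
              "pharmcat_schema_error")
    }
    if (length(m$probs) != length(m$scores) || any(m$probs < 0) ||
        abs(sum(m$probs) - 1) > 1e-8) {
      pc_stop(sprintf("cohort config: '%s' probabilities malformed", key),
              "pharmcat_schema_error")
    }
  }
  invisible(config)
}

# allocate exact stratum counts for n units from proportions
# (largest-remainder rounding), then shuffle assignment
allocate_mix <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(short)]] <- counts[frac_order[seq_len(short)]] + 1
  }
  sample(rep(names(mix), times = counts))
}

#' Generate a synthetic two-rater assessment cohort
#'
#' Simulates the study design: each trial receives independent assessments
#' from raters "A" and "B".  Rater A's item responses are drawn from the
#' config's per-item categorical model (item 1 is set deterministically
#' from the trial's phase).  Rater B starts from rater A's responses and,
#' for every item except item 1, moves to an adjacent allowed level with
#' probability `p_perturb` (direction uniform when two neighbours exist).
#' Item 1 is never perturbed because trial phase is objective.
#'
#' Disagreement is modelled at item level rather than by adding noise to
#' totals, so generated data exercise the validation and scoring paths.
#' The expected fraction of trials with identical totals has the closed
#' form \eqn{(1 - p)^m} where \eqn{m} is the number of perturbable items
#' with at least one adjacent level available (every perturbation lands on
#' a different allowed score, so it always changes the total); see
#' [expected_exact_agreement()].
#'
#' Random draws (response draws, one perturbation uniform and one
#' direction uniform per trial and item) are consumed in a fixed order
#' independent of `p_perturb`, so cohorts generated from the same seed at
#' different `p_perturb` values share common random numbers: raising `p`
#' can only add perturbations, never remove or redirect one.
#'
#' @param config a cohort configuration, see [default_study_config()].
#' @param instrument a `pharmcat_instrument`; default [default_instrument()].
#' @return An object of class `pharmcat_cohort`: list with `assessments`
#'   (data frame, two rows per trial, raters "A" and "B"), `config`,
#'   `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_config(seed = 7))
#' nrow(cohort$assessments)  # 120
generate_cohort <- function(config, instrument = default_instrument()) {
  validate_config(config, instrument)
  set.seed(config$seed)
  n <- config$n_trials
  ids <- item_ids(instrument)
  n_items <- length(ids)

  centre <- allocate_mix(config$centre_mix, n)
  type <- allocate_mix(config$type_mix, n)
  phase <- allocate_mix(config$phase_mix, n)

  scores_a <- matrix(0L, nrow = n, ncol = n_items,
                     dimnames = list(NULL, paste0("item_", ids)))
  phase_item <- has_phase_item(instrument)
  for (j in seq_len(n_items)) {
    key <- paste0("item_", ids[j])
    if (phase_item && ids[j] == 1L) {
      scores_a[, j] <- ifelse(phase == "I", 3L, 1L)
    } else {
      m <- config$item_model[[key]]
      scores_a[, j] <- sample(m$scores, n, replace = TRUE, prob = m$probs)
    }
  }

  scores_b <- scores_a
  for (j in seq_len(n_items)) {
    if (phase_item && ids[j] == 1L) next
    lev <- allowed_scores(instrument$items[[j]])
    # always draw both uniforms so the stream is p-independent (CRN)
    u <- stats::runif(n)
    dir_u <- stats::runif(n)
    hit <- u < config$p_perturb
    if (!any(hit)) next
    pos <- match(scores_b[hit, j], lev)
    L <- length(lev)
    step <- ifelse(pos == 1L, 1L,
                   ifelse(pos == L, -1L,
                          ifelse(dir_u[hit] < 0.5, -1L, 1L)))
    scores_b[hit, j] <- lev[pos + step]
  }

  trial_id <- sprintf("T%03d", seq_len(n))
  meta <- data.frame(trial_id = trial_id, centre_id = centre,
                     trial_type = type, phase = phase,
                     stringsAsFactors = FALSE)
  mk <- function(rater, m) {
    cbind(meta, rater_id = rater,
          as.data.frame(m, stringsAsFactors = FALSE))
  }
  df <- rbind(mk("A", scores_a), mk("B", scores_b))
  df <- df[order(match(df$trial_id, trial_id), df$rater_id), ]
  rownames(df) <- NULL

  structure(list(assessments = df, config = config, seed = config$seed),
            class = "pharmcat_cohort")
}

#' @export
print.pharmcat_cohort <- function(x, ...) {
  cat(sprintf("<pharmcat_cohort> %d trials x 2 raters (seed %d, p_perturb %.4f)\n",
              x$config$n_trials, x$seed, x$config$p_perturb))
  invisible(x)
}

#' Expected exact-agreement fraction under the perturbation model
#'
#' Closed form for the probability that rater B's total equals rater A's:
#' every perturbable item (any item except the phase item that has at
#' least one adjacent allowed level, i.e. at least two levels) changes the
#' total whenever it is perturbed, so the pair agrees exactly iff no item
#' is perturbed: \eqn{P = (1 - p)^m} with \eqn{m} the number of
#' perturbable items (14 for the default instrument).
#'
#' @param config a cohort configuration.
#' @param instrument a `pharmcat_instrument`.
#' @return Expected percent of trials with identical totals (0--100).
#' @export
expected_exact_agreement <- function(config,
                                     instrument = default_instrument()) {
  ids <- item_ids(instrument)
  perturbable <- if (has_phase_item(instrument)) setdiff(ids, 1L) else ids
  m <- sum(vapply(perturbable, function(id) {
    nrow(instrument$items[[match(id, ids)]]$levels) >= 2
  }, logical(1)))
  100 * (1 - config$p_perturb)^m
}
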