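test_that("pair_scores pairs the two raters per trial and rejects odd trials", {
  scores <- data.frame(
    trial_id = c("T1", "T1", "T2", "T2"),
    rater_id = c("A", "B", "A", "B"),
    total = c(20L, 21L, 30L, 30L))
  p <- pair_scores(scores)
  expect_identical(p$trial_id, c("T1", "T2"))
  expect_identical(p$total_a, c(20L, 30L))
  expect_identical(p$total_b, c(21L, 30L))

  expect_error(pair_scores(scores[-1, ]), "exactly 2 raters",
               class = "pharmcat_data_error")
})

test_that("score_diff_summary reproduces the published discrepancy breakdown", {
  pairs <- study_like_pairs()  # 46 identical, 11 off by 1, 2 by 2, 1 by 4
  s <- score_diff_summary(pairs)
  expect_identical(s$n, 60L)
  expect_identical(s$n_exact, 46L)
  expect_equal(s$mean_abs_diff, 19 / 60)            # 0.3166... -> "0.32"
  expect_equal(round_half_up(s$mean_abs_diff), 0.32)
  expect_equal(round_half_up(s$percent_exact), 76.67)
  expect_equal(round_half_up(s$percent_exact, 0), 77)
  expect_identical(s$diff_histogram,
                   c("0" = 46L, "1" = 11L, "2" = 2L, "4" = 1L))

  ident <- data.frame(total_a = rep(22L, 5), total_b = rep(22L, 5))
  s <- score_diff_summary(ident)
  expect_equal(s$percent_exact, 100)
  expect_equal(s$mean_abs_diff, 0)
  expect_identical(s$diff_histogram, c("0" = 5L))

  expect_error(score_diff_summary(data.frame(total_a = integer(),
                                             total_b = integer())),
               class = "pharmcat_insufficient_data")
})

test_that("cross_classification counts category pairs including boundary straddles", {
  cs <- cutoff_set(19, 25)
  diag3 <- data.frame(total_a = c(15, 20, 26), total_b = c(15, 21, 30))
  cc <- cross_classification(diag3, cs)
  expect_identical(unname(diag(cc$counts)), c(1L, 1L, 1L))
  expect_identical(sum(cc$counts), 3L)

  straddle <- data.frame(total_a = 19, total_b = 20)
  cc <- cross_classification(straddle, cs)
  expect_identical(cc$counts["low", "medium"], 1L)
  expect_identical(sum(cc$counts), 1L)
})

test_that("linear weighted kappa matches hand-computed and limiting cases", {
  expect_equal(linear_weighted_kappa(diag(c(20, 20, 20))), 1)

  # observed == chance expectation (all margins 3, n = 9) -> exactly 0
  expect_equal(linear_weighted_kappa(matrix(1L, 3, 3)), 0)

  # hand evaluation of the formula for a banded table, n = 80:
  # sum w*counts = 20 * 0.5 = 10; sum w * r_i c_j = 2750
  # kappa = 1 - (10 * 80) / 2750 = 0.70909...
  banded <- matrix(c(20, 5, 0, 5, 20, 5, 0, 5, 20), 3, 3, byrow = TRUE)
  expect_equal(linear_weighted_kappa(banded), 1 - 800 / 2750,
               tolerance = 1e-12)

  # undefined when both raters use a single category throughout
  one_cell <- matrix(c(9, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(linear_weighted_kappa(one_cell),
               class = "pharmcat_undefined_kappa")
})

test_that("kappa equals the textbook oracle on random tables and respects symmetry", {
  set.seed(505)
  for (i in 1:300) {
    m <- random_crossclass()
    k <- linear_weighted_kappa(m)
    expect_equal(k, oracle_linear_kappa(m), tolerance = 1e-12)
    expect_equal(linear_weighted_kappa(t(m)), k, tolerance = 1e-12)
    expect_lte(k, 1)
    # kappa = 1 iff all mass on the diagonal
    if (sum(m) > 0 && sum(m[row(m) != col(m)]) == 0) {
      expect_equal(k, 1)
    } else if (sum(m[row(m) != col(m)]) > 0) {
      expect_lt(k, 1)
    }
  }
})

test_that("agreement_report assembles all components coherently", {
  cs <- study_cutoffs()
  pairs <- study_like_pairs()
  rep_ <- agreement_report(pairs, cs)
  expect_identical(rep_$n_trials, 60L)
  expect_identical(rep_$n_exact, 46L)
  # all discrepant pairs were constructed within-category
  expect_identical(rep_$same_category_count, 60L)
  expect_equal(rep_$weighted_kappa, 1)
  expect_identical(rep_$n_exact, unname(rep_$diff_histogram["0"]))
  expect_identical(sum(rep_$diff_histogram), rep_$n_trials)

  # permutation invariance: shuffling pair order changes nothing
  set.seed(606)
  shuf <- agreement_report(pairs[sample(nrow(pairs)), ], cs)
  expect_equal(shuf[c("n_trials", "n_exact", "percent_exact",
                      "mean_abs_diff", "same_category_count",
                      "weighted_kappa")],
               rep_[c("n_trials", "n_exact", "percent_exact",
                      "mean_abs_diff", "same_category_count",
                      "weighted_kappa")])
  expect_identical(shuf$cross_class$counts, rep_$cross_class$counts)

  # single identical pair
  one <- agreement_report(data.frame(total_a = 22, total_b = 22), cs)
  expect_identical(one$n_trials, 1L)
  expect_equal(one$percent_exact, 100)
  expect_true(one$perfect_agreement)  # single category -> kappa undefined
  expect_true(is.na(one$weighted_kappa))

  # raw-total kappa flag: high but below 1 with the 14 discrepant pairs
  raw <- agreement_report(pairs, cs, kappa_on = "total")
  expect_lt(raw$weighted_kappa, 1)
  expect_gt(raw$weighted_kappa, 0.8)
})

test_that("mean_abs_diff is zero exactly when agreement is exact", {
  set.seed(707)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    pairs <- data.frame(total_a = sample(15:33, n, replace = TRUE))
    pairs$total_b <- pairs$total_a +
      sample(c(0, 0, 0, 1, -1, 2), n, replace = TRUE)
    s <- score_diff_summary(pairs)
    expect_identical(s$mean_abs_diff == 0, s$percent_exact == 100)
  }
})
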