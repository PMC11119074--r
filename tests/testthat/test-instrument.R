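test_that("default instrument matches the published item/level structure", {
  inst <- default_instrument()
  expect_s3_class(inst, "pharmcat_instrument")
  expect_length(inst$items, 15)
  expect_identical(vapply(inst$items, `[[`, integer(1), "item_id"), 1:15)

  level_sets <- lapply(inst$items, function(it) sort(it$levels$score))
  expected <- list(
    c(1L, 3L),              # 1 study phase
    c(2L, 3L),              # 2 type of drug
    1:3, 1:3, 1:3,          # 3-5
    c(2L, 3L),              # 6 pharmacy staff
    1:3,                    # 7 storage
    c(1L, 2L),              # 8 special material
    c(1L, 3L), c(1L, 3L), c(1L, 3L),  # 9-11
    1:3, 1:3,               # 12-13
    c(0L, 2L, 3L),          # 14 preparation procedure
    c(0L, 3L)               # 15 personalised administration
  )
  expect_identical(level_sets, expected)

  it1 <- inst$items[[1]]
  expect_identical(it1$levels$description[it1$levels$score == 3], "phase I")
  sections <- vapply(inst$items, `[[`, character(1), "section")
  expect_identical(as.integer(table(factor(sections, levels = c(
    "study_design", "drug_management", "drug_preparation")))),
    c(5L, 6L, 4L))
})

test_that("load_instrument round-trips and rejects malformed configs", {
  inst <- default_instrument()
  # round-trip through a JSON file equals the packaged default
  tmp <- withr::local_tempfile(fileext = ".json")
  file.copy(system.file("extdata", "pharmcat_instrument.json",
                        package = "pharmcat"), tmp)
  expect_identical(load_instrument(tmp), inst)

  one_item <- list(name = "mini", items = list(
    list(item_id = 1L, section = "drug_preparation", label = "solo",
         levels = data.frame(score = c(0L, 3L),
                             description = c("none", "full")))))
  mini <- load_instrument(one_item)
  expect_length(mini$items, 1)
  expect_identical(sort(mini$items[[1]]$levels$score), c(0L, 3L))

  dup <- list(name = "dup", items = list(
    list(item_id = 4L, section = "study_design", label = "a",
         levels = data.frame(score = c(1L, 2L), description = c("x", "y"))),
    list(item_id = 4L, section = "study_design", label = "b",
         levels = data.frame(score = c(1L, 2L), description = c("x", "y")))))
  expect_error(load_instrument(dup), "duplicate item_id 4",
               class = "pharmcat_schema_error")

  empty_levels <- list(name = "e", items = list(
    list(item_id = 1L, section = "study_design", label = "a",
         levels = list())))
  expect_error(load_instrument(empty_levels), "levels",
               class = "pharmcat_schema_error")

  bad_score <- list(name = "b", items = list(
    list(item_id = 1L, section = "study_design", label = "a",
         levels = data.frame(score = c(1L, 5L), description = c("x", "y")))))
  expect_error(load_instrument(bad_score), "0..3",
               class = "pharmcat_schema_error")

  single_level <- list(name = "s", items = list(
    list(item_id = 1L, section = "study_design", label = "a",
         levels = data.frame(score = 2L, description = "only"))))
  expect_error(load_instrument(single_level), "at least 2 levels",
               class = "pharmcat_schema_error")
})

test_that("validate_assessments flags disallowed, missing and phase-inconsistent scores", {
  inst <- default_instrument()
  good <- make_assessment(inst, level_index = 1)
  expect_identical(nrow(validate_assessments(good, inst)), 0L)

  bad <- good
  bad$item_1 <- 2L
  v <- validate_assessments(bad, inst)
  expect_identical(v$item_id, 1L)
  expect_match(v$problem, "score 2 not in \\{1,3\\}")

  incomplete <- good[, setdiff(names(good), "item_15")]
  v <- validate_assessments(incomplete, inst)
  expect_identical(v$item_id, 15L)
  expect_match(v$problem, "missing item 15")

  # item 1 must track phase: phase I trial scored 1 is flagged ...
  mismatch <- good
  mismatch$phase <- "I"   # item_1 stays 1
  v <- validate_assessments(mismatch, inst)
  expect_match(v$problem, "inconsistent with phase I")
  # ... unless the phase check is explicitly relaxed
  expect_identical(
    nrow(validate_assessments(mismatch, inst, check_phase = FALSE)), 0L)
})

test_that("total_score is the arithmetic sum and spans 15..44", {
  inst <- default_instrument()
  expect_identical(total_scores(make_assessment(inst, 1))$total, 15L)
  expect_identical(
    total_scores(make_assessment(inst, 10))$total, 44L)

  # worked example: explicit response vector summing to 23
  resp <- c(1L, 3L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 3L, 1L, 2L, 2L, 0L, 0L)
  a <- make_assessment(inst, 1)
  for (j in 1:15) a[[paste0("item_", j)]] <- resp[j]
  expect_identical(total_scores(a)$total, 23L)

  bad <- make_assessment(inst, 1)
  bad$item_2 <- 0L
  expect_error(total_scores(bad), "violation",
               class = "pharmcat_validation_error")
})

test_that("totals equal the recorded per-row sums for random valid assessments", {
  set.seed(101)
  df <- random_valid_assessments(80)
  got <- total_scores(df)$total
  expect_identical(got, attr(df, "oracle_totals"))
  expect_true(all(got >= 15 & got <= 44))
})

test_that("raising any single response strictly increases the total", {
  set.seed(202)
  inst <- default_instrument()
  df <- random_valid_assessments(10)
  for (r in seq_len(nrow(df))) {
    base <- total_scores(df[r, , drop = FALSE], check = FALSE)$total
    for (it in inst$items) {
      col <- paste0("item_", it$item_id)
      lev <- sort(it$levels$score)
      pos <- match(df[[col]][r], lev)
      if (pos < length(lev)) {
        bumped <- df[r, , drop = FALSE]
        bumped[[col]] <- lev[pos + 1]
        expect_gt(total_scores(bumped, check = FALSE)$total, base)
      }
    }
  }
})

test_that("score_bounds and achievable_totals agree with enumeration", {
  inst <- default_instrument()
  expect_identical(score_bounds(inst),
                   c(min_total = 15L, max_total = 44L))

  solo <- load_instrument(list(name = "solo", items = list(
    list(item_id = 1L, section = "drug_preparation", label = "a",
         levels = data.frame(score = c(0L, 3L), description = c("x", "y"))))))
  expect_identical(achievable_totals(solo), c(0L, 3L))
  expect_identical(score_bounds(solo), c(min_total = 0L, max_total = 3L))

  duo <- load_instrument(list(name = "duo", items = list(
    list(item_id = 1L, section = "study_design", label = "a",
         levels = data.frame(score = c(1L, 2L), description = c("x", "y"))),
    list(item_id = 2L, section = "study_design", label = "b",
         levels = data.frame(score = c(1L, 3L), description = c("x", "y"))))))
  expect_identical(score_bounds(duo), c(min_total = 2L, max_total = 5L))

  at <- achievable_totals(inst)
  expect_true(all(c(15L, 44L) %in% at))
  expect_identical(unname(score_bounds(inst)), range(at))

  # dynamic programming vs exhaustive enumeration on random instruments
  set.seed(303)
  for (i in 1:100) {
    ri <- random_small_instrument(sample(2:5, 1))
    expect_identical(achievable_totals(ri), enumerate_totals(ri))
    expect_identical(unname(score_bounds(ri)), range(achievable_totals(ri)))
  }
})
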