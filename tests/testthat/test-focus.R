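focus_fixture <- function() {
  tab <- simulate_rating_table(
    6, 10, list(rater_profile("resnet34", 0.8),
                rater_profile("vgg16", 0.7)), seed = 44)
  focus <- simulate_focus_ratings(tab, seed = 45)
  stages <- tibble::tibble(frame_id = tab$frame_id, stage = tab$reference)
  list(tab = tab, focus = focus, stages = stages)
}

test_that("rating proportions sum to 1 per model-stage cell", {
  f <- focus_fixture()
  props <- rating_proportions(f$focus, f$stages)
  sums <- props |>
    dplyr::group_by(.data$model_id, .data$stage) |>
    dplyr::summarise(s = sum(.data$proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # overall rows (stage NA) exist for each model
  expect_identical(sum(is.na(props$stage)), 6L)  # 2 models x 3 levels
})

test_that("rating proportions reproduce direct counts", {
  ratings <- tibble::tibble(
    frame_id = sprintf("F%02d", 1:10), model_id = "m",
    rating = c(rep("good", 6), rep("intermediate", 3), "poor"))
  stages <- stats::setNames(rep(4L, 10), ratings$frame_id)
  props <- rating_proportions(ratings, stages)
  by_level <- props[props$stage %in% 4L, ]
  expect_equal(by_level$proportion[by_level$rating == "good"], 0.6)
  expect_equal(by_level$proportion[by_level$rating == "intermediate"], 0.3)
  expect_equal(by_level$proportion[by_level$rating == "poor"], 0.1)
  # all-good: proportion 1 at the stage
  all_good <- rating_proportions(
    tibble::tibble(frame_id = ratings$frame_id, model_id = "m",
                   rating = "good"), stages)
  expect_equal(all_good$proportion[all_good$rating == "good" &
                                     !is.na(all_good$stage)], 1)
})

test_that("frames without a stage raise a keyed error", {
  ratings <- tibble::tibble(frame_id = "F99", model_id = "m", rating = "good")
  expect_error(rating_proportions(ratings, c(F01 = 1L)),
               "F99", class = "embryoxai_data_error")
})

test_that("model comparison on a rating level reproduces the chi-squared result", {
  frames <- sprintf("F%03d", 1:245)
  ratings <- dplyr::bind_rows(
    tibble::tibble(frame_id = frames, model_id = "resnet34",
                   rating = c(rep("good", 218), rep("poor", 27))),
    tibble::tibble(frame_id = frames, model_id = "vgg16",
                   rating = c(rep("good", 145), rep("poor", 100))))
  ts <- compare_models_on_rating(ratings, "resnet34", "vgg16", "good")
  expect_lt(ts$p_value, 0.001)
  direct <- chi_square_proportions(218, 245, 145, 245)
  expect_equal(ts$statistic, direct$statistic, tolerance = 1e-12)
  # identical rating vectors: p ~ 1
  same <- dplyr::bind_rows(
    tibble::tibble(frame_id = frames, model_id = "a",
                   rating = rep(c("good", "poor"), length.out = 245)),
    tibble::tibble(frame_id = frames, model_id = "b",
                   rating = rep(c("good", "poor"), length.out = 245)))
  expect_gt(compare_models_on_rating(same, "a", "b", "good")$p_value, 0.99)
})

test_that("extreme rating/accuracy coupling is detected by the exact test", {
  frames <- sprintf("F%02d", 1:60)
  ratings <- tibble::tibble(frame_id = frames, model_id = "m",
                            rating = c(rep("good", 30), rep("poor", 30)))
  correctness <- tibble::tibble(frame_id = frames, model_id = "m",
                                correct = c(rep(TRUE, 30), rep(FALSE, 30)))
  stages <- stats::setNames(rep(5L, 60), frames)
  out <- accuracy_by_focus(ratings, correctness, stages)
  expect_lt(out$tests$p_value, 1e-6)
})

test_that("cells below the minimum size are flagged and excluded from tests", {
  frames <- sprintf("F%02d", 1:12)
  ratings <- tibble::tibble(frame_id = frames, model_id = "m",
                            rating = c(rep("good", 10), "poor", "poor"))
  correctness <- tibble::tibble(frame_id = frames, model_id = "m",
                                correct = rep(TRUE, 12))
  stages <- stats::setNames(rep(3L, 12), frames)
  out <- accuracy_by_focus(ratings, correctness, stages)
  poor_cell <- out$cells[out$cells$rating == "poor", ]
  expect_true(poor_cell$too_few)
  expect_identical(nrow(out$tests), 0L)
})

test_that("focus cells partition the rated frames per stage and model", {
  f <- focus_fixture()
  correctness <- dplyr::bind_rows(
    tibble::tibble(frame_id = f$tab$frame_id, model_id = "resnet34",
                   correct = f$tab$resnet34 == f$tab$reference),
    tibble::tibble(frame_id = f$tab$frame_id, model_id = "vgg16",
                   correct = f$tab$vgg16 == f$tab$reference))
  out <- accuracy_by_focus(f$focus, correctness, f$stages)
  totals <- out$cells |>
    dplyr::group_by(.data$stage, .data$model_id) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  expect_true(all(totals$n == 10L))
})

test_that("null simulation: rating groups show no accuracy signal", {
  # ratings drawn independently of correctness: between-group differences
  # should be non-significant in at least 90% of replicates
  n_sim <- 200L
  frames <- sprintf("F%03d", 1:120)
  stages <- stats::setNames(rep(4L, 120), frames)
  sig <- withr::with_seed(77, {
    vapply(seq_len(n_sim), function(i) {
      ratings <- tibble::tibble(
        frame_id = frames, model_id = "m",
        rating = sample(c("good", "poor"), 120,
                        replace = TRUE, prob = c(0.6, 0.4)))
      correctness <- tibble::tibble(frame_id = frames, model_id = "m",
                                    correct = stats::runif(120) < 0.75)
      out <- accuracy_by_focus(ratings, correctness, stages)
      nrow(out$tests) > 0 && any(out$tests$p_value < 0.05)
    }, logical(1))
  })
  expect_gte(mean(!sig), 0.9)
})

test_that("consensus voting is majority with ties toward intermediate", {
  per_rater <- tibble::tibble(
    frame_id = rep(c("F1", "F2", "F3"), each = 3),
    model_id = "m",
    rater_id = rep(c("E1", "E2", "E3"), 3),
    rating = c("good", "good", "poor",
               "good", "poor", "intermediate",
               "poor", "poor", "poor"))
  cons <- consensus_focus_ratings(per_rater)
  expect_identical(cons$rating[cons$frame_id == "F1"], "good")
  expect_identical(cons$rating[cons$frame_id == "F2"], "intermediate")
  expect_identical(cons$rating[cons$frame_id == "F3"], "poor")
  strict <- consensus_focus_ratings(per_rater, rule = "strict")
  expect_identical(strict$frame_id, "F3")
})
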