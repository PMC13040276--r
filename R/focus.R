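focus_levels <- function() c("good", "intermediate", "poor")

assert_focus_table <- function(ratings) {
  need <- c("frame_id", "model_id", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss) > 0L) {
    abort(sprintf("focus-rating table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "embryoxai_data_error")
  }
  bad <- setdiff(unique(ratings$rating), focus_levels())
  if (length(bad) > 0L) {
    abort(sprintf("unknown rating level(s): %s", paste(bad, collapse = ", ")),
          class = "embryoxai_parse_error")
  }
  invisible(ratings)
}

stage_lookup <- function(stages) {
  if (is.data.frame(stages)) {
    stopifnot(all(c("frame_id", "stage") %in% names(stages)))
    setNames(encode_stage(stages$stage), stages$frame_id)
  } else {
    setNames(encode_stage(stages), names(stages))
  }
}

#' Consensus over per-rater spatial-focus ratings
#'
#' Reduces several raters' good/intermediate/poor assessments of the same
#' explanation to one consensus rating per frame and model: majority vote,
#' with ties resolved toward `"intermediate"` (the rule is explicit
#' because panel consensus discussions have no algorithmic record).
#'
#' @param ratings Tibble with columns `frame_id`, `model_id`, `rater_id`,
#'   `rating`.
#' @param rule `"majority"` (default) or `"strict"` — strict consensus
#'   keeps only unanimous frames.
#' @return A tibble `frame_id`, `model_id`, `rating` with one row per
#'   frame and model.
#' @export
consensus_focus_ratings <- function(ratings, rule = c("majority", "strict")) {
  rule <- match.arg(rule)
  stopifnot(all(c("frame_id", "model_id", "rater_id", "rating") %in% names(ratings)))
  ratings |>
    dplyr::group_by(.data$frame_id, .data$model_id) |>
    dplyr::summarise(rating = {
      tab <- table(factor(.data$rating, levels = focus_levels()))
      if (rule == "strict" && length(unique(.data$rating)) > 1L) {
        NA_character_
      } else {
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) "intermediate" else top
      }
    }, .groups = "drop") |>
    dplyr::filter(!is.na(.data$rating))
}

#' Proportions of good/intermediate/poor focus ratings
#'
#' Aggregates consensus spatial-focus ratings of explanation heatmaps into
#' per-model, per-stage proportions over the three levels, plus an overall
#' row per model (`stage = NA`). Within each model-stage cell the three
#' proportions sum to 1.
#'
#' @param ratings Focus-rating tibble: `frame_id`, `model_id`, `rating`.
#' @param stages Frame-to-stage mapping: a tibble with `frame_id` and
#'   `stage`, or a named vector.
#' @return A tibble: `model_id`, `stage`, `rating`, `n`, `cell_total`,
#'   `proportion`.
#' @export
rating_proportions <- function(ratings, stages) {
  assert_focus_table(ratings)
  lut <- stage_lookup(stages)
  missing_frames <- setdiff(unique(ratings$frame_id), names(lut))
  if (length(missing_frames) > 0L) {
    abort(sprintf("no stage known for frame(s): %s",
                  paste(head(missing_frames, 5L), collapse = ", ")),
          class = "embryoxai_data_error")
  }
  dat <- ratings |>
    dplyr::mutate(stage = unname(lut[.data$frame_id]),
                  rating = factor(.data$rating, levels = focus_levels()))
  per_stage <- dat |>
    dplyr::count(.data$model_id, .data$stage, .data$rating,
                 .drop = FALSE, name = "n")
  overall <- dat |>
    dplyr::count(.data$model_id, .data$rating, .drop = FALSE, name = "n") |>
    dplyr::mutate(stage = NA_integer_)
  dplyr::bind_rows(per_stage, overall) |>
    dplyr::group_by(.data$model_id, .data$stage) |>
    dplyr::mutate(cell_total = sum(.data$n),
                  proportion = ifelse(.data$cell_total > 0,
                                      .data$n / .data$cell_total, NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$cell_total > 0) |>
    dplyr::mutate(rating = as.character(.data$rating))
}

#' Compare two models on the frequency of one rating level
#'
#' Chi-squared comparison (Fisher fallback below expected count 5) of the
#' proportion of frames rated at `rating_level` between two models, on the
#' frames rated for both, optionally within one stage.
#'
#' @inheritParams rating_proportions
#' @param model_a,model_b Model ids present in `ratings`.
#' @param rating_level One of `"good"`, `"intermediate"`, `"poor"`.
#' @param stage Optional stage code 1..7 to restrict to.
#' @return A `test_result` from [chi_square_proportions()].
#' @export
compare_models_on_rating <- function(ratings, model_a, model_b, rating_level,
                                     stage = NULL, stages = NULL) {
  assert_focus_table(ratings)
  rating_level <- match.arg(rating_level, focus_levels())
  a <- ratings[ratings$model_id == model_a, ]
  b <- ratings[ratings$model_id == model_b, ]
  common <- intersect(a$frame_id, b$frame_id)
  if (!is.null(stage)) {
    lut <- stage_lookup(stages)
    common <- common[unname(lut[common]) == stage]
  }
  if (length(common) == 0L) {
    abort("no frames rated for both models",
          class = "embryoxai_insufficient_data_error")
  }
  ra <- a$rating[match(common, a$frame_id)]
  rb <- b$rating[match(common, b$frame_id)]
  chi_square_proportions(sum(ra == rating_level), length(common),
                         sum(rb == rating_level), length(common))
}

#' Classification accuracy by spatial-focus group
#'
#' Crosses the qualitative focus ratings with classification correctness:
#' for each stage, model and rating level, the proportion of frames the
#' model classified correctly. Cells with fewer than `min_cell` frames are
#' flagged `too_few` and excluded from testing. Within each stage and
#' model, every pair of unflagged rating groups is compared with
#' [chi_square_proportions()].
#'
#' @inheritParams rating_proportions
#' @param correctness Tibble `frame_id`, `model_id`, `correct` (logical):
#'   whether the model classified the frame correctly.
#' @param min_cell Smallest rating-group size eligible for testing
#'   (default 5).
#' @return A list with `cells` (tibble: `stage`, `model_id`, `rating`,
#'   `n`, `correct`, `proportion`, `too_few`) and `tests` (tibble of
#'   pairwise rating-group comparisons).
#' @export
accuracy_by_focus <- function(ratings, correctness, stages, min_cell = 5L) {
  assert_focus_table(ratings)
  stopifnot(all(c("frame_id", "model_id", "correct") %in% names(correctness)))
  lut <- stage_lookup(stages)
  dat <- ratings |>
    dplyr::inner_join(correctness, by = c("frame_id", "model_id"))
  if (nrow(dat) < nrow(ratings)) {
    miss <- dplyr::anti_join(ratings, correctness,
                             by = c("frame_id", "model_id"))
    abort(sprintf("correctness missing for %d rated frame(s), e.g. %s/%s",
                  nrow(miss), miss$frame_id[1L], miss$model_id[1L]),
          class = "embryoxai_data_error")
  }
  dat$stage <- unname(lut[dat$frame_id])
  cells <- dat |>
    dplyr::group_by(.data$stage, .data$model_id, .data$rating) |>
    dplyr::summarise(n = dplyr::n(), correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$correct / .data$n,
                  too_few = .data$n < min_cell)
  tests <- cells |>
    dplyr::filter(!.data$too_few) |>
    dplyr::group_by(.data$stage, .data$model_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2L) return(NULL)
      prs <- combn(seq_len(nrow(g)), 2L)
      purrr::map_dfr(seq_len(ncol(prs)), function(j) {
        i1 <- prs[1L, j]; i2 <- prs[2L, j]
        ts <- chi_square_proportions(g$correct[i1], g$n[i1],
                                     g$correct[i2], g$n[i2])
        tibble(stage = key$stage, model_id = key$model_id,
               rating_a = as.character(g$rating[i1]),
               rating_b = as.character(g$rating[i2]),
               statistic = ts$statistic, p_value = ts$p_value,
               fisher = ts$extras$fisher)
      })
    }) |>
    dplyr::bind_rows()
  list(cells = cells, tests = tests)
}
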