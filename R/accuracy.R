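round_half_up <- function(x) floor(x + 0.5)

#' Classification accuracy against the reference standard
#'
#' The proportion of frames labelled with the correct stage. When several
#' raters are given, their correctness is pooled: each rater-by-frame pair
#' is one trial, so 3 raters on 245 frames give 735 trials — the pooled
#' accuracy reported for a rater group.
#'
#' @param data A rating table.
#' @param rater_ids One or more rater column names.
#' @param by_stage If `TRUE`, break the result down by reference stage.
#' @return A tibble with columns `correct`, `total`, `proportion`, plus
#'   `stage` and `stage_name` when `by_stage = TRUE`.
#' @examples
#' tab <- simulate_rating_table(5, 7, list(rater_profile("E1", 0.9)), seed = 3)
#' accuracy(tab, "E1")
#' accuracy(tab, "E1", by_stage = TRUE)
#' @export
accuracy <- function(data, rater_ids, by_stage = FALSE) {
  assert_rating_table(data, raters = rater_ids)
  ref <- encode_stage(data$reference)
  long <- purrr::map_dfr(rater_ids, function(r) {
    tibble(stage = ref, correct = encode_stage(data[[r]]) == ref)
  })
  if (by_stage) {
    long |>
      dplyr::group_by(stage) |>
      dplyr::summarise(correct = sum(.data$correct), total = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(proportion = .data$correct / .data$total,
                    stage_name = decode_stage(.data$stage), .after = "stage")
  } else {
    tibble(correct = sum(long$correct), total = nrow(long),
           proportion = sum(long$correct) / nrow(long))
  }
}

#' Confusion matrix of a rater against the reference standard
#'
#' Counts are indexed `[reference stage, predicted stage]` over the full
#' 7-category coding. `row_proportions` are full-precision row-normalized
#' proportions; `display_percent` rounds them half-up to whole percent for
#' heatmap display, while the underlying proportions keep full precision.
#'
#' @param data A rating table.
#' @param rater_id A single rater column name.
#' @return A `confusion_matrix` object with elements `counts`,
#'   `row_proportions`, `display_percent`, `n`, `rater_id`.
#' @export
confusion <- function(data, rater_id) {
  stopifnot(length(rater_id) == 1L)
  assert_rating_table(data, raters = rater_id)
  ref <- encode_stage(data$reference)
  lab <- encode_stage(data[[rater_id]])
  K <- n_stages()
  counts <- unclass(table(factor(ref, levels = 1:K),
                          factor(lab, levels = 1:K)))
  dimnames(counts) <- list(reference = stage_names(),
                           predicted = stage_names())
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  structure(
    list(counts = counts, row_proportions = props,
         display_percent = round_half_up(props * 100),
         n = sum(counts), rater_id = rater_id),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rater:", x$rater_id, " n =", x$n, "\n")
  cat("row percent (reference x predicted):\n")
  print(x$display_percent)
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "count")) |>
    dplyr::mutate(proportion = as.vector(x$row_proportions),
                  display_percent = as.vector(x$display_percent))
}

#' Per-frame correctness grid for a set of raters
#'
#' @param data A rating table.
#' @param rater_ids Rater column names.
#' @return A logical matrix, frames by raters: `TRUE` where the rater's
#'   label equals the reference stage.
#' @export
correctness_grid <- function(data, rater_ids) {
  assert_rating_table(data, raters = rater_ids)
  ref <- encode_stage(data$reference)
  g <- vapply(rater_ids, function(r) encode_stage(data[[r]]) == ref,
              logical(nrow(data)))
  g <- matrix(g, nrow = nrow(data),
              dimnames = list(data$frame_id, rater_ids))
  g
}
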