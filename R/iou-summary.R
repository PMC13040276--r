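#' Distribution-free confidence interval for a median
#'
#' Order-statistic interval: with `B ~ Binomial(n, 1/2)` and
#' `l = qbinom(alpha/2, n, 1/2)`, the interval runs from the `l`-th to the
#' `(n + 1 - l)`-th order statistic, which covers the median with
#' probability at least `conf`.
#'
#' @param x Numeric vector.
#' @param conf Coverage level (default 0.95).
#' @return Named numeric vector `c(low, high)`; `NA` when `n < 6` (no
#'   interval of at least 95% coverage exists inside the sample).
#' @export
median_ci <- function(x, conf = 0.95) {
  n <- length(x)
  if (n < 6L) return(c(low = NA_real_, high = NA_real_))
  alpha <- 1 - conf
  l <- qbinom(alpha / 2, n, 0.5)
  if (l < 1L) l <- 1L
  u <- n + 1L - l
  xs <- sort(as.numeric(x))
  c(low = xs[l], high = xs[u])
}

#' Stage-wise IoU summary
#'
#' Per stage and model: the median IoU as a percent with its
#' distribution-free 95% interval (see [median_ci()]). Cells with fewer
#' than `min_n` frames report an undefined interval.
#'
#' @param records Tibble with columns `frame_id`, `stage` (code 1..7),
#'   `model` and `iou` in `[0, 1]`.
#' @param conf Interval coverage (default 0.95).
#' @param min_n Smallest cell size with a defined interval (default 6).
#' @return A tibble: `stage`, `stage_name`, `model`, `n`, `median_pct`,
#'   `ci_low_pct`, `ci_high_pct`.
#' @export
stagewise_iou_summary <- function(records, conf = 0.95, min_n = 6L) {
  stopifnot(all(c("frame_id", "stage", "model", "iou") %in% names(records)))
  if (nrow(records) == 0L) {
    abort("no IoU records", class = "embryoxai_empty_error")
  }
  records |>
    dplyr::group_by(.data$stage, .data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_pct = median(.data$iou) * 100,
      ci_low_pct = if (dplyr::n() >= min_n) median_ci(.data$iou, conf)[["low"]] * 100 else NA_real_,
      ci_high_pct = if (dplyr::n() >= min_n) median_ci(.data$iou, conf)[["high"]] * 100 else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(stage_name = decode_stage(.data$stage), .after = "stage") |>
    dplyr::arrange(.data$stage, .data$model)
}

#' Stage-wise paired model comparison of IoU
#'
#' For every stage and every pair of models, a Wilcoxon matched-pairs
#' signed-rank test on the per-frame IoU of frames scored under both
#' models.
#'
#' @inheritParams stagewise_iou_summary
#' @return A tibble: `stage`, `stage_name`, `model_a`, `model_b`, `n`
#'   (paired frames), `W`, `statistic`, `p_value`.
#' @export
stagewise_iou_tests <- function(records) {
  stopifnot(all(c("frame_id", "stage", "model", "iou") %in% names(records)))
  models <- sort(unique(records$model))
  if (length(models) < 2L) {
    abort("need at least two models to compare",
          class = "embryoxai_parameter_error")
  }
  pairs <- combn(models, 2L)
  out <- purrr::map_dfr(sort(unique(records$stage)), function(s) {
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- records[records$stage == s & records$model == pairs[1L, j], ]
      b <- records[records$stage == s & records$model == pairs[2L, j], ]
      common <- intersect(a$frame_id, b$frame_id)
      if (length(common) < 2L) return(NULL)
      va <- a$iou[match(common, a$frame_id)]
      vb <- b$iou[match(common, b$frame_id)]
      ts <- wilcoxon_signed_rank(va, vb)
      tibble(stage = s, stage_name = decode_stage(s),
             model_a = pairs[1L, j], model_b = pairs[2L, j],
             n = length(common), W = ts$extras$W,
             statistic = ts$statistic, p_value = ts$p_value)
    })
  })
  out
}
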