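new_test_result <- function(statistic, df, p_value, method, n = NA_integer_,
                            extras = list()) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         method = method, n = n, extras = extras),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method, "\n")
  cat(sprintf("  statistic = %.4f%s  p %s\n", x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(" (df = %d)", x$df) else "",
              format_p(x$p_value)))
  if (length(x$extras)) {
    cat("  extras:", paste(names(x$extras),
                           vapply(x$extras, function(e) format(e)[1], ""),
                           sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
tidy.test_result <- function(x, ...) {
  tibble(statistic = x$statistic,
         df = if (is.null(x$df)) NA_integer_ else x$df,
         p.value = x$p_value, method = x$method, n = x$n)
}

#' @export
glance.test_result <- function(x, ...) tidy(x)

#' Cochran's Q test for equality of matched proportions
#'
#' Tests whether several raters have the same marginal success rate on the
#' same set of frames, e.g. per-frame classification correctness of the
#' five operators. Frames on which every rater agrees (all correct or all
#' wrong) contribute nothing to the statistic.
#'
#' @param correctness A logical (or 0/1) matrix, frames by raters, with at
#'   least 2 raters and 2 frames.
#' @return A `test_result` with the Q statistic, `df = raters - 1` and a
#'   chi-squared p-value. A grid whose columns are identical but whose rows
#'   vary gives `Q = 0, p = 1`; a strictly constant grid is degenerate.
#' @examples
#' tab <- simulate_rating_table(5, 10,
#'   list(rater_profile("E1", 0.95), rater_profile("M1", 0.75),
#'        rater_profile("M2", 0.7)), seed = 4)
#' cochran_q(correctness_grid(tab, c("E1", "M1", "M2")))
#' @export
cochran_q <- function(correctness) {
  x <- as.matrix(correctness)
  storage.mode(x) <- "integer"
  if (ncol(x) < 2L || nrow(x) < 2L) {
    abort("need at least 2 raters and 2 frames",
          class = "embryoxai_parameter_error")
  }
  if (all(x == x[1L]) ) {
    abort("degenerate grid: all values identical, Q is undefined",
          class = "embryoxai_degenerate_error")
  }
  k <- ncol(x)
  Cj <- colSums(x)
  Ri <- rowSums(x)
  num <- (k - 1) * (k * sum(Cj^2) - sum(Cj)^2)
  den <- k * sum(Ri) - sum(Ri^2)
  if (den == 0) {
    # every row unanimous: no within-frame disagreement at all
    Q <- 0
  } else {
    Q <- num / den
  }
  df <- k - 1L
  new_test_result(statistic = Q, df = df,
                  p_value = pchisq(Q, df, lower.tail = FALSE),
                  method = "cochran_q", n = nrow(x))
}

mcnemar_one <- function(b, c) {
  nd <- b + c
  if (nd == 0L) {
    return(list(statistic = 0, p = 1, variant = "none", flag = "no_discordant"))
  }
  if (nd < 25L) {
    p <- min(1, 2 * pbinom(min(b, c), nd, 0.5))
    list(statistic = as.numeric(min(b, c)), p = p, variant = "exact_binomial",
         flag = NA_character_)
  } else {
    stat <- (abs(b - c) - 1)^2 / nd
    list(statistic = stat, p = pchisq(stat, 1L, lower.tail = FALSE),
         variant = "chisq_cc", flag = NA_character_)
  }
}

#' Pairwise McNemar tests with Holm adjustment
#'
#' Post-hoc follow-up to [cochran_q()]: for every pair of raters, a McNemar
#' test on the 2x2 discordance table of their per-frame correctness. The
#' exact two-sided binomial test is used when there are fewer than 25
#' discordant frames, otherwise the continuity-corrected chi-squared
#' statistic. All pairs in one call form a single Holm family.
#'
#' @inheritParams cochran_q
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return A tibble with one row per pair: `rater_a`, `rater_b`,
#'   discordant counts `b` (a correct, b wrong) and `c`, the statistic and
#'   variant used, `p_value` and `p_adj`, and a `flag` marking pairs with
#'   no discordant frames (reported as p = 1, not an error).
#' @export
mcnemar_pairwise <- function(correctness, adjust = "holm") {
  x <- as.matrix(correctness) > 0
  if (ncol(x) < 2L) {
    abort("need at least 2 raters", class = "embryoxai_parameter_error")
  }
  raters <- colnames(x) %||% paste0("rater", seq_len(ncol(x)))
  pairs <- combn(seq_len(ncol(x)), 2L)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    b <- sum(x[, i1] & !x[, i2])
    cc <- sum(!x[, i1] & x[, i2])
    r <- mcnemar_one(b, cc)
    tibble(rater_a = raters[i1], rater_b = raters[i2],
           b = b, c = cc, statistic = r$statistic, variant = r$variant,
           p_value = r$p, flag = r$flag)
  })
  rows$p_adj <- p.adjust(rows$p_value, method = adjust)
  rows
}

#' Chi-squared comparison of two proportions
#'
#' Pearson chi-squared test (no continuity correction, as in standard
#' statistical software output for proportion comparisons) on the 2x2 table
#' of hits and misses in two groups. When any expected or observed cell
#' count is below 5 the test falls back to Fisher's exact test, flagged in
#' `extras`.
#'
#' @param hits_a,n_a Successes and trials in group a.
#' @param hits_b,n_b Successes and trials in group b.
#' @return A `test_result`; `extras$fisher` records whether the Fisher
#'   fallback was used.
#' @examples
#' chi_square_proportions(218, 245, 145, 245)
#' @export
chi_square_proportions <- function(hits_a, n_a, hits_b, n_b) {
  if (n_a <= 0 || n_b <= 0 || hits_a > n_a || hits_b > n_b ||
      hits_a < 0 || hits_b < 0) {
    abort("hits must lie in [0, n] and n must be positive",
          class = "embryoxai_parameter_error")
  }
  m <- matrix(c(hits_a, n_a - hits_a, hits_b, n_b - hits_b),
              nrow = 2L, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5) || any(m < 5)) {
    ft <- fisher.test(m)
    new_test_result(statistic = unname(ft$estimate), df = NA_integer_,
                    p_value = ft$p.value, method = "chi_square",
                    n = n_a + n_b,
                    extras = list(fisher = TRUE,
                                  prop_a = hits_a / n_a, prop_b = hits_b / n_b))
  } else {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    new_test_result(statistic = unname(ct$statistic), df = 1L,
                    p_value = ct$p.value, method = "chi_square",
                    n = n_a + n_b,
                    extras = list(fisher = FALSE,
                                  prop_a = hits_a / n_a, prop_b = hits_b / n_b))
  }
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped; tied
#' absolute differences are mid-ranked. With 25 or fewer non-zero
#' differences and no ties the exact signed-rank null distribution is used;
#' otherwise the normal approximation with tie correction and continuity
#' correction. `extras` reports the signed-rank sum `W` (positive minus
#' negative rank sums) and the median difference.
#'
#' @param a,b Numeric vectors of equal length (paired observations).
#' @return A `test_result` with `method = "wilcoxon_signed_rank"`.
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L) {
    abort("`a` and `b` must have equal positive length",
          class = "embryoxai_parameter_error")
  }
  d <- a - b
  med_diff <- median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_test_result(statistic = 0, df = NA_integer_, p_value = 1,
                           method = "wilcoxon_signed_rank", n = 0L,
                           extras = list(W = 0, median_difference = med_diff,
                                         flag = "all_zero")))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  W <- V - sum(r[d < 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- min(1, 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  new_test_result(statistic = V, df = NA_integer_, p_value = min(1, p),
                  method = "wilcoxon_signed_rank", n = n,
                  extras = list(W = W, median_difference = med_diff,
                                exact = exact))
}
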