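quadratic_weights <- function(K) {
  d <- outer(1:K, 1:K, function(i, j) (i - j)^2)
  1 - d / (K - 1)^2
}

identity_weights <- function(K) {
  diag(K)
}

new_kappa_result <- function(estimate, standard_error, ci_low, ci_high,
                             statistic, p_value, method, n, ...) {
  structure(
    list(estimate = estimate, standard_error = standard_error,
         ci_low = ci_low, ci_high = ci_high, statistic = statistic,
         p_value = p_value, method = method, n = n, ...),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("<kappa_result> method:", x$method, " n =", x$n, "\n")
  cat(sprintf("  kappa = %.4f  SE = %.4f  95%% CI [%.4f, %.4f]  p %s\n",
              x$estimate, x$standard_error, x$ci_low, x$ci_high,
              format_p(x$p_value)))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 1e-3, "<0.001", sprintf("= %.3f", p))
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(estimate = x$estimate, std.error = x$standard_error,
         conf.low = x$ci_low, conf.high = x$ci_high,
         statistic = x$statistic, p.value = x$p_value,
         method = x$method, n = x$n)
}

#' @export
glance.kappa_result <- function(x, ...) tidy(x)

# Weighted kappa with the Fleiss-Cohen-Everitt large-sample variance, from a
# KxK contingency table of counts (rows rater a, columns rater b).
weighted_kappa_from_counts <- function(tab, w, conf_level = 0.95) {
  n <- sum(tab)
  p <- tab / n
  r <- rowSums(p)
  cl <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cl))
  if (1 - pe < .Machine$double.eps^0.5) {
    abort("degenerate table: chance agreement is 1 under the chosen weights",
          class = "embryoxai_degenerate_error")
  }
  kappa <- (po - pe) / (1 - pe)
  # row/column mean weights against the opposite marginal
  wi <- as.vector(w %*% cl)   # wbar_i. = sum_j w_ij c_j
  wj <- as.vector(r %*% w)    # wbar_.j = sum_i w_ij r_i
  wplus <- outer(wi, wj, `+`)
  var_hat <- (sum(p * (w - wplus * (1 - kappa))^2) -
                (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  var_hat <- max(var_hat, 0)
  var0 <- (sum(outer(r, cl) * (w - wplus)^2) - pe^2) / (n * (1 - pe)^2)
  var0 <- max(var0, 0)
  se <- sqrt(var_hat)
  z <- if (var0 > 0) kappa / sqrt(var0) else Inf * sign(kappa)
  half <- qnorm(1 - (1 - conf_level) / 2) * se
  list(estimate = kappa, se = se,
       ci_low = max(-1, kappa - half), ci_high = min(1, kappa + half),
       statistic = z, p_value = 2 * pnorm(-abs(z)),
       po = po, pe = pe, n = n)
}

#' Cohen's weighted kappa between two raters
#'
#' Chance-corrected agreement between two label columns of a rating table,
#' on the full 7-category ordinal coding. Quadratic weights
#' `w_ij = 1 - (i - j)^2 / (K - 1)^2` give partial credit to near-miss
#' stages, matching the ordinal nature of embryo development; the weight
#' denominator cancels from the estimate, so tables that use fewer
#' categories give the same kappa as a reduced coding would.
#'
#' The standard error is the Fleiss-Cohen-Everitt large-sample estimate;
#' the confidence interval is Wald, clipped to `[-1, 1]`; the p-value tests
#' `H0: kappa = 0` using the null-variance form.
#'
#' @param data A rating table (tibble with `reference` and rater columns).
#' @param rater_a,rater_b Column names of the two raters; `"reference"` is
#'   allowed, e.g. to score a rater against the reference standard.
#' @param weighting `"quadratic"` (default) or `"unweighted"`.
#' @param subgroup_stage Optional stage code 1..7: restrict to frames whose
#'   reference stage equals this code, while labels stay free over 1..7.
#'   This is the stage-specific agreement analysis; near-constant subgroup
#'   tables can legitimately yield negative kappa.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `kappa_result` object; see [tidy.kappa_result()].
#' @examples
#' tab <- simulate_rating_table(5, 10,
#'   list(rater_profile("E1", 0.9), rater_profile("E2", 0.85)), seed = 2)
#' cohen_weighted_kappa(tab, "E1", "E2")
#' @export
cohen_weighted_kappa <- function(data, rater_a, rater_b,
                                 weighting = c("quadratic", "unweighted"),
                                 subgroup_stage = NULL,
                                 conf_level = 0.95) {
  weighting <- match.arg(weighting)
  assert_rating_table(data, raters = setdiff(c(rater_a, rater_b), "reference"))
  if (!is.null(subgroup_stage)) {
    stopifnot(subgroup_stage %in% 1:7)
    data <- data[data$reference == subgroup_stage, , drop = FALSE]
    if (nrow(data) < 2L) {
      abort(sprintf("fewer than 2 frames with reference stage %d",
                    subgroup_stage),
            class = "embryoxai_insufficient_data_error")
    }
  }
  if (nrow(data) < 2L) {
    abort("need at least 2 frames", class = "embryoxai_insufficient_data_error")
  }
  a <- encode_stage(data[[rater_a]])
  b <- encode_stage(data[[rater_b]])
  if (length(unique(c(a, b))) < 2L) {
    abort("degenerate table: fewer than 2 distinct categories observed",
          class = "embryoxai_degenerate_error")
  }
  K <- n_stages()
  tab <- table(factor(a, levels = 1:K), factor(b, levels = 1:K))
  w <- if (weighting == "quadratic") quadratic_weights(K) else identity_weights(K)
  res <- weighted_kappa_from_counts(unclass(tab), w, conf_level)
  new_kappa_result(
    estimate = res$estimate, standard_error = res$se,
    ci_low = res$ci_low, ci_high = res$ci_high,
    statistic = res$statistic, p_value = res$p_value,
    method = if (weighting == "quadratic") "cohen_quadratic" else "cohen_unweighted",
    n = res$n, rater_a = rater_a, rater_b = rater_b,
    subgroup_stage = subgroup_stage, p_o = res$po, p_e = res$pe
  )
}

#' Fleiss' multirater kappa
#'
#' Chance-corrected agreement among three or more raters over the 7 stage
#' categories, with the Fleiss-Nee-Landis asymptotic standard error, a Wald
#' 95% interval clipped to `[-1, 1]`, and a two-sided p-value for
#' `H0: kappa = 0`. With exactly two raters use [cohen_weighted_kappa()].
#'
#' @inheritParams cohen_weighted_kappa
#' @param rater_ids Character vector of at least 3 rater columns.
#' @param conf_level Confidence level (default 0.95).
#' @return A `kappa_result` object with `method = "fleiss"`.
#' @export
fleiss_kappa <- function(data, rater_ids, conf_level = 0.95) {
  if (length(rater_ids) < 3L) {
    abort("Fleiss' kappa needs at least 3 raters; use cohen_weighted_kappa() for 2",
          class = "embryoxai_parameter_error")
  }
  assert_rating_table(data, raters = rater_ids)
  K <- n_stages()
  labs <- lapply(rater_ids, function(r) encode_stage(data[[r]]))
  m <- do.call(cbind, labs)                      # frames x raters
  N <- nrow(m)
  nr <- ncol(m)
  counts <- t(apply(m, 1L, function(x) tabulate(x, nbins = K)))
  pj <- colSums(counts) / (N * nr)
  Pe <- sum(pj^2)
  if (1 - Pe < .Machine$double.eps^0.5) {
    abort("degenerate table: a single category is used for every rating",
          class = "embryoxai_degenerate_error")
  }
  Pi <- (rowSums(counts^2) - nr) / (nr * (nr - 1))
  Pbar <- mean(Pi)
  kappa <- (Pbar - Pe) / (1 - Pe)
  qj <- 1 - pj
  spq <- sum(pj * qj)
  se0 <- sqrt(2 / (N * nr * (nr - 1))) * sqrt(spq^2 - sum(pj * qj * (qj - pj))) / spq
  z <- kappa / se0
  half <- qnorm(1 - (1 - conf_level) / 2) * se0
  new_kappa_result(
    estimate = kappa, standard_error = se0,
    ci_low = max(-1, kappa - half), ci_high = min(1, kappa + half),
    statistic = z, p_value = 2 * pnorm(-abs(z)),
    method = "fleiss", n = N, rater_ids = rater_ids,
    p_o = Pbar, p_e = Pe
  )
}
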