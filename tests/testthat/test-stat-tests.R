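test_that("Cochran's Q matches the brute-force formula on random grids", {
  for (s in 1:50) {
    withr::with_seed(s, {
      x <- matrix(stats::runif(12 * 4) < stats::runif(4)[col(matrix(0, 12, 4))],
                  nrow = 12)
    })
    if (all(x == x[1]) || all(rowSums(x) %in% c(0, ncol(x)))) next
    q <- cochran_q(x)
    expect_equal(q$statistic, oracle_cochran_q(x), tolerance = 1e-12)
    expect_identical(q$df, ncol(x) - 1L)
  }
})

test_that("identical rater columns give Q = 0 with p = 1", {
  col <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  x <- cbind(col, col, col)
  q <- cochran_q(x)
  expect_equal(q$statistic, 0)
  expect_equal(q$p_value, 1)
})

test_that("a strictly constant grid is degenerate for Q", {
  expect_error(cochran_q(matrix(TRUE, 5, 3)),
               class = "embryoxai_degenerate_error")
  expect_error(cochran_q(matrix(FALSE, 5, 3)),
               class = "embryoxai_degenerate_error")
})

test_that("with 2 raters Q equals the uncorrected McNemar chi-squared", {
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      x <- matrix(stats::runif(40) < 0.6, ncol = 2)
    })
    b <- sum(x[, 1] & !x[, 2]); cc <- sum(!x[, 1] & x[, 2])
    if (b + cc == 0) next
    mcnemar_uncorrected <- (b - cc)^2 / (b + cc)
    expect_equal(cochran_q(x)$statistic, mcnemar_uncorrected,
                 tolerance = 1e-12)
  }
})

test_that("Cochran's Q holds its type-I error rate under the null", {
  n_rep <- 1000L
  rejections <- withr::with_seed(99, {
    sum(vapply(seq_len(n_rep), function(i) {
      x <- matrix(stats::runif(30 * 5) < 0.7, ncol = 5)
      out <- tryCatch(cochran_q(x)$p_value < 0.05, error = function(e) NA)
      isTRUE(out)
    }, logical(1)))
  })
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rejections / n_rep - 0.05), 3 * se)
})

test_that("McNemar: identical pair gives p = 1 with a flag", {
  x <- cbind(a = c(TRUE, FALSE, TRUE), b = c(TRUE, FALSE, TRUE))
  r <- mcnemar_pairwise(x)
  expect_equal(r$p_value, 1)
  expect_identical(r$flag, "no_discordant")
})

test_that("McNemar exact binomial matches the tail-sum oracle", {
  # worked case (b, c) = (1, 10): p = 2 P(X <= 1 | n = 11)
  x <- cbind(a = c(rep(TRUE, 1), rep(FALSE, 10), rep(TRUE, 20)),
             b = c(rep(FALSE, 1), rep(TRUE, 10), rep(TRUE, 20)))
  r <- mcnemar_pairwise(x)
  expect_equal(r$p_value, 2 * pbinom(1, 11, 0.5), tolerance = 1e-12)
  expect_equal(r$p_value, 0.01171875, tolerance = 1e-8)
  expect_identical(r$variant, "exact_binomial")
  for (b in c(0, 2, 5)) {
    for (cc in c(3, 7)) {
      x <- cbind(a = c(rep(TRUE, b), rep(FALSE, cc)),
                 b = c(rep(FALSE, b), rep(TRUE, cc)))
      expect_equal(mcnemar_pairwise(x)$p_value, oracle_mcnemar_exact(b, cc),
                   tolerance = 1e-12)
    }
  }
})

test_that("McNemar switches to continuity-corrected chi-squared at 25 discordant", {
  x <- cbind(a = c(rep(TRUE, 18), rep(FALSE, 10)),
             b = c(rep(FALSE, 18), rep(TRUE, 10)))
  r <- mcnemar_pairwise(x)
  expect_identical(r$variant, "chisq_cc")
  expect_equal(r$statistic, (abs(18 - 10) - 1)^2 / 28, tolerance = 1e-12)
  # cross-check against the standard implementation
  ref <- stats::mcnemar.test(matrix(c(0, 18, 10, 0), 2), correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Holm adjustment reproduces the step-down walk-through", {
  # raw {0.01, 0.03, 0.04} -> {0.03, 0.06, 0.06}
  expect_equal(oracle_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  # Holm-adjusted p are monotone in raw-p order and never below raw
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- stats::runif(6)
      adj <- stats::p.adjust(p, "holm")
      expect_true(all(adj >= p))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))
      expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    }
  })
})

test_that("mcnemar_pairwise forms one Holm family over all pairs", {
  withr::with_seed(8, {
    x <- matrix(stats::runif(40 * 5) < rep(c(0.9, 0.85, 0.8, 0.6, 0.55),
                                           each = 40), ncol = 5)
  })
  r <- mcnemar_pairwise(x)
  expect_identical(nrow(r), 10L)
  expect_equal(r$p_adj, stats::p.adjust(r$p_value, "holm"))
})

test_that("chi-squared proportion test: trivial and reconstructed-count cases", {
  t0 <- chi_square_proportions(10, 20, 10, 20)
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1, tolerance = 1e-12)
  t1 <- chi_square_proportions(500, 1000, 501, 1000)
  expect_gt(t1$p_value, 0.9)
  # good-rating proportions 89% vs 59% of 245 frames
  t2 <- chi_square_proportions(218, 245, 145, 245)
  expect_lt(t2$p_value, 0.001)
  expect_false(t2$extras$fisher)
  expect_error(chi_square_proportions(30, 20, 5, 20),
               class = "embryoxai_parameter_error")
})

test_that("chi-squared falls back to Fisher below expected count 5", {
  t1 <- chi_square_proportions(20, 20, 0, 20)
  expect_true(t1$extras$fisher)
  expect_lt(t1$p_value, 1e-9)
  expect_equal(t1$p_value, stats::fisher.test(
    matrix(c(20, 0, 0, 20), 2, byrow = TRUE))$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank: identical, all-positive and tie handling", {
  t0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$extras$W, 0)
  expect_equal(t0$p_value, 1)
  expect_identical(t0$extras$flag, "all_zero")
  # differences (1, 2, 3): W = +6, exact two-sided p = 2/8
  t1 <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(t1$extras$W, 6)
  expect_equal(t1$p_value, 0.25, tolerance = 1e-12)
  expect_true(t1$extras$exact)
  expect_equal(t1$extras$median_difference, 2)
})

test_that("Wilcoxon exact p matches the standard implementation without ties", {
  for (s in 1:25) {
    withr::with_seed(300 + s, {
      n <- sample(5:20, 1)
      a <- stats::rnorm(n)
      b <- stats::rnorm(n)
    })
    mine <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Wilcoxon normal approximation matches wilcox.test with ties", {
  withr::with_seed(12, {
    a <- sample(1:5, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
  })
  mine <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_false(mine$extras$exact)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon holds its type-I error rate under the null", {
  n_rep <- 1000L
  rejections <- withr::with_seed(101, {
    sum(vapply(seq_len(n_rep), function(i) {
      a <- stats::rnorm(50)
      b <- stats::rnorm(50)
      wilcoxon_signed_rank(a, b)$p_value < 0.05
    }, logical(1)))
  })
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rejections / n_rep - 0.05), 3 * se)
})
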