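make_pair_table <- function(a, b) {
  tibble::tibble(embryo_id = "E1",
                 frame_id = sprintf("F%03d", seq_along(a)),
                 reference = a, A = a, B = b)
}

test_that("identical raters give kappa exactly 1 with a degenerate CI", {
  a <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 3L, 3L)
  k <- cohen_weighted_kappa(make_pair_table(a, a), "A", "B")
  expect_equal(k$estimate, 1, tolerance = 1e-12)
  expect_equal(k$standard_error, 0, tolerance = 1e-8)
  expect_equal(c(k$ci_low, k$ci_high), c(1, 1), tolerance = 1e-8)
  expect_lt(k$p_value, 0.05)
})

test_that("hand-computed two-category example gives kappa 0.5", {
  # a = (1,1,2,2), b = (1,2,2,2): p_o = 3/4, p_e = 1/2 on two categories,
  # and the quadratic weight denominator cancels, so kappa = 0.5
  k <- cohen_weighted_kappa(make_pair_table(c(1L, 1L, 2L, 2L),
                                            c(1L, 2L, 2L, 2L)), "A", "B")
  expect_equal(k$estimate, 0.5, tolerance = 1e-12)
  ku <- cohen_weighted_kappa(make_pair_table(c(1L, 1L, 2L, 2L),
                                             c(1L, 2L, 2L, 2L)), "A", "B",
                             weighting = "unweighted")
  expect_equal(ku$estimate, 0.5, tolerance = 1e-12)
})

test_that("weighted kappa matches the brute-force oracle on random tables", {
  for (s in 1:60) {
    n <- sample(4:12, 1)
    tab <- random_rating_table(n, seed = s)
    # ensure non-degenerate
    if (length(unique(c(tab$A, tab$B))) < 2) next
    kq <- cohen_weighted_kappa(tab, "A", "B")$estimate
    ku <- cohen_weighted_kappa(tab, "A", "B", weighting = "unweighted")$estimate
    expect_equal(kq, oracle_weighted_kappa(tab$A, tab$B, TRUE),
                 tolerance = 1e-12)
    expect_equal(ku, oracle_weighted_kappa(tab$A, tab$B, FALSE),
                 tolerance = 1e-12)
  }
})

test_that("flipping one agreeing frame to disagreement lowers kappa", {
  withr::with_seed(5, {
    a <- sample(1:7, 40, replace = TRUE)
  })
  b <- a
  k1 <- cohen_weighted_kappa(make_pair_table(a, b), "A", "B")$estimate
  b[1] <- if (b[1] == 7L) 1L else b[1] + 1L
  k2 <- cohen_weighted_kappa(make_pair_table(a, b), "A", "B")$estimate
  expect_lt(k2, k1)
})

test_that("quadratic kappa is invariant under reversing the ordinal coding", {
  tab <- random_rating_table(30, seed = 9)
  k1 <- cohen_weighted_kappa(tab, "A", "B")$estimate
  rev_tab <- tab
  rev_tab$A <- 8L - tab$A
  rev_tab$B <- 8L - tab$B
  rev_tab$reference <- 8L - tab$reference
  k2 <- cohen_weighted_kappa(rev_tab, "A", "B")$estimate
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("subgroup kappa filters by reference stage and can go negative", {
  # reference all stage 2; raters disagree systematically on nearby codes
  tab <- tibble::tibble(
    embryo_id = "E1", frame_id = sprintf("F%02d", 1:8),
    reference = rep(2L, 8),
    A = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
    B = c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
  )
  k <- cohen_weighted_kappa(tab, "A", "B", subgroup_stage = 2L)
  expect_lt(k$estimate, 0)
  expect_identical(k$n, 8L)
  expect_error(cohen_weighted_kappa(tab, "A", "B", subgroup_stage = 5L),
               class = "embryoxai_insufficient_data_error")
})

test_that("degenerate single-category tables are rejected", {
  tab <- make_pair_table(rep(3L, 5), rep(3L, 5))
  expect_error(cohen_weighted_kappa(tab, "A", "B"),
               class = "embryoxai_degenerate_error")
})

test_that("kappa CI is ordered, clipped, and contains the estimate", {
  for (s in 101:115) {
    tab <- random_rating_table(10, seed = s)
    if (length(unique(c(tab$A, tab$B))) < 2) next
    k <- cohen_weighted_kappa(tab, "A", "B")
    expect_lte(k$ci_low, k$estimate)
    expect_gte(k$ci_high, k$estimate)
    expect_gte(k$ci_low, -1)
    expect_lte(k$ci_high, 1)
    expect_gte(k$p_value, 0)
    expect_lte(k$p_value, 1)
  }
})

test_that("Fleiss kappa is 1 for unanimous raters and matches the oracle", {
  tab <- tibble::tibble(
    embryo_id = "E1", frame_id = sprintf("F%02d", 1:6),
    reference = c(1L, 2L, 3L, 4L, 5L, 6L)
  )
  tab$R1 <- tab$R2 <- tab$R3 <- tab$reference
  expect_equal(fleiss_kappa(tab, c("R1", "R2", "R3"))$estimate, 1,
               tolerance = 1e-12)
  for (s in 1:40) {
    n <- sample(3:10, 1)
    t2 <- random_rating_table(n, raters = c("R1", "R2", "R3"), seed = 200 + s)
    m <- cbind(t2$R1, t2$R2, t2$R3)
    if (length(unique(as.vector(m))) < 2) next
    expect_equal(fleiss_kappa(t2, c("R1", "R2", "R3"))$estimate,
                 oracle_fleiss_kappa(m), tolerance = 1e-12)
  }
})

test_that("Fleiss kappa rejects <3 raters and zero-variance tables", {
  tab <- random_rating_table(6, raters = c("R1", "R2", "R3"), seed = 3)
  expect_error(fleiss_kappa(tab, c("R1", "R2")),
               class = "embryoxai_parameter_error")
  tab$R1 <- tab$R2 <- tab$R3 <- 4L
  expect_error(fleiss_kappa(tab, c("R1", "R2", "R3")),
               class = "embryoxai_degenerate_error")
})

test_that("tidy/glance on kappa results return one-row tibbles", {
  tab <- random_rating_table(20, seed = 77)
  k <- cohen_weighted_kappa(tab, "A", "B")
  td <- tidy(k)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_named(td, c("estimate", "std.error", "conf.low", "conf.high",
                     "statistic", "p.value", "method", "n"))
  expect_identical(glance(k), td)
})
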