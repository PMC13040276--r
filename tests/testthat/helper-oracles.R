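# Brute-force reference implementations of the agreement statistics,
# written directly from their defining formulas with explicit loops.
# They share no code with the package implementations.

oracle_weighted_kappa <- function(a, b, quadratic = TRUE, K = 7) {
  n <- length(a)
  po <- 0
  pe <- 0
  for (i in 1:K) {
    for (j in 1:K) {
      w <- if (quadratic) 1 - (i - j)^2 / (K - 1)^2 else as.numeric(i == j)
      pij <- sum(a == i & b == j) / n
      ri <- sum(a == i) / n
      cj <- sum(b == j) / n
      po <- po + w * pij
      pe <- pe + w * ri * cj
    }
  }
  (po - pe) / (1 - pe)
}

oracle_fleiss_kappa <- function(m, K = 7) {
  N <- nrow(m)
  r <- ncol(m)
  Pi <- numeric(N)
  for (i in 1:N) {
    s <- 0
    for (j in 1:K) {
      nij <- sum(m[i, ] == j)
      s <- s + nij * (nij - 1)
    }
    Pi[i] <- s / (r * (r - 1))
  }
  pj <- numeric(K)
  for (j in 1:K) pj[j] <- sum(m == j) / (N * r)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

oracle_cochran_q <- function(x) {
  x <- as.matrix(x) * 1L
  k <- ncol(x)
  Cj <- numeric(k)
  for (j in 1:k) Cj[j] <- sum(x[, j])
  Ri <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) Ri[i] <- sum(x[i, ])
  num <- 0
  Cbar <- sum(Cj) / k
  for (j in 1:k) num <- num + (Cj[j] - Cbar)^2
  den <- 0
  for (i in seq_len(nrow(x))) den <- den + Ri[i] * (k - Ri[i])
  k * (k - 1) * num / den
}

oracle_mcnemar_exact <- function(b, c) {
  nd <- b + c
  m <- min(b, c)
  tail <- 0
  for (x in 0:m) tail <- tail + choose(nd, x) * 0.5^nd
  min(1, 2 * tail)
}

oracle_holm <- function(p) {
  o <- order(p)
  m <- length(p)
  adj <- numeric(m)
  running <- 0
  for (k in 1:m) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

random_rating_table <- function(n, raters = c("A", "B"), seed) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      embryo_id = "E1",
      frame_id = sprintf("F%03d", seq_len(n)),
      reference = sample(1:7, n, replace = TRUE)
    )
    for (r in raters) out[[r]] <- sample(1:7, n, replace = TRUE)
    out
  })
}
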