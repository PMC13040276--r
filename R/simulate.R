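#' Define a simulated rater's error profile
#'
#' A simulated rater labels a frame of true stage `s` correctly with
#' probability `a_s` (`accuracy`, recycled over the 7 stages if scalar).
#' When it errs, the wrong stage `j != s` is drawn with probability
#' proportional to `rho^(|j - s| - 1)`: geometric decay over ordinal
#' distance, so small `rho` concentrates errors on ordinally adjacent
#' stages, the pattern observed for both embryologists and networks.
#'
#' @param rater_id Character scalar naming the rater (becomes a column of
#'   the simulated table).
#' @param accuracy Per-stage probability of a correct label; scalar or
#'   length-7 vector, each in `[0, 1]`.
#' @param adjacency_decay Geometric decay `rho` in `(0, 1)` of the error
#'   distribution over ordinal distance. Default 0.25 (heavily adjacent).
#' @return An object of class `rater_profile`.
#' @examples
#' rater_profile("E1", accuracy = 0.95)
#' rater_profile("vgg16", accuracy = c(0.8, 0.7, 0.8, 0.5, 0.8, 0.9, 1.0))
#' @export
rater_profile <- function(rater_id, accuracy = 0.9, adjacency_decay = 0.25) {
  stopifnot(is.character(rater_id), length(rater_id) == 1L)
  if (length(accuracy) == 1L) accuracy <- rep(accuracy, n_stages())
  if (length(accuracy) != n_stages() || anyNA(accuracy) ||
      any(accuracy < 0) || any(accuracy > 1)) {
    abort("`accuracy` must be 7 probabilities in [0, 1]",
          class = "embryoxai_parameter_error")
  }
  if (!is.numeric(adjacency_decay) || length(adjacency_decay) != 1L ||
      adjacency_decay <= 0 || adjacency_decay >= 1) {
    abort("`adjacency_decay` must lie strictly in (0, 1)",
          class = "embryoxai_parameter_error")
  }
  structure(
    list(rater_id = rater_id,
         accuracy = as.numeric(accuracy),
         adjacency_decay = adjacency_decay),
    class = "rater_profile"
  )
}

#' @export
print.rater_profile <- function(x, ...) {
  cat("<rater_profile> ", x$rater_id, "\n", sep = "")
  cat("  per-stage accuracy: ", paste(format(x$accuracy), collapse = " "), "\n")
  cat("  adjacency decay rho:", x$adjacency_decay, "\n")
  invisible(x)
}

#' Analytic confusion matrix of a simulated rater
#'
#' Row `s` gives the label distribution of the rater on frames whose true
#' stage is `s`: `a_s` on the diagonal, and off-diagonal mass
#' `(1 - a_s) * rho^(|j - s| - 1)` normalized over `j != s`.
#'
#' @param profile A [rater_profile()].
#' @return A 7x7 row-stochastic matrix.
#' @export
rater_confusion <- function(profile) {
  stopifnot(inherits(profile, "rater_profile"))
  K <- n_stages()
  rho <- profile$adjacency_decay
  C <- matrix(0, K, K, dimnames = list(true = 1:K, labelled = 1:K))
  for (s in 1:K) {
    w <- rho^(abs(1:K - s) - 1)
    w[s] <- 0
    C[s, ] <- (1 - profile$accuracy[s]) * w / sum(w)
    C[s, s] <- profile$accuracy[s]
  }
  C
}

#' Simulate a multi-rater stage-label table
#'
#' Generates per-frame reference stages according to `frames_per_stage`,
#' spreads frames over `n_embryos` embryos, and draws every rater's label
#' independently from that rater's confusion distribution
#' (see [rater_confusion()]). Identical seed and inputs give identical
#' tables.
#'
#' @param n_embryos Number of embryos the frames are attributed to.
#' @param frames_per_stage Frame count per stage: a scalar (recycled) or a
#'   length-7 vector ordered by stage code.
#' @param profiles A list of [rater_profile()] objects (at least one).
#' @param seed Integer seed; drives all randomness, global RNG state is
#'   left untouched.
#' @return A tibble with columns `embryo_id`, `frame_id`, `reference`, and
#'   one integer stage-code column per rater.
#' @examples
#' tab <- simulate_rating_table(
#'   n_embryos = 4, frames_per_stage = 3,
#'   profiles = list(rater_profile("E1", 0.9), rater_profile("E2", 0.8)),
#'   seed = 1
#' )
#' head(tab)
#' @export
simulate_rating_table <- function(n_embryos, frames_per_stage, profiles, seed) {
  if (!is.numeric(n_embryos) || n_embryos < 1) {
    abort("`n_embryos` must be >= 1", class = "embryoxai_parameter_error")
  }
  if (length(frames_per_stage) == 1L) {
    frames_per_stage <- rep(frames_per_stage, n_stages())
  }
  if (length(frames_per_stage) != n_stages() || any(frames_per_stage < 0)) {
    abort("`frames_per_stage` must be 7 non-negative counts",
          class = "embryoxai_parameter_error")
  }
  if (length(profiles) < 1L ||
      !all(vapply(profiles, inherits, logical(1), "rater_profile"))) {
    abort("`profiles` must be a non-empty list of rater_profile objects",
          class = "embryoxai_parameter_error")
  }
  frames_per_stage <- as.integer(frames_per_stage)
  total <- sum(frames_per_stage)
  if (total == 0L) {
    abort("zero frames requested", class = "embryoxai_empty_error")
  }
  reference <- rep(1:7, times = frames_per_stage)
  embryo_id <- sprintf("E%03d", ((seq_len(total) - 1L) %% n_embryos) + 1L)
  frame_id <- sprintf("F%04d", seq_len(total))
  out <- tibble(embryo_id = embryo_id, frame_id = frame_id,
                reference = as.integer(reference))
  withr::with_seed(seed, {
    for (p in profiles) {
      C <- rater_confusion(p)
      lab <- integer(total)
      for (s in 1:7) {
        idx <- which(reference == s)
        if (length(idx) > 0L) {
          lab[idx] <- sample(1:7, length(idx), replace = TRUE, prob = C[s, ])
        }
      }
      out[[p$rater_id]] <- lab
    }
  })
  out
}

#' Closed-form quadratic-weighted kappa between two simulated raters
#'
#' For two raters acting independently given the true stage, the joint
#' label distribution is `P(i, j) = sum_s pi_s C1[s, i] C2[s, j]` where
#' `pi` is the stage prevalence and `C1`, `C2` the raters' confusion
#' matrices. The quadratic-weighted kappa of that joint distribution is the
#' population value that the sample estimate converges to.
#'
#' @param profile_a,profile_b [rater_profile()] objects.
#' @param prevalence Stage prevalence `pi`, length 7, summing to 1
#'   (default uniform).
#' @return The population quadratic-weighted kappa (scalar).
#' @export
expected_pairwise_kappa <- function(profile_a, profile_b,
                                    prevalence = rep(1 / 7, 7)) {
  stopifnot(length(prevalence) == 7, all(prevalence >= 0))
  prevalence <- prevalence / sum(prevalence)
  C1 <- rater_confusion(profile_a)
  C2 <- rater_confusion(profile_b)
  P <- matrix(0, 7, 7)
  for (s in 1:7) P <- P + prevalence[s] * outer(C1[s, ], C2[s, ])
  w <- quadratic_weights(7)
  po <- sum(w * P)
  pe <- sum(w * outer(rowSums(P), colSums(P)))
  (po - pe) / (1 - pe)
}

#' Simulate qualitative spatial-focus ratings of explanation heatmaps
#'
#' Draws one "good"/"intermediate"/"poor" consensus rating per frame and
#' model, from per-model rating probabilities (optionally stage-specific).
#' Ratings are drawn independently of classification correctness, so the
#' generator is a null model for the focus-versus-accuracy analysis.
#'
#' @param table A rating table (used for its `frame_id` and `reference`).
#' @param model_probs A named list: for each model id either a length-3
#'   probability vector `(good, intermediate, poor)` or a 7x3 matrix with
#'   one row per stage.
#' @param seed Integer seed.
#' @return A tibble with columns `frame_id`, `model_id`, `rating`.
#' @export
simulate_focus_ratings <- function(table,
                                   model_probs = list(
                                     resnet34 = c(0.89, 0.10, 0.01),
                                     vgg16 = c(0.59, 0.14, 0.27)
                                   ),
                                   seed = 1L) {
  assert_rating_table(table, raters = character(0))
  levs <- c("good", "intermediate", "poor")
  withr::with_seed(seed, {
    res <- purrr::imap(model_probs, function(p, model) {
      if (is.matrix(p)) {
        stopifnot(nrow(p) == 7, ncol(p) == 3)
        pm <- p
      } else {
        stopifnot(length(p) == 3)
        pm <- matrix(p, nrow = 7, ncol = 3, byrow = TRUE)
      }
      pm <- pm / rowSums(pm)
      rating <- vapply(table$reference, function(s) {
        sample(levs, 1L, prob = pm[s, ])
      }, character(1))
      tibble(frame_id = table$frame_id, model_id = model, rating = rating)
    })
  })
  dplyr::bind_rows(res)
}
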