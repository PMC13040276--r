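#' Read a ratings CSV
#'
#' Expected header: `embryo_id,frame_id,reference,<rater>...` with stage
#' values given as codes 1..7 or names (`t2`..`t9`, `tM`, `tB`); `t8` and
#' `t9` normalize to the merged code 5. Malformed stage values are
#' reported with their line number; duplicate `(embryo_id, frame_id)` keys
#' and header-only files are errors.
#'
#' @param path CSV file path.
#' @return A rating table tibble with integer stage codes.
#' @export
read_ratings <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("embryo_id", "frame_id", "reference")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
          class = "embryoxai_data_error")
  }
  raters <- setdiff(names(raw), need)
  if (length(raters) == 0L) {
    abort(sprintf("%s: no rater columns", path), class = "embryoxai_data_error")
  }
  if (nrow(raw) == 0L) {
    abort(sprintf("%s: no data rows", path), class = "embryoxai_empty_error")
  }
  key <- paste(raw$embryo_id, raw$frame_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), ]
    abort(sprintf("%s: duplicate (embryo_id, frame_id) key: (%s, %s)",
                  path, d$embryo_id[1L], d$frame_id[1L]),
          class = "embryoxai_data_error")
  }
  for (col in c("reference", raters)) {
    raw[[col]] <- tryCatch(
      encode_stage(raw[[col]]),
      embryoxai_parse_error = function(e) {
        bad_line <- which(is.na(suppressWarnings(
          tryCatch(encode_stage_or_na(raw[[col]]), error = function(...) NULL)
        )))
        abort(sprintf("%s: column '%s': %s (first at data line %d)",
                      path, col, conditionMessage(e),
                      if (length(bad_line)) bad_line[1L] else NA_integer_),
              class = "embryoxai_parse_error")
      })
  }
  raw
}

encode_stage_or_na <- function(label) {
  out <- rep(NA_integer_, length(label))
  for (i in seq_along(label)) {
    out[i] <- tryCatch(encode_stage(label[i]), error = function(e) NA_integer_)
  }
  out
}

#' Read a focus-rating CSV
#'
#' Expected header: `frame_id,model_id,rating` with ratings in
#' good/intermediate/poor.
#'
#' @param path CSV file path.
#' @return A focus-rating tibble.
#' @export
read_focus_ratings <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_focus_table(raw)
  raw
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates and writes everything a downstream analysis consumes:
#' `ratings.csv` (simulated rater table), `focus_ratings.csv`, and per
#' frame and simulated model a Grad-CAM overlay PNG, a LIME overlay PNG
#' and the ground-truth mask PNG, plus `manifest.csv` tying them together.
#' Deterministic under a fixed seed.
#'
#' @param dir Output directory (created if absent).
#' @param config List overriding defaults: `n_embryos`, `frames_per_stage`,
#'   `profiles` (list of [rater_profile()]), `models` (character ids),
#'   `image_size`, `images_per_stage` (frames per stage that get overlay
#'   renders; `Inf` renders all).
#' @param seed Integer seed.
#' @return Invisibly, a list with the written paths and the in-memory
#'   tables.
#' @export
make_fixture_bundle <- function(dir, config = list(), seed = 7L) {
  cfg <- utils::modifyList(list(
    n_embryos = 31L,
    frames_per_stage = 35L,
    profiles = list(
      rater_profile("E1", 0.92), rater_profile("E2", 0.90),
      rater_profile("E3", 0.88),
      rater_profile("resnet34", 0.79, adjacency_decay = 0.3),
      rater_profile("vgg16", 0.74, adjacency_decay = 0.3)
    ),
    models = c("resnet34", "vgg16"),
    image_size = 112L,
    images_per_stage = 2L
  ), config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory %s", dir),
          class = "embryoxai_io_error")
  }
  tab <- simulate_rating_table(cfg$n_embryos, cfg$frames_per_stage,
                               cfg$profiles, seed = seed)
  readr::write_csv(tab, file.path(dir, "ratings.csv"))
  focus <- simulate_focus_ratings(tab, seed = seed + 1L)
  readr::write_csv(focus, file.path(dir, "focus_ratings.csv"))

  sz <- cfg$image_size
  img_dir <- file.path(dir, "overlays")
  dir.create(img_dir, showWarnings = FALSE)
  sel <- tab |>
    dplyr::group_by(.data$reference) |>
    dplyr::slice_head(n = if (is.finite(cfg$images_per_stage))
      cfg$images_per_stage else dplyr::n()) |>
    dplyr::ungroup()
  manifest <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    purrr::map_dfr(cfg$models, function(model) {
      fseed <- seed + 13L * i + 131L * match(model, cfg$models)
      sim <- simulate_explanation_pair(sz, sz, stage = sel$reference[i],
                                       model = model, seed = fseed)
      stem <- sprintf("%s_%s", sel$frame_id[i], model)
      p_g <- file.path(img_dir, paste0(stem, "_gradcam.png"))
      p_l <- file.path(img_dir, paste0(stem, "_lime.png"))
      p_t <- file.path(img_dir, paste0(stem, "_truth.png"))
      write_overlay_png(sim$gradcam, p_g)
      write_overlay_png(sim$lime, p_l)
      write_mask_png(sim$truth$truth_mask, p_t)
      tibble(frame_id = sel$frame_id[i], stage = sel$reference[i],
             model = model, gradcam_path = p_g, lime_path = p_l,
             truth_path = p_t)
    })
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(list(dir = dir, ratings = tab, focus = focus,
                 manifest = manifest))
}

#' Simulate one Grad-CAM/LIME explanation pair with known truth
#'
#' Draws a ground-truth attention disc for the frame, renders the Grad-CAM
#' overlay from it, and renders a LIME overlay whose superpixel regions
#' overlap the attention region to a model- and stage-dependent degree, so
#' downstream IoU varies by stage and model as in real explanation pairs.
#' `overlap_shift` 0 keeps the LIME region centered on the attention
#' region; larger values displace it by that fraction of the radius.
#'
#' @param width,height Image size in pixels.
#' @param stage Stage code 1..7 (drives the default displacement).
#' @param model Model id; the second model listed gets larger
#'   displacements at the morula/blastocyst stages, mimicking
#'   divergent-late-stage behavior.
#' @param overlap_shift Optional explicit displacement fraction.
#' @param seed Integer seed.
#' @return List: `truth` ([attention_field()]), `gradcam`, `lime`
#'   (overlay arrays), `lime_regions` (list of masks).
#' @export
simulate_explanation_pair <- function(width, height, stage = 4L,
                                      model = "resnet34",
                                      overlap_shift = NULL, seed = 1L) {
  shift <- overlap_shift %||% {
    base <- 0.55
    if (stage >= 6L && grepl("vgg", model)) 1.6 else base
  }
  rad <- min(width, height) * 0.42
  truth <- attention_field(width, height, kind = "disc",
                           center = c(width / 2, height / 2), radius = rad,
                           relevance_cutoff = 0.25)
  grad <- render_gradcam_overlay(truth, seed = seed)
  truth_r <- rad * sqrt(1 - truth$relevance_cutoff)
  ang <- withr::with_seed(seed, stats::runif(1, 0, 2 * pi))
  lime_center <- c(width / 2 + cos(ang) * shift * truth_r,
                   height / 2 + sin(ang) * shift * truth_r)
  lime_r <- truth_r * 0.8
  margin <- 4 + lime_r
  lime_center <- pmin(pmax(lime_center, margin),
                      c(width, height) - margin)
  regions <- list(disc_mask(width, height, lime_center, lime_r))
  lime <- render_lime_overlay(regions, background = 128, line_width = 2L)
  list(truth = truth, gradcam = grad, lime = lime, lime_regions = regions)
}
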