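#' Default pipeline configuration
#'
#' The default simulated study mirrors the scale of a time-lapse test set:
#' 245 frames from 31 embryos over the 7 merged stages (equal per-stage
#' counts), three embryologist-like raters and two model-like raters with
#' adjacent-stage error structure, plus rendered explanation overlays for
#' a per-stage subset of frames.
#'
#' @return A nested configuration list; override any entry and pass to
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    simulate = list(
      n_embryos = 31L,
      frames_per_stage = 35L,
      raters = list(
        list(id = "E1", accuracy = 0.92, adjacency_decay = 0.25),
        list(id = "E2", accuracy = 0.90, adjacency_decay = 0.25),
        list(id = "E3", accuracy = 0.88, adjacency_decay = 0.25),
        list(id = "resnet34", accuracy = 0.79, adjacency_decay = 0.3),
        list(id = "vgg16", accuracy = 0.74, adjacency_decay = 0.3)
      ),
      human_raters = c("E1", "E2", "E3"),
      model_raters = c("resnet34", "vgg16"),
      focus = list(resnet34 = c(0.89, 0.10, 0.01),
                   vgg16 = c(0.59, 0.14, 0.27)),
      image_size = 112L,
      images_per_stage = 4L
    )
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "embryoxai_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML path",
          class = "embryoxai_config_error")
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$input)
  if (has_sim == has_inp) {
    abort("config must contain exactly one of `simulate` or `input`",
          class = "embryoxai_config_error")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "embryoxai_pipeline_error", parent = e)
  })
}

kappa_row <- function(kr, label) {
  tidy(kr) |> dplyr::mutate(comparison = label, .before = 1L)
}

#' Run the full evaluation pipeline
#'
#' Executes every analysis stage in order: ingest or simulate the rating
#' table, compute accuracy and confusion matrices, the agreement battery
#' (weighted kappa against the reference, all pairwise kappas, Fleiss'
#' kappa among the human raters, stage-specific kappas, Cochran's Q with
#' Holm-adjusted McNemar post-hocs), the focus-rating analysis, and the
#' explanation-overlap (IoU) analysis. Identical config and seed give an
#' identical bundle.
#'
#' @param config A configuration list (see [default_config()]) or a path
#'   to a YAML file with the same structure.
#' @return A `report_bundle` list; write it out with [write_report()].
#' @examples
#' \donttest{
#' cfg <- default_config()
#' cfg$simulate$frames_per_stage <- 6L
#' cfg$simulate$images_per_stage <- 1L
#' bundle <- run_pipeline(cfg)
#' bundle$accuracy
#' }
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_run_config(config)
  seed <- cfg$seed

  # ---- ingest / simulate -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    profiles <- run_stage("simulate", lapply(sim$raters, function(r) {
      rater_profile(r$id, accuracy = unlist(r$accuracy),
                    adjacency_decay = r$adjacency_decay %||% 0.25)
    }))
    table <- run_stage("simulate", simulate_rating_table(
      sim$n_embryos %||% 31L, unlist(sim$frames_per_stage %||% 35L),
      profiles, seed = seed))
    humans <- sim$human_raters %||% grep("^E", rater_columns(table), value = TRUE)
    models <- sim$model_raters %||% setdiff(rater_columns(table), humans)
    focus <- run_stage("focus_simulate", simulate_focus_ratings(
      table, model_probs = lapply(sim$focus %||%
        setNames(rep(list(c(0.7, 0.2, 0.1)), length(models)), models), unlist),
      seed = seed + 1L))
  } else {
    inp <- cfg$input
    table <- run_stage("ingest", read_ratings(inp$ratings))
    humans <- inp$human_raters %||% grep("^E", rater_columns(table), value = TRUE)
    models <- inp$model_raters %||% setdiff(rater_columns(table), humans)
    focus <- if (!is.null(inp$focus_ratings)) {
      run_stage("ingest", read_focus_ratings(inp$focus_ratings))
    }
  }
  raters <- rater_columns(table)

  # ---- accuracy / confusion ---------------------------------------------
  acc <- run_stage("accuracy", {
    per <- purrr::map_dfr(raters, function(r) {
      accuracy(table, r) |> dplyr::mutate(rater = r, .before = 1L)
    })
    pooled <- if (length(humans) > 1L) {
      accuracy(table, humans) |>
        dplyr::mutate(rater = paste(humans, collapse = "+"), .before = 1L)
    }
    dplyr::bind_rows(pooled, per)
  })
  acc_by_stage <- run_stage("accuracy", purrr::map_dfr(raters, function(r) {
    accuracy(table, r, by_stage = TRUE) |> dplyr::mutate(rater = r, .before = 1L)
  }))
  conf <- run_stage("confusion", setNames(lapply(raters, confusion,
                                                 data = table), raters))

  # ---- agreement battery -------------------------------------------------
  kappa_ref <- run_stage("kappa", purrr::map_dfr(raters, function(r) {
    kappa_row(cohen_weighted_kappa(table, r, "reference"),
              paste0(r, " vs reference"))
  }))
  pair_idx <- combn(raters, 2L)
  kappa_pair <- run_stage("kappa", purrr::map_dfr(
    seq_len(ncol(pair_idx)), function(j) {
      kappa_row(cohen_weighted_kappa(table, pair_idx[1L, j], pair_idx[2L, j]),
                paste(pair_idx[1L, j], pair_idx[2L, j], sep = "-"))
    }))
  fleiss <- if (length(humans) >= 3L) {
    run_stage("kappa", kappa_row(fleiss_kappa(table, humans),
                                 paste(humans, collapse = "+")))
  }
  stage_kappa <- run_stage("stage_kappa", purrr::map_dfr(1:7, function(s) {
    rows <- NULL
    if (length(humans) >= 3L) {
      hk <- tryCatch(
        fleiss_kappa(table[table$reference == s, , drop = FALSE], humans),
        error = function(e) NULL)
      if (!is.null(hk)) {
        rows <- dplyr::bind_rows(rows, kappa_row(hk, "embryologists") |>
                                   dplyr::mutate(stage = s, .before = 1L))
      }
    }
    if (length(models) == 2L) {
      mk <- tryCatch(
        cohen_weighted_kappa(table, models[1L], models[2L], subgroup_stage = s),
        error = function(e) NULL)
      if (!is.null(mk)) {
        rows <- dplyr::bind_rows(rows, kappa_row(mk, "models") |>
                                   dplyr::mutate(stage = s, .before = 1L))
      }
    }
    rows
  }))

  grid <- run_stage("cochran", correctness_grid(table, raters))
  # a constant grid (e.g. all raters perfect) leaves Q undefined; report NULL
  q_test <- tryCatch(run_stage("cochran", cochran_q(grid)),
                     embryoxai_pipeline_error = function(e) {
                       if (inherits(e$parent, "embryoxai_degenerate_error"))
                         NULL else stop(e)
                     })
  mcnemar <- run_stage("mcnemar", mcnemar_pairwise(grid))

  # ---- focus-rating analysis --------------------------------------------
  focus_out <- NULL
  if (!is.null(focus) && length(models) > 0L) {
    stages_lut <- tibble(frame_id = table$frame_id, stage = table$reference)
    correct <- purrr::map_dfr(intersect(models, raters), function(m) {
      tibble(frame_id = table$frame_id, model_id = m,
             correct = table[[m]] == table$reference)
    })
    focus_out <- run_stage("focus", {
      props <- rating_proportions(focus, stages_lut)
      comps <- if (length(unique(focus$model_id)) >= 2L) {
        ms <- sort(unique(focus$model_id))[1:2]
        purrr::map_dfr(focus_levels(), function(lev) {
          ts <- compare_models_on_rating(focus, ms[1L], ms[2L], lev)
          tidy(ts) |> dplyr::mutate(rating = lev,
                                    model_a = ms[1L], model_b = ms[2L],
                                    prop_a = ts$extras$prop_a,
                                    prop_b = ts$extras$prop_b, .before = 1L)
        })
      }
      afc <- accuracy_by_focus(focus, correct, stages_lut)
      list(proportions = props, model_comparisons = comps,
           accuracy_by_focus = afc$cells, focus_tests = afc$tests)
    })
  }

  # ---- explanation overlap ----------------------------------------------
  iou_out <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if ((sim$images_per_stage %||% 0L) > 0L && length(models) > 0L) {
      iou_out <- run_stage("iou", {
        sel <- table |>
          dplyr::group_by(.data$reference) |>
          dplyr::slice_head(n = sim$images_per_stage) |>
          dplyr::ungroup()
        sz <- sim$image_size %||% 112L
        recs <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
          purrr::map_dfr(models, function(m) {
            fseed <- seed + 13L * i + 131L * match(m, models)
            pair <- simulate_explanation_pair(sz, sz,
                                              stage = sel$reference[i],
                                              model = m, seed = fseed)
            gm <- gradcam_to_mask(pair$gradcam)
            lm <- suppressWarnings(lime_to_mask(pair$lime))
            tibble(frame_id = sel$frame_id[i], stage = sel$reference[i],
                   model = m, iou = iou(gm, lm)$iou)
          })
        })
        list(records = recs,
             summary = stagewise_iou_summary(recs),
             tests = if (length(models) >= 2L) stagewise_iou_tests(recs))
      })
    }
  } else if (!is.null(cfg$input$manifest)) {
    iou_out <- run_stage("iou", {
      man <- readr::read_csv(cfg$input$manifest,
                             col_types = readr::cols(), progress = FALSE)
      recs <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
        gm <- gradcam_to_mask(read_overlay_png(man$gradcam_path[i], "gradcam"))
        lm <- suppressWarnings(lime_to_mask(read_overlay_png(man$lime_path[i], "lime")))
        tibble(frame_id = man$frame_id[i],
               stage = encode_stage(man$stage[i]),
               model = man$model[i], iou = iou(gm, lm)$iou)
      })
      list(records = recs,
           summary = stagewise_iou_summary(recs),
           tests = if (length(unique(recs$model)) >= 2L)
             stagewise_iou_tests(recs))
    })
  }

  structure(
    list(
      table = table,
      raters = raters, human_raters = humans, model_raters = models,
      accuracy = acc, accuracy_by_stage = acc_by_stage,
      confusion = conf,
      kappa_vs_reference = kappa_ref,
      kappa_pairwise = kappa_pair,
      fleiss = fleiss,
      stage_kappa = stage_kappa,
      cochran_q = if (!is.null(q_test)) tidy(q_test),
      mcnemar = mcnemar,
      focus = focus_out,
      iou = iou_out,
      provenance = list(
        config_hash = rlang::hash(cfg),
        seed = seed,
        package_version = as.character(utils::packageVersion("embryoxai"))
      )
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  frames:", nrow(x$table), " raters:", paste(x$raters, collapse = ", "), "\n")
  cat("  pooled/overall accuracy:\n")
  print(x$accuracy, n = 3)
  cat("  kappa vs reference:\n")
  print(x$kappa_vs_reference[, c("comparison", "estimate", "conf.low",
                                 "conf.high", "p.value")], n = 5)
  invisible(x)
}

md_table <- function(df, digits = 3) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ round(.x, digits)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the machine-readable bundle), Markdown tables
#' mirroring the standard report surfaces (kappa against the reference,
#' pairwise kappa, accuracy, IoU summary), and optionally PNG figures.
#' Output is byte-identical across runs with the same config and seed.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param figures If `TRUE`, also write confusion heatmap, stage-kappa
#'   forest plot and IoU-median figures as PNG.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, figures = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  json_path <- file.path(dir, "report.json")
  payload <- list(
    provenance = bundle$provenance,
    accuracy = bundle$accuracy,
    accuracy_by_stage = bundle$accuracy_by_stage,
    kappa_vs_reference = bundle$kappa_vs_reference,
    kappa_pairwise = bundle$kappa_pairwise,
    fleiss = bundle$fleiss,
    stage_kappa = bundle$stage_kappa,
    cochran_q = bundle$cochran_q,
    mcnemar = bundle$mcnemar,
    confusion_counts = lapply(bundle$confusion, function(cm) unclass(cm$counts)),
    focus = bundle$focus,
    iou = if (!is.null(bundle$iou)) bundle$iou[c("records", "summary", "tests")]
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  written <- c(written, json_path)
  md_path <- file.path(dir, "report.md")
  md <- c(
    "# Evaluation report",
    "",
    sprintf("seed %d, config %s, embryoxai %s", bundle$provenance$seed,
            bundle$provenance$config_hash, bundle$provenance$package_version),
    "", "## Accuracy", "", md_table(bundle$accuracy),
    "", "## Weighted kappa vs reference standard", "",
    md_table(bundle$kappa_vs_reference[, c("comparison", "estimate",
                                           "conf.low", "conf.high", "p.value")]),
    "", "## Pairwise weighted kappa", "",
    md_table(bundle$kappa_pairwise[, c("comparison", "estimate",
                                       "conf.low", "conf.high", "p.value")])
  )
  if (!is.null(bundle$iou)) {
    md <- c(md, "", "## Stage-wise IoU", "", md_table(bundle$iou$summary))
  }
  writeLines(paste(md, collapse = "\n"), md_path)
  written <- c(written, md_path)
  if (figures) {
    for (r in names(bundle$confusion)) {
      p <- file.path(dir, sprintf("confusion_%s.png", r))
      ggplot2::ggsave(p, autoplot(bundle$confusion[[r]]),
                      width = 5, height = 4, dpi = 150)
      written <- c(written, p)
    }
    if (nrow(bundle$stage_kappa %||% tibble()) > 0L) {
      p <- file.path(dir, "stage_kappa.png")
      ggplot2::ggsave(p, plot_stage_kappa(bundle$stage_kappa),
                      width = 6, height = 4, dpi = 150)
      written <- c(written, p)
    }
    if (!is.null(bundle$iou)) {
      p <- file.path(dir, "iou_medians.png")
      ggplot2::ggsave(p, plot_iou_medians(bundle$iou$summary),
                      width = 6, height = 4, dpi = 150)
      written <- c(written, p)
    }
  }
  invisible(written)
}
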