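#' Pipeline configuration
#'
#' Orchestration parameters for [run_pipeline()]: how many synthetic
#' colonies to generate, the simulation settings shared by all of them, the
#' landmark frames (374/672/960 are the Day 4/7/10 frames of a 15-min
#' acquisition that started ~7.5 h after plating), the contact threshold
#' and statistics level, and which stages to run.
#'
#' @param sim a [simulation_config()]; its `rng_seed` is re-derived per
#'   colony from `rng_seed` below.
#' @param n_colonies number of independent single-founder experiments.
#' @param day4_frame,day7_frame,day10_frame landmark frames.
#' @param neighbor_threshold_px contact rule threshold (px).
#' @param alpha uncorrected significance level.
#' @param rng_seed master seed; colony `i` simulates with
#'   `rng_seed * 1000 + i`.
#' @param do_classify,do_stats,do_viz stage toggles.
#' @param out_dir optional output directory; when set, all artifacts are
#'   written there as CSV/JSON.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(n_frames = 672),
                            n_colonies = 5L,
                            day4_frame = 374L, day7_frame = 672L,
                            day10_frame = 960L,
                            neighbor_threshold_px = 15,
                            alpha = 0.05, rng_seed = 1L,
                            do_classify = TRUE, do_stats = TRUE,
                            do_viz = TRUE, out_dir = NULL) {
  if (is.list(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(simulation_config, sim)
  }
  if (!(day4_frame < day7_frame && day7_frame < day10_frame)) {
    stop("landmark frames must be strictly increasing")
  }
  if (neighbor_threshold_px <= 0) stop("neighbor_threshold_px must be > 0")
  structure(list(sim = sim, n_colonies = as.integer(n_colonies),
                 day4_frame = as.integer(day4_frame),
                 day7_frame = as.integer(day7_frame),
                 day10_frame = as.integer(day10_frame),
                 neighbor_threshold_px = neighbor_threshold_px,
                 alpha = alpha, rng_seed = as.integer(rng_seed),
                 do_classify = do_classify, do_stats = do_stats,
                 do_viz = do_viz, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full synthetic-colony analysis pipeline
#'
#' Stages, in order: simulate `n_colonies` independent experiments; export
#' and rebuild each lineage from its tracking matrix (exercising the same
#' path used for real tracking data); build the pooled per-cell feature
#' table; classify fates, progeny classes, twin asynchrony and colony
#' origin; run the statistical layer (lifetime summary, filtered Spearman
#' screen, per-progeny generation-area trends, generation dispersion, PCA +
#' k-means); and emit drawing specs. Every stage logs its counts. The whole
#' run is deterministic for a fixed `rng_seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result` with elements `config`,
#'   `experiments`, `forests`, `features` (pooled), `fates`, `classes`,
#'   `asynchrony`, `origins`, `colony_metrics`, `lifetime_summary`,
#'   `correlations`, `trends`, `dispersion`, `embedding`, `trees`,
#'   `glyphs` (stages that were toggled off are `NULL`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("pipeline: %d colonies, seed %d, frames to %d", config$n_colonies,
      config$rng_seed, config$sim$n_frames)

  experiments <- forests <- trees <- glyphs <- vector("list",
                                                      config$n_colonies)
  feats <- asyn <- origins <- list()
  fates <- character()
  metrics <- vector("list", config$n_colonies)

  for (i in seq_len(config$n_colonies)) {
    cfg_i <- config$sim
    cfg_i$rng_seed <- config$rng_seed * 1000L + i
    exp_i <- simulate_colony(cfg_i)
    m <- export_tracking_matrix(exp_i)
    f <- build_forest(m)
    experiments[[i]] <- exp_i
    forests[[i]] <- f

    tr <- exp_i$tracks
    fate_i <- stats::setNames(exp_i$cells$fate,
                              as.character(exp_i$cells$cell_id))
    ft <- build_feature_table(f, tr, fates = fate_i,
                              day4_frame = min(config$day4_frame,
                                               cfg_i$n_frames))
    ft$colony_id <- sprintf("colony%02d_%s", i, ft$colony_id)
    ft$cell_id <- sprintf("colony%02d_%s", i, ft$cell_id)
    feats[[i]] <- ft
    fates <- c(fates, stats::setNames(
      fate_i, sprintf("colony%02d_%s", i, names(fate_i))))

    if (config$do_classify) {
      asyn[[i]] <- classify_asynchrony(f, sd_d = "auto")
      origins[[i]] <- classify_origin(f, f$records$cell_id,
                                      colony_id = sprintf("colony%02d", i))
    }
    d7 <- min(config$day7_frame, cfg_i$n_frames)
    at7 <- tr[tr$frame == d7, ]
    metrics[[i]] <- colony_hull_metrics(
      positions = cbind(at7$x_um, at7$y_um), areas_um2 = at7$area_um2)
    if (config$do_viz) {
      trees[[i]] <- render_tree(f, tr)
      d4 <- min(config$day4_frame, cfg_i$n_frames)
      at4 <- tr[tr$frame == d4, ]
      snap <- merge(at4, exp_i$cells[, c("cell_id", "generation")],
                    by = "cell_id")
      cls <- classify_progeny(progeny_counts(f, d4))
      glyphs[[i]] <- render_glyph(snap, classes = cls, fates = fate_i)
    }
    say("  colony %d: %d cells, %d divisions", i, nrow(exp_i$cells),
        sum(exp_i$cells$fate == "divided"))
  }

  features <- do.call(rbind, feats)
  filt <- attr(feats[[1L]], "filters")
  attr(features, "filters") <- filt
  say("features: %d cells x %d columns", nrow(features), ncol(features))

  lifetime_summary <- dividing_lifetime_stats(forests)
  say("lifetimes: %d dividing cells, %.3f +/- %.3f d",
      lifetime_summary$n, lifetime_summary$mean_d, lifetime_summary$sd_d)

  correlations <- trends <- dispersion <- embedding <- NULL
  if (config$do_stats) {
    correlations <- correlation_matrix(features, alpha = config$alpha)
    trends <- generation_area_trend(features)
    dispersion <- unlist(lapply(forests, function(f) {
      generation_dispersion(f, min(config$day4_frame, config$sim$n_frames))
    }))
    emb_props <- c("avg_area", "max_area", "area_at_birth",
                   "avg_area_first_083d", "total_distance_traveled",
                   "avg_n_neighbors", "max_n_neighbors", "cum_n_neighbors",
                   "n_neighbors_at_birth", "generation")
    embedding <- tryCatch(
      pca_embed(features, properties = emb_props,
                seed = config$rng_seed),
      error = function(e) NULL)
    say("stats: %d correlation pairs (Bonferroni p = %.2e), %d trends",
        correlations$m, correlations$bonferroni_p, nrow(trends))
  }

  res <- structure(list(
    config = config, experiments = experiments, forests = forests,
    features = features, fates = fates,
    classes = if (config$do_classify) {
      do.call(rbind, lapply(seq_along(forests), function(i) {
        cls <- classify_progeny(progeny_counts(
          forests[[i]], min(config$day4_frame, config$sim$n_frames)))
        cls$founder_id <- sprintf("colony%02d_%s", i, cls$founder_id)
        cls
      }))
    } else NULL,
    asynchrony = if (config$do_classify) do.call(rbind, asyn) else NULL,
    origins = if (config$do_classify) do.call(rbind, origins) else NULL,
    colony_metrics = metrics, lifetime_summary = lifetime_summary,
    correlations = correlations, trends = trends, dispersion = dispersion,
    embedding = embedding,
    trees = if (config$do_viz) trees else NULL,
    glyphs = if (config$do_viz) glyphs else NULL
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir,
                                                       quiet = quiet)
  res
}

write_pipeline_outputs <- function(res, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  for (i in seq_along(res$experiments)) {
    m <- export_tracking_matrix(res$experiments[[i]])
    write_object_matrix(m, file.path(out_dir,
                                     sprintf("matrix_%02d.csv", i)))
    write_forest_json(res$forests[[i]],
                      file.path(out_dir, sprintf("forest_%02d.json", i)))
  }
  write_feature_table(res$features, file.path(out_dir, "features.csv"))
  if (!is.null(res$correlations)) {
    utils::write.csv(res$correlations$pairs,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(res$trends)) {
    utils::write.csv(res$trends, file.path(out_dir, "trends.csv"),
                     row.names = FALSE, na = "")
  }
  summary_js <- list(
    n_colonies = cfg$n_colonies,
    lifetime_summary = res$lifetime_summary,
    confluency = vapply(res$colony_metrics, `[[`, numeric(1), "confluency"),
    approx_diameter_mm = vapply(res$colony_metrics, `[[`, numeric(1),
                                "approx_diameter_mm")
  )
  jsonlite::write_json(summary_js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) message("outputs written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d colonies, %d cells pooled\n",
              x$config$n_colonies, nrow(x$features)))
  cat(sprintf("  dividing-cell lifetime %.3f +/- %.3f d (n = %d)\n",
              x$lifetime_summary$mean_d, x$lifetime_summary$sd_d,
              x$lifetime_summary$n))
  invisible(x)
}
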