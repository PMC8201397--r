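# Step-wise pipeline: stages communicate only via files in the output
# directory, so each stage is independently runnable, testable and
# replaceable. Every step writes a manifest recording the inputs it
# read, their checksums, the configuration hash and the seed; the report
# step refuses to summarize artifacts produced under inconsistent
# configurations. Manifests carry no timestamps, so a rerun with the
# same config and seed is byte-identical.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving
#' \code{\link{run_step}}. \code{config} may be a YAML file path or a
#' named list; missing entries take the defaults below.
#'
#' @param config YAML path or list. Recognized entries:
#'   \code{output_dir}; \code{seed}; \code{synthetic} (list:
#'   \code{preset} \code{"default"} or \code{"field"}, plus any
#'   \code{\link{synthetic_config}} overrides); \code{cell_size_m}
#'   (default 0.25); \code{quadrat_size_m} (default 1);
#'   \code{exclude_indices}; \code{exclude_samples}; \code{response};
#'   \code{max_candidates}; \code{marginal} (list: \code{focal},
#'   \code{moderator}).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    output_dir = "uavfield_out", seed = 42L,
    synthetic = list(preset = "default"),
    cell_size_m = 0.25, quadrat_size_m = 1,
    exclude_indices = character(), exclude_samples = character(),
    response = "ear_dry_weight_g", max_candidates = 20L,
    marginal = list(focal = "above_dw", moderator = "stem_dw"))
  cfg <- utils::modifyList(defaults, config)
  stop_if_not_scalar_pos(cfg$cell_size_m, "cell_size_m")
  stop_if_not_scalar_pos(cfg$quadrat_size_m, "quadrat_size_m")
  if (!cfg$synthetic$preset %in% c("default", "field")) {
    stop("synthetic$preset must be 'default' or 'field'", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_steps <- c("simulate", "indices", "extract", "select", "predict",
                    "grid", "test-cultivar", "test-traits", "report")

art_path <- function(config, ...) file.path(config$output_dir, ...)

require_artifact <- function(config, rel, producer) {
  p <- art_path(config, rel)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s' — run step '%s' first", rel, producer),
         call. = FALSE)
  }
  p
}

write_manifest <- function(config, step, inputs, outputs) {
  man <- list(
    step = step,
    package = "uavfield",
    version = as.character(utils::packageVersion("uavfield")),
    seed = config$seed,
    config_hash = config_hash(config),
    inputs = if (length(inputs)) {
      as.list(stats::setNames(unname(tools::md5sum(
        art_path(config, inputs))), inputs))
    } else list(),
    outputs = as.list(outputs))
  jsonlite::write_json(man, art_path(config, sprintf("manifest_%s.json", step)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_index_dir <- function(config) {
  dir <- art_path(config, "indices")
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no index rasters found in ", dir, call. = FALSE)
  layers <- lapply(files, read_ascii_grid)
  names(layers) <- sub("\\.asc$", "", basename(files))
  build_index_stack(layers, exclude = config$exclude_indices)
}

build_synthetic_config <- function(config) {
  ov <- config$synthetic
  preset <- ov$preset %||% "default"
  ov$preset <- NULL
  ov$random_seed <- config$seed
  fn <- if (preset == "field") synthetic_config_field_preset else synthetic_config
  do.call(fn, ov)
}

#' Run one pipeline step
#'
#' Steps, in order: \code{simulate} (synthetic experiment to files),
#' \code{indices} (assemble the index stack, apply exclusions),
#' \code{extract} (quadrat covariates joined with harvest data),
#' \code{select} (all-subsets AIC search), \code{predict} (pixel map),
#' \code{grid} (cell classification, aggregation, plot summaries),
#' \code{test-cultivar} and \code{test-traits} (mixed-model inference),
#' \code{report} (consistency check + summary JSON). Each step validates
#' that the artifacts of its prerequisite steps exist and names the
#' producing step in its error if not.
#'
#' @param step step name.
#' @param config a \code{\link{pipeline_config}} (or anything it
#'   accepts).
#' @param verbose print progress lines.
#' @return Invisibly, a list of the step's main outputs.
#' @export
run_step <- function(step, config, verbose = FALSE) {
  step <- match.arg(step, pipeline_steps)
  config <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("[%s] starting", step)
  out <- switch(
    step,
    simulate = {
      scfg <- build_synthetic_config(config)
      exp <- generate_experiment(scfg)
      dir.create(art_path(config, "indices"), showWarnings = FALSE)
      write_layout_geojson(exp$layout, art_path(config, "layout.geojson"))
      write_points_geojson(exp$samples, art_path(config, "points.geojson"))
      write_csv(exp$samples, art_path(config, "samples.csv"))
      write_csv(exp$traits, art_path(config, "traits.csv"))
      for (nm in names(exp$stack$layers)) {
        write_ascii_grid(exp$stack$layers[[nm]],
                         art_path(config, "indices", paste0(nm, ".asc")))
      }
      write_ascii_grid(exp$truth$latent, art_path(config, "truth_latent.asc"))
      write_csv(data.frame(term = names(exp$truth$true_fixed_effects),
                           value = unname(exp$truth$true_fixed_effects)),
                art_path(config, "truth_fixed_effects.csv"))
      write_csv(exp$truth$plot_effects, art_path(config, "truth_plot_effects.csv"))
      write_manifest(config, "simulate", character(),
                     c("layout.geojson", "points.geojson", "samples.csv",
                       "traits.csv", "indices/", "truth_latent.asc"))
      list(experiment = exp)
    },
    indices = {
      require_artifact(config, "manifest_simulate.json", "simulate")
      stack <- read_index_dir(config)
      write_csv(data.frame(layer = names(stack$layers),
                           rows = stack$dim[1], cols = stack$dim[2],
                           pixel_size_m = stack$pixel_size),
                art_path(config, "stack_layers.csv"))
      write_manifest(config, "indices", "layout.geojson", "stack_layers.csv")
      list(stack = stack)
    },
    extract = {
      require_artifact(config, "stack_layers.csv", "indices")
      require_artifact(config, "points.geojson", "simulate")
      require_artifact(config, "samples.csv", "simulate")
      stack <- read_index_dir(config)
      points <- read_points_geojson(art_path(config, "points.geojson"))
      harvest <- utils::read.csv(art_path(config, "samples.csv"),
                                 check.names = FALSE)
      cov <- extract_point_covariates(stack, points, config$quadrat_size_m)
      model_data <- join_samples(
        cov, harvest[c("sample_id", config$response, "straw_dry_weight_g",
                       "mature_ear_count")],
        exclude_ids = config$exclude_samples)
      write_csv(model_data, art_path(config, "model_data.csv"))
      write_manifest(config, "extract",
                     c("stack_layers.csv", "points.geojson", "samples.csv"),
                     "model_data.csv")
      list(model_data = model_data)
    },
    select = {
      require_artifact(config, "model_data.csv", "extract")
      md <- utils::read.csv(art_path(config, "model_data.csv"),
                            check.names = FALSE)
      sel <- select_yield_model(md, response = config$response,
                                exclude = config$exclude_indices,
                                max_candidates = config$max_candidates)
      write_csv(as.data.frame(sel$table), art_path(config, "selection_table.csv"))
      write_best_model(sel$best, art_path(config, "best_model.txt"))
      write_manifest(config, "select", "model_data.csv",
                     c("selection_table.csv", "best_model.txt"))
      list(selection = sel)
    },
    predict = {
      require_artifact(config, "best_model.txt", "select")
      require_artifact(config, "stack_layers.csv", "indices")
      best <- read_best_model(art_path(config, "best_model.txt"))
      stack <- read_index_dir(config)
      map <- predict_pixels(best, stack)
      write_ascii_grid(map, art_path(config, "predicted.asc"))
      write_manifest(config, "predict", c("best_model.txt", "stack_layers.csv"),
                     "predicted.asc")
      list(map = map)
    },
    grid = {
      require_artifact(config, "predicted.asc", "predict")
      require_artifact(config, "layout.geojson", "simulate")
      require_artifact(config, "samples.csv", "simulate")
      require_artifact(config, "traits.csv", "simulate")
      layout <- read_layout_geojson(art_path(config, "layout.geojson"))
      map <- read_ascii_grid(art_path(config, "predicted.asc"))
      grid <- build_grid(layout, config$cell_size_m)
      cells <- classify_cells(grid, layout)
      write_csv(cells, art_path(config, "cell_status.csv"))
      agg <- aggregate_cells(map, cells, grid)
      write_csv(agg, art_path(config, "cells.csv"))
      samples <- utils::read.csv(art_path(config, "samples.csv"),
                                 check.names = FALSE)
      summ <- summarize_plots(agg, samples, config$response)
      s_df <- as.data.frame(summ)
      s_df$pct_outside <- attr(summ, "pct_outside")
      write_csv(s_df, art_path(config, "plot_summary.csv"))
      traits <- utils::read.csv(art_path(config, "traits.csv"),
                                check.names = FALSE)
      meta <- layout$plots[c("plot_id", "row_id", "cultivar", "sowing_date",
                             "role")]
      obs <- merge(merge(agg, meta, by = "plot_id"),
                   traits[c("plot_id", "stem_dw", "seed_dw", "above_dw",
                            "w100")], by = "plot_id")
      obs$yield <- obs$y_hat
      obs$cell_id <- sprintf("c_%03d_%03d", obs$cell_i, obs$cell_j)
      obs <- obs[order(obs$cell_id), ]
      write_csv(obs, art_path(config, "cell_observations.csv"))
      write_manifest(config, "grid",
                     c("predicted.asc", "layout.geojson", "samples.csv",
                       "traits.csv"),
                     c("cell_status.csv", "cells.csv", "plot_summary.csv",
                       "cell_observations.csv"))
      list(cells = agg, summary = summ, observations = obs)
    },
    `test-cultivar` = {
      require_artifact(config, "cell_observations.csv", "grid")
      obs <- utils::read.csv(art_path(config, "cell_observations.csv"),
                             check.names = FALSE)
      res <- cultivar_analysis(obs)
      write_csv(data.frame(
        term = c("cultivar", "sowing_date"),
        statistic = c(res$lrt_cultivar$statistic, res$lrt_sowing$statistic),
        df = c(res$lrt_cultivar$df, res$lrt_sowing$df),
        p.value = c(res$lrt_cultivar$p.value, res$lrt_sowing$p.value)),
        art_path(config, "cultivar_lrt.csv"))
      write_csv(res$contrasts, art_path(config, "cultivar_contrasts.csv"))
      write_csv(data.frame(cultivar = names(res$emm),
                           emmean = as.numeric(res$emm)),
                art_path(config, "cultivar_emm.csv"))
      write_csv(data.frame(component = names(res$fit$varcomp),
                           variance = unname(res$fit$varcomp)),
                art_path(config, "cultivar_varcomp.csv"))
      write_manifest(config, "test-cultivar", "cell_observations.csv",
                     c("cultivar_lrt.csv", "cultivar_contrasts.csv",
                       "cultivar_emm.csv", "cultivar_varcomp.csv"))
      list(cultivar = res)
    },
    `test-traits` = {
      require_artifact(config, "cell_observations.csv", "grid")
      obs <- utils::read.csv(art_path(config, "cell_observations.csv"),
                             check.names = FALSE)
      res <- trait_analysis(obs)
      write_csv(res$lrt, art_path(config, "trait_lrt.csv"))
      write_csv(data.frame(term = names(res$fit$fixed),
                           estimate = unname(res$fit$fixed),
                           se = unname(res$fit$se)),
                art_path(config, "trait_coefficients.csv"))
      me <- marginal_effects(res$fit, config$marginal$focal,
                             config$marginal$moderator)
      write_csv(me, art_path(config, "marginal_effects.csv"))
      write_manifest(config, "test-traits", "cell_observations.csv",
                     c("trait_lrt.csv", "trait_coefficients.csv",
                       "marginal_effects.csv"))
      list(traits = res, marginal = me)
    },
    report = {
      mans <- list.files(config$output_dir, pattern = "^manifest_.*\\.json$",
                         full.names = TRUE)
      if (!length(mans)) {
        stop("missing artifact 'manifest_simulate.json' — run step 'simulate' first",
             call. = FALSE)
      }
      parsed <- lapply(mans, jsonlite::read_json)
      hashes <- vapply(parsed, `[[`, character(1), "config_hash")
      if (length(unique(hashes)) != 1) {
        stop("inconsistent config hashes across step manifests; ",
             "rerun the pipeline under one configuration", call. = FALSE)
      }
      sel <- utils::read.csv(require_artifact(config, "selection_table.csv",
                                              "select"))
      ps <- utils::read.csv(require_artifact(config, "plot_summary.csv",
                                             "grid"))
      lrt <- utils::read.csv(require_artifact(config, "cultivar_lrt.csv",
                                              "test-cultivar"))
      cells <- utils::read.csv(require_artifact(config, "cells.csv", "grid"))
      rep <- list(
        config_hash = unique(hashes),
        n_models = nrow(sel),
        best_spec = sel$spec[1], best_r_squared = sel$r_squared[1],
        best_aic = sel$aic[1],
        n_retained_cells = nrow(cells),
        mean_cells_per_plot = mean(table(cells$plot_id)),
        pct_manual_outside_iqr = ps$pct_outside[1],
        cultivar_lrt_p = lrt$p.value[lrt$term == "cultivar"],
        sowing_lrt_p = lrt$p.value[lrt$term == "sowing_date"])
      jsonlite::write_json(rep, art_path(config, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_manifest(config, "report",
                     c("selection_table.csv", "plot_summary.csv",
                       "cultivar_lrt.csv", "cells.csv"), "report.json")
      rep
    })
  say("[%s] done", step)
  invisible(out)
}

#' Run the analysis chain on a generated experiment in memory
#'
#' Convenience companion to the file-based steps: quadrat covariate
#' extraction, all-subsets selection, pixel prediction, gridding and
#' aggregation, plot summaries, and assembly of the cell observation
#' table ready for \code{\link{cultivar_analysis}} /
#' \code{\link{trait_analysis}}.
#'
#' @param experiment a \code{synthetic_experiment} (or a list with the
#'   same \code{layout}, \code{stack}, \code{samples}, \code{traits}
#'   elements built from real data).
#' @param cell_size_m analysis cell size, meters.
#' @param response response column in the sample table.
#' @return list: \code{selection} (a
#'   \code{\link{select_yield_model}} fit), \code{map}, \code{grid},
#'   \code{cells} (aggregated predictions), \code{summary} (per-plot
#'   IQR comparison), \code{observations} (cell table with treatment
#'   metadata and traits).
#' @export
analyze_experiment <- function(experiment, cell_size_m = 0.25,
                               response = "ear_dry_weight_g") {
  cov <- extract_point_covariates(experiment$stack, experiment$samples)
  md <- join_samples(cov, experiment$samples[c("sample_id", response)])
  sel <- select_yield_model(md, response = response)
  map <- predict_pixels(sel$best, experiment$stack)
  grid <- build_grid(experiment$layout, cell_size_m)
  cells <- classify_cells(grid, experiment$layout)
  agg <- aggregate_cells(map, cells, grid)
  summ <- summarize_plots(agg, experiment$samples, response)
  meta <- experiment$layout$plots[c("plot_id", "row_id", "cultivar",
                                    "sowing_date", "role")]
  obs <- merge(agg, meta, by = "plot_id")
  if (!is.null(experiment$traits)) {
    obs <- merge(obs, experiment$traits[c("plot_id", "stem_dw", "seed_dw",
                                          "above_dw", "w100")],
                 by = "plot_id")
  }
  obs$yield <- obs$y_hat
  list(selection = sel, map = map, grid = grid, cells = agg,
       summary = summ, observations = obs)
}

#' Run several pipeline steps in order
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param steps steps to run, in pipeline order (default: all).
#' @param verbose print progress.
#' @return Invisibly, the last step's outputs.
#' @export
run_pipeline <- function(config, steps = pipeline_steps, verbose = FALSE) {
  steps <- match.arg(steps, pipeline_steps, several.ok = TRUE)
  out <- NULL
  for (s in steps) out <- run_step(s, config, verbose = verbose)
  invisible(out)
}
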