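#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one validated list.
#' Defaults are the study constants: 0.5 m crown slices, a 2 m outer layer,
#' a 30 mm branch-unit threshold, 30 replicate QSMs per tree and 1000
#' bootstrap repetitions. A configuration can also be read from a YAML file
#' whose keys match the argument names.
#'
#' @param d_max_mm Branch-unit diameter threshold, mm.
#' @param layer_depth Outer-layer depth, m.
#' @param slice_height Crown slice height, m.
#' @param random_effects Fit the hurdle parts with nested random intercepts.
#' @param sample_counts Sample ZTNB counts during upscaling instead of using
#'   expected values.
#' @param n_replicates Replicate QSMs per tree in simulation.
#' @param bootstrap_B Bootstrap repetitions for the resource CIs.
#' @param dbh_grid dbh values at which resource budgets are reported, cm.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(d_max_mm = 30, layer_depth = 2, slice_height = 0.5,
                            random_effects = TRUE, sample_counts = FALSE,
                            n_replicates = 30, bootstrap_B = 1000,
                            dbh_grid = c(10, 25), seed = 1L) {
  cfg <- list(
    d_max_mm = d_max_mm, layer_depth = layer_depth, slice_height = slice_height,
    random_effects = random_effects, sample_counts = sample_counts,
    n_replicates = n_replicates, bootstrap_B = bootstrap_B,
    dbh_grid = dbh_grid, seed = as.integer(seed)
  )
  num <- c("d_max_mm", "layer_depth", "slice_height", "n_replicates", "bootstrap_B")
  if (any(vapply(cfg[num], function(v) v <= 0, logical(1)))) {
    abort("numeric configuration options must be positive",
      class = "bloomscale_error_config"
    )
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration keys.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path),
      class = "bloomscale_error_config"
    )
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")),
      class = "bloomscale_error_config"
    )
  }
  do.call(pipeline_config, vals)
}

#' Run the full branch-to-resources pipeline
#'
#' Sequences every stage on simulated or supplied data: cumulate and
#' subsample the branch table, fit the two-part hurdle model, upscale over
#' all replicate QSMs, aggregate per-tree medians, screen tree-dimension
#' predictors, fit the dbh and crown-volume allometries, and compute
#' resource budgets with bootstrap + Monte Carlo CIs. When `branch_data` or
#' `forest` is `NULL` the corresponding synthetic generator fills in, using
#' the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param branch_data A list as returned by [generate_branch_dataset()]
#'   (tibbles `branches`, `trees`), or `NULL` to simulate.
#' @param forest A list as returned by [generate_forest()] (tibbles `trees`,
#'   `cylinders`), or `NULL` to simulate.
#' @param n_trees Number of trees when simulating the forest.
#' @return A list of class `flower_pipeline` with elements `subsample`,
#'   `hurdle`, `totals`, `tree_estimates`, `screening`, `tree_models`
#'   (dbh and crown volume), `budget`, and `config`.
#' @export
run_flower_pipeline <- function(config = pipeline_config(), branch_data = NULL,
                                forest = NULL, n_trees = 39) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "bloomscale_error_pipeline", parent = e
      )
    })
  }

  branch_data <- branch_data %||% stage(
    "simulate-branches",
    generate_branch_dataset(seed = config$seed)
  )
  forest <- forest %||% stage("simulate-forest", generate_forest(
    synthetic_forest_spec(
      n_trees = n_trees, n_replicates = config$n_replicates,
      seed = config$seed
    )
  ))

  sub <- stage(
    "subsample",
    subsample_branches(branch_data$branches, branch_data$trees)
  )
  hurdle <- stage("fit-branch", fit_flower_hurdle(
    sub, branch_data$trees,
    random_effects = config$random_effects
  ))
  totals <- stage("upscale", upscale_qsms(
    forest$cylinders, hurdle$coefficients,
    seed = config$seed,
    d_max_mm = config$d_max_mm, layer_depth = config$layer_depth,
    slice_height = config$slice_height, sample_counts = config$sample_counts
  ))
  estimates <- stage("aggregate", aggregate_tree_estimates(totals))

  metrics <- stage("tree-metrics", {
    forest$cylinders |>
      dplyr::filter(.data$replicate_id == min(.data$replicate_id)) |>
      dplyr::group_by(.data$tree_id) |>
      dplyr::group_modify(~ derive_tree_metrics(.x, slice_height = config$slice_height)) |>
      dplyr::ungroup()
  })
  tree_data <- dplyr::inner_join(estimates, metrics, by = "tree_id")

  screening <- stage("screen", screen_predictors(tree_data))
  tree_models <- stage("fit-tree", list(
    dbh = fit_tree_model(tree_data, "dbh"),
    crown_volume = fit_tree_model(tree_data, "crown_volume")
  ))
  budget <- stage("resources", bootstrap_resource_ci(
    tree_data, config$dbh_grid,
    B = config$bootstrap_B, seed = config$seed
  ))

  structure(
    list(
      subsample = sub, hurdle = hurdle, totals = totals,
      tree_estimates = tree_data, screening = screening,
      tree_models = tree_models, budget = budget, config = config
    ),
    class = "flower_pipeline"
  )
}

#' @export
print.flower_pipeline <- function(x, ...) {
  cat("Flower pipeline result\n")
  cat(" subsampled branches:", nrow(x$subsample), "\n")
  cat(" trees upscaled:", nrow(x$tree_estimates), "\n")
  cat(
    " dbh model: log(flowers) =",
    signif(x$tree_models$dbh$coefficients["intercept"], 3), "+",
    signif(x$tree_models$dbh$coefficients["slope"], 3), "* dbh\n"
  )
  cat(" budget rows:", nrow(x$budget), "\n")
  invisible(x)
}
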