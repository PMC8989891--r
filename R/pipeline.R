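# End-to-end pipeline driver and demo workspace. All stage computation
# lives in the module functions; this file only chains them, derives
# per-stage seeds from one master seed, and writes artifacts plus a run
# manifest.

derive_seed <- function(master, stage) {
  # documented per-stage seed derivation; keeps results < 2^31
  offsets <- c(occurrences = 11L, absences = 23L, ensemble = 37L)
  as.integer(master + offsets[[stage]])
}

#' Create a complete synthetic demo workspace on disk
#'
#' Materializes covariate rasters (one ASCII grid per layer), a land-use
#' raster, an occurrence CSV and a JSON pipeline configuration, all
#' generated from one seed, runnable by [run_pipeline()].
#'
#' @param dir Workspace directory (created).
#' @param seed Master seed.
#' @param config A [synthetic_config()]; the default demo uses a 100 x 200
#'   grid so the full pipeline runs in minutes on one CPU.
#' @param brt A [brt_config()] for the pipeline configuration file.
#' @param n_models Ensemble size written to the configuration.
#' @return Path of the written configuration file, invisibly.
#' @export
make_demo <- function(dir, seed = 1L,
                      config = synthetic_config(grid_shape = c(100, 200),
                                                seed = seed),
                      brt = brt_config(learning_rate = 0.05,
                                       tree_complexity = 3,
                                       max_trees = 300),
                      n_models = 30) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stack <- generate_env_stack(config)
  suit <- true_suitability(stack, config$true_weights, config$true_quadratic)
  occ <- sample_occurrences(suit, config$n_presence,
                            seed = derive_seed(seed, "occurrences"))
  lu <- generate_landuse(config)
  paths <- write_stack(stack, file.path(dir, "covariates"))
  write_ascii_grid(lu$codes, file.path(dir, "landuse.asc"), grid = lu$grid)
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  cfg <- list(
    covariates = as.list(paths),
    categorical = "soil_class",
    landuse = file.path(dir, "landuse.asc"),
    landuse_classes = as.list(igbp_classes()),
    occurrences = file.path(dir, "occurrences.csv"),
    envelope = unclass(envelope_rule()),
    envelope_logic = "or",
    brt = unclass(brt),
    n_models = n_models,
    train_fraction = 0.5,
    threshold = 0.5,
    allowed_classes = marginal_classes(),
    utilization = 0.30,
    goal = 28,
    seed = seed,
    out_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}

#' Run the full marginal-land pipeline from a configuration
#'
#' Stages: occurrence gridding and envelope pseudo-absence sampling ->
#' bootstrapped BRT ensemble -> threshold + land-use masking and area
#' tabulation -> biodiesel/GHG scenarios. Writes all artifacts to the
#' configured output directory and returns (and writes) a manifest with the
#' configuration hash, seeds, AUC summary, relative-contribution table
#' (descending), area table and scenario results.
#'
#' @param config Path to a JSON configuration (as written by [make_demo()])
#'   or an equivalent list.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stack <- stage("load", {
    s <- read_stack(unlist(config$covariates),
                    categorical = config$categorical)
    lu_layer <- read_ascii_grid(config$landuse)
    if (!grids_identical(s$grid, lu_layer$grid))
      stop("land-use raster grid does not match the covariate grid")
    attr(s, "landuse") <- lu_layer
    s
  })
  lu <- structure(list(grid = stack$grid,
                       codes = attr(stack, "landuse")$values,
                       classes = unlist(config$landuse_classes)),
                  class = "landuse_map")

  table <- stage("occurrences", {
    occ <- utils::read.csv(config$occurrences)
    rule <- do.call(envelope_rule, config$envelope)
    build_cell_table(occ, stack, rule, logic = config$envelope_logic,
                     seed = derive_seed(seed, "absences"))
  })

  ens <- stage("ensemble", {
    brt <- do.call(brt_config, config$brt)
    run_ensemble(table, stack, brt, n_models = config$n_models,
                 train_fraction = config$train_fraction,
                 seed = derive_seed(seed, "ensemble"))
  })

  # relative contribution: refit one model on the full table for the
  # manifest's RC table (the ensemble members keep their own split records)
  rc <- stage("relative_contribution", {
    brt <- do.call(brt_config, config$brt)
    brt$seed <- derive_seed(seed, "ensemble")
    model <- fit_brt(table, brt, n_trees = max(50L, round(mean(ens$n_trees))))
    relative_influence(model)
  })

  areas <- stage("marginal_land", {
    suitable <- threshold_suitability(ens$mean, config$threshold)
    marginal <- mask_by_landuse(suitable, lu,
                                allowed = unlist(config$allowed_classes))
    write_ascii_grid(marginal$codes, file.path(out_dir, "marginal.asc"),
                     grid = marginal$grid)
    tabulate_areas(marginal)
  })

  scenario <- stage("bioenergy", {
    total_mha <- areas$grand_total / 1e6
    if (total_mha <= 0) {
      warning("no marginal land found; skipping scenario arithmetic")
      NULL
    } else {
      biodiesel_scenario(scenario_params(total_mha,
                                         utilization = config$utilization,
                                         goal = config$goal))
    }
  })

  write_ascii_grid(ens$mean, file.path(out_dir, "suitability_mean.asc"))
  write_ascii_grid(ens$sd, file.path(out_dir, "suitability_sd.asc"))
  utils::write.csv(table, file.path(out_dir, "cell_table.csv"),
                   row.names = FALSE)
  write_area_table(areas, file.path(out_dir, "area_table.csv"))
  write_auc_summary(ens, file.path(out_dir, "auc.json"))
  if (!is.null(scenario))
    jsonlite::write_json(scenario[setdiff(names(scenario), "params")],
                         file.path(out_dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = seed,
    config_md5 = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA,
    stage_seeds = list(absences = derive_seed(seed, "absences"),
                       ensemble = derive_seed(seed, "ensemble")),
    n_presence = sum(table$label == 1),
    n_absence = sum(table$label == 0),
    auc = ens$auc_summary,
    selected_trees = ens$n_trees,
    relative_contribution = as.list(rc),
    area_grand_total_ha = areas$grand_total,
    area_class_totals_ha = as.list(areas$class_totals),
    composition_pct = as.list(areas$composition_pct),
    scenario = if (!is.null(scenario))
      scenario[setdiff(names(scenario), "params")] else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
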