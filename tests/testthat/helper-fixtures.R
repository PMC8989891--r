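# Small synthetic fixtures built in code at test time.

# Compact study system: 20 degrees of latitude on a coarse grid so area
# weighting is nontrivial while everything stays fast.
small_config <- function(seed = 3, n_presence = 400, grid = c(80, 120),
                         resolution = 0.25, ...) {
  synthetic_config(grid_shape = grid, resolution_deg = resolution,
                   origin = c(-10, 45), n_presence = n_presence,
                   seed = seed, ...)
}

small_stack <- function(seed = 3, ...) {
  generate_env_stack(small_config(seed = seed, ...))
}

# Design table produced by the full occurrence pipeline (envelope absences).
small_table <- function(seed = 3, n_presence = 400) {
  cfg <- small_config(seed = seed, n_presence = n_presence)
  st <- generate_env_stack(cfg)
  suit <- true_suitability(st, cfg$true_weights, cfg$true_quadratic)
  occ <- sample_occurrences(suit, n_presence, seed = seed + 1)
  tab <- suppressMessages(build_cell_table(occ, st, seed = seed + 2))
  list(config = cfg, stack = st, suitability = suit, table = tab)
}

# Two-layer stack with hand-set temperature/precipitation values for
# envelope truth-table tests.
tiny_climate_stack <- function(tavg, prec) {
  g <- grid_spec(nrow(tavg), ncol(tavg), resolution = 1, origin = c(0, 10))
  env_stack(list(tavg = tavg, prec = prec), g)
}

# The sigma-3, planted-weights configuration of the effect-recovery
# experiment (strong vapr, weak srad, neutral uniform background).
recovery_config <- function(seed) {
  specs <- default_covariate_specs()
  for (nm in names(specs)) specs[[nm]]$sigma <- 3
  synthetic_config(grid_shape = c(100, 100), resolution_deg = 0.2,
                   origin = c(-10, 45), n_presence = 300, seed = seed,
                   covariate_specs = specs,
                   true_weights = c(vapr = 3, srad = 1.5),
                   true_quadratic = NULL)
}

# One replicate of the recovery experiment; returns the relative influence
# of a model fitted to presences vs uniform background absences.
recovery_ri <- function(seed) {
  cfg <- recovery_config(seed)
  st <- generate_env_stack(cfg)
  suit <- true_suitability(st, cfg$true_weights)
  occ <- sample_occurrences(suit, cfg$n_presence, seed = seed + 5000)
  pres <- grid_occurrences(occ, st$grid)
  bg <- geo_layer(valid_mask(st), st$grid)
  abs <- sample_pseudo_absences(bg, pres, n = nrow(pres), seed = seed + 6000)
  tab <- extract_covariates(pres, abs, st)
  model <- fit_brt(tab, brt_config(learning_rate = 0.05, tree_complexity = 2,
                                   max_trees = 150, seed = seed),
                   n_trees = 150)
  relative_influence(model, sort = FALSE)
}

# Fixed 10-row instance with two continuous predictors, used against the
# boosting oracle.
hand_dataset <- function() {
  data.frame(
    x1 = c(0.1, 0.3, 0.5, 0.8, 1.2, 1.4, 1.9, 2.3, 2.6, 3.0),
    x2 = c(2.0, 0.7, 1.5, 2.2, 0.3, 1.8, 0.9, 2.5, 1.1, 0.4),
    label = c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1))
}
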