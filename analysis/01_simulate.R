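#!/usr/bin/env Rscript
# Stage 1: materialize the synthetic study system.
#
# Builds a complete workspace emulating the real inputs of a global
# suitability assessment: nine spatially autocorrelated covariate rasters
# (climate, soil, topography) on a 0.05-degree grid spanning 20 degrees of
# latitude, a known niche-shaped true suitability surface, 1923 occurrence
# records sampled from it (with duplicate records, as in a GBIF download),
# and a clumped IGBP-style land-use map.

suppressPackageStartupMessages(library(marginalsdm))

seed <- 42L
dir.create("results", showWarnings = FALSE)
ws <- file.path("results", "workspace")

cfg <- synthetic_config(seed = seed) # the default 400 x 240 study system
cfg_path <- make_demo(ws, seed = seed, config = cfg,
                      brt = brt_config(learning_rate = 0.1,
                                       tree_complexity = 3,
                                       max_trees = 100, step_size = 50,
                                       patience = 2),
                      n_models = 30)

stack <- read_stack(setNames(
  file.path(ws, "covariates", paste0(names(cfg$covariate_specs), ".asc")),
  names(cfg$covariate_specs)), categorical = "soil_class")
occ <- read.csv(file.path(ws, "occurrences.csv"))

cat("workspace:", ws, "\n")
cat("grid:", stack$grid$nrow, "x", stack$grid$ncol, "cells at",
    stack$grid$resolution, "deg;", sum(valid_mask(stack)), "valid cells\n")
cat("occurrence records:", nrow(occ), "\n")
tv <- stack$layers$tavg
cat(sprintf("temperature range %.1f to %.1f degC (envelope bounds 5.8/28.4)\n",
            min(tv, na.rm = TRUE), max(tv, na.rm = TRUE)))
frac <- sum(envelope_mask(stack)$values) / sum(valid_mask(stack))
cat(sprintf("%.1f%% of valid cells are envelope-eligible background\n",
            100 * frac))
cat("config written to", cfg_path, "\n")
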