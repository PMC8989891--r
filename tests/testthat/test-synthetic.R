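test_that("generated stacks honour the construction contract", {
  cfg <- small_config(seed = 7, grid = c(100, 200))
  st <- generate_env_stack(cfg)
  expect_s3_class(st, "env_stack")
  expect_length(st$layers, 9)
  expect_true(all(vapply(st$layers, function(m)
    all(dim(m) == c(100, 200)), logical(1))))
  tv <- st$layers$tavg
  expect_lt(min(tv, na.rm = TRUE), 5.8)
  expect_gt(max(tv, na.rm = TRUE), 28.4)
  # categorical soil layer is integer-coded
  sc <- st$layers$soil_class[!is.na(st$layers$soil_class)]
  expect_true(all(sc == round(sc)))
  # the border "ocean" is NoData in every layer
  expect_true(all(is.na(st$layers$vapr[1:5, ])))
  # envelope feasibility: at least 1% of valid cells eligible
  frac <- sum(envelope_mask(st)$values) / sum(valid_mask(st))
  expect_gte(frac, 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7)
  expect_identical(generate_env_stack(cfg), generate_env_stack(cfg))
  lu1 <- generate_landuse(cfg); lu2 <- generate_landuse(cfg)
  expect_identical(lu1$codes, lu2$codes)
})

test_that("infeasible covariate ranges are rejected at configuration", {
  specs <- default_covariate_specs()
  specs$tavg$range <- c(10, 20)
  expect_error(small_config(covariate_specs = specs), "envelope infeasible")
  specs <- default_covariate_specs()
  specs$prec$range <- c(500, 1800)
  expect_error(small_config(covariate_specs = specs), "envelope infeasible")
  specs <- default_covariate_specs()
  specs$elev$range <- c(100, 100)
  expect_error(small_config(covariate_specs = specs), "degenerate range")
})

test_that("true suitability is the inverse logit of the weighted sum", {
  st <- small_stack(seed = 11)
  # all weights zero -> 0.5 on every valid cell
  flat <- true_suitability(st, weights = c(vapr = 0))
  expect_true(all(abs(flat$values[!is.na(flat$values)] - 0.5) < 1e-15))
  # hand computation at one cell with two nonzero weights
  w <- c(vapr = 0.8, elev = -0.3)
  suit <- true_suitability(st, w)
  r <- 20; c <- 30
  zs <- vapply(names(w), function(nm) {
    v <- st$layers[[nm]]
    (v[r, c] - mean(v, na.rm = TRUE)) / sd(as.vector(v), na.rm = TRUE)
  }, numeric(1))
  eta <- sum(w * zs)
  expect_equal(suit$values[r, c], 1 / (1 + exp(-eta)), tolerance = 1e-12)
  # a very large weight saturates toward an above-the-mean indicator
  sat <- true_suitability(st, c(vapr = 1e4))
  v <- st$layers$vapr
  above <- v > mean(v, na.rm = TRUE)
  ok <- !is.na(v)
  expect_true(mean((sat$values[ok] > 0.5) == above[ok]) > 0.999)
  # NoData propagates, and unknown layers error
  expect_true(all(is.na(suit$values[is.na(v)])))
  expect_error(true_suitability(st, c(banana = 1)), "unknown layer")
})

test_that("occurrence sampling tracks suitability and is reproducible", {
  g <- grid_spec(20, 25, 0.25, c(-10, 45))
  set.seed(2)
  suit <- geo_layer(matrix(runif(500), 20, 25), g)
  occ1 <- sample_occurrences(suit, 1000, seed = 9)
  occ2 <- sample_occurrences(suit, 1000, seed = 9)
  expect_identical(occ1, occ2)
  expect_equal(nrow(occ1), 1000)
  # empirical per-cell counts track suitability across all cells
  cells <- point_to_cell(g, occ1$lon, occ1$lat)
  counts <- tabulate(cells$cell_id, nbins = 500)
  expect_gt(cor(counts, as.vector(t(suit$values)), method = "spearman"), 0.5)
})

test_that("degenerate suitability supports are handled", {
  g <- grid_spec(5, 5, 1, c(0, 10))
  v <- matrix(0, 5, 5); v[3, 4] <- 1
  occ <- sample_occurrences(geo_layer(v, g), 5, seed = 1)
  cells <- point_to_cell(g, occ$lon, occ$lat)
  expect_true(all(cells$row == 3 & cells$col == 4))
  expect_error(sample_occurrences(geo_layer(matrix(0, 5, 5), g), 3),
               "all-zero")
})

test_that("land-use maps are clumped, reproducible and match class fractions", {
  cfg <- small_config(seed = 13, grid = c(200, 200), resolution = 0.1)
  lu <- generate_landuse(cfg)
  probs <- default_landuse_probs()
  valid <- !is.na(lu$codes)
  frac <- table(lu$codes[valid]) / sum(valid)
  for (code in names(probs))
    expect_lt(abs(frac[[code]] - probs[[code]]), 0.05)
  # clumped: neighbouring cells agree far more often than under iid draws
  same <- mean(lu$codes[, -1][valid[, -1] & valid[, -200]] ==
                 lu$codes[, -200][valid[, -1] & valid[, -200]], na.rm = TRUE)
  expect_gt(same, 0.8)
  # concentrated probabilities give a uniform map
  cfg2 <- small_config(seed = 13,
                       landuse_class_probs = c(`10` = 1))
  lu2 <- generate_landuse(cfg2)
  expect_true(all(lu2$codes[!is.na(lu2$codes)] == 10))
  # probabilities must sum to one
  cfg$landuse_class_probs <- c(`9` = 0.6, `10` = 0.5)
  expect_error(generate_landuse(cfg), "sum to 1")
})
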