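make_landuse <- function(codes, grid) {
  structure(list(grid = grid, codes = codes, classes = igbp_classes()),
            class = "landuse_map")
}

test_that("suitability thresholding is inclusive and validated", {
  g <- grid_spec(2, 2, 1, c(0, 10))
  m <- geo_layer(matrix(c(0.5, 0.2, NA, 0.9), 2, 2), g)
  s <- threshold_suitability(m, 0.5)
  expect_true(s$values[1, 1])   # exactly at the threshold counts
  expect_false(s$values[2, 1])
  expect_false(s$values[1, 2])  # NoData -> FALSE
  expect_true(s$values[2, 2])
  expect_equal(sum(threshold_suitability(m, 0)$values), 3) # all valid cells
  zero <- geo_layer(matrix(0, 2, 2), g)
  expect_equal(sum(threshold_suitability(zero, 0.5)$values), 0)
  expect_error(threshold_suitability(m, 1.5), "outside")
})

test_that("land-use masking keeps only suitable cells of allowed classes", {
  g <- grid_spec(2, 3, 1, c(0, 10))
  suit <- geo_layer(matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), 2, 3), g)
  codes <- matrix(c(12, 10, 9, 9, NA, 10), 2, 3) # cropland, grass, savanna...
  lu <- make_landuse(codes, g)
  marg <- mask_by_landuse(suit, lu)
  expect_true(is.na(marg$codes[1, 1]))  # suitable cropland excluded
  expect_equal(marg$codes[2, 1], 10)    # suitable grassland retained
  expect_true(is.na(marg$codes[2, 2]))  # unsuitable savanna excluded
  expect_equal(marg$codes[1, 2], 9)
  expect_true(is.na(marg$codes[1, 3]))  # NoData stays NoData
  # enlarging the allowed set never shrinks the marginal set
  more <- mask_by_landuse(suit, lu, allowed = c(marginal_classes(),
                                                "croplands"))
  expect_true(all(which(!is.na(marg$codes)) %in% which(!is.na(more$codes))))
  g2 <- grid_spec(2, 3, 0.5, c(0, 10))
  expect_error(mask_by_landuse(suit, make_landuse(codes, g2)),
               "different grids")
})

test_that("spherical cell areas match the closed form and scale with latitude", {
  # direct literal evaluation of A = R^2 dlam (sin N - sin S) at the equator
  r_m <- 6371.0088 * 1000
  want <- r_m^2 * (0.05 * pi / 180) * (sin(0.05 * pi / 180) - 0) / 1e4
  expect_equal(cell_area_ha(0.05, 0, 0.05), want, tolerance = 1e-12)
  expect_equal(round(want), 3091)
  # a cell at 60N is about half the equatorial cell (cosine scaling)
  eq <- cell_area_ha(0.025, -0.025, 0.05)
  at60 <- cell_area_ha(60.025, 59.975, 0.05)
  expect_lt(abs(at60 / eq - 0.5), 0.001)
  expect_error(cell_area_ha(0, 1, 0.05), "inverted")
  expect_error(cell_area_ha(95, 85, 0.05), "poles")
})

test_that("summing a global grid recovers the sphere area", {
  g <- grid_spec(180, 360, 1, c(-180, 90))
  total_ha <- sum(row_cell_areas(g)) * g$ncol
  sphere_ha <- 4 * pi * (6371.0088 * 1000)^2 / 1e4
  expect_lt(abs(total_ha / sphere_ha - 1), 1e-4)
})

test_that("area tabulation matches published composition arithmetic", {
  # published per-class totals (Mha) -> composition percentages
  totals <- c("woody savannas" = 494.80, "savannas" = 358.71,
              "grasslands" = 257.10, "open shrublands" = 198.65,
              "closed shrublands" = 2.59)
  pct <- composition_percentages(totals)
  expect_equal(round(unname(pct), 2), c(37.72, 27.34, 19.60, 15.14, 0.20))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("tabulated hectares equal the summed cell areas", {
  g <- grid_spec(40, 10, 0.5, c(0, 20)) # spans 20 degrees of latitude
  codes <- matrix(10, 40, 10)
  codes[1:5, ] <- NA
  marg <- make_landuse(codes, g)
  at <- tabulate_areas(marg)
  manual <- sum(matrix(row_cell_areas(g), 40, 10)[!is.na(codes)])
  expect_equal(at$grand_total, manual, tolerance = 1e-9)
  expect_equal(names(at$class_totals), "grasslands")
  expect_equal(unname(at$composition_pct), 100)
  # flat-count mode: cells x nominal hectares
  flat <- tabulate_areas(marg, flat_count = TRUE)
  expect_equal(flat$grand_total, sum(!is.na(codes)) * 2500)
})

test_that("zone totals are consistent and empty rasters warn", {
  g <- grid_spec(20, 12, 0.5, c(0, 20))
  codes <- matrix(sample(c(9, 10, NA), 240, replace = TRUE), 20, 12)
  marg <- make_landuse(codes, g)
  zones <- generate_zones(g, 3)
  at <- tabulate_areas(marg, zones)
  expect_equal(sum(at$zone_totals), at$grand_total)
  expect_equal(sum(at$class_totals), at$grand_total, tolerance = 1e-9)
  global <- tabulate_areas(marg)
  expect_equal(at$grand_total, global$grand_total, tolerance = 1e-9)
  empty <- make_landuse(matrix(NA_real_, 20, 12), g)
  expect_warning(et <- tabulate_areas(empty), "undefined")
  expect_equal(et$grand_total, 0)
})
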