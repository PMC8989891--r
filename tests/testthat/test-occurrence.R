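test_that("1923 records spread over 670 cells grid to exactly 670 presences", {
  g <- grid_spec(50, 50, resolution = 0.05, origin = c(100, 40))
  set.seed(17)
  target_cells <- sample(50 * 50, 670)
  row <- (target_cells - 1) %/% 50 + 1
  col <- (target_cells - 1) %% 50 + 1
  # each chosen cell gets one record, the rest are duplicates within them
  pick <- c(seq_len(670), sample(670, 1923 - 670, replace = TRUE))
  lon <- g$origin_lon + (col[pick] - 1 + runif(1923)) * g$resolution
  lat <- g$origin_lat - (row[pick] - 1 + runif(1923)) * g$resolution
  pres <- grid_occurrences(data.frame(lon = lon, lat = lat), g)
  expect_equal(nrow(pres), 670)
  expect_setequal(pres$cell_id, (row - 1) * 50 + col)
})

test_that("gridding deduplicates, drops outside points, and is idempotent", {
  g <- grid_spec(10, 10, 1, c(0, 10))
  pts <- data.frame(lon = c(0.2, 0.5, 0.9, 20), lat = c(9.1, 9.5, 9.8, 5))
  expect_message(pres <- grid_occurrences(pts, g), "1 point")
  expect_equal(nrow(pres), 1L) # three in-grid points share cell (1,1)
  expect_equal(attr(pres, "n_dropped"), 1)
  expect_error(grid_occurrences(pts[0, ], g), "empty")
  # idempotence: gridding the presence cell centers returns the same set
  centers <- data.frame(
    lon = g$origin_lon + (pres$col - 0.5) * g$resolution,
    lat = g$origin_lat - (pres$row - 0.5) * g$resolution)
  again <- grid_occurrences(centers, g)
  expect_equal(again$cell_id, pres$cell_id)
})

test_that("the envelope mask implements the climatic exclusion rule", {
  tavg <- matrix(c(20, 3, 20, 30, NA, 20), 2, 3)
  prec <- matrix(c(1000, 1000, 200, 1000, 1000, NA), 2, 3)
  st <- tiny_climate_stack(tavg, prec)
  m <- envelope_mask(st, envelope_rule())
  expect_false(m$values[1, 1]) # 20 degC, 1000 mm: inside on both axes
  expect_true(m$values[2, 1])  # 3 degC: temperature clause
  expect_true(m$values[1, 2])  # 200 mm: precipitation clause
  expect_true(m$values[2, 2])  # 30 degC: beyond the upper temperature bound
  expect_false(m$values[1, 3]) # NoData never eligible
  expect_false(m$values[2, 3])
  # AND logic requires violating both axes
  m_and <- envelope_mask(st, envelope_rule(), logic = "and")
  expect_false(m_and$values[2, 1])
  cold_dry <- tiny_climate_stack(matrix(3, 1, 1), matrix(100, 1, 1))
  expect_true(envelope_mask(cold_dry, envelope_rule(), logic = "and")$values[1, 1])
  expect_error(envelope_mask(tiny_climate_stack(tavg, prec), envelope_rule(),
                             temp_layer = "nope"), "missing layer")
})

test_that("pseudo-absences are envelope-compliant, disjoint and balanced", {
  fix <- small_table(seed = 19)
  tab <- fix$table
  expect_equal(sum(tab$label == 1), sum(tab$label == 0))
  expect_false(any(duplicated(tab$cell_id)))
  # every absence satisfies the envelope predicate (post-hoc assertion)
  mask <- envelope_mask(fix$stack, envelope_rule())
  absn <- tab[tab$label == 0, ]
  expect_true(all(mask$values[cbind(absn$row, absn$col)]))
  # and no absence is a presence cell
  expect_length(intersect(tab$cell_id[tab$label == 1], absn$cell_id), 0)
})

test_that("pseudo-absence sampling handles edge cases", {
  g <- grid_spec(3, 3, 1, c(0, 10))
  mask <- geo_layer(matrix(c(rep(TRUE, 5), rep(FALSE, 4)), 3, 3), g)
  none <- sample_pseudo_absences(mask, data.frame(cell_id = integer()), n = 0)
  expect_equal(nrow(none), 0)
  expect_error(
    sample_pseudo_absences(mask, data.frame(cell_id = integer()), n = 10),
    "shortfall 5")
  # same seed, same sample
  pres <- data.frame(cell_id = 1L)
  a1 <- sample_pseudo_absences(mask, pres, n = 3, seed = 4)
  a2 <- sample_pseudo_absences(mask, pres, n = 3, seed = 4)
  expect_identical(a1, a2)
  expect_false(1L %in% a1$cell_id)
})

test_that("covariate extraction preserves labels and drops NoData rows", {
  st <- small_stack(seed = 23)
  # poke a NoData hole into one layer at a known valid cell
  ok <- which(valid_mask(st), arr.ind = TRUE)
  hole <- ok[1, ]
  st$layers$elev[hole[1], hole[2]] <- NA
  pres <- data.frame(cell_id = 1L, row = hole[1], col = hole[2])
  pres$cell_id <- (hole[1] - 1) * st$grid$ncol + hole[2]
  other <- ok[2:4, ]
  absn <- data.frame(cell_id = (other[, 1] - 1) * st$grid$ncol + other[, 2],
                     row = other[, 1], col = other[, 2])
  expect_message(tab <- extract_covariates(pres, absn, st), "1 cell")
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$label == 0))
  expect_s3_class(tab$soil_class, "factor")
  # presence/absence overlap is rejected
  expect_error(extract_covariates(absn, absn, st), "both labels")
})
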