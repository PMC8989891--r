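#' @useDynLib marginalsdm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis rnorm runif sd setNames quantile complete.cases aggregate
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Synthetic study system: spatially autocorrelated covariate rasters with a
# known logistic suitability surface, occurrence points drawn from it, and a
# clumped categorical land-use map. This emulates the structure of the real
# inputs (WorldClim-style climate, ISRIC-style soil, SRTM-style topography,
# MODIS IGBP-style land cover) so the whole pipeline is testable offline.
# Only ranges and smoothness are controlled, not the real layers' marginal
# distributions.
# ---------------------------------------------------------------------------

#' Default per-layer specifications for the nine environmental covariates
#'
#' Each continuous spec gives the Gaussian smoothing sigma (in cells) and the
#' value range the smoothed field is affinely rescaled into. Ranges are set
#' to realistic magnitudes for each quantity; temperature and precipitation
#' ranges straddle the climatic envelope bounds (5.8-28.4 degC, 400-1900 mm)
#' so envelope-based pseudo-absence sampling is feasible. The temperature
#' layer additionally mixes in a monotone north-south gradient
#' (`gradient_weight`) so the envelope partitions the map spatially.
#'
#' @return Named list of per-layer spec lists.
#' @export
default_covariate_specs <- function() {
  list(
    vapr       = list(sigma = 8,  range = c(0.1, 3.5)),       # kPa
    tavg       = list(sigma = 10, range = c(-5, 33),          # degC
                      gradient_weight = 0.6),
    srad       = list(sigma = 12, range = c(8000, 25000)),    # kJ m-2 day-1
    prec       = list(sigma = 8,  range = c(100, 2600)),      # mm yr-1
    swc        = list(sigma = 6,  range = c(2, 45)),          # % volumetric
    soil_depth = list(sigma = 6,  range = c(10, 200)),        # cm
    elev       = list(sigma = 5,  range = c(0, 4500)),        # m
    slope      = list(sigma = 4,  range = c(0, 30)),          # degrees
    soil_class = list(sigma = 10, n_classes = 8)              # categorical
  )
}

#' Default true effect sizes of the synthetic suitability surface
#'
#' Standardized log-odds coefficients. The ordering mirrors what global
#' suitability modelling for Pistacia chinensis finds: water vapor pressure
#' dominates, then temperature, with solar radiation and precipitation
#' smaller and soil/topography negligible.
#'
#' @return Named numeric vector.
#' @export
default_true_weights <- function() {
  c(vapr = 2.0, tavg = 1.0, srad = 0.4, prec = 0.4)
}

#' Default quadratic (niche-shaped) effects of the synthetic suitability
#'
#' Negative quadratic terms on standardized temperature and precipitation
#' give the truth a climatic optimum: suitability collapses toward the
#' climatic extremes, which is what the pseudo-absence envelope assumes
#' about the species' tolerance.
#'
#' @return Named numeric vector of quadratic effects.
#' @export
default_true_quadratic <- function() {
  c(tavg = -2, prec = -2)
}

#' Default land-use class probabilities (IGBP-like codes)
#'
#' Includes the five maskable marginal classes (codes 6, 7, 8, 9, 10:
#' closed/open shrublands, woody savannas, savannas, grasslands) and two
#' excluded classes (4 = deciduous broadleaf forest, 12 = croplands).
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_landuse_probs <- function() {
  c(`4` = 0.15, `6` = 0.05, `7` = 0.15, `8` = 0.20,
    `9` = 0.15, `10` = 0.15, `12` = 0.15)
}

#' IGBP-like land-cover class dictionary
#' @return Named character vector mapping integer codes to class names.
#' @export
igbp_classes <- function() {
  c(`4` = "deciduous broadleaf forest",
    `6` = "closed shrublands",
    `7` = "open shrublands",
    `8` = "woody savannas",
    `9` = "savannas",
    `10` = "grasslands",
    `12` = "croplands",
    `13` = "urban")
}

#' The land-use classes counted as marginal land
#' @return Character vector of the five allowed class names.
#' @export
marginal_classes <- function() {
  c("woody savannas", "savannas", "closed shrublands",
    "open shrublands", "grasslands")
}

#' Configuration of the synthetic study system
#'
#' Defaults define the study conditions: a 400 x 240 grid at 0.05 degrees
#' (20 degrees of latitude, so latitude-corrected cell areas vary
#' materially), 1923 occurrence records (drawn with replacement, so they
#' deduplicate to fewer presence cells, as GBIF downloads do), and the
#' covariate/land-use structure above.
#'
#' @param grid_shape Integer length-2 `(rows, cols)`.
#' @param resolution_deg Cell size in degrees.
#' @param origin `(lon, lat)` of the upper-left corner.
#' @param n_presence Number of occurrence records to draw.
#' @param covariate_specs As [default_covariate_specs()].
#' @param true_weights Named standardized log-odds effects; see
#'   [default_true_weights()].
#' @param true_quadratic Optional named quadratic effects on standardized
#'   covariates.
#' @param landuse_class_probs Named probabilities over land-use codes.
#' @param border_frac Fraction of each dimension masked as NoData "ocean"
#'   on every edge.
#' @param seed Integer seed controlling all generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(grid_shape = c(400, 240),
                             resolution_deg = 0.05,
                             origin = c(-10, 45),
                             n_presence = 1923,
                             covariate_specs = default_covariate_specs(),
                             true_weights = default_true_weights(),
                             true_quadratic = default_true_quadratic(),
                             landuse_class_probs = default_landuse_probs(),
                             border_frac = 0.05,
                             seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            resolution_deg > 0, n_presence >= 1,
            border_frac >= 0, border_frac < 0.5)
  for (nm in names(covariate_specs)) {
    sp <- covariate_specs[[nm]]
    if (!is.null(sp$range) && sp$range[1] >= sp$range[2])
      stop("degenerate range for covariate '", nm, "' (min >= max)")
  }
  tr <- covariate_specs$tavg$range
  if (is.null(tr) || tr[1] >= 5.8 || tr[2] <= 28.4)
    stop("temperature range must straddle the envelope bounds 5.8-28.4 degC; ",
         "envelope infeasible")
  pr <- covariate_specs$prec$range
  if (is.null(pr) || pr[1] >= 400 || pr[2] <= 1900)
    stop("precipitation range must straddle the envelope bounds 400-1900 mm; ",
         "envelope infeasible")
  structure(list(grid_shape = as.integer(grid_shape),
                 resolution_deg = resolution_deg, origin = origin,
                 n_presence = as.integer(n_presence),
                 covariate_specs = covariate_specs,
                 true_weights = true_weights,
                 true_quadratic = true_quadratic,
                 landuse_class_probs = landuse_class_probs,
                 border_frac = border_frac, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Separable Gaussian smoothing by banded row/column weight matrices,
# row-normalized so edges are handled without padding artefacts.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  smooth_1d <- function(n) {
    idx <- seq_len(n)
    W <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
    W[abs(outer(idx, idx, `-`)) > ceiling(3 * sigma)] <- 0
    W / rowSums(W)
  }
  Wr <- smooth_1d(nrow(mat))
  Wc <- smooth_1d(ncol(mat))
  Wr %*% mat %*% t(Wc)
}

rescale_to <- function(m, range) {
  lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
  if (hi - lo < .Machine$double.eps) return(matrix(mean(range), nrow(m), ncol(m)))
  range[1] + (m - lo) / (hi - lo) * (range[2] - range[1])
}

border_mask <- function(nrow, ncol, border_frac) {
  br <- floor(border_frac * nrow)
  bc <- floor(border_frac * ncol)
  m <- matrix(TRUE, nrow, ncol)
  if (br > 0) m[c(seq_len(br), nrow - seq_len(br) + 1), ] <- FALSE
  if (bc > 0) m[, c(seq_len(bc), ncol - seq_len(bc) + 1)] <- FALSE
  m
}

#' Generate the nine-layer synthetic environmental stack
#'
#' Continuous layers are Gaussian-smoothed white noise affinely rescaled
#' into each covariate's range; the temperature layer blends in a monotone
#' north-south gradient (cosine of latitude, normalized) so that cold cells
#' concentrate at high latitude; soil class is a clumped integer-coded
#' categorical layer; a border "ocean" is NoData in all layers. Generation
#' fails loudly if fewer than 1% of valid cells satisfy the default
#' pseudo-absence envelope.
#'
#' @param config A [synthetic_config()].
#' @return An `env_stack` with layers vapr, tavg, srad, prec, swc,
#'   soil_depth, elev, slope, soil_class.
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- grid_spec(config$grid_shape[1], config$grid_shape[2],
                 config$resolution_deg, config$origin)
  ok <- border_mask(g$nrow, g$ncol, config$border_frac)
  lats <- cell_center_lats(g)
  layers <- list()
  for (nm in names(config$covariate_specs)) {
    sp <- config$covariate_specs[[nm]]
    noise <- gauss_smooth(matrix(rnorm(g$nrow * g$ncol), g$nrow, g$ncol),
                          sp$sigma)
    if (!is.null(sp$n_classes)) {           # categorical layer
      u <- matrix(rank(noise, ties.method = "first") / (length(noise) + 1),
                  g$nrow, g$ncol)
      vals <- matrix(as.numeric(findInterval(u, seq(0, 1,
                       length.out = sp$n_classes + 1),
                       rightmost.closed = TRUE)), g$nrow, g$ncol)
    } else {
      field <- rescale_to(noise, c(0, 1))
      gw <- sp$gradient_weight
      if (!is.null(gw) && gw > 0) {
        grad <- cos(lats * pi / 180)
        grad <- (grad - min(grad)) / (max(grad) - min(grad))
        field <- gw * matrix(grad, g$nrow, g$ncol) + (1 - gw) * field
      }
      vals <- rescale_to(field, sp$range)
    }
    vals[!ok] <- NA
    layers[[nm]] <- vals
  }
  stack <- env_stack(layers, g, categorical = "soil_class")
  mask <- envelope_mask(stack, envelope_rule())
  frac <- sum(mask$values, na.rm = TRUE) / sum(valid_mask(stack))
  if (frac < 0.01)
    stop(sprintf(paste0("envelope infeasible on generated stack: only %.2f%% ",
                        "of valid cells satisfy the pseudo-absence envelope"),
                 100 * frac))
  stack
}

#' Evaluate the known true suitability surface
#'
#' The ground truth is logistic: continuous covariates are standardized over
#' valid cells, combined as intercept + sum(w_j z_j) + sum(q_j z_j^2), and
#' passed through the inverse logit. NoData propagates.
#'
#' @param stack An `env_stack`.
#' @param weights Named linear effects on standardized covariates; names
#'   must be continuous layers of the stack.
#' @param quadratic Optional named quadratic effects.
#' @param intercept Log-odds intercept (default 0).
#' @return A `geo_layer` of probabilities in (0, 1).
#' @export
true_suitability <- function(stack, weights = default_true_weights(),
                             quadratic = NULL, intercept = 0) {
  stopifnot(inherits(stack, "env_stack"))
  nms <- unique(c(names(weights), names(quadratic)))
  unknown <- setdiff(nms, names(stack$layers))
  if (length(unknown))
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
  if (any(nms %in% stack$categorical))
    stop("true_suitability weights must name continuous layers")
  g <- stack$grid
  eta <- matrix(intercept, g$nrow, g$ncol)
  for (nm in nms) {
    v <- stack$layers[[nm]]
    z <- (v - mean(v, na.rm = TRUE)) / sd(as.vector(v), na.rm = TRUE)
    w <- if (!is.null(weights) && nm %in% names(weights)) weights[[nm]] else 0
    q <- if (!is.null(quadratic) && nm %in% names(quadratic)) quadratic[[nm]] else 0
    eta <- eta + w * z + q * z^2
  }
  eta[!valid_mask(stack)] <- NA
  geo_layer(plogis(eta), g)
}

#' Sample occurrence records from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability (so the same cell can yield several records, emulating
#' duplicate GBIF records), then each record is jittered uniformly within
#' its cell.
#'
#' @param suitability A `geo_layer` of nonnegative weights.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return data.frame with columns `lon`, `lat`, `record_id`.
#' @export
sample_occurrences <- function(suitability, n, seed = 1L) {
  stopifnot(inherits(suitability, "geo_layer"), n >= 1)
  g <- suitability$grid
  w <- as.vector(suitability$values) # column-major
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all-zero suitability: nothing to sample from")
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (idx - 1) %% g$nrow + 1
  col <- (idx - 1) %/% g$nrow + 1
  lon <- g$origin_lon + (col - 1) * g$resolution + runif(n) * g$resolution
  lat <- g$origin_lat - (row - 1) * g$resolution - runif(n) * g$resolution
  data.frame(lon = lon, lat = lat, record_id = seq_len(n))
}

#' Generate a spatially clumped categorical land-use map
#'
#' A Gaussian-smoothed noise field is rank-transformed to uniform and cut at
#' the cumulative class probabilities, which yields clumped patches whose
#' empirical class fractions match the requested probabilities (up to
#' NoData-border effects), rather than i.i.d. salt-and-pepper noise.
#'
#' @param config A [synthetic_config()]; uses `landuse_class_probs`,
#'   the grid, the border mask and `seed` (offset so the land-use field is
#'   independent of the covariate fields).
#' @param sigma Smoothing sigma in cells (default 10).
#' @return A `landuse_map`: list(grid, codes matrix, classes dictionary).
#' @export
generate_landuse <- function(config, sigma = 10) {
  stopifnot(inherits(config, "synthetic_config"))
  probs <- config$landuse_class_probs
  if (abs(sum(probs) - 1) > 1e-9)
    stop("land-use class probabilities must sum to 1 (got ", sum(probs), ")")
  g <- grid_spec(config$grid_shape[1], config$grid_shape[2],
                 config$resolution_deg, config$origin)
  set.seed(config$seed + 104729L) # independent stream from the covariates
  noise <- gauss_smooth(matrix(rnorm(g$nrow * g$ncol), g$nrow, g$ncol), sigma)
  u <- matrix(rank(noise, ties.method = "first") / (length(noise) + 1),
              g$nrow, g$ncol)
  breaks <- c(0, cumsum(probs))
  codes <- as.integer(names(probs))[findInterval(u, breaks,
                                                 rightmost.closed = TRUE)]
  codes <- matrix(as.numeric(codes), g$nrow, g$ncol)
  codes[!border_mask(g$nrow, g$ncol, config$border_frac)] <- NA
  cls <- igbp_classes()
  missing <- setdiff(names(probs), names(cls))
  if (length(missing)) cls[missing] <- paste("class", missing)
  structure(list(grid = g, codes = codes, classes = cls),
            class = "landuse_map")
}

#' @export
print.landuse_map <- function(x, ...) {
  tab <- table(x$codes)
  cat("landuse_map:", paste(sprintf("%s=%d", x$classes[names(tab)], tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Generate an integer zone map (longitude bands)
#'
#' A simple stand-in for continent/country zone rasters: the grid is split
#' into `n_zones` equal-width longitude bands.
#'
#' @param grid A `grid_spec`.
#' @param n_zones Number of bands.
#' @param names Optional zone names (default "zone_1"...).
#' @return list(grid, zones matrix, names).
#' @export
generate_zones <- function(grid, n_zones = 3,
                           names = paste0("zone_", seq_len(n_zones))) {
  stopifnot(n_zones >= 1, length(names) == n_zones)
  band <- ceiling(seq_len(grid$ncol) / (grid$ncol / n_zones))
  band <- pmin(band, n_zones)
  zones <- matrix(rep(band, each = grid$nrow), grid$nrow, grid$ncol)
  structure(list(grid = grid, zones = zones, names = names),
            class = "zone_map")
}
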