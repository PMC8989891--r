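# Marginal-land extraction and area accounting: threshold the mean
# suitability map, keep only allowed land-use classes, and tabulate
# latitude-corrected spherical cell areas by zone and class.

EARTH_RADIUS_KM <- 6371.0088 # IUGG mean Earth radius

#' Threshold a suitability map
#'
#' @param mean_map `geo_layer` with values in `[0, 1]`.
#' @param threshold Suitability cutoff in `[0, 1]` (default 0.5). The rule
#'   is inclusive: a cell exactly at the threshold counts as suitable.
#' @return Logical `geo_layer`; NoData -> FALSE.
#' @export
threshold_suitability <- function(mean_map, threshold = 0.5) {
  stopifnot(inherits(mean_map, "geo_layer"))
  if (threshold < 0 || threshold > 1) stop("threshold outside [0, 1]")
  v <- mean_map$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("suitability values outside [0, 1]")
  m <- v >= threshold
  m[is.na(m)] <- FALSE
  geo_layer(m, mean_map$grid)
}

#' Mask suitable cells by allowed land-use classes
#'
#' Keeps the land-use code where a cell is both suitable and in an allowed
#' class (by default the five marginal classes: woody savannas, savannas,
#' closed shrublands, open shrublands, grasslands); everything else becomes
#' NoData.
#'
#' @param suitable Logical `geo_layer` from [threshold_suitability()].
#' @param landuse A `landuse_map`.
#' @param allowed Character vector of allowed class names.
#' @return A `landuse_map` carrying codes only on marginal cells.
#' @export
mask_by_landuse <- function(suitable, landuse, allowed = marginal_classes()) {
  stopifnot(inherits(suitable, "geo_layer"), inherits(landuse, "landuse_map"))
  if (!grids_identical(suitable$grid, landuse$grid))
    stop("suitability and land-use rasters are on different grids")
  codes_allowed <- as.numeric(names(landuse$classes)[landuse$classes %in% allowed])
  out <- landuse$codes
  out[!(suitable$values & landuse$codes %in% codes_allowed)] <- NA
  structure(list(grid = landuse$grid, codes = out, classes = landuse$classes),
            class = "landuse_map")
}

#' Spherical area of a latitude-longitude cell, in hectares
#'
#' A = R^2 * d_lambda * (sin(phi_N) - sin(phi_S)), R = 6371.0088 km.
#'
#' @param lat_north,lat_south Cell edge latitudes in degrees (vectorized);
#'   north edge must not be south of the south edge.
#' @param resolution_deg Cell width in degrees of longitude.
#' @return Hectares.
#' @export
cell_area_ha <- function(lat_north, lat_south, resolution_deg) {
  if (any(abs(c(lat_north, lat_south)) > 90)) stop("latitude beyond poles")
  if (any(lat_north < lat_south)) stop("inverted cell edges")
  r_m <- EARTH_RADIUS_KM * 1000
  dlam <- resolution_deg * pi / 180
  a_m2 <- r_m^2 * dlam * (sin(lat_north * pi / 180) - sin(lat_south * pi / 180))
  a_m2 / 1e4
}

#' Per-row cell areas of a grid, in hectares
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `grid$nrow` (north to south).
#' @export
row_cell_areas <- function(grid) {
  north <- grid$origin_lat - (seq_len(grid$nrow) - 1) * grid$resolution
  cell_area_ha(north, north - grid$resolution, grid$resolution)
}

#' Composition percentages from per-class totals
#'
#' `100 * class_total / grand_total`, the land-use composition statistic
#' reported for marginal-land assessments.
#'
#' @param class_totals Named numeric vector of per-class areas (any unit).
#' @return Named percentages summing to 100 (all-zero input returns zeros
#'   with a warning).
#' @export
composition_percentages <- function(class_totals) {
  total <- sum(class_totals)
  if (total <= 0) {
    warning("empty marginal raster: composition percentages undefined, ",
            "reporting 0")
    return(setNames(rep(0, length(class_totals)), names(class_totals)))
  }
  100 * class_totals / total
}

#' Tabulate marginal-land areas by zone and land-use class
#'
#' Sums latitude-corrected spherical cell areas (or, with
#' `flat_count = TRUE`, a nominal 2500 ha per 0.05-degree cell, the
#' "5 x 5 km cell" reading) per (zone, class), with per-zone and per-class
#' totals and composition percentages.
#'
#' @param marginal A `landuse_map` from [mask_by_landuse()].
#' @param zones A `zone_map` on the same grid, or `"global"` for a single
#'   zone.
#' @param flat_count Use a flat nominal area per cell instead of spherical
#'   areas.
#' @param nominal_ha Nominal per-cell hectares for `flat_count` (default
#'   2500).
#' @return An `area_table`: `table` (zone x class data.frame of hectares),
#'   `zone_totals`, `class_totals`, `grand_total` (hectares),
#'   `composition_pct`.
#' @export
tabulate_areas <- function(marginal, zones = "global", flat_count = FALSE,
                           nominal_ha = 2500) {
  stopifnot(inherits(marginal, "landuse_map"))
  g <- marginal$grid
  if (identical(zones, "global")) {
    zmat <- matrix(1L, g$nrow, g$ncol)
    znames <- "global"
  } else {
    stopifnot(inherits(zones, "zone_map"))
    if (!grids_identical(g, zones$grid))
      stop("zone raster on a different grid")
    zmat <- zones$zones
    znames <- zones$names
  }
  area_row <- if (flat_count) rep(nominal_ha, g$nrow) else row_cell_areas(g)
  area_mat <- matrix(area_row, g$nrow, g$ncol)
  idx <- which(!is.na(marginal$codes))
  codes_all <- sort(unique(as.vector(marginal$codes)))
  class_names <- marginal$classes[as.character(codes_all)]
  tab <- matrix(0, length(znames), length(codes_all),
                dimnames = list(znames, class_names))
  if (length(idx)) {
    df <- data.frame(zone = zmat[idx], code = marginal$codes[idx],
                     area = area_mat[idx])
    agg <- aggregate(area ~ zone + code, df, sum)
    for (i in seq_len(nrow(agg)))
      tab[agg$zone[i], match(agg$code[i], codes_all)] <- agg$area[i]
  }
  zone_totals <- rowSums(tab)
  class_totals <- colSums(tab)
  df <- as.data.frame(tab)
  names(df) <- colnames(tab) # keep class names verbatim (with spaces)
  structure(list(table = df,
                 zone_totals = zone_totals, class_totals = class_totals,
                 grand_total = sum(zone_totals),
                 composition_pct = composition_percentages(class_totals)),
            class = "area_table")
}

#' @export
print.area_table <- function(x, ...) {
  cat(sprintf("area_table: %.2f Mha total\n", x$grand_total / 1e6))
  comp <- x$composition_pct
  for (nm in names(sort(comp, decreasing = TRUE)))
    cat(sprintf("  %-26s %10.2f Mha  %6.2f%%\n", nm,
                x$class_totals[nm] / 1e6, comp[nm]))
  invisible(x)
}

#' Write an area table as CSV (zone rows, class columns, totals)
#' @param x An `area_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(x, path) {
  out <- cbind(zone = rownames(x$table), x$table,
               total = unname(x$zone_totals))
  totals <- out[0, , drop = FALSE]
  totals[1, "zone"] <- "total"
  for (nm in names(x$class_totals)) totals[1, nm] <- x$class_totals[[nm]]
  totals[1, "total"] <- x$grand_total
  out <- rbind(out, totals)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
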