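#' Define a geographic raster grid
#'
#' A grid is a regular lattice of square cells in geographic coordinates
#' (EPSG:4326). The origin is the upper-left corner of the upper-left cell;
#' rows run north to south, columns west to east. Cell intervals are
#' half-open: a point on a shared edge belongs to the cell whose north or
#' west edge it lies on, so every point maps to exactly one cell.
#'
#' @param nrow,ncol Grid dimensions (positive integers).
#' @param resolution Cell size in decimal degrees (default 0.05, i.e. the
#'   ~5 km cells used for global suitability mapping).
#' @param origin Numeric length-2: (longitude, latitude) of the grid's
#'   upper-left corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, resolution = 0.05, origin = c(0, 45)) {
  stopifnot(length(nrow) == 1, length(ncol) == 1, nrow >= 1, ncol >= 1,
            resolution > 0, length(origin) == 2)
  if (origin[2] > 90 || origin[2] - nrow * resolution < -90)
    stop("grid extends beyond the poles")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 resolution = resolution,
                 origin_lon = origin[1], origin_lat = origin[2],
                 crs = "EPSG:4326"),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells @ %g deg, origin (%g, %g), %s\n",
              x$nrow, x$ncol, x$resolution, x$origin_lon, x$origin_lat, x$crs))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$resolution - b$resolution) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol
}

#' Latitudes of cell centers, north to south
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `grid$nrow`.
#' @export
cell_center_lats <- function(grid) {
  grid$origin_lat - (seq_len(grid$nrow) - 0.5) * grid$resolution
}

#' Longitudes of cell centers, west to east
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `grid$ncol`.
#' @export
cell_center_lons <- function(grid) {
  grid$origin_lon + (seq_len(grid$ncol) - 0.5) * grid$resolution
}

#' Map points to grid cells
#'
#' Uses the half-open cell convention: row = floor((origin_lat - lat)/res),
#' col = floor((lon - origin_lon)/res), both 0-based, returned 1-based.
#' Points outside the grid get NA row/col.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Point coordinates (vectors of equal length).
#' @return data.frame with columns `row`, `col`, `cell_id`
#'   (`(row-1)*ncol + col`).
#' @export
point_to_cell <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  row0 <- floor((grid$origin_lat - lat) / grid$resolution)
  col0 <- floor((lon - grid$origin_lon) / grid$resolution)
  inside <- row0 >= 0 & row0 < grid$nrow & col0 >= 0 & col0 < grid$ncol
  row <- ifelse(inside, row0 + 1, NA_integer_)
  col <- ifelse(inside, col0 + 1, NA_integer_)
  data.frame(row = as.integer(row), col = as.integer(col),
             cell_id = as.integer((row - 1) * grid$ncol + col))
}

#' Construct a single-layer geographic raster
#'
#' Values are stored as an `nrow x ncol` matrix with NA marking NoData
#' ("ocean"); the NoData convention is NA internally and a sentinel value
#' only in files.
#'
#' @param values Numeric matrix matching the grid dimensions.
#' @param grid A `grid_spec`.
#' @return An object of class `geo_layer`.
#' @export
geo_layer <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(values = values, grid = grid), class = "geo_layer")
}

#' @export
print.geo_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("geo_layer: %d x %d, %d valid cells, range [%g, %g]\n",
              x$grid$nrow, x$grid$ncol, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Construct a multi-layer environmental raster stack
#'
#' @param layers Named list of numeric matrices sharing the grid dimensions.
#' @param grid A `grid_spec`.
#' @param categorical Character vector naming integer-coded categorical
#'   layers (e.g. `"soil_class"`).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, grid, categorical = character()) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nrow || ncol(m) != grid$ncol)
      stop("layer '", nm, "' does not match the grid dimensions")
  }
  if (!all(categorical %in% names(layers)))
    stop("categorical names not present among layers")
  structure(list(layers = layers, grid = grid, categorical = categorical),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$nrow, x$grid$ncol,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' A cell is valid iff no layer has NoData there; modelling and area
#' accounting only ever see valid cells.
#'
#' @param stack An `env_stack`.
#' @return Logical matrix.
#' @export
valid_mask <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(m) !is.na(m)))
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by GDAL/QGIS/ArcGIS; NoData is
#' written as the sentinel `nodata`.
#'
#' @param layer A `geo_layer` (or numeric matrix with `grid` supplied).
#' @param path Output path (conventionally `.asc`).
#' @param grid Required when `layer` is a bare matrix.
#' @param nodata Sentinel written for NA cells (default -9999).
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, grid = NULL, nodata = -9999,
                             digits = 10) {
  if (inherits(layer, "geo_layer")) {
    grid <- layer$grid
    values <- layer$values
  } else {
    stopifnot(inherits(grid, "grid_spec"))
    values <- layer
  }
  hdr <- c(sprintf("ncols %d", grid$ncol),
           sprintf("nrows %d", grid$nrow),
           sprintf("xllcorner %.10f", grid$origin_lon),
           sprintf("yllcorner %.10f", grid$origin_lat - grid$nrow * grid$resolution),
           sprintf("cellsize %.10f", grid$resolution),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A `geo_layer`; NoData sentinel cells become NA.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nrow <- as.integer(hdr$nrows); ncol <- as.integer(hdr$ncols)
  res <- hdr$cellsize
  values <- matrix(scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                        quiet = TRUE),
                   nrow = nrow, ncol = ncol, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) values[values == hdr$nodata_value] <- NA
  g <- grid_spec(nrow, ncol, res,
                 origin = c(hdr$xllcorner, hdr$yllcorner + nrow * res))
  geo_layer(values, g)
}

#' Write every layer of a stack as ASCII grids
#' @param stack An `env_stack`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], p, grid = stack$grid)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of ASCII grids into a stack
#' @param paths Named character vector of `.asc` paths (names become layer
#'   names).
#' @param categorical Character vector of categorical layer names.
#' @return An `env_stack`; errors if grids disagree.
#' @export
read_stack <- function(paths, categorical = character()) {
  stopifnot(!is.null(names(paths)))
  lys <- lapply(paths, read_ascii_grid)
  g <- lys[[1]]$grid
  for (k in seq_along(lys)) {
    if (!grids_identical(g, lys[[k]]$grid))
      stop("layer '", names(paths)[k], "' is on a different grid")
  }
  env_stack(lapply(lys, `[[`, "values"), g, categorical = categorical)
}
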