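# Occurrence processing: gridding raw records to presence cells, climatic
# envelope pseudo-absence sampling, covariate extraction.

#' Climatic envelope rule for pseudo-absence sampling
#'
#' Cells outside the species' broad climatic tolerance are eligible as
#' pseudo-absences: mean annual temperature below `temp_low` or above
#' `temp_high`, or annual precipitation below `precip_low` or above
#' `precip_high`. Defaults are the published tolerance bounds for
#' P. chinensis (5.8-28.4 degC, 400-1900 mm).
#'
#' @param temp_low,temp_high Temperature bounds in degC.
#' @param precip_low,precip_high Precipitation bounds in mm.
#' @return An `envelope_rule`.
#' @export
envelope_rule <- function(temp_low = 5.8, temp_high = 28.4,
                          precip_low = 400, precip_high = 1900) {
  stopifnot(temp_low < temp_high, precip_low < precip_high)
  structure(list(temp_low = temp_low, temp_high = temp_high,
                 precip_low = precip_low, precip_high = precip_high),
            class = "envelope_rule")
}

#' Aggregate occurrence points to distinct presence cells
#'
#' Multiple records falling in one cell count once (1923 GBIF-style records
#' typically deduplicate to far fewer cells). Points outside the grid are
#' dropped with a message.
#'
#' @param points data.frame with `lon`, `lat` (finite).
#' @param grid A `grid_spec`.
#' @return data.frame of distinct presence cells: `cell_id`, `row`, `col`,
#'   with attribute `n_dropped`.
#' @export
grid_occurrences <- function(points, grid) {
  if (is.null(points) || nrow(points) == 0) stop("empty occurrence table")
  stopifnot(all(is.finite(points$lon)), all(is.finite(points$lat)))
  cells <- point_to_cell(grid, points$lon, points$lat)
  dropped <- sum(is.na(cells$cell_id))
  if (dropped > 0)
    message(dropped, " point(s) outside the grid dropped")
  cells <- cells[!is.na(cells$cell_id), , drop = FALSE]
  if (nrow(cells) == 0) stop("no occurrence points fall inside the grid")
  out <- unique(cells[order(cells$cell_id), c("cell_id", "row", "col")])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Boolean raster of envelope-eligible pseudo-absence cells
#'
#' With `logic = "or"` (default) a cell is eligible if it violates the
#' temperature clause OR the precipitation clause; `"and"` requires both.
#' NoData cells are never eligible.
#'
#' @param stack An `env_stack` containing `tavg` and `prec` layers (names
#'   configurable).
#' @param rule An [envelope_rule()].
#' @param logic `"or"` or `"and"` combination of the two clauses.
#' @param temp_layer,precip_layer Layer names.
#' @return A `geo_layer` of logicals (NoData -> FALSE).
#' @export
envelope_mask <- function(stack, rule = envelope_rule(),
                          logic = c("or", "and"),
                          temp_layer = "tavg", precip_layer = "prec") {
  logic <- match.arg(logic)
  stopifnot(inherits(stack, "env_stack"), inherits(rule, "envelope_rule"))
  for (nm in c(temp_layer, precip_layer))
    if (!nm %in% names(stack$layers)) stop("missing layer '", nm, "'")
  tv <- stack$layers[[temp_layer]]
  pv <- stack$layers[[precip_layer]]
  tbad <- tv < rule$temp_low | tv > rule$temp_high
  pbad <- pv < rule$precip_low | pv > rule$precip_high
  m <- if (logic == "or") tbad | pbad else tbad & pbad
  m[is.na(m)] <- FALSE
  m[!valid_mask(stack)] <- FALSE
  geo_layer(m, stack$grid)
}

#' Sample pseudo-absence cells within the envelope
#'
#' Uniform sampling without replacement from envelope-eligible cells that
#' are not presence cells.
#'
#' @param mask A logical `geo_layer` from [envelope_mask()].
#' @param presence_cells data.frame with `cell_id` (as from
#'   [grid_occurrences()]).
#' @param n Number of absences (default: one per presence, the balanced
#'   design).
#' @param seed Integer seed.
#' @return data.frame `cell_id`, `row`, `col` of absence cells.
#' @export
sample_pseudo_absences <- function(mask, presence_cells,
                                   n = nrow(presence_cells), seed = 1L) {
  stopifnot(inherits(mask, "geo_layer"))
  g <- mask$grid
  m <- mask$values
  # matrix is column-major; enumerate eligible cells by (row, col)
  elig <- which(m, arr.ind = TRUE)
  elig_id <- (elig[, 1] - 1) * g$ncol + elig[, 2]
  keep <- !(elig_id %in% presence_cells$cell_id)
  elig <- elig[keep, , drop = FALSE]
  elig_id <- elig_id[keep]
  if (n == 0)
    return(data.frame(cell_id = integer(), row = integer(), col = integer()))
  if (length(elig_id) < n)
    stop("insufficient eligible cells for pseudo-absences: need ", n,
         ", have ", length(elig_id), " (shortfall ", n - length(elig_id), ")")
  set.seed(seed)
  pick <- sample.int(length(elig_id), n, replace = FALSE)
  out <- data.frame(cell_id = as.integer(elig_id[pick]),
                    row = as.integer(elig[pick, 1]),
                    col = as.integer(elig[pick, 2]))
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract covariate values for presence and absence cells
#'
#' One row per cell with all stack layers read at the cell's own pixel (all
#' layers are pre-resampled to the common grid, so no interpolation). Rows
#' with NoData in any layer are dropped with a message; soil class (and any
#' categorical layer) is returned as a factor.
#'
#' @param presence_cells,absence_cells data.frames with `row`, `col`,
#'   `cell_id`.
#' @param stack An `env_stack`.
#' @return data.frame (the model's design table): `cell_id`, `row`, `col`,
#'   `label` (1 presence / 0 absence), then one column per layer. Attribute
#'   `n_dropped` counts NoData rows removed.
#' @export
extract_covariates <- function(presence_cells, absence_cells, stack) {
  stopifnot(inherits(stack, "env_stack"))
  both <- intersect(presence_cells$cell_id, absence_cells$cell_id)
  if (length(both))
    stop("cells carry both labels: ", paste(utils::head(both), collapse = ","))
  cells <- rbind(
    data.frame(cell_id = presence_cells$cell_id, row = presence_cells$row,
               col = presence_cells$col, label = 1L),
    data.frame(cell_id = absence_cells$cell_id, row = absence_cells$row,
               col = absence_cells$col, label = 0L))
  if (any(cells$row < 1 | cells$row > stack$grid$nrow |
          cells$col < 1 | cells$col > stack$grid$ncol))
    stop("cells outside the grid")
  for (nm in names(stack$layers)) {
    m <- stack$layers[[nm]]
    cells[[nm]] <- m[cbind(cells$row, cells$col)]
  }
  ok <- stats::complete.cases(cells)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " cell(s) with NoData covariates dropped")
  cells <- cells[ok, , drop = FALSE]
  for (nm in stack$categorical)
    cells[[nm]] <- factor(cells[[nm]], levels = sort(unique(
      as.vector(stack$layers[[nm]][!is.na(stack$layers[[nm]])]))))
  rownames(cells) <- NULL
  attr(cells, "n_dropped") <- n_dropped
  cells
}

#' Build the full design table from points and a stack
#'
#' Convenience wrapper: grid occurrences, build the envelope mask, sample
#' balanced pseudo-absences, extract covariates.
#'
#' @param points Occurrence data.frame (`lon`, `lat`).
#' @param stack An `env_stack`.
#' @param rule An [envelope_rule()].
#' @param logic Envelope clause combination, see [envelope_mask()].
#' @param seed Integer seed for absence sampling.
#' @return The design table from [extract_covariates()].
#' @export
build_cell_table <- function(points, stack, rule = envelope_rule(),
                             logic = "or", seed = 1L) {
  pres <- grid_occurrences(points, stack$grid)
  mask <- envelope_mask(stack, rule, logic = logic)
  abs <- sample_pseudo_absences(mask, pres, n = nrow(pres), seed = seed)
  extract_covariates(pres, abs, stack)
}
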