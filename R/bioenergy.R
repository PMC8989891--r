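# Biodiesel and GHG-abatement scenario arithmetic over marginal-land area.
#
# The literature coefficients behind the published scenario ranges (fruit
# oil content, per-hectare yield, conversion rate, per-litre abatement) are
# not printed anywhere accessible, so the module takes them as explicit
# parameters. The shipped defaults are BACK-CALCULATED (synthetic, not
# sourced) from the published 30%-utilization scenario over 1311.85 Mha:
# yields 375.54e9 / (1311.85e6 * 0.3) ~ 954.3 and 667.31e9 / (...) ~ 1695.7
# L/ha/yr; abatement 0.27e12 / 375.54e9 ~ 0.719 and 1.95e12 / 667.31e9
# ~ 2.922 kg CO2e/L.

#' Back-calculate an implied per-hectare biodiesel yield
#'
#' @param total_area Marginal-land area in Mha.
#' @param utilization Fraction of the area cultivated, in (0, 1].
#' @param volume Biodiesel volume in billion litres per year.
#' @return Litres per hectare per year.
#' @export
implied_yield <- function(total_area, utilization, volume) {
  if (total_area <= 0 || utilization <= 0) stop("zero or negative denominator")
  if (volume < 0) stop("negative volume")
  (volume * 1e9) / (total_area * 1e6 * utilization)
}

#' Scenario parameters for biodiesel and GHG-abatement arithmetic
#'
#' @param total_area Marginal-land area in Mha (> 0).
#' @param utilization Fraction of the area cultivated, in (0, 1]; 0.30 is
#'   the conservative published scenario, 0.50 the optimistic one.
#' @param yield_low,yield_high Biodiesel yield range in L/ha/yr
#'   (defaults back-calculated, see above).
#' @param abatement_low,abatement_high GHG abatement per litre of biodiesel
#'   displacing fossil fuel, kg CO2e/L (defaults back-calculated).
#' @param goal Annual emissions-reduction goal in Gt CO2e (28, the 1.5-degC
#'   pathway figure).
#' @return A `scenario_params`.
#' @export
scenario_params <- function(total_area,
                            utilization = 0.30,
                            yield_low = 375.54e9 / (1311.85e6 * 0.3),
                            yield_high = 667.31e9 / (1311.85e6 * 0.3),
                            abatement_low = 0.27e12 / 375.54e9,
                            abatement_high = 1.95e12 / 667.31e9,
                            goal = 28) {
  if (total_area <= 0) stop("total_area must be positive")
  stopifnot(utilization > 0, utilization <= 1,
            yield_low <= yield_high, abatement_low <= abatement_high,
            yield_low >= 0, abatement_low >= 0, goal > 0)
  structure(list(total_area = total_area, utilization = utilization,
                 yield_low = yield_low, yield_high = yield_high,
                 abatement_low = abatement_low,
                 abatement_high = abatement_high, goal = goal),
            class = "scenario_params")
}

#' Compute a biodiesel / GHG-abatement scenario
#'
#' volume = area x utilization x yield; abatement = volume x per-litre
#' factor, cross-matched low-with-low and high-with-high; goal share =
#' abatement / goal x 100. All values are exact (unrounded); rounding to
#' two decimals happens only in [format.scenario_result()].
#'
#' @param params A [scenario_params()].
#' @return A `scenario_result`: `volume_low`/`volume_high` (billion litres
#'   per year), `abatement_low`/`abatement_high` (Gt CO2e per year),
#'   `goal_share_low`/`goal_share_high` (percent).
#' @export
biodiesel_scenario <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  ha <- params$total_area * 1e6 * params$utilization
  vol_low <- ha * params$yield_low / 1e9
  vol_high <- ha * params$yield_high / 1e9
  ab_low <- vol_low * 1e9 * params$abatement_low / 1e12   # Gt CO2e
  ab_high <- vol_high * 1e9 * params$abatement_high / 1e12
  structure(list(volume_low = vol_low, volume_high = vol_high,
                 abatement_low = ab_low, abatement_high = ab_high,
                 goal_share_low = 100 * ab_low / params$goal,
                 goal_share_high = 100 * ab_high / params$goal,
                 params = params),
            class = "scenario_result")
}

#' @export
format.scenario_result <- function(x, ...) {
  r2 <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  sprintf(paste0("biodiesel %s-%s BL/yr; abatement %s-%s GtCO2e/yr; ",
                 "%s%%-%s%% of the %g GtCO2e goal"),
          r2(x$volume_low), r2(x$volume_high),
          r2(x$abatement_low), r2(x$abatement_high),
          r2(x$goal_share_low), r2(x$goal_share_high), x$params$goal)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
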