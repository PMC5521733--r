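# Carbon-emission accounting and valuation. Conversion from forest to
# agriculture releases the carbon held aboveground, belowground, in dead
# organic matter, and in peat; mineral soil carbon is conservatively
# assumed unchanged. Emissions are expressed as tCO2e/ha, valued under a
# market or social price regime, and the one-off stock value is
# annualized over the policy horizon with the standard annuity factor.

#' CO2-equivalent emissions from converting one hectare
#'
#' `(agb + bgb + dom + peat_depth * peat_c_per_m) * 44/12` tCO2e/ha.
#' Mineral soil carbon contributes zero. All arguments are vectorized.
#'
#' @param agb_c,bgb_c,dom_c above-ground, below-ground and
#'   dead-organic-matter carbon, tC/ha.
#' @param peat_depth peat depth, m (0 for mineral soils).
#' @param peat_c_per_m peat carbon density, tC/ha per metre of depth.
#' @return Emissions in tCO2e/ha.
#' @export
cell_emissions <- function(agb_c, bgb_c = 0, dom_c = 0, peat_depth = 0,
                           peat_c_per_m = 500) {
  if (any(c(agb_c, bgb_c, dom_c, peat_depth, peat_c_per_m) < 0)) {
    stop("carbon pools and peat depth must be non-negative", call. = FALSE)
  }
  (agb_c + bgb_c + dom_c + peat_depth * peat_c_per_m) * 44 / 12
}

#' Value emissions at a carbon price
#'
#' @param emissions tCO2e/ha.
#' @param price carbon price, currency per tonne.
#' @param basis `"per_tCO2"` if the price is quoted per tonne of CO2e,
#'   `"per_tC"` if per tonne of carbon (converted by 12/44).
#' @return One-off value, currency/ha.
#' @export
price_emissions <- function(emissions, price, basis = c("per_tCO2", "per_tC")) {
  basis <- match.arg(basis)
  if (any(price < 0)) stop("price must be non-negative", call. = FALSE)
  if (basis == "per_tCO2") emissions * price else emissions * price * 12 / 44
}

#' Annualize a present value over a horizon
#'
#' `pv * r / (1 - (1 + r)^-T)` for `r > 0`; the continuity limit `pv / T`
#' at `r = 0`. Discounting the annuity back over the horizon recovers the
#' present value exactly.
#'
#' @param pv present value (currency).
#' @param r annual discount rate (>= 0).
#' @param horizon horizon in years (>= 1).
#' @return Equivalent annual flow, currency/yr.
#' @export
annualize <- function(pv, r, horizon) {
  if (any(r < 0)) stop("discount rate must be >= 0", call. = FALSE)
  if (any(horizon < 1)) stop("horizon must be >= 1", call. = FALSE)
  n <- max(length(pv), length(r), length(horizon))
  pv <- rep_len(pv, n)
  r <- rep_len(r, n)
  horizon <- rep_len(horizon, n)
  unname(ifelse(r > 0, pv * r / (1 - (1 + r)^(-horizon)), pv / horizon))
}

#' Annualized per-hectare carbon-emission value map
#'
#' Applies [cell_emissions()], [price_emissions()] and [annualize()] to
#' every cell of a landscape grid.
#'
#' @param grid a `landscape_grid`.
#' @param price carbon price, currency/t.
#' @param model a [carbon_price_model()] supplying basis, discount rate,
#'   horizon and peat carbon density.
#' @return Numeric per-cell carbon value, currency/ha/yr.
#' @export
carbon_value_map <- function(grid, price, model = carbon_price_model()) {
  em <- cell_emissions(
    grid$agb_carbon, grid$bgb_carbon, grid$dom_carbon,
    grid$peat_depth, model$peat_c_per_m
  )
  annualize(
    price_emissions(em, price, model$price_basis),
    model$discount_rate, model$horizon
  )
}
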