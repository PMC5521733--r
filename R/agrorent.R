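# Agricultural rents of converted cells under four crop-replacement
# scenarios. A and B replace forest with crops sampled from the national
# crop composition (net and gross of production costs); C and D replace
# it with the crop of highest potential rent per cell (net and gross).
# Costs follow a von Thunen structure: labour (person-days times the
# national wage), fertilizer (usage times price), and -- for the
# maximum-rent cash-crop scenarios -- transport of the produce to the
# nearest market by truck. A one-off timber windfall from clearing is
# annualized and added, and pasture cells converted to cattle earn
# carcass revenue.

#' Scenario specification
#'
#' @param id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A `scenario_spec` list with `id`, `crop_source`
#'   (`national_sample` for A/B, `max_rent` for C/D) and `deduct_costs`
#'   (TRUE for A/C, FALSE for B/D).
#' @export
scenario_spec <- function(id) {
  if (!is.character(id) || length(id) != 1L || !id %in% c("A", "B", "C", "D")) {
    config_error("scenario", "must be one of A, B, C, D")
  }
  structure(
    list(
      id = id,
      crop_source = if (id %in% c("A", "B")) "national_sample" else "max_rent",
      deduct_costs = id %in% c("A", "C")
    ),
    class = "scenario_spec"
  )
}

#' Transport cost of produce to the nearest market
#'
#' One truck, one driver, returning empty: round-trip distance is
#' `2 * travel_time * speed`; the load cost is fuel over that distance
#' plus the driver's wage over the round-trip time; cost per tonne
#' divides by the load mass `capacity_m3 * density_t_per_m3`.
#'
#' @param travel_time one-way travel time to market, hours (vectorized).
#' @param wage_h driver wage, currency/h.
#' @param fuel_price currency/L.
#' @param capacity_m3 truck capacity (default 18 m3).
#' @param speed_kmh average speed (default 45 km/h).
#' @param fuel_l_per_km fuel consumption (default 0.3 L/km).
#' @param density_t_per_m3 load density converting volume to mass
#'   (default 1 t/m3).
#' @return Cost in currency per tonne transported.
#' @export
transport_cost <- function(travel_time, wage_h, fuel_price,
                           capacity_m3 = 18, speed_kmh = 45,
                           fuel_l_per_km = 0.3, density_t_per_m3 = 1) {
  if (any(capacity_m3 <= 0)) stop("truck capacity must be positive", call. = FALSE)
  if (any(c(travel_time, wage_h, fuel_price, speed_kmh, fuel_l_per_km,
    density_t_per_m3) < 0)) {
    stop("transport inputs must be non-negative", call. = FALSE)
  }
  dist <- 2 * travel_time * speed_kmh
  load_cost <- dist * fuel_l_per_km * fuel_price + 2 * travel_time * wage_h
  load_cost / (capacity_m3 * density_t_per_m3)
}

#' Per-hectare production cost components
#'
#' Labour (`persondays * wage_day`), fertilizer (`usage * price`) and,
#' when enabled, transport (`cost per tonne * yield`). Gross-rent
#' scenarios set the total to zero.
#'
#' @param persondays person-days/ha/yr for the crop.
#' @param wage_day currency/day.
#' @param fertilizer_usage kg/ha/yr.
#' @param fertilizer_price currency/kg.
#' @param transport_per_t currency/t (0 when transport not applicable).
#' @param yield t/ha/yr moved to market.
#' @param deduct logical; FALSE returns a zero total (gross rents).
#' @param include_transport logical; transport only applies to the
#'   maximum-rent scenarios' transported cash crops.
#' @return List with `labor`, `fertilizer`, `transport`, `total`
#'   (currency/ha/yr), each vectorized.
#' @export
production_costs <- function(persondays, wage_day, fertilizer_usage = 0,
                             fertilizer_price = 0, transport_per_t = 0,
                             yield = 0, deduct = TRUE,
                             include_transport = FALSE) {
  labor <- persondays * wage_day
  fertilizer <- fertilizer_usage * fertilizer_price
  transport <- if (include_transport) transport_per_t * yield else 0 * labor
  total <- (labor + fertilizer + transport) * as.numeric(deduct)
  list(
    labor = labor * as.numeric(deduct),
    fertilizer = fertilizer * as.numeric(deduct),
    transport = transport * as.numeric(deduct),
    total = total
  )
}

#' Net agricultural rent
#'
#' `AR = yield * price - costs`; negative rents are preserved.
#'
#' @param yield t/ha/yr.
#' @param price currency/t.
#' @param costs currency/ha/yr.
#' @return Rent in currency/ha/yr.
#' @export
net_rent <- function(yield, price, costs = 0) {
  if (any(yield < 0) || any(price < 0)) {
    stop("yield and price must be non-negative", call. = FALSE)
  }
  yield * price - costs
}

#' Annualized timber windfall from clearing
#'
#' One-off revenue `growing_stock * commercial_fraction * export_price`,
#' converted to an annual flow with [annualize()].
#'
#' @param growing_stock m3/ha.
#' @param commercial_fraction fraction of the stock in commercial
#'   species, in `[0, 1]`.
#' @param export_price currency/m3.
#' @param r discount rate.
#' @param horizon years.
#' @return currency/ha/yr.
#' @export
timber_rent <- function(growing_stock, commercial_fraction, export_price,
                        r = 0.05, horizon = 100) {
  if (any(commercial_fraction < 0 | commercial_fraction > 1)) {
    stop("commercial_fraction must lie in [0, 1]", call. = FALSE)
  }
  annualize(growing_stock * commercial_fraction * export_price, r, horizon)
}

#' Cattle rent
#'
#' `stocking * carcass_efficiency * price - costs`.
#'
#' @param stocking head/ha.
#' @param carcass_eff carcass mass per head, t/head.
#' @param price currency/t.
#' @param costs currency/ha/yr.
#' @return currency/ha/yr.
#' @export
cattle_rent <- function(stocking, carcass_eff, price, costs = 0) {
  if (any(c(stocking, carcass_eff, price) < 0)) {
    stop("cattle inputs must be non-negative", call. = FALSE)
  }
  stocking * carcass_eff * price - costs
}

# national wage with fallback: agricultural wage when available, else
# manufacturing wage; both missing is an error
wage_day_lookup <- function(econ) {
  cp <- econ$country_params
  w <- ifelse(!is.na(cp$agri_wage_day), cp$agri_wage_day, cp$manu_wage_day)
  if (anyNA(w)) {
    stop(
      "no agricultural or manufacturing wage for country ",
      paste(cp$country_id[is.na(w)], collapse = ", "),
      call. = FALSE
    )
  }
  stats::setNames(w, cp$country_id)
}

# price matrix crops x countries from the econ tables or a Monte Carlo
# price draw; missing combinations fall back to a donor country, then 0
price_matrix <- function(econ, prices = NULL, donor = NULL) {
  cp <- if (is.null(prices)) {
    transform(econ$crop_prices, price = price_mean)
  } else {
    prices
  }
  crops <- unique(econ$crop_prices$crop)
  countries <- sort(unique(econ$crop_prices$country_id))
  P <- matrix(NA_real_, length(crops), length(countries),
    dimnames = list(crops, as.character(countries))
  )
  P[cbind(
    match(cp$crop, crops),
    match(as.character(cp$country_id), colnames(P))
  )] <- cp$price
  if (anyNA(P)) {
    if (!is.null(donor) && as.character(donor) %in% colnames(P)) {
      for (jj in seq_len(ncol(P))) {
        miss <- is.na(P[, jj])
        P[miss, jj] <- P[miss, as.character(donor)]
      }
    }
    if (anyNA(P)) {
      warning("missing crop-country prices set to 0", call. = FALSE)
      P[is.na(P)] <- 0
    }
  }
  P
}

# per-cell candidate rent for every crop: potential yields, mean (or
# drawn) prices, and the full cost set of the maximum-rent scenarios
# (labour + fertilizer + transport for transported crops); cattle uses
# stocking x carcass efficiency and labour only. Used for the C/D argmax
# and exported for post-hoc optimality checks.

#' Candidate rent matrix under the maximum-rent cost structure
#'
#' @param grid a `landscape_grid`.
#' @param econ an `econ_tables`.
#' @param prices optional drawn prices (`crop`, `country_id`, `price`).
#' @param deduct deduct production costs (TRUE for scenario C, FALSE
#'   for D)?
#' @param donor optional donor country for missing prices.
#' @return Matrix cells x crops of rents, currency/ha/yr.
#' @export
potential_rent_matrix <- function(grid, econ, prices = NULL, deduct = TRUE,
                                  donor = NULL) {
  crops <- attr(grid, "crop_set")
  P <- price_matrix(econ, prices, donor)
  wday <- wage_day_lookup(econ)
  cpars <- econ$crop_params
  ctry <- as.character(grid$country_id)
  cpc <- econ$country_params
  whour <- stats::setNames(cpc$wage_hour, cpc$country_id)
  fuel <- stats::setNames(cpc$fuel_price, cpc$country_id)
  fertp <- stats::setNames(cpc$fertilizer_price, cpc$country_id)
  ceff <- stats::setNames(cpc$carcass_efficiency, cpc$country_id)
  tpt <- transport_cost(grid$travel_time, whour[ctry], fuel[ctry])
  out <- matrix(NA_real_, nrow(grid), length(crops),
    dimnames = list(NULL, crops)
  )
  for (u in crops) {
    pu <- P[u, ctry]
    if (u == "cattle") {
      gross <- grid$cattle_stocking * ceff[ctry] * pu
      labor <- cpars$persondays[cpars$crop == u] * wday[ctry]
      cost <- labor
    } else {
      y <- grid[[paste0("potyield_", u)]]
      gross <- y * pu
      labor <- cpars$persondays[cpars$crop == u] * wday[ctry]
      fert <- grid$fertilizer_usage * fertp[ctry]
      trans <- if (cpars$is_transported[cpars$crop == u]) tpt * y else 0
      cost <- labor + fert + trans
    }
    out[, u] <- if (deduct) gross - cost else gross
  }
  out
}

#' Assign a replacement crop to every cell
#'
#' Scenarios A/B draw a crop per cell from the country's area-weighted
#' crop composition (seeded; identical draws for A and B under the same
#' seed, so gross/net comparisons share assignments). Scenarios C/D take
#' the argmax of [potential_rent_matrix()] (net rents for C, gross for
#' D); ties break by crop-set order, deterministically.
#'
#' @param grid a `landscape_grid`.
#' @param scenario a [scenario_spec()] or scenario id.
#' @param econ an `econ_tables`.
#' @param seed integer seed (A/B only).
#' @param prices optional drawn prices for the C/D argmax.
#' @param donor optional donor country for missing prices.
#' @return Character vector: one crop id per cell.
#' @export
assign_crops <- function(grid, scenario, econ, seed = 1L, prices = NULL,
                         donor = NULL) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  crops <- attr(grid, "crop_set")
  if (scenario$crop_source == "national_sample") {
    comp <- attr(grid, "crop_composition")
    out <- character(nrow(grid))
    with_seed(derive_seed(seed, "crop_assignment"), {
      for (cn in sort(unique(grid$country_id))) {
        cc <- comp[comp$country_id == cn, , drop = FALSE]
        if (nrow(cc) == 0L || sum(cc$weight) <= 0) {
          stop("no crops available for country ", cn, call. = FALSE)
        }
        sel <- grid$country_id == cn
        out[sel] <- sample(cc$crop, sum(sel),
          replace = TRUE, prob = cc$weight
        )
      }
    })
    out
  } else {
    R <- potential_rent_matrix(grid, econ, prices,
      deduct = scenario$deduct_costs, donor = donor
    )
    crops[max.col(R, ties.method = "first")]
  }
}

#' Per-cell agricultural rent map
#'
#' Computes the annual net (or gross) rent of each deforested cell under
#' a scenario: `yield * price - costs` for the assigned crop (current
#' yields for A/B, potential yields for C/D; cattle earns carcass
#' revenue), plus the annualized timber windfall. Cells without forest
#' loss carry 0.
#'
#' @param grid a `landscape_grid`.
#' @param scenario a [scenario_spec()] or id.
#' @param econ an `econ_tables`.
#' @param seed seed for the A/B crop draw.
#' @param assignment optional precomputed per-cell crop assignment.
#' @param prices optional drawn prices (`crop`, `country_id`, `price`).
#' @param include_timber add the annualized timber windfall?
#' @param r,horizon annualization parameters for the timber windfall.
#' @param donor optional donor country for missing prices.
#' @return List of class `rent_map`: `ar` (currency/ha/yr per cell) and
#'   `crop` (assignment, `NA` on cells without loss).
#' @export
rent_map <- function(grid, scenario, econ, seed = 1L, assignment = NULL,
                     prices = NULL, include_timber = TRUE, r = 0.05,
                     horizon = 100, donor = NULL) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  if (is.null(assignment)) {
    assignment <- assign_crops(grid, scenario, econ, seed, prices, donor)
  }
  stopifnot(length(assignment) == nrow(grid))
  P <- price_matrix(econ, prices)
  wday <- wage_day_lookup(econ)
  cpc <- econ$country_params
  whour <- stats::setNames(cpc$wage_hour, cpc$country_id)
  fuel <- stats::setNames(cpc$fuel_price, cpc$country_id)
  fertp <- stats::setNames(cpc$fertilizer_price, cpc$country_id)
  ceff <- stats::setNames(cpc$carcass_efficiency, cpc$country_id)
  cpars <- econ$crop_params
  ctry <- as.character(grid$country_id)
  loss <- grid$forest_loss_area > 0
  use_potential <- scenario$crop_source == "max_rent"
  with_transport <- scenario$crop_source == "max_rent"
  tpt <- transport_cost(grid$travel_time, whour[ctry], fuel[ctry])

  ar <- numeric(nrow(grid))
  for (u in unique(assignment[loss])) {
    sel <- loss & assignment == u
    pu <- P[u, ctry[sel]]
    persondays <- cpars$persondays[cpars$crop == u]
    if (u == "cattle") {
      gross <- grid$cattle_stocking[sel] * ceff[ctry[sel]] * pu
      cost <- persondays * wday[ctry[sel]]
    } else {
      ycol <- paste0(if (use_potential) "potyield_" else "yield_", u)
      y <- grid[[ycol]][sel]
      gross <- y * pu
      cost <- persondays * wday[ctry[sel]] +
        grid$fertilizer_usage[sel] * fertp[ctry[sel]]
      if (with_transport && cpars$is_transported[cpars$crop == u]) {
        cost <- cost + tpt[sel] * y
      }
    }
    ar[sel] <- gross - as.numeric(scenario$deduct_costs) * cost
  }
  if (include_timber) {
    timber <- timber_rent(
      cpc$growing_stock, cpc$commercial_fraction, cpc$timber_export_price,
      r, horizon
    )
    names(timber) <- cpc$country_id
    ar[loss] <- ar[loss] + timber[ctry[loss]]
  }
  crop_out <- ifelse(loss, assignment, NA_character_)
  structure(list(ar = ar, crop = crop_out, scenario = scenario$id),
    class = "rent_map"
  )
}
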