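# Net economic impact of deforestation: per-cell integration of the
# externality value (total ecosystem-service value including annualized
# carbon emissions, less the cost of operationalizing its
# internalization) against the agricultural rent gained, scaled by the
# deforested area, and aggregation to country and global totals.

#' Per-hectare cost of internalizing ES values
#'
#' A payment-for-ecosystem-services program incurs transaction and
#' implementation costs (preparation, administration, community support,
#' protected-area management, law enforcement, monitoring), expressed as
#' person-hours per hectare and year and priced at the national wage.
#'
#' @param internalization data frame with `category` and `person_hours`
#'   (h/ha/yr), as in `econ_tables$internalization`.
#' @param wage_h national wage, currency/h (vectorized over countries).
#' @return currency/ha/yr, one value per wage supplied.
#' @export
internalization_cost <- function(internalization, wage_h) {
  if (any(internalization$person_hours < 0)) {
    stop("person-hours must be non-negative", call. = FALSE)
  }
  sum(internalization$person_hours) * wage_h
}

#' Integrate value and rent maps into a net-impact grid
#'
#' Per-cell impact is `(value - internalization - AR) * A`: the
#' externality value of the lost services (per ha/yr), less the per-ha
#' internalization cost, less the agricultural rent gained, times the
#' deforested area of the cell. Cells without loss have zero impact.
#' Positive impact means deforestation destroys more value than it
#' creates. For carbon-only comparisons pass the carbon value map as
#' `value_map` with `internalization = 0` (internalization applies to ES
#' payment programs, not to the carbon market).
#'
#' @param value_map per-cell externality value, currency/ha/yr (TEV
#'   including annualized carbon, or carbon alone).
#' @param ar_map per-cell agricultural rent, currency/ha/yr (or a
#'   `rent_map`).
#' @param grid the `landscape_grid` supplying areas and countries.
#' @param internalization per-cell or per-country-named cost,
#'   currency/ha/yr; default 0.
#' @param loss_area optional override of `grid$forest_loss_area`
#'   (e.g. a perturbed loss map).
#' @return An `impact_grid` data frame: `cell_id`, `country_id`, `area`,
#'   `tev`, `ar`, `impact` (currency/yr).
#' @export
compute_impact <- function(value_map, ar_map, grid, internalization = 0,
                           loss_area = NULL) {
  if (inherits(ar_map, "rent_map")) ar_map <- ar_map$ar
  a <- if (is.null(loss_area)) grid$forest_loss_area else loss_area
  n <- nrow(grid)
  if (length(value_map) != n || length(ar_map) != n || length(a) != n) {
    stop(
      sprintf(
        "geometry mismatch: grid has %d cells, value %d, ar %d, area %d",
        n, length(value_map), length(ar_map), length(a)
      ),
      call. = FALSE
    )
  }
  intern <- if (!is.null(names(internalization))) {
    unname(internalization[as.character(grid$country_id)])
  } else {
    internalization
  }
  net <- value_map - intern - ar_map
  out <- data.frame(
    cell_id = grid$cell_id,
    country_id = grid$country_id,
    area = a,
    tev = value_map - intern,
    ar = ar_map,
    impact = net * a
  )
  class(out) <- c("impact_grid", "data.frame")
  out
}

#' Aggregate a net-impact grid
#'
#' Sums impact (and area-weighted value and rent totals) over cells,
#' countries, or globally. The global total equals the sum of country
#' totals by construction.
#'
#' @param impact an `impact_grid`.
#' @param level `"cell"`, `"country"`, or `"global"`.
#' @return Data frame with `level`, `id`, `impact_total`, `tev_total`,
#'   `ar_total` (the value/rent totals are area-weighted, currency/yr).
#' @export
aggregate_impact <- function(impact, level = c("country", "global", "cell")) {
  level <- match.arg(level)
  if (level == "cell") {
    return(data.frame(
      level = "cell", id = impact$cell_id,
      impact_total = impact$impact,
      tev_total = impact$tev * impact$area,
      ar_total = impact$ar * impact$area
    ))
  }
  grp <- factor(
    if (level == "country") impact$country_id else rep("global", nrow(impact))
  )
  agg <- function(x) as.numeric(tapply(x, grp, sum))
  data.frame(
    level = level,
    id = levels(grp),
    impact_total = agg(impact$impact),
    tev_total = agg(impact$tev * impact$area),
    ar_total = agg(impact$ar * impact$area)
  )
}

#' Cube-root-transformed value-rent contrast
#'
#' `TEV^(1/3) - AR^(1/3)` with a sign-preserving cube root, the
#' transformed contrast used for cross-country comparison of externality
#' value against agricultural rent.
#'
#' @param tev_total externality total (currency/yr).
#' @param ar_total rent total (currency/yr); negative totals are handled
#'   by the signed root.
#' @return Transformed contrast.
#' @export
cube_root_contrast <- function(tev_total, ar_total) {
  signed_cbrt(tev_total) - signed_cbrt(ar_total)
}
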