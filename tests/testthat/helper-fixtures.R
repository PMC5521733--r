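# Shared fixtures: small seeded synthetic worlds, and scalar brute-force
# rent computation kept deliberately independent of the vectorized
# implementation (it re-derives every component from the raw tables).

small_world <- function(seed = 1, nx = 10, ny = 10, n_countries = 3,
                        n_records = 78, ...) {
  cfg <- synth_config(
    grid_nx = nx, grid_ny = ny, n_countries = n_countries,
    n_records = n_records, rng_seed = seed, ...
  )
  grid <- generate_landscape(cfg)
  list(
    cfg = cfg, grid = grid,
    records = generate_valuation_dataset(cfg, grid),
    econ = generate_econ_tables(cfg)
  )
}

# true-model terms of the default generative configuration
true_terms <- function() {
  c("es_class", "method_class", "temperature", "year", "richness_birds")
}

# scalar rent for one cell and one crop, recomputed from first principles
brute_cell_rent <- function(grid, i, crop, scenario_id, econ,
                            prices = NULL, include_timber = TRUE,
                            r = 0.05, horizon = 100) {
  cn <- grid$country_id[i]
  cp <- econ$country_params[econ$country_params$country_id == cn, ]
  wage_day <- if (!is.na(cp$agri_wage_day)) cp$agri_wage_day else cp$manu_wage_day
  price_tab <- if (is.null(prices)) {
    transform(econ$crop_prices, price = price_mean)
  } else {
    prices
  }
  p <- price_tab$price[price_tab$crop == crop & price_tab$country_id == cn]
  persondays <- econ$crop_params$persondays[econ$crop_params$crop == crop]
  transported <- econ$crop_params$is_transported[econ$crop_params$crop == crop]
  deduct <- scenario_id %in% c("A", "C")
  potential <- scenario_id %in% c("C", "D")

  if (crop == "cattle") {
    gross <- grid$cattle_stocking[i] * cp$carcass_efficiency * p
    cost <- persondays * wage_day
  } else {
    y <- grid[[paste0(if (potential) "potyield_" else "yield_", crop)]][i]
    gross <- y * p
    cost <- persondays * wage_day +
      grid$fertilizer_usage[i] * cp$fertilizer_price
    if (potential && transported) {
      dist <- 2 * grid$travel_time[i] * 45
      load <- dist * 0.3 * cp$fuel_price + 2 * grid$travel_time[i] * cp$wage_hour
      cost <- cost + (load / 18) * y
    }
  }
  ar <- gross - if (deduct) cost else 0
  if (include_timber) {
    pv <- cp$growing_stock * cp$commercial_fraction * cp$timber_export_price
    ar <- ar + pv * r / (1 - (1 + r)^(-horizon))
  }
  ar
}

# per-cell total ES value implied by the generative truth (year fixed at
# its expected value, the realized country intercepts included)
true_tev_map <- function(grid, cfg, country_effects,
                         multipliers = c(
                           cultural = 5, provisioning = 5, regulating = 6
                         )) {
  classes <- c("cultural", "provisioning", "regulating")
  methods <- c("cost-based", "stated preference", "revealed preference")
  comp <- sapply(classes, function(cl) {
    logp <- sapply(methods, function(mm) {
      nd <- as.data.frame(grid)
      nd$es_class <- cl
      nd$method_class <- mm
      nd$year <- 2005
      tevtrade:::true_linear_predictor(nd, cfg$true_beta) +
        country_effects[as.character(grid$country_id)]
    })
    exp(rowMeans(logp))
  })
  drop(comp %*% multipliers[classes])
}
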