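# Synthetic landscapes, valuation datasets and economic tables with known
# ground truth. The generator mirrors the structure of the real study
# inputs -- a 0.1-degree pantropical grid, a curated table of
# ecosystem-service valuation observations, and tables of prices, wages
# and cost parameters -- but every quantity is drawn from a configured,
# seeded model so downstream estimates can be checked against truth.

#' Names of the spatial covariates carried by the landscape grid
#'
#' These mirror the covariates used to explain variation in
#' ecosystem-service values: climate, accessibility, population, altitude,
#' GDP, protection status, four taxon richness layers, and carbon density
#' as a forest-type surrogate.
#'
#' @return Character vector of covariate column names.
#' @export
es_covariate_names <- function() {
  c(
    "temperature", "precipitation", "accessibility", "population",
    "altitude", "gdp", "protected", "richness_birds",
    "richness_amphibians", "richness_mammals", "richness_plants",
    "carbon_density"
  )
}

#' Default tropical crop set
#'
#' The 18 major tropical crops (top crops by harvested area and
#' production value in the tropics) plus cattle.
#'
#' @return Character vector of crop identifiers.
#' @export
default_crop_set <- function() {
  c(
    "banana", "bean", "cassava", "cocoa", "coconut", "coffee", "cotton",
    "cowpea", "groundnut", "maize", "millet", "oil_palm", "rice",
    "rubber", "sorghum", "soybean", "sugar_cane", "wheat", "cattle"
  )
}

#' Default ground-truth coefficients of the value-generating model
#'
#' Log ecosystem-service value is generated as
#' `alpha + sum(beta_j x_j) + a_c + eps` with a country random intercept
#' `a_c ~ N(0, sigma_country^2)` and residual `eps ~ N(0, sigma_resid^2)`.
#' Factor effects are dummy contrasts against the baselines
#' (cultural services; cost-based valuation). Signs follow the empirical
#' pattern for tropical-forest valuations: value rises with temperature
#' and falls with publication year and bird richness.
#'
#' @return Named numeric vector including an `"(Intercept)"` entry.
#' @export
default_true_beta <- function() {
  # the intercept offsets the raw-scale covariate contributions at their
  # typical values (year 2005, temperature 25 C, 350 bird species) so
  # that a typical service is worth about exp(4) ~ 55 currency/ha/yr
  c(
    "(Intercept)" = 4.0 + 0.03 * 2005 - 0.08 * 25 + 0.004 * 350,
    "es_classprovisioning" = 0.5,
    "es_classregulating" = 0.8,
    "method_classrevealed preference" = -0.6,
    "method_classstated preference" = 0.9,
    "temperature" = 0.08,
    "year" = -0.03,
    "richness_birds" = -0.004
  )
}

#' Configuration for the synthetic-data generators
#'
#' @param grid_nx,grid_ny cell counts along x and y (each >= 1).
#' @param cell_area hectares per cell.
#' @param n_countries number of countries; countries are contiguous
#'   column strips (or contiguous row-major runs when there are more
#'   countries than columns).
#' @param true_beta named coefficients of the generative log-value model;
#'   see [default_true_beta()].
#' @param sigma_country standard deviation of the country random
#'   intercept on the log scale (>= 0).
#' @param sigma_resid residual standard deviation on the log scale (>= 0).
#' @param n_records number of valuation observations to generate; the
#'   default of 78 matches the size of the reference valuation dataset.
#' @param crop_set crop identifiers; see [default_crop_set()].
#' @param price_cv coefficient of variation of crop prices (sd = mean * cv).
#' @param peat_fraction proportion of cells flagged as peat soil.
#' @param peat_depth_mean,peat_depth_max mean (exponential) and truncation
#'   cap of peat depth in metres.
#' @param dom_carbon dead-organic-matter carbon, tC/ha, added as a
#'   constant layer (IPCC-table style).
#' @param forest_loss_fraction proportion of cells with forest loss.
#' @param collinear_covariate optional list `(source, name, sd)` that adds
#'   a near-duplicate of an existing covariate plus Gaussian noise, to
#'   exercise the collinearity diagnostics.
#' @param rng_seed integer master seed.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(grid_nx = 20L, grid_ny = 20L, cell_area = 10000,
                         n_countries = 3L, true_beta = default_true_beta(),
                         sigma_country = 0.5, sigma_resid = 1.0,
                         n_records = 78L, crop_set = default_crop_set(),
                         price_cv = 0.2, peat_fraction = 0.1,
                         peat_depth_mean = 3, peat_depth_max = 10,
                         dom_carbon = 5,
                         forest_loss_fraction = 0.3,
                         collinear_covariate = NULL, rng_seed = 1L) {
  cfg <- list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    cell_area = cell_area, n_countries = as.integer(n_countries),
    true_beta = true_beta, sigma_country = sigma_country,
    sigma_resid = sigma_resid, n_records = as.integer(n_records),
    crop_set = crop_set, price_cv = price_cv,
    peat_fraction = peat_fraction, peat_depth_mean = peat_depth_mean,
    peat_depth_max = peat_depth_max, dom_carbon = dom_carbon,
    forest_loss_fraction = forest_loss_fraction,
    collinear_covariate = collinear_covariate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$grid_nx < 1L) config_error("grid_nx", "must be >= 1")
  if (cfg$grid_ny < 1L) config_error("grid_ny", "must be >= 1")
  if (cfg$cell_area <= 0) config_error("cell_area", "must be positive")
  n_cells <- cfg$grid_nx * cfg$grid_ny
  if (cfg$n_countries < 1L) config_error("n_countries", "must be >= 1")
  if (cfg$n_countries > n_cells) {
    config_error("n_countries", "must not exceed the grid cell count")
  }
  for (f in c("sigma_country", "sigma_resid", "price_cv", "peat_fraction",
    "forest_loss_fraction", "peat_depth_mean", "peat_depth_max",
    "dom_carbon")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      config_error(f, "must be a non-negative scalar")
    }
  }
  for (f in c("peat_fraction", "forest_loss_fraction")) {
    if (cfg[[f]] > 1) config_error(f, "must be <= 1")
  }
  if (cfg$n_records < 1L) config_error("n_records", "must be >= 1")
  if (length(cfg$crop_set) < 1L) config_error("crop_set", "must be non-empty")
  if (is.null(names(cfg$true_beta)) ||
    !("(Intercept)" %in% names(cfg$true_beta))) {
    config_error("true_beta", "must be named and include '(Intercept)'")
  }
  invisible(cfg)
}

# uniform sampling ranges of the spatial covariates (units in docs)
covariate_ranges <- function() {
  list(
    temperature = c(20, 30), # degrees C
    precipitation = c(1000, 3500), # mm/yr
    accessibility = c(0.5, 20), # h to nearest city
    population = c(1, 500), # habitants/km2
    altitude = c(0, 1500), # m
    gdp = c(500, 20000), # per-capita, currency
    richness_birds = c(100, 600),
    richness_amphibians = c(10, 150),
    richness_mammals = c(20, 200),
    richness_plants = c(500, 5000),
    carbon_density = c(50, 250) # tC/ha
  )
}

# plausible farm-gate base prices (currency/t) and labour inputs
crop_base_params <- function(crop_set) {
  base <- c(
    banana = 300, bean = 600, cassava = 120, cocoa = 2300, coconut = 250,
    coffee = 2000, cotton = 1400, cowpea = 500, groundnut = 900,
    maize = 180, millet = 300, oil_palm = 130, rice = 260, rubber = 1600,
    sorghum = 220, soybean = 350, sugar_cane = 35, wheat = 200,
    cattle = 2500
  )
  days <- c(
    banana = 120, bean = 60, cassava = 80, cocoa = 150, coconut = 50,
    coffee = 180, cotton = 110, cowpea = 55, groundnut = 90, maize = 60,
    millet = 50, oil_palm = 100, rice = 130, rubber = 140, sorghum = 50,
    soybean = 45, sugar_cane = 140, wheat = 40, cattle = 20
  )
  yld <- list( # current-yield uniform range, t/ha/yr
    banana = c(5, 25), bean = c(0.4, 1.5), cassava = c(5, 20),
    cocoa = c(0.2, 0.8), coconut = c(2, 8), coffee = c(0.3, 1.2),
    cotton = c(0.5, 2), cowpea = c(0.2, 1), groundnut = c(0.5, 2),
    maize = c(1, 5), millet = c(0.4, 1.5), oil_palm = c(8, 22),
    rice = c(1.5, 5), rubber = c(0.5, 1.8), sorghum = c(0.5, 2),
    soybean = c(1, 3.5), sugar_cane = c(30, 90), wheat = c(1, 4),
    cattle = c(NA, NA)
  )
  unknown <- setdiff(crop_set, names(base))
  if (length(unknown)) {
    base[unknown] <- 500
    days[unknown] <- 80
    for (u in unknown) yld[[u]] <- c(0.5, 3)
  }
  list(price = base[crop_set], persondays = days[crop_set], yield_range = yld[crop_set])
}

#' Generate a synthetic landscape grid
#'
#' Produces a per-cell table of biophysical and economic state: country
#' membership (contiguous blocks), forest-loss area, carbon pools, peat,
#' spatial covariates, per-crop current and potential yields, pasture
#' fraction, cattle stocking, travel time and fertilizer usage. Cell ids
#' are 0-based, row-major from the north-west corner.
#'
#' @param config a [synth_config()].
#' @return A `landscape_grid` data frame (one row per cell) with
#'   attributes `nx`, `ny`, `cell_area`, `crop_set` and
#'   `crop_composition` (per-country area-weighted crop shares used by
#'   the national-sampling scenarios).
#' @export
generate_landscape <- function(config) {
  validate_synth_config(config)
  with_seed(derive_seed(config$rng_seed, "landscape"), {
    nx <- config$grid_nx
    ny <- config$grid_ny
    n <- nx * ny
    cell_id <- seq_len(n) - 1L
    row <- cell_id %/% nx
    col <- cell_id %% nx
    if (nx >= config$n_countries) {
      country_id <- as.integer(col * config$n_countries / nx) + 1L
    } else {
      country_id <- as.integer(cell_id * config$n_countries / n) + 1L
    }

    loss_flag <- stats::rbinom(n, 1L, config$forest_loss_fraction)
    forest_loss_area <- loss_flag *
      stats::runif(n, 0.02, 0.20) * config$cell_area

    agb <- stats::runif(n, 80, 200)
    bgb <- agb * stats::runif(n, 0.18, 0.25)
    dom <- rep(config$dom_carbon, n)
    peat_flag <- stats::rbinom(n, 1L, config$peat_fraction)
    peat_depth <- peat_flag *
      pmin(stats::rexp(n, 1 / max(config$peat_depth_mean, 1e-12)),
        config$peat_depth_max)

    grid <- data.frame(
      cell_id = cell_id, row = row, col = col,
      x = col + 0.5, y = row + 0.5,
      country_id = country_id,
      forest_loss_area = forest_loss_area,
      agb_carbon = agb, bgb_carbon = bgb, dom_carbon = dom,
      peat_depth = peat_depth
    )
    for (v in names(covariate_ranges())) {
      rg <- covariate_ranges()[[v]]
      grid[[v]] <- stats::runif(n, rg[1], rg[2])
    }
    grid$protected <- stats::rbinom(n, 1L, 0.2)
    if (!is.null(config$collinear_covariate)) {
      cc <- config$collinear_covariate
      grid[[cc$name]] <- grid[[cc$source]] +
        stats::rnorm(n, 0, cc$sd)
    }

    bp <- crop_base_params(config$crop_set)
    for (u in setdiff(config$crop_set, "cattle")) {
      rg <- bp$yield_range[[u]]
      cur <- stats::runif(n, rg[1], rg[2])
      grid[[paste0("yield_", u)]] <- cur
      grid[[paste0("potyield_", u)]] <- cur * stats::runif(n, 1.2, 2.5)
    }
    grid$pasture_fraction <- stats::runif(n, 0, 0.5)
    grid$cattle_stocking <- stats::runif(n, 0.3, 2) # head/ha
    grid$travel_time <- stats::runif(n, 0.5, 20) # h, one-way
    grid$fertilizer_usage <- stats::runif(n, 0, 300) # kg/ha/yr

    # national crop composition: Dirichlet area shares, cattle share tied
    # to the country's mean pasture fraction
    comp <- do.call(rbind, lapply(seq_len(config$n_countries), function(cn) {
      w <- stats::rgamma(length(config$crop_set), shape = 2)
      w <- w / sum(w)
      if ("cattle" %in% config$crop_set) {
        pf <- mean(grid$pasture_fraction[grid$country_id == cn])
        w[config$crop_set == "cattle"] <- pf
        w <- w / sum(w)
      }
      data.frame(
        country_id = cn, crop = config$crop_set, weight = w,
        stringsAsFactors = FALSE
      )
    }))

    attr(grid, "nx") <- nx
    attr(grid, "ny") <- ny
    attr(grid, "cell_area") <- config$cell_area
    attr(grid, "crop_set") <- config$crop_set
    attr(grid, "crop_composition") <- comp
    class(grid) <- c("landscape_grid", "data.frame")
    validate_landscape(grid)
    grid
  })
}

validate_landscape <- function(grid) {
  stopifnot(inherits(grid, "data.frame"))
  ca <- attr(grid, "cell_area")
  if (any(grid$forest_loss_area < 0) || any(grid$forest_loss_area > ca)) {
    stop("forest_loss_area must lie in [0, cell_area]", call. = FALSE)
  }
  stocks <- c("agb_carbon", "bgb_carbon", "dom_carbon", "peat_depth")
  for (s in stocks) {
    if (any(grid[[s]] < 0)) stop(s, " must be non-negative", call. = FALSE)
  }
  if (anyNA(grid$country_id)) stop("every cell needs a country_id", call. = FALSE)
  invisible(grid)
}

# evaluate the generative linear predictor for a record table
true_linear_predictor <- function(df, true_beta) {
  eta <- rep(true_beta[["(Intercept)"]], nrow(df))
  dummies <- list(
    "es_classprovisioning" = df$es_class == "provisioning",
    "es_classregulating" = df$es_class == "regulating",
    "method_classrevealed preference" = df$method_class == "revealed preference",
    "method_classstated preference" = df$method_class == "stated preference"
  )
  for (nm in setdiff(names(true_beta), "(Intercept)")) {
    if (nm %in% names(dummies)) {
      eta <- eta + true_beta[[nm]] * as.numeric(dummies[[nm]])
    } else if (nm %in% names(df)) {
      eta <- eta + true_beta[[nm]] * df[[nm]]
    } else {
      stop("true_beta names unknown term: ", nm, call. = FALSE)
    }
  }
  eta
}

#' Generate a synthetic valuation dataset from a landscape
#'
#' Each record is an ecosystem-service valuation observation located on a
#' grid cell, with an ES class (cultural / provisioning / regulating), a
#' valuation-method class (cost-based / stated preference / revealed
#' preference), publication year, valued forest area, and the cell's
#' spatial covariates. Log values follow the configured generative model
#' `alpha + sum(beta_j x_j) + a_c + eps`.
#'
#' @param config a [synth_config()].
#' @param grid a [generate_landscape()] grid.
#' @return A `valuation_records` data frame with attribute `truth`, a
#'   list holding the generative `beta`, the realized per-country random
#'   intercepts `country_effects`, the noise-free linear predictor `eta`,
#'   and the configured standard deviations -- the oracle for recovery
#'   tests.
#' @export
generate_valuation_dataset <- function(config, grid) {
  validate_synth_config(config)
  if (config$n_records < config$n_countries) {
    warning(
      "fewer records than countries: some countries will lack records ",
      "and be predicted from fixed effects only",
      call. = FALSE
    )
  }
  with_seed(derive_seed(config$rng_seed, "records"), {
    n <- config$n_records
    idx <- sample.int(nrow(grid), n, replace = TRUE)
    rec <- data.frame(
      record_id = seq_len(n),
      cell_id = grid$cell_id[idx],
      x = grid$x[idx], y = grid$y[idx],
      country = grid$country_id[idx],
      es_class = sample(c("cultural", "provisioning", "regulating"), n,
        replace = TRUE
      ),
      method_class = sample(
        c("cost-based", "stated preference", "revealed preference"), n,
        replace = TRUE
      ),
      peer_reviewed = stats::rbinom(n, 1L, 0.7),
      year = sample(1994:2016, n, replace = TRUE),
      forest_area = stats::rlnorm(n, log(1000), 1),
      stringsAsFactors = FALSE
    )
    covs <- intersect(
      c(es_covariate_names(),
        if (!is.null(config$collinear_covariate)) config$collinear_covariate$name),
      names(grid)
    )
    for (v in covs) rec[[v]] <- grid[[v]][idx]

    a_c <- stats::rnorm(config$n_countries, 0, config$sigma_country)
    names(a_c) <- as.character(seq_len(config$n_countries))
    eps <- stats::rnorm(n, 0, config$sigma_resid)
    eta <- true_linear_predictor(rec, config$true_beta)
    rec$log_value <- eta + a_c[as.character(rec$country)] + eps
    rec$value <- exp(rec$log_value)

    attr(rec, "truth") <- list(
      beta = config$true_beta, country_effects = a_c, eta = eta,
      sigma_country = config$sigma_country, sigma_resid = config$sigma_resid
    )
    class(rec) <- c("valuation_records", "data.frame")
    rec
  })
}

#' Generate synthetic economic parameter tables
#'
#' Emulates the economic input tables: farm-gate price mean and sd per
#' crop-country pair, labour requirements per crop, national wages, fuel,
#' fertilizer and timber parameters, cattle carcass efficiency, a daily
#' market carbon-price series centred on 13.6 currency/t, a pool of
#' social-cost-of-carbon draws with mean 30 currency/t (five scenario
#' strata of 1,000 draws each), and internalization person-hours per
#' cost category.
#'
#' @param config a [synth_config()].
#' @return An `econ_tables` list with elements `crop_prices`,
#'   `crop_params`, `country_params`, `carbon_market_series`, `scc_pool`
#'   and `internalization`.
#' @export
generate_econ_tables <- function(config) {
  validate_synth_config(config)
  if (length(config$crop_set) < 1L) config_error("crop_set", "must be non-empty")
  with_seed(derive_seed(config$rng_seed, "econ"), {
    crops <- config$crop_set
    nc <- config$n_countries
    bp <- crop_base_params(crops)

    cp <- expand.grid(
      crop = crops, country_id = seq_len(nc),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    cp$price_mean <- bp$price[cp$crop] * stats::runif(nrow(cp), 0.8, 1.2)
    cp$price_sd <- cp$price_mean * config$price_cv

    crop_params <- data.frame(
      crop = crops,
      persondays = bp$persondays[crops],
      is_transported = TRUE,
      stringsAsFactors = FALSE
    )

    agri_wage_day <- stats::runif(nc, 2, 15)
    country_params <- data.frame(
      country_id = seq_len(nc),
      agri_wage_day = agri_wage_day,
      manu_wage_day = agri_wage_day * 1.3,
      wage_hour = agri_wage_day / 8,
      fuel_price = stats::runif(nc, 0.5, 1.5), # currency/L
      fertilizer_price = stats::runif(nc, 0.3, 1.0), # currency/kg
      growing_stock = stats::runif(nc, 100, 300), # m3/ha
      commercial_fraction = stats::runif(nc, 0.1, 0.4),
      timber_export_price = stats::runif(nc, 30, 80), # currency/m3
      carcass_efficiency = stats::runif(nc, 0.15, 0.30) # t/head
    )

    n_days <- 1300L
    market <- data.frame(
      day = seq_len(n_days),
      price = pmax(stats::rnorm(n_days, 13.6, 2), 0.1)
    )
    scc_means <- c(15, 22, 30, 38, 45) # five scenario strata, mean 30
    scc_pool <- unlist(lapply(scc_means, function(m) {
      pmax(stats::rnorm(1000L, m, 0.2 * m), 0.1)
    }))

    internalization <- data.frame(
      category = c(
        "preparation", "administration", "community_support",
        "pa_management", "law_enforcement", "monitoring"
      ),
      person_hours = c(0.5, 0.8, 1.0, 1.2, 0.8, 0.7) # h/ha/yr
    )

    econ <- list(
      crop_prices = cp, crop_params = crop_params,
      country_params = country_params,
      carbon_market_series = market, scc_pool = scc_pool,
      internalization = internalization
    )
    class(econ) <- "econ_tables"
    econ
  })
}

#' Default carbon price model
#'
#' Market and social reference prices with the pricing basis, discount
#' rate and horizon used to annualize the one-off emission value. The
#' basis is an explicit switch because allowance prices are convention-
#' dependent: `per_tCO2` treats the quoted price as per tonne of CO2e,
#' `per_tC` as per tonne of carbon (converted by 12/44).
#'
#' @param price_basis `"per_tCO2"` (default) or `"per_tC"`.
#' @param discount_rate annual discount rate (default 0.05).
#' @param horizon years over which the one-off emission value is
#'   annualized (default 100).
#' @param peat_c_per_m carbon density of peat, tC/ha per metre of depth.
#' @return A `carbon_price_model` list.
#' @export
carbon_price_model <- function(price_basis = c("per_tCO2", "per_tC"),
                               discount_rate = 0.05, horizon = 100,
                               peat_c_per_m = 500) {
  price_basis <- match.arg(price_basis)
  if (discount_rate < 0 || discount_rate >= 1) {
    config_error("discount_rate", "must lie in [0, 1)")
  }
  if (horizon < 1) config_error("horizon", "must be >= 1")
  structure(
    list(
      price_basis = price_basis, discount_rate = discount_rate,
      horizon = horizon, peat_c_per_m = peat_c_per_m
    ),
    class = "carbon_price_model"
  )
}
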