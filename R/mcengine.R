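# Joint Monte Carlo propagation of every uncertainty source: bootstrap
# spread of the ES meta-model, classification error of the forest-loss
# map, market and social carbon-price variability, crop-price
# variability, and the stochastic crop assignment of the
# national-sampling scenarios. One master seed spawns an independent
# stream per source and replicate, so switching one source off leaves
# every other draw unchanged.

#' Uncertainty-propagation specification
#'
#' @param n_reps number of Monte Carlo replicates (reference default 200).
#' @param loss_accuracy probability that a loss cell is retained as loss
#'   (classification accuracy of loss, default 0.87).
#' @param noloss_accuracy probability that a no-loss cell stays no-loss
#'   (default 0.997).
#' @param sources named logical flags activating each source:
#'   `carbon_market`, `carbon_social`, `crop_prices`, `es_bootstrap`,
#'   `crop_assignment`, `forest_loss`.
#' @param seed master seed.
#' @return An `uncertainty_spec` list.
#' @export
uncertainty_spec <- function(n_reps = 200L, loss_accuracy = 0.87,
                             noloss_accuracy = 0.997,
                             sources = c(
                               carbon_market = TRUE, carbon_social = TRUE,
                               crop_prices = TRUE, es_bootstrap = TRUE,
                               crop_assignment = TRUE, forest_loss = TRUE
                             ),
                             seed = 1L) {
  if (n_reps < 1L) config_error("n_reps", "must be >= 1")
  for (f in c("loss_accuracy", "noloss_accuracy")) {
    v <- get(f)
    if (v < 0 || v > 1) config_error(f, "must lie in [0, 1]")
  }
  defaults <- c(
    carbon_market = TRUE, carbon_social = TRUE, crop_prices = TRUE,
    es_bootstrap = TRUE, crop_assignment = TRUE, forest_loss = TRUE
  )
  defaults[names(sources)] <- sources
  structure(
    list(
      n_reps = as.integer(n_reps), loss_accuracy = loss_accuracy,
      noloss_accuracy = noloss_accuracy, sources = defaults,
      seed = as.integer(seed)
    ),
    class = "uncertainty_spec"
  )
}

#' Perturb a forest-loss map to emulate classification error
#'
#' Each loss cell remains loss with probability `loss_accuracy`
#' (otherwise its loss area is zeroed); each no-loss cell remains
#' no-loss with probability `noloss_accuracy` (otherwise it is assigned
#' the national mean loss area among the country's loss cells, falling
#' back to the global mean where a country has none).
#'
#' @param grid a `landscape_grid`.
#' @param spec an [uncertainty_spec()].
#' @param seed integer seed for this draw.
#' @return Perturbed per-cell loss area, ha.
#' @export
perturb_loss_map <- function(grid, spec, seed = 1L) {
  loss <- grid$forest_loss_area
  is_loss <- loss > 0
  mean_by_country <- tapply(loss[is_loss], grid$country_id[is_loss], mean)
  global_mean <- if (any(is_loss)) mean(loss[is_loss]) else 0
  with_seed(derive_seed(seed, "loss_perturb"), {
    out <- loss
    keep <- stats::runif(length(loss)) < spec$loss_accuracy
    out[is_loss & !keep] <- 0
    flip <- stats::runif(length(loss)) >= spec$noloss_accuracy
    add <- !is_loss & flip
    if (any(add)) {
      m <- as.numeric(mean_by_country[as.character(grid$country_id[add])])
      m[is.na(m)] <- global_mean
      out[add] <- m
    }
    out
  })
}

#' Draw one set of prices from their uncertainty distributions
#'
#' The market carbon price is a uniform draw from the daily price
#' series; the social price a uniform draw from the pool of
#' social-cost-of-carbon values; each crop-country price an independent
#' normal draw (mean, sd from the tables) clamped at zero. Inactive
#' sources return the series/pool/table means. Each source uses its own
#' derived seed, so ablating one leaves the others' draws unchanged.
#'
#' @param econ an `econ_tables`.
#' @param spec an [uncertainty_spec()].
#' @param seed integer seed for this replicate.
#' @return List with `carbon_market`, `carbon_social` (currency/t) and
#'   `crop_prices` (`crop`, `country_id`, `price`).
#' @export
sample_prices <- function(econ, spec, seed = 1L) {
  draw_one <- function(x) x[sample.int(length(x), 1L)]
  cm <- if (spec$sources[["carbon_market"]]) {
    with_seed(
      derive_seed(seed, "carbon_market"),
      draw_one(econ$carbon_market_series$price)
    )
  } else {
    mean(econ$carbon_market_series$price)
  }
  cs <- if (spec$sources[["carbon_social"]]) {
    with_seed(derive_seed(seed, "carbon_social"), draw_one(econ$scc_pool))
  } else {
    mean(econ$scc_pool)
  }
  cp <- econ$crop_prices
  price <- if (spec$sources[["crop_prices"]]) {
    with_seed(
      derive_seed(seed, "crop_prices"),
      pmax(stats::rnorm(nrow(cp), cp$price_mean, cp$price_sd), 0)
    )
  } else {
    cp$price_mean
  }
  list(
    carbon_market = cm, carbon_social = cs,
    crop_prices = data.frame(
      crop = cp$crop, country_id = cp$country_id, price = price,
      stringsAsFactors = FALSE
    )
  )
}

#' Run the joint Monte Carlo uncertainty propagation
#'
#' Per replicate: pick one bootstrap TEV map at random, perturb the
#' forest-loss map, draw carbon and crop prices, redraw the crop
#' assignment (national-sampling scenarios), recompute the rent map and
#' the net-impact grid, and aggregate. Collects the per-cell impact
#' matrix and per-replicate aggregate tables.
#'
#' @param grid a `landscape_grid`.
#' @param es an `es_map_ensemble` from [bootstrap_es_maps()] (its point
#'   map is used whenever the `es_bootstrap` source is off).
#' @param econ an `econ_tables`.
#' @param scenario a [scenario_spec()] or id.
#' @param spec an [uncertainty_spec()].
#' @param carbon a [carbon_price_model()].
#' @param carbon_price_type `"market"` or `"social"`.
#' @param internalize deduct internalization costs from the ES value?
#' @param carbon_only compare carbon value alone against rents (no ES
#'   value, no internalization)?
#' @param include_timber add the annualized timber windfall to rents?
#' @return An `outcome_ensemble`: `impact` (cells x M matrix),
#'   `aggregates` (per-replicate country and global totals), the
#'   uncertainty spec
#'   and the failure count. Aborts if more than 10% of replicates fail.
#' @export
run_monte_carlo <- function(grid, es, econ, scenario, spec,
                            carbon = carbon_price_model(),
                            carbon_price_type = c("market", "social"),
                            internalize = TRUE, carbon_only = FALSE,
                            include_timber = TRUE) {
  carbon_price_type <- match.arg(carbon_price_type)
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  stopifnot(inherits(es, "es_map_ensemble"))
  M <- spec$n_reps
  n <- nrow(grid)
  cpc <- econ$country_params
  intern <- if (internalize && !carbon_only) {
    stats::setNames(
      internalization_cost(econ$internalization, cpc$wage_hour),
      cpc$country_id
    )
  } else {
    0
  }
  fixed_assignment <- assign_crops(
    grid, scenario, econ,
    seed = derive_seed(spec$seed, "fixed_assignment")
  )
  impact_mat <- matrix(NA_real_, n, M)
  agg_list <- vector("list", M)
  failures <- 0L
  for (r in seq_len(M)) {
    rep_seed <- derive_seed(spec$seed, "mc_rep", r)
    res <- tryCatch(
      {
        tev_es <- if (spec$sources[["es_bootstrap"]]) {
          b <- with_seed(
            derive_seed(rep_seed, "es_pick"),
            sample.int(es$B, 1L)
          )
          es$maps[, b]
        } else {
          es$point_map
        }
        loss <- if (spec$sources[["forest_loss"]]) {
          perturb_loss_map(grid, spec, seed = derive_seed(rep_seed, "loss"))
        } else {
          grid$forest_loss_area
        }
        pr <- sample_prices(econ, spec, seed = rep_seed)
        cprice <- if (carbon_price_type == "market") {
          pr$carbon_market
        } else {
          pr$carbon_social
        }
        cval <- carbon_value_map(grid, cprice, carbon)
        assignment <- if (
          scenario$crop_source == "national_sample" &&
            spec$sources[["crop_assignment"]]
        ) {
          assign_crops(grid, scenario, econ,
            seed = derive_seed(rep_seed, "crops")
          )
        } else {
          fixed_assignment
        }
        rents <- rent_map(grid, scenario, econ,
          assignment = assignment, prices = pr$crop_prices,
          include_timber = include_timber,
          r = carbon$discount_rate, horizon = carbon$horizon
        )
        value_map <- if (carbon_only) cval else tev_es + cval
        impact <- compute_impact(value_map, rents, grid,
          internalization = intern, loss_area = loss
        )
        list(
          impact = impact$impact,
          agg = rbind(
            aggregate_impact(impact, "country"),
            aggregate_impact(impact, "global")
          )
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > 0.1 * M) {
        stop(
          "more than 10% of Monte Carlo replicates failed; last error: ",
          conditionMessage(res),
          call. = FALSE
        )
      }
    } else {
      impact_mat[, r] <- res$impact
      res$agg$rep <- r
      agg_list[[r]] <- res$agg
    }
  }
  ok <- !vapply(agg_list, is.null, logical(1))
  structure(
    list(
      impact = impact_mat[, ok, drop = FALSE],
      aggregates = do.call(rbind, agg_list[ok]),
      M = sum(ok), failures = failures,
      spec = spec, scenario = scenario$id,
      carbon_price_type = carbon_price_type
    ),
    class = "outcome_ensemble"
  )
}

#' Reduce a Monte Carlo ensemble to percentile maps and tables
#'
#' Empirical percentiles (linear-interpolation definition, R quantile
#' type 7) per cell and per aggregate.
#'
#' @param ensemble an `outcome_ensemble`.
#' @param probs percentiles in percent (default 2.5, 50, 97.5).
#' @return List with `cell` (cells x percentile matrix) and `aggregate`
#'   (long table: level, id, percentile, impact).
#' @export
reduce_percentiles <- function(ensemble, probs = c(2.5, 50, 97.5)) {
  p <- probs / 100
  cellq <- t(apply(ensemble$impact, 1, stats::quantile, probs = p, type = 7))
  colnames(cellq) <- paste0("p", probs)
  agg <- ensemble$aggregates
  key <- paste(agg$level, agg$id, sep = ":")
  rows <- lapply(unique(key), function(k) {
    sub <- agg[key == k, , drop = FALSE]
    q <- stats::quantile(sub$impact_total, probs = p, type = 7)
    data.frame(
      level = sub$level[1], id = sub$id[1],
      percentile = probs, impact = as.numeric(q)
    )
  })
  list(cell = cellq, aggregate = do.call(rbind, rows))
}
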