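no_sources <- c(
  carbon_market = FALSE, carbon_social = FALSE, crop_prices = FALSE,
  es_bootstrap = FALSE, crop_assignment = FALSE, forest_loss = FALSE
)

# a tiny ES ensemble around a fixed point map, cheap to build
tiny_es <- function(w, B = 4, seed = 1) {
  top <- select_top(enumerate_models(w$records, c("temperature", "year")))
  bootstrap_es_maps(w$records, w$grid,
    B = B, seed = seed, top_set = top
  )
}

test_that("uncertainty specs validate their fields", {
  expect_error(uncertainty_spec(n_reps = 0), "n_reps")
  expect_error(uncertainty_spec(loss_accuracy = 1.2), "loss_accuracy")
  s <- uncertainty_spec(sources = c(crop_prices = FALSE))
  expect_false(s$sources[["crop_prices"]])
  expect_true(s$sources[["carbon_market"]])
})

test_that("loss-map perturbation honours the accuracy probabilities", {
  w <- small_world(seed = 41, nx = 100, ny = 100, forest_loss_fraction = 1)
  g <- w$grid
  spec_id <- uncertainty_spec(loss_accuracy = 1, noloss_accuracy = 1)
  expect_identical(perturb_loss_map(g, spec_id, seed = 1), g$forest_loss_area)

  spec_rm <- uncertainty_spec(loss_accuracy = 0, noloss_accuracy = 1)
  expect_true(all(perturb_loss_map(g, spec_rm, seed = 1) == 0))

  spec <- uncertainty_spec(loss_accuracy = 0.87, noloss_accuracy = 0.997)
  pert <- perturb_loss_map(g, spec, seed = 2)
  retained <- sum(pert > 0 & g$forest_loss_area > 0)
  sd3 <- 3 * sqrt(10000 * 0.87 * 0.13)
  expect_gt(retained, 8700 - sd3)
  expect_lt(retained, 8700 + sd3)
})

test_that("flipped no-loss cells receive the national mean loss area", {
  w <- small_world(seed = 42, nx = 20, ny = 20, forest_loss_fraction = 0.3)
  g <- w$grid
  spec <- uncertainty_spec(loss_accuracy = 1, noloss_accuracy = 0)
  pert <- perturb_loss_map(g, spec, seed = 3)
  was_noloss <- g$forest_loss_area == 0
  means <- tapply(
    g$forest_loss_area[!was_noloss], g$country_id[!was_noloss], mean
  )
  expect_equal(
    pert[was_noloss],
    as.numeric(means[as.character(g$country_id[was_noloss])])
  )
})

test_that("price draws honour their distributions and ablation", {
  w <- small_world(seed = 43, nx = 4, ny = 4)
  econ <- w$econ
  econ$carbon_market_series <- data.frame(day = 1, price = 42)
  spec <- uncertainty_spec(seed = 1)
  expect_equal(sample_prices(econ, spec, seed = 5)$carbon_market, 42)

  econ0 <- w$econ
  econ0$crop_prices$price_sd <- 0
  pr0 <- sample_prices(econ0, spec, seed = 6)
  expect_equal(pr0$crop_prices$price, econ0$crop_prices$price_mean)

  # ablation returns the means and leaves other sources' draws unchanged
  off <- uncertainty_spec(sources = c(crop_prices = FALSE))
  pr_off <- sample_prices(w$econ, off, seed = 7)
  expect_equal(pr_off$crop_prices$price, w$econ$crop_prices$price_mean)
  pr_on <- sample_prices(w$econ, spec, seed = 7)
  expect_identical(pr_on$carbon_market, pr_off$carbon_market)
  expect_identical(pr_on$carbon_social, pr_off$carbon_social)

  # 10,000 normal draws: sample mean within 3 standard errors
  econ_big <- w$econ
  econ_big$crop_prices <- data.frame(
    crop = "maize", country_id = seq_len(10000),
    price_mean = 100, price_sd = 10
  )
  draws <- sample_prices(econ_big, spec, seed = 8)$crop_prices$price
  expect_lt(abs(mean(draws) - 100), 3 * 10 / sqrt(10000))
})

test_that("degenerate specs collapse the ensemble to the point estimate", {
  w <- small_world(seed = 44, nx = 5, ny = 5)
  es <- tiny_es(w)
  spec <- uncertainty_spec(
    n_reps = 6, loss_accuracy = 1, noloss_accuracy = 1,
    sources = no_sources, seed = 9
  )
  ens <- run_monte_carlo(w$grid, es, w$econ, "C", spec)
  expect_identical(ens$M, 6L)
  expect_true(all(apply(ens$impact, 1, stats::var) == 0))
  pct <- reduce_percentiles(ens)
  expect_identical(unname(pct$cell[, "p2.5"]), ens$impact[, 1])
  expect_identical(unname(pct$cell[, "p97.5"]), ens$impact[, 1])
})

test_that("ensembles are bit-identical under a repeated seed", {
  w <- small_world(seed = 45, nx = 5, ny = 5)
  es <- tiny_es(w)
  spec <- uncertainty_spec(n_reps = 5, seed = 77)
  e1 <- run_monte_carlo(w$grid, es, w$econ, "A", spec)
  e2 <- run_monte_carlo(w$grid, es, w$econ, "A", spec)
  expect_identical(e1$impact, e2$impact)
  expect_identical(e1$aggregates, e2$aggregates)
})

test_that("adding an uncertainty source does not reduce ensemble variance", {
  deltas <- numeric(20)
  for (s in 1:20) {
    w <- small_world(seed = 400 + s, nx = 5, ny = 5)
    es <- tiny_es(w, seed = s)
    base_sources <- c(
      carbon_market = TRUE, carbon_social = FALSE, crop_prices = FALSE,
      es_bootstrap = FALSE, crop_assignment = FALSE, forest_loss = FALSE
    )
    spec1 <- uncertainty_spec(n_reps = 15, sources = base_sources, seed = s)
    spec2 <- uncertainty_spec(
      n_reps = 15,
      sources = replace(base_sources, "crop_prices", TRUE), seed = s
    )
    v1 <- mean(apply(run_monte_carlo(w$grid, es, w$econ, "A", spec1)$impact, 1, stats::var))
    v2 <- mean(apply(run_monte_carlo(w$grid, es, w$econ, "A", spec2)$impact, 1, stats::var))
    deltas[s] <- v2 - v1
  }
  expect_gt(mean(deltas), 0)
})

test_that("percentile reduction matches analytic quantiles and is monotone", {
  fake <- structure(
    list(
      impact = matrix(stats::runif(3 * 10000), nrow = 3),
      aggregates = data.frame(
        level = "global", id = "global",
        impact_total = stats::runif(10000), tev_total = 0, ar_total = 0,
        rep = 1:10000
      ),
      M = 10000L
    ),
    class = "outcome_ensemble"
  )
  pct <- reduce_percentiles(fake)
  expect_lt(max(abs(pct$cell[, "p2.5"] - 0.025)), 0.01)
  expect_lt(max(abs(pct$cell[, "p50"] - 0.5)), 0.02)
  expect_true(all(pct$cell[, "p2.5"] <= pct$cell[, "p50"]))
  expect_true(all(pct$cell[, "p50"] <= pct$cell[, "p97.5"]))
  agg <- pct$aggregate
  expect_lt(abs(agg$impact[agg$percentile == 2.5] - 0.025), 0.01)
})
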