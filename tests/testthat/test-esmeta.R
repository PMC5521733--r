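# helpers to build hand-specified models for averaging arithmetic
fake_model <- function(intercept, beta = numeric(), terms = character()) {
  structure(
    list(
      terms = terms, fixef = c("(Intercept)" = intercept, beta),
      fixef_se = NULL, alpha = intercept, beta = beta,
      sigma_country = 0, sigma_resid = 1,
      country_effects = stats::setNames(numeric(0), character(0)),
      loglik = 0, k = 2, n = 10, aicc = 0,
      train_means = c(year = NA_real_, forest_area = NA_real_),
      one_country = FALSE, singular = FALSE
    ),
    class = "es_model"
  )
}

fake_set <- function(models, weights) {
  structure(
    list(
      models = models, terms_list = lapply(models, `[[`, "terms"),
      aicc = vapply(models, `[[`, numeric(1), "aicc"),
      delta_aicc = rep(0, length(models)), akaike_weight = weights,
      top_mask = rep(TRUE, length(models)), failed = list(),
      cutoff = NA_real_, n_candidates = NA_integer_
    ),
    class = "es_model_set"
  )
}

test_that("screening drops flagged records and annualizes NPVs", {
  raw <- data.frame(
    value = c(10, 20, 30, 40, NA),
    benefit_transfer = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    has_location = TRUE, has_es_type = TRUE, has_method = TRUE,
    is_npv = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    npv = c(NA, NA, NA, NA, 1000),
    discount_rate = c(NA, NA, NA, NA, 0.05),
    horizon = c(NA, NA, NA, NA, 100),
    es_class = "cultural", method_class = "cost-based", country = 1
  )
  out <- screen_records(raw)
  expect_identical(nrow(out), 4L)
  expect_identical(attr(out, "screening_report")[["benefit_transfer"]], 1L)
  # the NPV record is converted to its equivalent annual flow
  expect_equal(out$value[out$is_npv], 1000 * 0.05 / (1 - 1.05^-100),
    tolerance = 1e-12
  )
  expect_equal(out$log_value, log(out$value))

  # disabling every rule is the identity on the record set
  none <- stats::setNames(
    rep(FALSE, 5),
    c("benefit_transfer", "has_location", "has_es_type", "has_method",
      "npv_needs_rate")
  )
  raw2 <- raw[1:4, ]
  expect_identical(nrow(screen_records(raw2, none)), 4L)

  all_bt <- transform(raw[1:4, ], benefit_transfer = TRUE)
  expect_error(screen_records(all_bt), "no records survive")
})

test_that("AICc matches hand arithmetic and its limits", {
  expect_equal(aicc(-20, 3, 10), 50)
  expect_lt(abs(aicc(-20, 3, 1e9) - (-2 * -20 + 6)), 1e-6)
  # equal likelihoods: fewer parameters wins
  expect_lt(aicc(-20, 3, 78), aicc(-20, 4, 78))
  expect_error(aicc(-20, 9, 10), "undefined")
})

test_that("mixed-model fit recovers a zero-noise generative model", {
  cfg <- synth_config(
    sigma_country = 0, sigma_resid = 1e-8, n_records = 40, rng_seed = 3
  )
  g <- generate_landscape(cfg)
  r <- generate_valuation_dataset(cfg, g)
  m <- suppressWarnings(fit_mixed_model(r, true_terms()))
  tb <- default_true_beta()
  expect_lt(max(abs(m$fixef[names(tb)] - tb)), 1e-4)
  expect_equal(m$sigma_country, 0, tolerance = 1e-6)
})

test_that("degenerate groupings and collinear designs are handled", {
  w <- small_world(seed = 4)
  r1 <- w$records[w$records$country == 1, ]
  m1 <- fit_mixed_model(r1, c("temperature"))
  expect_true(m1$one_country)
  expect_identical(m1$sigma_country, 0)

  r2 <- w$records
  r2$temp_copy <- r2$temperature
  expect_error(
    fit_mixed_model(r2, c("temperature", "temp_copy")),
    "collinear.*temp_copy"
  )
})

test_that("enumeration fits every subset and weights are coherent", {
  w <- small_world(seed = 5)
  cand <- c("temperature", "year", "richness_birds")
  set <- enumerate_models(w$records, cand)
  expect_identical(length(set$models), 8L)
  expect_identical(length(set$failed), 0L)
  expect_identical(min(set$delta_aicc), 0)
  expect_equal(sum(set$akaike_weight), 1, tolerance = 1e-12)
  # stored AICc agrees with recomputation from stored loglik/k/n
  for (m in set$models) {
    expect_identical(m$aicc, aicc(m$loglik, m$k, m$n))
  }
})

test_that("Akaike weights for delta {0, 2} match the closed form", {
  m1 <- fake_model(1)
  m1$aicc <- 100
  m2 <- fake_model(2)
  m2$aicc <- 102
  set <- tevtrade:::model_set_from_models(list(m1, m2))
  expect_equal(set$akaike_weight, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(sum(set$akaike_weight), 1, tolerance = 1e-12)
})

test_that("top-model selection is boundary-inclusive and renormalizes", {
  m <- lapply(c(100, 101.9, 102.1), function(a) {
    f <- fake_model(1)
    f$aicc <- a
    f
  })
  set <- tevtrade:::model_set_from_models(m)
  top <- select_top(set, cutoff = 2)
  expect_identical(length(top$models), 2L)
  expect_equal(sum(top$akaike_weight), 1, tolerance = 1e-12)

  one <- select_top(tevtrade:::model_set_from_models(m[1]), cutoff = 2)
  expect_identical(length(one$models), 1L)
})

test_that("model-averaged predictions are convex weightings", {
  nd <- data.frame(country = 1)
  set <- fake_set(list(fake_model(1), fake_model(2)), c(0.6, 0.4))
  expect_equal(average_predict(set, nd), 1.4)

  single <- fake_set(list(fake_model(3)), 1)
  expect_equal(average_predict(single, nd), 3)

  # with real fits the average lies within the component-prediction range
  w <- small_world(seed = 6)
  top <- select_top(enumerate_models(w$records, c("temperature", "year")))
  nd2 <- w$records[1:5, ]
  preds <- sapply(top$models, function(m) predict(m, nd2))
  preds <- matrix(preds, nrow = 5)
  avg <- average_predict(top, nd2)
  expect_true(all(avg >= apply(preds, 1, min) - 1e-12))
  expect_true(all(avg <= apply(preds, 1, max) + 1e-12))
})

test_that("unseen countries fall back to fixed effects only", {
  w <- small_world(seed = 7)
  m <- fit_mixed_model(w$records, c("temperature"))
  nd <- w$records[1, ]
  nd$country <- 999
  p_new <- predict(m, nd)
  nd_known <- w$records[1, ]
  expect_equal(
    p_new,
    predict(m, nd_known) - m$country_effects[[as.character(nd_known$country)]]
  )
  # absent mandatory covariate is a named error
  expect_error(predict(m, data.frame(country = 1)), "temperature")
})

test_that("TEV surface combines class values with the multipliers", {
  w <- small_world(seed = 8)
  g <- w$grid
  # class-only model: cultural 10, provisioning 20, regulating 30 per ha
  m <- fake_model(log(10),
    beta = c(
      "es_classprovisioning" = log(2), "es_classregulating" = log(3)
    ),
    terms = "es_class"
  )
  set <- fake_set(list(m), 1)
  tev <- predict_tev_grid(set, g,
    multipliers = c(cultural = 5, provisioning = 6, regulating = 5)
  )
  expect_equal(as.numeric(tev), rep(5 * 10 + 6 * 20 + 5 * 30, nrow(g)))
  expect_true(all(predict_tev_grid(set, g,
    multipliers = c(cultural = 0, provisioning = 0, regulating = 0)
  ) == 0))
  expect_error(
    predict_tev_grid(set, g,
      multipliers = c(cultural = -1, provisioning = 5, regulating = 6)
    ),
    "multipliers"
  )
})

test_that("TEV prediction is invariant to record and cell order", {
  w <- small_world(seed = 9, nx = 6, ny = 6)
  cand <- c("temperature", "year")
  top1 <- select_top(enumerate_models(w$records, cand))
  shuffled <- w$records[sample.int(nrow(w$records)), ]
  top2 <- select_top(enumerate_models(shuffled, cand))
  t1 <- predict_tev_grid(top1, w$grid)
  t2 <- predict_tev_grid(top2, w$grid)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-8)

  perm <- sample.int(nrow(w$grid))
  gp <- w$grid[perm, ]
  attributes(gp)[c("nx", "ny", "cell_area", "crop_set", "crop_composition")] <-
    attributes(w$grid)[c("nx", "ny", "cell_area", "crop_set", "crop_composition")]
  expect_equal(as.numeric(predict_tev_grid(top1, gp)), as.numeric(t1)[perm])
})

test_that("bootstrap ensemble collapses under zero noise and tracks the point map", {
  # no year/forest_area terms: those are filled with per-resample
  # training means at prediction time, a legitimate bootstrap source
  # that would keep even zero-noise maps from coinciding
  tb <- c(
    "(Intercept)" = 2, "es_classprovisioning" = 0.5,
    "es_classregulating" = 0.8, "temperature" = 0.05
  )
  cfg <- synth_config(
    true_beta = tb, sigma_country = 0, sigma_resid = 1e-8, n_records = 40,
    grid_nx = 6, grid_ny = 6, rng_seed = 10
  )
  g <- generate_landscape(cfg)
  r <- generate_valuation_dataset(cfg, g)
  es <- suppressWarnings(
    bootstrap_es_maps(r, g,
      B = 5, candidate_terms = c("es_class", "temperature"), seed = 1
    )
  )
  expect_identical(dim(es$maps), c(nrow(g), 5L))
  expect_lt(max(apply(es$maps, 1, stats::sd) / rowMeans(es$maps)), 1e-4)
  expect_equal(es$maps[, 1], as.numeric(es$point_map), tolerance = 1e-4)
})

test_that("through-origin slope and LOO limits behave", {
  expect_equal(through_origin_slope(c(1, 2), c(2, 4)), 2)
  cfg <- synth_config(
    sigma_country = 0, sigma_resid = 1e-8, n_records = 25, rng_seed = 11
  )
  g <- generate_landscape(cfg)
  r <- generate_valuation_dataset(cfg, g)
  cv <- suppressWarnings(loo_cv(r, true_terms(), procedure = "top"))
  expect_lt(cv$mape, 1e-6)
  expect_equal(cv$slope, 1, tolerance = 1e-6)
})

test_that("direct benefit transfer uses leave-one-out stratum means", {
  r <- data.frame(
    es_class = c("cultural", "cultural", "provisioning", "provisioning"),
    log_value = c(1, 3, 2, 4)
  )
  dbt <- direct_benefit_transfer(r, "global")
  expect_equal(dbt$predictions$predicted, c(3, 1, 4, 2))
  expect_equal(dbt$mape, mean(c(2 / 1, 2 / 3, 2 / 2, 2 / 4)))

  same <- data.frame(es_class = rep("cultural", 4), log_value = rep(2, 4))
  expect_equal(direct_benefit_transfer(same, "global")$mape, 0)

  # a singleton stratum falls back to the global mean, flagged
  r$region <- c("r1", "r1", "r1", "r2")
  reg <- direct_benefit_transfer(r, "regional")
  expect_true(reg$predictions$fallback[4])
  expect_equal(reg$predictions$predicted[4], mean(c(1, 3, 2)))
})

test_that("diagnostics flag collinearity and spatial independence", {
  w <- small_world(seed = 12, n_records = 120)
  r <- w$records
  d <- diagnostics(r, c("temperature", "precipitation", "accessibility"))
  expect_true(all(d$vif < 5))
  expect_true(d$bp_pvalue >= 0 && d$bp_pvalue <= 1)
  # independently drawn covariates and noise: no spatial trend
  expect_lt(abs(d$slope), 2 * d$slope_se + 1e-12)

  r$temp_dup <- r$temperature + stats::rnorm(nrow(r), 0, 0.001)
  d2 <- diagnostics(r, c("temperature", "temp_dup"))
  expect_gt(max(d2$vif), 100)

  r$temp_exact <- r$temperature
  d3 <- diagnostics(r, c("temperature", "temp_exact"))
  expect_true(any(is.infinite(d3$vif)))
})
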