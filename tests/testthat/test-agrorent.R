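test_that("scenario specifications pin the crop source and cost flag", {
  expect_identical(scenario_spec("A")$crop_source, "national_sample")
  expect_true(scenario_spec("A")$deduct_costs)
  expect_false(scenario_spec("B")$deduct_costs)
  expect_identical(scenario_spec("C")$crop_source, "max_rent")
  expect_false(scenario_spec("D")$deduct_costs)
  expect_error(scenario_spec("E"), "A, B, C, D")
})

test_that("transport cost follows the round-trip truck model", {
  expect_identical(transport_cost(0, 5, 1), 0)
  # t=2h, wage 5/h, fuel 1/L, 0.3 L/km, 18 m3, 45 km/h, 1 t/m3
  expect_equal(transport_cost(2, 5, 1), 74 / 18, tolerance = 0.01)
  # defaults: 1h at zero wage costs fuel over 90 km spread over 18 t
  expect_equal(transport_cost(1, 0, 1), 90 * 0.3 / 18)
  expect_error(transport_cost(1, 1, 1, capacity_m3 = 0), "capacity")
})

test_that("production costs assemble enabled components", {
  pc <- production_costs(100, 2)
  expect_equal(pc$labor, 200)
  expect_equal(pc$total, 200)
  # gross-rent scenarios zero the total
  expect_equal(production_costs(100, 2, deduct = FALSE)$total, 0)
  # transport only when included
  with_t <- production_costs(100, 2, 50, 0.5,
    transport_per_t = 4, yield = 3, include_transport = TRUE
  )
  without_t <- production_costs(100, 2, 50, 0.5)
  expect_equal(with_t$total - without_t$total, 12)
  expect_gte(with_t$total, without_t$total)
})

test_that("rent primitives match hand arithmetic", {
  expect_equal(net_rent(2, 300, 100), 500)
  expect_equal(net_rent(2, 300), 600)
  expect_equal(net_rent(1, 50, 100), -50) # negative rents preserved
  expect_error(net_rent(-1, 10), "non-negative")

  expect_identical(timber_rent(200, 0, 50), 0)
  expect_equal(timber_rent(200, 0.3, 50), 3000 * 0.0503831, tolerance = 0.05)
  expect_equal(timber_rent(200, 0.3, 50, r = 0), 30)
  expect_error(timber_rent(200, 1.2, 50), "\\[0, 1\\]")

  expect_equal(cattle_rent(1, 0.25, 2000, 100), 400)
  expect_equal(cattle_rent(0, 0.25, 2000, 100), -100)
  expect_equal(
    cattle_rent(2, 0.25, 2000) , 2 * cattle_rent(1, 0.25, 2000)
  )
})

test_that("national crop sampling honours composition weights", {
  w <- small_world(seed = 21, nx = 100, ny = 100, n_countries = 1)
  g <- w$grid
  comp <- attr(g, "crop_composition")
  comp <- comp[comp$crop %in% c("maize", "rice"), ]
  comp$weight <- c(0.7, 0.3)
  attr(g, "crop_composition") <- comp
  a <- assign_crops(g, "A", w$econ, seed = 2)
  n <- length(a)
  n_maize <- sum(a == "maize")
  sd3 <- 3 * sqrt(n * 0.7 * 0.3)
  expect_gt(n_maize, 0.7 * n - sd3)
  expect_lt(n_maize, 0.7 * n + sd3)
  # seeded reproducibility, and A/B share draws under one seed
  expect_identical(a, assign_crops(g, "A", w$econ, seed = 2))
  expect_identical(a, assign_crops(g, "B", w$econ, seed = 2))
  expect_false(identical(a, assign_crops(g, "A", w$econ, seed = 3)))

  comp1 <- comp[comp$crop == "maize", ]
  attr(g, "crop_composition") <- comp1
  expect_true(all(assign_crops(g, "A", w$econ, seed = 1) == "maize"))

  comp0 <- comp[0, ]
  attr(g, "crop_composition") <- comp0
  expect_error(assign_crops(g, "A", w$econ), "no crops")
})

test_that("maximum-rent assignment is an argmax with fixed tie-breaking", {
  w <- small_world(seed = 22, nx = 8, ny = 8)
  a <- assign_crops(w$grid, "C", w$econ)
  R <- potential_rent_matrix(w$grid, w$econ, deduct = TRUE)
  chosen <- R[cbind(seq_len(nrow(R)), match(a, colnames(R)))]
  expect_true(all(chosen >= apply(R, 1, max) - 1e-9))
  # deterministic regardless of seed
  expect_identical(a, assign_crops(w$grid, "C", w$econ, seed = 99))
})

test_that("rent maps obey degenerate and dominance properties", {
  w0 <- small_world(seed = 23, forest_loss_fraction = 0)
  rm0 <- rent_map(w0$grid, "A", w0$econ)
  expect_true(all(rm0$ar == 0))
  expect_true(all(is.na(rm0$crop)))

  w <- small_world(seed = 24)
  rmA <- rent_map(w$grid, "A", w$econ, seed = 5)
  rmB <- rent_map(w$grid, "B", w$econ, seed = 5)
  expect_true(all(rmB$ar - rmA$ar >= -1e-9))
  rmC <- rent_map(w$grid, "C", w$econ)
  rmD <- rent_map(w$grid, "D", w$econ)
  expect_true(all(rmD$ar - rmC$ar >= -1e-9))
  # non-loss cells carry zero rent
  expect_true(all(rmA$ar[w$grid$forest_loss_area == 0] == 0))
})

test_that("rent of a cell equals the scalar brute-force computation", {
  w <- small_world(seed = 25, nx = 5, ny = 5)
  for (sc in c("A", "B", "C", "D")) {
    rm <- rent_map(w$grid, sc, w$econ, seed = 7)
    loss <- which(w$grid$forest_loss_area > 0)
    for (i in loss[1:5]) {
      expect_equal(
        rm$ar[i],
        brute_cell_rent(w$grid, i, rm$crop[i], sc, w$econ),
        tolerance = 1e-9
      )
    }
  }
})

test_that("missing crop-country prices fall back to donor then zero", {
  w <- small_world(seed = 26, nx = 4, ny = 4, n_countries = 2)
  econ <- w$econ
  drop_row <- econ$crop_prices$crop == "maize" & econ$crop_prices$country_id == 1
  econ$crop_prices <- econ$crop_prices[!drop_row, ]
  P_donor <- tevtrade:::price_matrix(econ, donor = 2)
  expect_equal(
    P_donor["maize", "1"], P_donor["maize", "2"]
  )
  expect_warning(P0 <- tevtrade:::price_matrix(econ), "set to 0")
  expect_identical(P0["maize", "1"], 0)
})
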