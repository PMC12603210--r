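test_that("zero-shock solve reproduces the calibrated baseline", {
  st <- get_study()
  expect_lt(st$model$calibration_residual, 1e-8)
  eq0 <- solve_equilibrium(st$model, shocks = NULL)
  expect_lte(eq0$diagnostics$iterations, 2)
  base <- st$baseline$market
  joined <- dplyr::inner_join(eq0$state, base,
                              by = c("region_id", "commodity_id"))
  expect_equal(joined$supply, joined$production, tolerance = 1e-6)
  expect_equal(joined$demand.x, joined$demand.y, tolerance = 1e-6)
  expect_equal(joined$price_ratio, rep(1, nrow(joined)), tolerance = 1e-6)
})

test_that("a symmetric two-region baseline calibrates symmetrically", {
  m <- calibrate_baseline(symmetric_two_region_baseline())
  expect_equal(unname(m$wdom[1, 1]), unname(m$wdom[2, 1]))
  expect_equal(unname(m$PC0[1, 1]), unname(m$PC0[2, 1]))
  expect_lt(m$calibration_residual, 1e-10)
})

test_that("calibration rejects an unbalanced baseline with a report", {
  bl <- symmetric_two_region_baseline()
  bl$market$demand[1] <- 120 # no flows support this
  expect_error(calibrate_baseline(bl), "not balanced")
})

test_that("solver price matches the closed-form one-market oracle", {
  m <- closed_market_model(eps_supply = 0.5, eps_demand = -0.5)
  eq <- solve_equilibrium(m, tibble::tibble(region_id = "A",
                                            commodity_id = "x", s = 0.1),
                          control = solver_control(tolerance = 1e-12))
  oracle_p <- (1 / 0.9)^(1 / (0.5 + 0.5))
  expect_equal(eq$state$price_ratio, oracle_p, tolerance = 1e-8)
  expect_equal(eq$state$price_ratio, 1.1111, tolerance = 1e-4)
  expect_equal(eq$state$supply, 0.9487, tolerance = 1e-4)

  m2 <- closed_market_model(eps_supply = 0.5, eps_demand = -0.3)
  eq2 <- solve_equilibrium(m2, tibble::tibble(region_id = "A",
                                              commodity_id = "x", s = 0.1),
                           control = solver_control(tolerance = 1e-12))
  expect_equal(eq2$state$price_ratio, (1 / 0.9)^(1 / 0.8), tolerance = 1e-8)
  expect_equal(eq2$state$price_ratio, 1.1408, tolerance = 1e-4)
  expect_equal(eq2$state$supply, 0.9613, tolerance = 1e-4)
  revenue_change <- eq2$state$price_ratio * eq2$state$supply - 1
  expect_equal(100 * revenue_change, 9.7, tolerance = 0.05)
})

test_that("King-Davenant revenue reversal at unit demand elasticity", {
  solve_rev <- function(eps_d) {
    m <- closed_market_model(eps_supply = 0.5, eps_demand = eps_d)
    eq <- solve_equilibrium(m, tibble::tibble(region_id = "A",
                                              commodity_id = "x", s = 0.1),
                            control = solver_control(tolerance = 1e-10))
    eq$state$price_ratio * eq$state$supply
  }
  expect_gt(solve_rev(-0.4), 1) # inelastic: revenue rises
  expect_lt(solve_rev(-1.6), 1) # elastic: revenue falls
})

test_that("supply response passes shocks through and intensification buffers", {
  st <- get_study()
  m <- st$model
  base <- supply_response(m)
  mk <- dplyr::arrange(st$baseline$market, region_id, commodity_id)
  expect_equal(base$supply, mk$production, tolerance = 1e-12)

  # fixed prices, eta irrelevant: a 10% shock cuts supply by exactly 10%
  sh <- tibble::tibble(region_id = mk$region_id[1],
                       commodity_id = mk$commodity_id[1], s = 0.1)
  shocked <- supply_response(m, shocks = sh)
  i <- shocked$region_id == sh$region_id & shocked$commodity_id == sh$commodity_id
  expect_equal(shocked$supply[i], 0.9 * base$supply[i], tolerance = 1e-12)

  # price response: realized yield falls by less than the shock
  m1 <- closed_market_model(eps_supply = 0.5, eps_demand = -0.5, eta = 0.2)
  eq <- solve_equilibrium(m1, tibble::tibble(region_id = "A",
                                             commodity_id = "x", s = 0.1))
  expect_gt(eq$state$price_ratio, 1)
  expect_gt(eq$state$yield_multiplier, 0.9)
  expect_lt(eq$state$yield_multiplier, 1)
})

test_that("Armington allocation follows CES value-share algebra", {
  # all prices at base: calibrated shares and quantities returned unchanged
  out <- armington_allocate(
    total_demand = 100, base_demand = 100, domestic_ratio = 1,
    import_ratios = c(1, 1), share_domestic = 0.6,
    import_shares = c(0.7, 0.3), sigma_top = 2, sigma_origin = 2,
    base_domestic_qty = 60, base_import_qty = c(28, 12))
  expect_equal(out$import_value_shares, c(0.7, 0.3))
  expect_equal(out$domestic_qty, 60)
  expect_equal(out$import_qty, c(28, 12))

  # origin 2 price +10% at sigma 2: shares shift by p^(1-sigma) renormalised
  out2 <- armington_allocate(100, 100, 1, c(1, 1.1), 0.6, c(0.7, 0.3),
                             2, 2, 60, c(28, 12))
  w2 <- c(0.7, 0.3 / 1.1) / sum(c(0.7, 0.3 / 1.1))
  expect_equal(out2$import_value_shares, w2, tolerance = 1e-12)
  expect_equal(out2$import_value_shares, c(0.7196, 0.2804), tolerance = 2e-4)

  # sigma -> 0: fixed quantity proportions regardless of prices
  out3 <- armington_allocate(100, 100, 1, c(1, 1.4), 0.6, c(0.7, 0.3),
                             1e-9, 1e-9, 60, c(28, 12))
  expect_equal(out3$import_qty[1] / out3$import_qty[2], 28 / 12,
               tolerance = 1e-6)

  # sigma = 1 uses the log-form limit, not an error
  out4 <- armington_allocate(100, 100, 1, c(1, 1.1), 0.6, c(0.7, 0.3),
                             1, 1, 60, c(28, 12))
  expect_equal(out4$import_price_index, exp(0.3 * log(1.1)), tolerance = 1e-9)
})

test_that("price transmission is ad valorem with wedge revenue", {
  out <- apply_price_transmission(100, 0.25)
  expect_equal(out$landed_price, 125)
  expect_equal(out$wedge_revenue_per_unit, 25)
  expect_equal(apply_price_transmission(7, 0)$landed_price, 7)
  expect_error(apply_price_transmission(10, -0.1), "tau")
})

test_that("converged states clear every market and are deterministic", {
  st <- get_study()
  eq <- get_mean_eq()
  expect_true(eq$diagnostics$converged)
  expect_lte(eq$diagnostics$max_residual, 1e-6)
  # supply equals world use good-by-good
  tot_exports <- eq$state |>
    dplyr::group_by(region_id, commodity_id) |>
    dplyr::summarise(x = sum(exports), .groups = "drop")
  resid <- abs(eq$state$supply -
                 (eq$state$domestic_use + eq$state$exports)) /
    pmax(eq$state$supply, 1e-9)
  expect_lt(max(resid), 1e-6)
  # bit-identical re-solve
  eq2 <- solve_equilibrium(st$model, shocks_at_level(st$shocks, "mean"))
  expect_identical(eq$state, eq2$state)
})

test_that("a Europe-confined shock raises world prices and foreign output", {
  st <- get_study()
  eq <- get_mean_eq()
  dep <- st$baseline$commodities$commodity_id[
    st$baseline$commodities$pollination_dependent]
  rg <- st$baseline$regions
  extra <- rg$region_id[!rg$in_europe]
  base <- st$baseline$market
  for (cm in dep) {
    sub <- eq$state[eq$state$commodity_id == cm, ]
    # production-weighted world price ratio weakly above 1
    bb <- base[base$commodity_id == cm, ]
    wt <- bb$production[match(sub$region_id, bb$region_id)]
    expect_gte(sum(sub$price_ratio * wt) / sum(wt), 1 - 1e-9)
    # extra-European production weakly up
    expect_gte(sum(sub$supply[sub$region_id %in% extra]),
               sum(bb$production[bb$region_id %in% extra]) - 1e-9)
  }
})

test_that("land expansion buffers the aggregate production decline", {
  st <- get_study()
  eq <- get_mean_eq()
  rg <- st$baseline$regions
  eur <- tibble::tibble(region_id = rg$region_id[rg$in_europe],
                        bloc = "europe")
  agg <- aggregate_outputs(st$model, eq, blocs = eur, by_group = FALSE)
  expect_lt(agg$yield_pct, 0)
  expect_lt(agg$production_pct, 0)
  # positive land supply elasticity: output falls less than yields
  expect_gt(agg$production_pct, agg$yield_pct)
  expect_gt(agg$land_pct, 0)
})

test_that("trade indicators follow their ratio definitions", {
  # closed economy producing what it eats: self-sufficiency 100%
  m <- closed_market_model()
  ind <- compute_trade_indicators(m)
  expect_equal(ind$self_sufficiency, 100)
  expect_equal(ind$export_intensity, 0)
  expect_equal(ind$import_penetration, 0)

  bl <- symmetric_two_region_baseline()
  bl$market$production <- c(103.4, 100)
  bl$market$demand <- c(100, 103.4)
  bl$trade$qty <- c(10, 6.6) # A exports 10, imports 6.6: net export 3.4
  ind2 <- compute_trade_indicators(bl)
  expect_equal(ind2$self_sufficiency[ind2$bloc == "A"], 103.4)
  expect_equal(ind2$export_intensity[ind2$bloc == "A"], 100 * 10 / 103.4)
  expect_equal(ind2$import_penetration[ind2$bloc == "A"], 100 * 6.6 / 100)

  # bloc aggregation nets out intra-bloc flows
  both <- compute_trade_indicators(
    bl, blocs = tibble::tibble(region_id = c("A", "B"), bloc = "world"))
  expect_equal(both$export_intensity, 0)
  expect_equal(both$self_sufficiency, 100 * 203.4 / 203.4)

  # zero denominator: undefined, not zero
  bl2 <- symmetric_two_region_baseline()
  bl2$trade$qty <- c(10, 0)
  bl2$market$production <- c(10, 0)
  bl2$market$demand <- c(0, 10)
  ind3 <- compute_trade_indicators(bl2)
  expect_true(is.na(ind3$self_sufficiency[ind3$bloc == "A"]))
  expect_true(is.na(ind3$export_intensity[ind3$bloc == "B"]))
})

test_that("aggregate outputs value-weight changes and reject empty groups", {
  st <- get_study()
  eq0 <- solve_equilibrium(st$model, shocks = NULL)
  agg0 <- aggregate_outputs(st$model, eq0)
  expect_true(all(abs(agg0$yield_pct) < 1e-6))
  expect_true(all(abs(agg0$production_pct) < 1e-6))
  expect_true(all(abs(agg0$land_pct) < 1e-6))
  expect_error(
    aggregate_outputs(st$model, eq0,
                      blocs = tibble::tibble(region_id = "nope", bloc = "b")),
    "empty")
})

test_that("non-convergence fails loudly with a residual trajectory", {
  m <- closed_market_model()
  err <- tryCatch(
    solve_equilibrium(m, tibble::tibble(region_id = "A", commodity_id = "x",
                                        s = 0.5),
                      control = solver_control(max_iter = 2)),
    error = function(e) e)
  expect_s3_class(err, "pollishock_convergence_error")
  expect_true(length(attr(err, "trajectory")) > 0 ||
                length(err$trajectory) > 0)
})
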