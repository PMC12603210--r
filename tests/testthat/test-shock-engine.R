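test_that("value shares normalise within each region-commodity cell", {
  pv <- tibble::tibble(
    region_id = c("R1", "R1", "R1"),
    commodity_id = c("c1", "c1", "c2"),
    crop_id = c("a", "b", "c"),
    value = c(60, 40, 5))
  sh <- map_crops_to_commodities(pv)
  expect_equal(sh$share[sh$crop_id == "a"], 0.6)
  expect_equal(sh$share[sh$crop_id == "b"], 0.4)
  expect_equal(sh$share[sh$crop_id == "c"], 1.0)

  zero <- tibble::tibble(region_id = "R1", commodity_id = c("c1", "c2"),
                         crop_id = c("a", "b"), value = c(10, 0))
  expect_warning(out <- map_crops_to_commodities(zero), "zero total")
  expect_false("c2" %in% out$commodity_id)

  expect_error(map_crops_to_commodities(dplyr::mutate(pv, value = -value)),
               "non-negative")
  pv2 <- pv
  pv2$commodity_id[2] <- "c2" # crop b now in two commodities? no - rename crop
  pv2$crop_id[3] <- "a"       # crop a mapped to both c1 and c2
  expect_error(map_crops_to_commodities(pv2), "more than one commodity")
})

test_that("mean commodity shock follows the share-weighted phi*D formula", {
  shares <- tibble::tibble(region_id = "R1", commodity_id = "c1",
                           crop_id = c("a", "b"), share = c(0.6, 0.4))
  dep <- tibble::tibble(crop_id = c("a", "b"), D_mean = c(0.5, 1.0))
  phi <- tibble::tibble(commodity_id = "c1", phi = 0.5)
  out <- compute_commodity_shock(shares, phi, dep)
  expect_equal(out$s_mean, 0.5 * (0.6 * 0.5 + 0.4 * 1.0)) # 0.35
  expect_equal(out$multiplier_mean, 1 - out$s_mean)

  # zero wild contribution means no shock
  out0 <- compute_commodity_shock(shares,
                                  tibble::tibble(commodity_id = "c1", phi = 0),
                                  dep)
  expect_equal(out0$s_mean, 0)

  # full dependence capped at 99.9%
  s1 <- tibble::tibble(region_id = "R1", commodity_id = "c1",
                       crop_id = "a", share = 1)
  d1 <- tibble::tibble(crop_id = "a", D_mean = 1)
  p1 <- tibble::tibble(commodity_id = "c1", phi = 1)
  expect_equal(compute_commodity_shock(s1, p1, d1)$s_mean, 0.999)

  # a dependent commodity without phi is an error, never a silent default
  expect_error(
    compute_commodity_shock(shares,
                            tibble::tibble(commodity_id = "zz", phi = 0.5),
                            dep),
    "phi")
})

test_that("single-crop commodity reproduces the printed rapeseed shock", {
  s <- tibble::tibble(region_id = "EU", commodity_id = "rapeseed",
                      crop_id = "rapeseed", share = 1)
  d <- tibble::tibble(crop_id = "rapeseed", D_mean = 0.270)
  p <- tibble::tibble(commodity_id = "rapeseed", phi = 0.596)
  out <- compute_commodity_shock(s, p, d)
  expect_equal(shock_percent(out$s_mean), 16.1)
})

test_that("triangular quantile matches the closed form and inverts the CDF", {
  expect_equal(triangular_quantile(0.025, 0, 0.5, 1),
               sqrt(0.025 * 1 * 0.5), tolerance = 1e-12)
  expect_equal(triangular_quantile(0.025, 0, 0.5, 1), 0.11180,
               tolerance = 1e-4)
  expect_equal(triangular_quantile(0.975, 0, 0.5, 1), 0.88820,
               tolerance = 1e-4)
  expect_equal(triangular_quantile(0, 0.2, 0.3, 0.9), 0.2)
  expect_equal(triangular_quantile(1, 0.2, 0.3, 0.9), 0.9)
  expect_equal(triangular_quantile(0.7, 0.3, 0.3, 0.3), 0.3)
  expect_error(triangular_quantile(0.5, 1, 0.5, 0), "lower > upper")

  # round-trip Q(F) and F(Q) over a deterministic grid of shapes
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1); c_ <- a + runif(1); b <- c_ + runif(1)
    p <- runif(1)
    q <- triangular_quantile(p, a, c_, b)
    expect_equal(triangular_cdf(q, a, c_, b), p, tolerance = 1e-9)
  }
})

test_that("shock bounds use triangular quantiles with proportional fallback", {
  # single crop, buckwheat-style: no bounds -> +/-50% of the mean shock
  s <- tibble::tibble(region_id = "EU", commodity_id = "othcer",
                      crop_id = "buckwheat", share = 1)
  d <- tibble::tibble(crop_id = "buckwheat", D_mean = 0.187,
                      D_min = NA_real_, D_max = NA_real_)
  p <- tibble::tibble(commodity_id = "othcer", phi = 0.230)
  out <- derive_shock_bounds(s, p, d)
  expect_equal(out$s_low, out$s_mean * 0.5)
  expect_equal(out$s_high, out$s_mean * 1.5)
  expect_equal(shock_percent(out$s_mean), 4.3)
  expect_equal(shock_percent(out$s_high), 6.5)

  # degenerate dependence bounds collapse to the mean
  d2 <- tibble::tibble(crop_id = "buckwheat", D_mean = 0.187,
                       D_min = 0.187, D_max = 0.187)
  out2 <- derive_shock_bounds(s, p, d2)
  expect_equal(out2$s_low, out2$s_mean)
  expect_equal(out2$s_high, out2$s_mean)

  # zero coverage: the quantiles coincide at the triangular median, so the
  # interval shrinks onto the mean-median gap (a point for symmetric
  # triangles)
  d3 <- tibble::tibble(crop_id = "buckwheat", D_mean = 0.4,
                       D_min = 0.1, D_max = 0.8)
  out3 <- derive_shock_bounds(s, p, d3, coverage = 0)
  med_s <- triangular_quantile(0.5, 0.1, 0.4, 0.8) * p$phi
  expect_equal(out3$s_low, min(out3$s_mean, med_s), tolerance = 1e-12)
  expect_equal(out3$s_high, max(out3$s_mean, med_s), tolerance = 1e-12)
  d3s <- tibble::tibble(crop_id = "buckwheat", D_mean = 0.4,
                        D_min = 0.1, D_max = 0.7)
  out3s <- derive_shock_bounds(s, p, d3s, coverage = 0)
  expect_equal(out3s$s_low, out3s$s_mean, tolerance = 1e-12)
  expect_equal(out3s$s_high, out3s$s_mean, tolerance = 1e-12)
  expect_error(derive_shock_bounds(s, p, d3, coverage = 1.2), "coverage")

  # bounds are ordered for arbitrary multi-crop tables
  st <- get_study()
  expect_true(all(st$shocks$s_low <= st$shocks$s_mean + 1e-12))
  expect_true(all(st$shocks$s_mean <= st$shocks$s_high + 1e-12))
  expect_true(all(st$shocks$s_high <= 0.999))
})

test_that("shock is monotone in dependence and wild contribution", {
  set.seed(11)
  for (i in 1:20) {
    shares <- tibble::tibble(region_id = "R", commodity_id = "c",
                             crop_id = c("a", "b"),
                             share = local({
                               w <- runif(2); w / sum(w)
                             }))
    d <- tibble::tibble(crop_id = c("a", "b"), D_mean = runif(2, 0, 0.9))
    p <- tibble::tibble(commodity_id = "c", phi = runif(1, 0, 0.9))
    base <- compute_commodity_shock(shares, p, d)$s_mean
    d_up <- d; d_up$D_mean <- pmin(1, d_up$D_mean + runif(2, 0, 0.1))
    p_up <- p; p_up$phi <- min(1, p_up$phi + runif(1, 0, 0.1))
    expect_gte(compute_commodity_shock(shares, p_up, d)$s_mean, base)
    expect_gte(compute_commodity_shock(shares, p, d_up)$s_mean, base)
  }
})

test_that("annualised decline rate inverts compound decay", {
  expect_equal(annual_decline_rate(0.5, 1), 0.5)
  expect_equal(annual_decline_rate(0.75, 2), 0.5)
  expect_equal(round_half_up(100 * annual_decline_rate(0.90, 14), 1), 15.2)
  expect_error(annual_decline_rate(1, 10), "cumulative_decline")
  sp <- decline_spec(0.9, 14)
  expect_equal((1 - sp$annual_rate)^sp$n_periods, 1 - sp$cumulative_decline,
               tolerance = 1e-9)
})

test_that("shock table zeroes non-European regions and swaps sources cleanly", {
  shares <- tibble::tibble(region_id = c("EU1", "ROW1"),
                           commodity_id = "c1", crop_id = "a", share = 1)
  d_new <- tibble::tibble(crop_id = "a", D_mean = 0.6, D_min = 0.4,
                          D_max = 0.8)
  d_old <- tibble::tibble(crop_id = "a", D_mean = 0.3, D_min = 0.2,
                          D_max = 0.4)
  p <- tibble::tibble(commodity_id = "c1", phi = 0.5)
  regions <- tibble::tibble(region_id = c("EU1", "ROW1"),
                            in_europe = c(TRUE, FALSE))
  tab <- build_shock_table(shares, p, d_new, regions)
  expect_equal(tab$s_mean[tab$region_id == "ROW1"], 0)
  expect_equal(tab$multiplier_mean[tab$region_id == "ROW1"], 1)
  expect_equal(tab$s_mean[tab$region_id == "EU1"], 0.3)

  # identical inputs give identical outputs (pure function)
  expect_identical(tab, build_shock_table(shares, p, d_new, regions))

  # swapping the dependence source changes values, not the schema
  tab_old <- build_shock_table(shares, p, d_old, regions)
  expect_identical(names(tab), names(tab_old))
  expect_lt(tab_old$s_mean[tab_old$region_id == "EU1"],
            tab$s_mean[tab$region_id == "EU1"])

  expect_error(
    build_shock_table(shares, p, d_new,
                      tibble::tibble(region_id = "EU1", in_europe = TRUE)),
    "not classified")
})
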