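test_that("the three CI scenarios produce bracketing envelopes", {
  st <- get_study()
  ci <- run_ci_scenarios(st$model, st$shocks)
  expect_named(ci$runs, c("low", "mean", "high"))
  n_ind <- nrow(scenario_indicators(st$model, ci$runs$mean))
  expect_equal(nrow(ci$indicators), 3 * n_ind)
  expect_true(all(ci$envelope$env_min <= ci$envelope$mean + 1e-12))
  expect_true(all(ci$envelope$mean <= ci$envelope$env_max + 1e-12))

  # degenerate bounds: three identical results
  degen <- st$shocks
  degen$s_low <- degen$s_mean
  degen$s_high <- degen$s_mean
  ci2 <- run_ci_scenarios(st$model, degen)
  expect_equal(ci2$envelope$low, ci2$envelope$mean, tolerance = 1e-12)
  expect_equal(ci2$envelope$high, ci2$envelope$mean, tolerance = 1e-12)
})

test_that("the factorial grid is complete and centred on the core run", {
  st <- get_study()
  # 2 factors x 3 levels keeps the unit test quick: 9 runs
  f2 <- sensitivity_factors(names = c("wild_contribution",
                                      "dependence_ratio"))
  g <- run_sensitivity_grid(st$model, st$shares, st$phi, st$dependence,
                            factors = f2)
  expect_equal(nrow(g$results), 9)
  expect_equal(nrow(dplyr::distinct(
    g$results[, c("wild_contribution", "dependence_ratio")])), 9)

  central <- g$results[g$results$wild_contribution == 1 &
                         g$results$dependence_ratio == 1, ]
  core <- solve_equilibrium(st$model, shocks_at_level(st$shocks, "mean"))
  core_ind <- scenario_indicators(st$model, core)
  for (i in seq_len(nrow(core_ind))) {
    expect_equal(central[[core_ind$indicator[i]]], core_ind$value[i],
                 tolerance = 1e-10)
  }
  # envelope across runs brackets the core run
  for (nm in core_ind$indicator) {
    expect_gte(core_ind$value[core_ind$indicator == nm],
               min(g$results[[nm]]) - 1e-9)
    expect_lte(core_ind$value[core_ind$indicator == nm],
               max(g$results[[nm]]) + 1e-9)
  }

  # repeated runs are identical (no hidden randomness)
  g2 <- run_sensitivity_grid(st$model, st$shares, st$phi, st$dependence,
                             factors = f2)
  expect_identical(g$results, g2$results)

  expect_error(sensitivity_factors(names = c("a", "a")), "duplicate")
  expect_error(validate_factors <- sensitivity_factors(levels = c(0.5, 1.5)),
               "3")
})

test_that("dependence-source comparison is zero for identical sources", {
  st <- get_study()
  cmp <- compare_dependence_sources(st$model, st$shares, st$phi,
                                    st$dependence, st$dependence)
  expect_equal(cmp$headline_relative_change_pct, 0, tolerance = 1e-9)
  expect_true(all(abs(cmp$shock_delta$delta) < 1e-12))
})

test_that("uniformly lower dependence ratios shrink the welfare loss", {
  st <- get_study()
  older <- st$dependence
  older$D_mean <- older$D_mean * 0.6
  older$D_min <- older$D_min * 0.6
  older$D_max <- older$D_max * 0.6
  cmp <- compare_dependence_sources(st$model, st$shares, st$phi,
                                    st$dependence, older)
  expect_lt(abs(cmp$world_total_b), abs(cmp$world_total_a))
  expect_gt(cmp$headline_relative_change_pct, 0)
  expect_true(all(cmp$shock_delta$delta <= 1e-12))

  mismatched <- older[-1, ]
  expect_error(
    compare_dependence_sources(st$model, st$shares, st$phi,
                               st$dependence, mismatched),
    "crop sets")
})

test_that("weighted regression recovers planted relationships", {
  # exact line y = 2x + 1: weights are irrelevant, fit is perfect
  votes <- tibble::tibble(
    member_state = sprintf("MS%d", 1:5),
    rejection_share_nrl = NA_real_,
    rejection_share_sur = NA_real_,
    population = c(1, 5, 2, 7, 3))
  x <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  votes$rejection_share_nrl <- 2 * x + 0.1
  votes$rejection_share_sur <- 2 * x + 0.1
  wf <- tibble::tibble(member_state = votes$member_state,
                       welfare_change = x)
  fit <- suppressWarnings(vote_association(votes, wf))
  nrl <- fit[fit$proposal == "nrl", ]
  expect_equal(nrl$slope, 2, tolerance = 1e-9)
  expect_equal(nrl$intercept, 0.1, tolerance = 1e-9)
  expect_equal(nrl$r_squared, 1, tolerance = 1e-9)
  expect_equal(nrl$n, 5)

  # constant response: zero slope
  votes2 <- votes
  votes2$rejection_share_nrl <- 0.4
  votes2$rejection_share_sur <- 0.4
  fit2 <- suppressWarnings(vote_association(votes2, wf))
  expect_equal(fit2$slope[fit2$proposal == "avg"], 0, tolerance = 1e-9)

  # three points (0,0), (1,1), (2,4) with weights (1,1,2): the weighted
  # normal equations give slope 23/11 and intercept -4/11
  votes3 <- tibble::tibble(member_state = c("a", "b", "c"),
                           rejection_share_nrl = c(0, 1, 4) / 4, # y/4 in [0,1]
                           rejection_share_sur = 0.5,
                           population = c(1, 1, 2))
  wf3 <- tibble::tibble(member_state = c("a", "b", "c"),
                        welfare_change = c(0, 1, 2))
  fit3 <- suppressWarnings(vote_association(votes3, wf3))
  nrl3 <- fit3[fit3$proposal == "nrl", ]
  # response was scaled by 1/4, so slope and intercept scale the same way
  expect_equal(4 * nrl3$slope, 23 / 11, tolerance = 1e-9)
  expect_equal(4 * nrl3$intercept, -4 / 11, tolerance = 1e-9)

  expect_error(vote_association(votes3[1:2, ], wf3), "at least 3")
})
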