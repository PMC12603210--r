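# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The default 6-region x 6-commodity synthetic study, calibrated.
get_study <- function(seed = 42) {
  key <- paste0("study", seed)
  if (is.null(.fixture_cache[[key]])) {
    st <- generate_synthetic_study(synth_config(seed = seed))
    st$model <- calibrate_baseline(st$baseline)
    .fixture_cache[[key]] <- st
  }
  .fixture_cache[[key]]
}

get_mean_eq <- function(seed = 42) {
  key <- paste0("eq", seed)
  if (is.null(.fixture_cache[[key]])) {
    st <- get_study(seed)
    .fixture_cache[[key]] <- solve_equilibrium(
      st$model, shocks_at_level(st$shocks, "mean"))
  }
  .fixture_cache[[key]]
}

# Closed one-region, one-commodity market with unit baseline (p0 = q0 = 1).
closed_market_model <- function(eps_supply = 0.5, eps_demand = -0.5,
                                eta = 0, lambda = 0) {
  regions <- tibble::tibble(
    region_id = "A", name = "A", in_europe = TRUE, in_eu = TRUE,
    gdp = 100, population = 10, households = 5,
    land_endowment = 2, lambda_land = lambda)
  comm <- tibble::tibble(commodity_id = "x", group = "cereals",
                         pollination_dependent = TRUE)
  market <- tibble::tibble(region_id = "A", commodity_id = "x",
                           production = 1, demand = 1,
                           producer_price = 1, area = 1)
  trade <- tibble::tibble(origin = character(), destination = character(),
                          commodity_id = character(), qty = numeric())
  wedges <- tibble::tibble(origin = character(), destination = character(),
                           commodity_id = character(), tau = numeric())
  el <- tibble::tibble(region_id = "A", commodity_id = "x",
                       eps_supply = eps_supply, eta_yield = eta,
                       eps_demand = eps_demand,
                       sigma_top = 2, sigma_origin = 2)
  calibrate_baseline(ps_baseline(regions, comm, market, trade, wedges, el))
}

# Two mirror-image regions (one European, one not) trading symmetrically.
symmetric_two_region_baseline <- function(tau = 0.1) {
  regions <- tibble::tibble(
    region_id = c("A", "B"), name = c("A", "B"),
    in_europe = c(TRUE, FALSE), in_eu = c(TRUE, FALSE),
    gdp = 1e4, population = 100, households = 40,
    land_endowment = 30, lambda_land = 0.1)
  comm <- tibble::tibble(commodity_id = "x", group = "vegetables_fruits",
                         pollination_dependent = TRUE)
  market <- tibble::tibble(
    region_id = c("A", "B"), commodity_id = "x",
    production = 100, demand = 100, producer_price = 10, area = 25)
  trade <- tibble::tibble(origin = c("A", "B"), destination = c("B", "A"),
                          commodity_id = "x", qty = 10)
  wedges <- tibble::tibble(origin = c("A", "B"), destination = c("B", "A"),
                           commodity_id = "x", tau = tau)
  el <- tibble::tibble(region_id = c("A", "B"), commodity_id = "x",
                       eps_supply = 0.5, eta_yield = 0.2,
                       eps_demand = -0.5, sigma_top = 2, sigma_origin = 3)
  ps_baseline(regions, comm, market, trade, wedges, el)
}
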