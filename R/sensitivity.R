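#' Standard scenario indicator set
#'
#' The compact set of headline indicators reported for every scenario run:
#' welfare components by bloc, value-weighted yield/production/price changes
#' and physical land-use change for Europe and the world, plus (when a
#' nutrient table is supplied) the EU all-food vitamin A change.
#'
#' @param model A `ps_model`.
#' @param eq A `ps_equilibrium`.
#' @param coefficients Optional nutrient coefficient table.
#' @return Tibble `(indicator, value)`.
#' @export
scenario_indicators <- function(model, eq, coefficients = NULL) {
  rg <- model$baseline$regions
  wf <- bloc_welfare(welfare_account(model, eq), rg)
  pick <- function(b, col) {
    v <- wf[[col]][wf$bloc == b]
    if (length(v) == 0) NA_real_ else v
  }
  world_blocs <- tibble(region_id = rg$region_id, bloc = "world")
  eur_blocs <- tibble(region_id = rg$region_id,
                      bloc = ifelse(rg$in_europe, "europe", "extra_europe"))
  agg_w <- aggregate_outputs(model, eq, blocs = world_blocs, by_group = FALSE)
  agg_e <- aggregate_outputs(model, eq, blocs = eur_blocs, by_group = FALSE)
  gete <- function(df, b, col) {
    v <- df[[col]][df$bloc == b]
    if (length(v) == 0) NA_real_ else v
  }
  dep_ids <- model$baseline$commodities$commodity_id[
    model$baseline$commodities$pollination_dependent]
  dep_prod_pct <- function(region_ids) {
    base <- model$baseline$market |>
      filter(.data$region_id %in% region_ids,
             .data$commodity_id %in% dep_ids)
    scen <- eq$state |>
      filter(.data$region_id %in% region_ids,
             .data$commodity_id %in% dep_ids)
    100 * (sum(scen$supply) / sum(base$production) - 1)
  }
  out <- tibble(
    indicator = c("welfare_total_world", "welfare_total_europe",
                  "welfare_total_eu", "welfare_total_extra_europe",
                  "delta_cs_eu", "delta_cs_world", "delta_ps_world",
                  "yield_pct_europe", "production_pct_europe",
                  "production_pct_world", "price_pct_europe",
                  "land_pct_europe", "land_pct_world",
                  "dependent_production_pct_europe",
                  "dependent_production_pct_extra_europe"),
    value = c(pick("world", "total"), pick("europe", "total"),
              pick("eu", "total"), pick("extra_europe", "total"),
              pick("eu", "delta_cs"), pick("world", "delta_cs"),
              pick("world", "delta_ps"),
              gete(agg_e, "europe", "yield_pct"),
              gete(agg_e, "europe", "production_pct"),
              gete(agg_w, "world", "production_pct"),
              gete(agg_e, "europe", "price_pct"),
              gete(agg_e, "europe", "land_pct"),
              gete(agg_w, "world", "land_pct"),
              dep_prod_pct(rg$region_id[rg$in_europe]),
              dep_prod_pct(rg$region_id[!rg$in_europe])))
  if (!is.null(coefficients)) {
    nut <- nutrition_change_report(model, eq, coefficients)
    va <- nut |>
      filter(.data$bloc == "eu", .data$group == "all_food",
             .data$nutrient == "vitA")
    out <- bind_rows(out, tibble(indicator = "vita_pct_eu",
                                 value = va$pct_change[1]))
  }
  out
}

#' Run the three confidence-interval scenarios
#'
#' Solves the model at the low, mean and high shock levels of a
#' confidence-bounded shock table and reports per-indicator envelopes
#' (minimum, mean-scenario value, maximum over the three runs). Any
#' non-converged member run fails the whole call.
#'
#' @param model A `ps_model`.
#' @param shock_table Shock table with `s_low`, `s_mean`, `s_high` columns
#'   (see [build_shock_table()]).
#' @param coefficients Optional nutrient coefficient table forwarded to
#'   [scenario_indicators()].
#' @param control Solver settings.
#' @return A `ps_ci_run` list: `runs` (named list of equilibria),
#'   `indicators` (long tibble with a `level` column) and `envelope`
#'   (per indicator: low/mean/high values plus env_min/env_max).
#' @export
run_ci_scenarios <- function(model, shock_table, coefficients = NULL,
                             control = solver_control()) {
  levels <- c("low", "mean", "high")
  runs <- purrr::map(levels, function(lv) {
    solve_equilibrium(model, shocks_at_level(shock_table, lv),
                      control = control)
  })
  names(runs) <- levels
  ind <- purrr::imap(runs, function(eq, lv) {
    mutate(scenario_indicators(model, eq, coefficients), level = lv)
  }) |>
    bind_rows()
  envelope <- ind |>
    tidyr::pivot_wider(names_from = "level", values_from = "value") |>
    mutate(env_min = pmin(.data$low, .data$mean, .data$high),
           env_max = pmax(.data$low, .data$mean, .data$high))
  structure(list(runs = runs, indicators = ind, envelope = envelope),
            class = "ps_ci_run")
}

#' Sensitivity factor design
#'
#' The four-factor design of the sensitivity grid: multiplicative levels
#' applied to the wild-pollinator contribution, the dependence ratios, the
#' supply elasticities, and the Armington trade elasticities (both nests
#' scaled jointly). Each factor has exactly three levels with the central
#' level 1.0 (the core scenario).
#'
#' @param levels Numeric vector of three multipliers including 1.0; default
#'   `c(0.5, 1, 1.5)`.
#' @param names Factor names; duplicates are rejected.
#' @return Named list of level vectors.
#' @export
sensitivity_factors <- function(levels = c(0.5, 1, 1.5),
                                names = c("wild_contribution",
                                          "dependence_ratio",
                                          "supply_elasticity",
                                          "trade_elasticity")) {
  if (anyDuplicated(names) > 0) {
    stop_bad_input("duplicate sensitivity factor names")
  }
  factors <- lapply(names, function(n) levels)
  names(factors) <- names
  validate_factors(factors)
  factors
}

validate_factors <- function(factors) {
  if (anyDuplicated(names(factors)) > 0) {
    stop_bad_input("duplicate sensitivity factor names")
  }
  ok <- vapply(factors, function(lv) {
    length(lv) == 3 && any(abs(lv - 1) < 1e-12) && all(lv > 0)
  }, logical(1))
  if (!all(ok)) {
    stop_bad_input(
      "every sensitivity factor needs exactly 3 positive levels incl. 1.0")
  }
  known <- c("wild_contribution", "dependence_ratio", "supply_elasticity",
             "trade_elasticity")
  unknown <- setdiff(names(factors), known)
  if (length(unknown) > 0) {
    stop_bad_input("unknown sensitivity factor(s): %s",
                   paste(unknown, collapse = ", "))
  }
  invisible(factors)
}

scale_model_elasticities <- function(model, supply_mult = 1, trade_mult = 1) {
  model$arr$ES <- model$arr$ES * supply_mult
  model$arr$S1 <- model$arr$S1 * trade_mult
  model$arr$S2 <- model$arr$S2 * trade_mult
  model
}

scale_dependence <- function(dependence, mult) {
  dep <- as_tibble(dependence)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  dep$D_mean <- clamp(dep$D_mean * mult)
  if ("D_min" %in% names(dep)) dep$D_min <- clamp(dep$D_min * mult)
  if ("D_max" %in% names(dep)) dep$D_max <- clamp(dep$D_max * mult)
  dep
}

scale_phi <- function(phi, mult) {
  phi <- as_tibble(phi)
  phi$phi <- pmin(pmax(phi$phi * mult, 0), 1)
  phi
}

#' Full-factorial sensitivity grid
#'
#' Runs the complete factorial of the sensitivity factor levels (3^k runs;
#' 81 for the default four factors), re-deriving the shock table and
#' re-solving the model for every level tuple. The all-central tuple is the
#' core scenario. The run is deterministic: no randomness is involved.
#'
#' @param model A `ps_model`.
#' @param shares,phi,dependence Shock-engine inputs (see
#'   [build_shock_table()]); dependence-side factors rescale these
#'   (clamped to `[0, 1]`), elasticity factors rescale the model.
#' @param factors Output of [sensitivity_factors()].
#' @param coefficients Optional nutrient coefficient table.
#' @param control Solver settings.
#' @return A `ps_grid` list: `results` (one row per run: factor levels plus
#'   each indicator as a column) and `summary` (median, IQR, min, max per
#'   indicator).
#' @export
run_sensitivity_grid <- function(model, shares, phi, dependence,
                                 factors = sensitivity_factors(),
                                 coefficients = NULL,
                                 control = solver_control()) {
  validate_factors(factors)
  regions <- model$baseline$regions
  grid <- tidyr::expand_grid(!!!factors)
  mult_of <- function(row, name) {
    if (name %in% names(row)) row[[name]] else 1
  }
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    dep_i <- scale_dependence(dependence, mult_of(row, "dependence_ratio"))
    phi_i <- scale_phi(phi, mult_of(row, "wild_contribution"))
    model_i <- scale_model_elasticities(
      model,
      supply_mult = mult_of(row, "supply_elasticity"),
      trade_mult = mult_of(row, "trade_elasticity"))
    shocks <- build_shock_table(shares, phi_i, dep_i, regions)
    eq <- solve_equilibrium(model_i, shocks_at_level(shocks, "mean"),
                            control = control)
    ind <- scenario_indicators(model_i, eq, coefficients)
    bind_cols(row, tidyr::pivot_wider(ind, names_from = "indicator",
                                      values_from = "value"))
  })
  results <- bind_rows(rows)
  ind_cols <- setdiff(names(results), names(factors))
  summary <- results |>
    tidyr::pivot_longer(all_of(ind_cols), names_to = "indicator",
                        values_to = "value") |>
    group_by(.data$indicator) |>
    summarise(median = median(.data$value),
              q25 = quantile(.data$value, 0.25, names = FALSE),
              q75 = quantile(.data$value, 0.75, names = FALSE),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop")
  structure(list(results = results, summary = summary, factors = factors),
            class = "ps_grid")
}

#' Compare two dependence-ratio sources
#'
#' Runs the identical shock-to-welfare pipeline with two alternative
#' crop-dependence tables (e.g. a recent review versus an older source) and
#' reports the headline relative difference in the magnitude of the world
#' welfare loss, alongside per-commodity shock deltas.
#'
#' @param model A `ps_model`.
#' @param shares,phi Shock-engine inputs shared by both runs.
#' @param dependence_a Reference dependence table.
#' @param dependence_b Alternative dependence table; must cover the same
#'   crop set as `dependence_a`.
#' @param control Solver settings.
#' @return List with both welfare tables, the per-commodity mean shocks
#'   under each source, and `headline_relative_change_pct` (positive when
#'   the alternative source implies a smaller world welfare loss).
#' @export
compare_dependence_sources <- function(model, shares, phi, dependence_a,
                                       dependence_b,
                                       control = solver_control()) {
  crops_a <- sort(unique(as_tibble(dependence_a)$crop_id))
  crops_b <- sort(unique(as_tibble(dependence_b)$crop_id))
  if (!identical(crops_a, crops_b)) {
    stop_bad_input("dependence sources cover different crop sets")
  }
  regions <- model$baseline$regions
  run_one <- function(dep) {
    shocks <- build_shock_table(shares, phi, dep, regions)
    eq <- solve_equilibrium(model, shocks_at_level(shocks, "mean"),
                            control = control)
    wf <- bloc_welfare(welfare_account(model, eq), regions)
    list(shocks = shocks, eq = eq, welfare = wf,
         world_total = wf$total[wf$bloc == "world"])
  }
  a <- run_one(dependence_a)
  b <- run_one(dependence_b)
  shock_delta <- a$shocks |>
    group_by(.data$commodity_id) |>
    summarise(s_mean_a = mean(.data$s_mean), .groups = "drop") |>
    left_join(
      b$shocks |>
        group_by(.data$commodity_id) |>
        summarise(s_mean_b = mean(.data$s_mean), .groups = "drop"),
      by = "commodity_id") |>
    mutate(delta = .data$s_mean_b - .data$s_mean_a)
  list(
    welfare_a = a$welfare, welfare_b = b$welfare,
    world_total_a = a$world_total, world_total_b = b$world_total,
    shock_delta = shock_delta,
    headline_relative_change_pct = relative_change(
      abs(a$world_total), abs(b$world_total), digits = Inf))
}

#' Population-weighted vote association
#'
#' Descriptive weighted least-squares regression of the share of members of
#' parliament rejecting biodiversity-related proposals on the projected
#' consumer welfare change (share of GDP), weighted by member-state
#' population. Reported per proposal (nature-restoration and
#' pesticide-reduction votes) and for their average; the association does
#' not imply causality.
#'
#' @param votes Tibble `(member_state, rejection_share_nrl,
#'   rejection_share_sur, population)`; shares in `[0, 1]`.
#' @param welfare Tibble `(member_state, welfare_change)`; typically the
#'   consumer-surplus change as a share of GDP.
#' @return A `ps_association` tibble `(proposal, slope, intercept,
#'   r_squared, p_value, n)`; fitted `lm` objects are kept in the
#'   `"fits"` attribute.
#' @export
vote_association <- function(votes, welfare) {
  votes <- as_tibble(votes)
  assert_columns(votes, c("member_state", "rejection_share_nrl",
                          "rejection_share_sur", "population"), "votes")
  assert_fraction(votes$rejection_share_nrl, "rejection_share_nrl")
  assert_fraction(votes$rejection_share_sur, "rejection_share_sur")
  welfare <- as_tibble(welfare)
  assert_columns(welfare, c("member_state", "welfare_change"), "welfare")
  df <- inner_join(votes, welfare, by = "member_state")
  if (nrow(df) < 3) stop_bad_input("need at least 3 matched member states")
  if (any(df$population <= 0)) stop_bad_input("weights must be > 0")
  df$rejection_share_avg <-
    (df$rejection_share_nrl + df$rejection_share_sur) / 2
  fit_one <- function(col) {
    lm(stats::reformulate("welfare_change", response = col),
       data = df, weights = df$population)
  }
  proposals <- c(nrl = "rejection_share_nrl", sur = "rejection_share_sur",
                 avg = "rejection_share_avg")
  fits <- lapply(proposals, fit_one)
  out <- purrr::imap(fits, function(fit, nm) {
    sm <- summary(fit)
    tibble(proposal = nm,
           slope = coef(fit)[["welfare_change"]],
           intercept = coef(fit)[["(Intercept)"]],
           r_squared = sm$r.squared,
           p_value = sm$coefficients["welfare_change", "Pr(>|t|)"],
           n = nrow(df))
  }) |>
    bind_rows()
  attr(out, "fits") <- fits
  attr(out, "data") <- df
  class(out) <- c("ps_association", class(out))
  out
}
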