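#' Per-capita daily nutrient availability
#'
#' Converts consumed quantities into per-capita, per-day availability of
#' each nutrient: `sum_c q_c * kappa_c / population / 365`. Availability is
#' supply reaching consumers, not intake adjusted for waste.
#'
#' @param consumption Tibble `(region_id, commodity_id, qty)`; `qty` in
#'   product tons.
#' @param coefficients Tibble `(commodity_id, kcal_per_ton, vitA_per_ton,
#'   folate_per_ton)`; nutrient units are carried opaquely (per product
#'   ton). Every consumed commodity must have a row.
#' @param population Tibble `(region_id, population)` (or a single number
#'   for a single-region table).
#' @return Tibble `(region_id, nutrient, per_capita_daily)`.
#' @export
nutrient_availability <- function(consumption, coefficients, population) {
  consumption <- as_tibble(consumption)
  assert_columns(consumption, c("region_id", "commodity_id", "qty"),
                 "consumption")
  coefficients <- as_tibble(coefficients)
  assert_columns(coefficients,
                 c("commodity_id", "kcal_per_ton", "vitA_per_ton",
                   "folate_per_ton"), "coefficients")
  if (any(coefficients$kcal_per_ton < 0 | coefficients$vitA_per_ton < 0 |
            coefficients$folate_per_ton < 0)) {
    stop_bad_input("nutrient coefficients must be >= 0")
  }
  if (is.numeric(population)) {
    population <- tibble(region_id = unique(consumption$region_id),
                         population = population)
  }
  assert_columns(population, c("region_id", "population"), "population")
  if (any(population$population <= 0)) {
    stop_bad_input("population must be > 0")
  }
  missing <- setdiff(unique(consumption$commodity_id),
                     coefficients$commodity_id)
  if (length(missing) > 0) {
    stop_bad_input("no nutrient coefficients for consumed commodity: %s",
                   paste(missing, collapse = ", "))
  }
  consumption |>
    inner_join(coefficients, by = "commodity_id") |>
    tidyr::pivot_longer(cols = c("kcal_per_ton", "vitA_per_ton",
                                 "folate_per_ton"),
                        names_to = "nutrient", values_to = "kappa") |>
    mutate(nutrient = sub("_per_ton$", "", .data$nutrient)) |>
    group_by(.data$region_id, .data$nutrient) |>
    summarise(total = sum(.data$qty * .data$kappa), .groups = "drop") |>
    inner_join(as_tibble(population), by = "region_id") |>
    mutate(per_capita_daily = .data$total / .data$population / 365) |>
    select("region_id", "nutrient", "per_capita_daily")
}

#' Food-security change report
#'
#' Percent change in per-capita availability of kilocalories, vitamin A and
#' folate between the baseline and a shocked equilibrium, per region bloc
#' and crop group (`vegetables_fruits` and `all_food`). Population cancels
#' in the percent change, so the report is a consumption-weighted nutrient
#' aggregate change.
#'
#' @param model A `ps_model`.
#' @param eq A `ps_equilibrium`.
#' @param coefficients Nutrient coefficient table (see
#'   [nutrient_availability()]).
#' @param blocs Optional tibble `(region_id, bloc)`; defaults to eu /
#'   non_eu_europe / extra_europe from the baseline flags.
#' @return A `ps_nutrition` tibble
#'   `(bloc, group, nutrient, baseline, scenario, pct_change)`.
#' @export
nutrition_change_report <- function(model, eq, coefficients, blocs = NULL) {
  stopifnot(inherits(model, "ps_model"), inherits(eq, "ps_equilibrium"))
  if (is.null(blocs)) {
    rg <- model$baseline$regions
    blocs <- tibble(
      region_id = rg$region_id,
      bloc = ifelse(rg$in_eu, "eu",
                    ifelse(rg$in_europe, "non_eu_europe", "extra_europe")))
  }
  blocs <- as_tibble(blocs)
  comm <- model$baseline$commodities
  groups <- list(
    vegetables_fruits = comm$commodity_id[comm$group == "vegetables_fruits"],
    all_food = comm$commodity_id)
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    stop_bad_input("empty commodity group: %s", paste(empty, collapse = ", "))
  }
  coefficients <- as_tibble(coefficients)
  assert_columns(coefficients,
                 c("commodity_id", "kcal_per_ton", "vitA_per_ton",
                   "folate_per_ton"), "coefficients")
  missing <- setdiff(comm$commodity_id, coefficients$commodity_id)
  if (length(missing) > 0) {
    stop_bad_input("no nutrient coefficients for commodity: %s",
                   paste(missing, collapse = ", "))
  }
  base <- model$baseline$market |>
    select("region_id", "commodity_id", qty = "demand")
  scen <- eq$state |>
    select("region_id", "commodity_id", qty = "demand")
  long <- function(df, label) {
    df |>
      inner_join(blocs, by = "region_id") |>
      inner_join(coefficients, by = "commodity_id") |>
      tidyr::pivot_longer(cols = c("kcal_per_ton", "vitA_per_ton",
                                   "folate_per_ton"),
                          names_to = "nutrient", values_to = "kappa") |>
      mutate(nutrient = sub("_per_ton$", "", .data$nutrient),
             when = label)
  }
  both <- bind_rows(long(base, "baseline"), long(scen, "scenario"))
  out <- purrr::map(names(groups), function(g) {
    both |>
      filter(.data$commodity_id %in% groups[[g]]) |>
      group_by(.data$bloc, .data$nutrient, .data$when) |>
      summarise(total = sum(.data$qty * .data$kappa), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "when", values_from = "total") |>
      mutate(group = g,
             pct_change = ifelse(.data$baseline > 0,
                                 100 * (.data$scenario / .data$baseline - 1),
                                 0))
  }) |>
    bind_rows() |>
    select("bloc", "group", "nutrient", "baseline", "scenario", "pct_change")
  class(out) <- c("ps_nutrition", class(out))
  out
}
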