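#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_errorbar
#'   geom_boxplot geom_abline geom_hline facet_wrap labs theme_minimal
#'   autoplot position_dodge geom_jitter
NULL

#' @export
ggplot2::autoplot

#' Bar chart of commodity shocks with confidence bounds
#'
#' @param shocks A shock table with `s_mean`, `s_low`, `s_high` (fractions),
#'   e.g. from [build_shock_table()] or [derive_shock_bounds()].
#' @param region Optional single region to display; default averages over
#'   regions with a non-zero shock.
#' @return A ggplot object (shocks shown in percent).
#' @export
plot_shock_table <- function(shocks, region = NULL) {
  df <- as_tibble(shocks)
  if (!is.null(region)) {
    df <- filter(df, .data$region_id == region)
  } else {
    df <- df |>
      filter(.data$s_mean > 0) |>
      group_by(.data$commodity_id) |>
      summarise(across(c("s_mean", "s_low", "s_high"), mean),
                .groups = "drop")
  }
  ggplot(df, aes(x = stats::reorder(.data$commodity_id, -.data$s_mean),
                 y = 100 * .data$s_mean)) +
    geom_col(fill = "#8c6bb1") +
    geom_errorbar(aes(ymin = 100 * .data$s_low, ymax = 100 * .data$s_high),
                  width = 0.25) +
    labs(x = NULL, y = "productivity shock (%)",
         title = "Commodity productivity shocks with 95% bounds") +
    theme_minimal()
}

#' Equilibrium impact plot
#'
#' Percentage changes in producer price, supply, demand and land by
#' commodity, one facet per variable, coloured by region.
#'
#' @param object A `ps_equilibrium`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_equilibrium <- function(object, ...) {
  df <- object$state |>
    mutate(price = 100 * (.data$price_ratio - 1)) |>
    select("region_id", "commodity_id", "price", "supply", "demand") |>
    tidyr::pivot_longer(cols = c("price", "supply", "demand"),
                        names_to = "variable", values_to = "value")
  ggplot(df, aes(x = .data$commodity_id, y = .data$value,
                 colour = .data$region_id)) +
    geom_point() +
    facet_wrap(~variable, scales = "free_y") +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = NULL, y = NULL, colour = "region",
         title = "Post-shock equilibrium by commodity") +
    theme_minimal()
}

#' Welfare decomposition plot
#'
#' @param object A `ps_welfare` tibble from [welfare_account()].
#' @param ... Unused.
#' @return A ggplot object: stacked CS/PS/Gov components per region with
#'   the total overlaid.
#' @export
autoplot.ps_welfare <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("delta_cs", "delta_ps", "delta_gov"),
                        names_to = "component", values_to = "value")
  ggplot(df, aes(x = .data$region_id, y = .data$value,
                 fill = .data$component)) +
    geom_col() +
    geom_point(data = as_tibble(object),
               aes(x = .data$region_id, y = .data$total),
               inherit.aes = FALSE, shape = 18, size = 3) +
    labs(x = NULL, y = "welfare change (value units)",
         title = "Welfare decomposition by region",
         fill = NULL) +
    theme_minimal()
}

#' Sensitivity grid distribution plot
#'
#' One box per indicator over all factorial runs, with the all-central
#' (core) run marked.
#'
#' @param object A `ps_grid`.
#' @param indicators Optional subset of indicator names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_grid <- function(object, indicators = NULL, ...) {
  long <- tidy.ps_grid(object)
  if (!is.null(indicators)) {
    long <- filter(long, .data$indicator %in% indicators)
  }
  central <- object$results
  for (f in names(object$factors)) {
    central <- filter(central, abs(central[[f]] - 1) < 1e-12)
  }
  central_long <- central |>
    tidyr::pivot_longer(cols = -all_of(names(object$factors)),
                        names_to = "indicator", values_to = "value")
  if (!is.null(indicators)) {
    central_long <- filter(central_long, .data$indicator %in% indicators)
  }
  ggplot(long, aes(x = .data$indicator, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    geom_point(data = central_long, colour = "red", shape = 18, size = 3) +
    facet_wrap(~indicator, scales = "free") +
    labs(x = NULL, y = NULL,
         title = "Sensitivity grid: distribution across factorial runs",
         subtitle = "red diamond = core (all-central) run") +
    theme_minimal()
}

#' Vote-association scatter plot
#'
#' Member-state scatter of rejection shares against the welfare change,
#' point size by population weight, with the fitted weighted regression
#' lines per proposal.
#'
#' @param object A `ps_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_association <- function(object, ...) {
  df <- attr(object, "data")
  long <- df |>
    tidyr::pivot_longer(cols = c("rejection_share_nrl",
                                 "rejection_share_sur",
                                 "rejection_share_avg"),
                        names_to = "proposal", values_to = "rejection") |>
    mutate(proposal = sub("rejection_share_", "", .data$proposal))
  coefs <- as_tibble(object)
  ggplot(long, aes(x = .data$welfare_change, y = .data$rejection,
                   colour = .data$proposal)) +
    geom_point(aes(size = .data$population), alpha = 0.6) +
    geom_abline(data = coefs,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = .data$proposal)) +
    labs(x = "consumer welfare change (share of GDP)",
         y = "share of members rejecting",
         title = "Welfare exposure vs voting behaviour",
         size = "population") +
    theme_minimal()
}
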