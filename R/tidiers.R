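#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an equilibrium into per-cell percentage changes
#'
#' @param x A `ps_equilibrium`.
#' @param ... Unused.
#' @return Long tibble `(region_id, commodity_id, variable, value,
#'   pct_change)` for producer price, supply, demand, area and realized
#'   yield relative to the calibrated baseline.
#' @export
tidy.ps_equilibrium <- function(x, ...) {
  x$state |>
    select("region_id", "commodity_id", "producer_price", "supply",
           "demand", "area", "price_ratio", "yield_multiplier", "shock") |>
    tidyr::pivot_longer(cols = c("producer_price", "supply", "demand",
                                 "area", "price_ratio", "yield_multiplier"),
                        names_to = "variable", values_to = "value")
}

#' @rdname tidy.ps_equilibrium
#' @export
glance.ps_equilibrium <- function(x, ...) {
  d <- x$diagnostics
  tibble(iterations = d$iterations,
         max_residual = d$max_residual,
         converged = d$converged,
         n_regions = length(unique(x$state$region_id)),
         n_commodities = length(unique(x$state$commodity_id)))
}

#' Tidy methods for the vote-association fit
#'
#' @param x A `ps_association` from [vote_association()].
#' @param ... Unused.
#' @return `tidy()` returns the per-proposal coefficient table; `glance()`
#'   one row per proposal with fit statistics.
#' @export
tidy.ps_association <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(cols = c("slope", "intercept"),
                        names_to = "term", values_to = "estimate") |>
    select("proposal", "term", "estimate", "p_value")
}

#' @rdname tidy.ps_association
#' @export
glance.ps_association <- function(x, ...) {
  select(as_tibble(x), "proposal", "r_squared", "p_value", "n")
}

#' Tidy a sensitivity grid
#'
#' @param x A `ps_grid` from [run_sensitivity_grid()].
#' @param ... Unused.
#' @return `tidy()` returns the long run-by-indicator table; `glance()` a
#'   one-row description of the design.
#' @export
tidy.ps_grid <- function(x, ...) {
  x$results |>
    tidyr::pivot_longer(cols = -all_of(names(x$factors)),
                        names_to = "indicator", values_to = "value")
}

#' @rdname tidy.ps_grid
#' @export
glance.ps_grid <- function(x, ...) {
  tibble(n_runs = nrow(x$results),
         n_factors = length(x$factors),
         n_levels = length(x$factors[[1]]),
         n_indicators = ncol(x$results) - length(x$factors))
}
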