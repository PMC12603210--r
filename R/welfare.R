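#' Money-metric consumer surplus change
#'
#' Marshallian surplus change for a price move `p0 -> p1`:
#' `-(integral of D(p) dp from p0 to p1)`, negative when the price rises.
#' With no income effects in the partial-equilibrium demand curve this
#' coincides with the compensating income change. For the calibrated
#' constant-elasticity demand `D(p) = q0 (p/p0)^eps` the closed form is
#' used (`eps = -1` by the log form); alternatively any demand function can
#' be supplied and is integrated numerically.
#'
#' @param p0,p1 Initial and final price (> 0).
#' @param q0 Quantity demanded at `p0` (for the constant-elasticity form).
#' @param elasticity Demand own-price elasticity (< 0).
#' @param demand Optional function `D(p)`; overrides the closed form.
#' @return Surplus change in the same currency units as `p * q`.
#' @examples
#' consumer_surplus_change(1, 1.2, demand = function(p) 2 - p) # -0.18
#' consumer_surplus_change(1, 1.1111, q0 = 1, elasticity = -0.5)
#' @export
consumer_surplus_change <- function(p0, p1, q0 = NULL, elasticity = NULL,
                                    demand = NULL) {
  if (any(p0 <= 0) || any(p1 <= 0)) stop_bad_input("prices must be > 0")
  if (!is.null(demand)) {
    mapply(function(a, b) {
      -integrate(demand, lower = a, upper = b, rel.tol = 1e-10)$value
    }, p0, p1)
  } else {
    if (is.null(q0) || is.null(elasticity)) {
      stop_bad_input("supply either a demand function or q0 + elasticity")
    }
    cs_closed_form(p0, p1, q0, elasticity)
  }
}

cs_closed_form <- function(p0, p1, q0, eps) {
  r <- p1 / p0
  ifelse(abs(1 + eps) > 1e-9,
         -q0 * p0 * (r^(1 + eps) - 1) / (1 + eps),
         -q0 * p0 * log(r))
}

# Producer surplus under a constant-elasticity supply curve q = k p^eps_s:
# PS(p) = integral_0^p q(t) dt = p q / (1 + eps_s).
ps_level <- function(p, q, eps_s) p * q / (1 + eps_s)

#' Per-region welfare account for a scenario
#'
#' Decomposes the welfare change of an equilibrium (relative to the
#' calibrated baseline) into consumer surplus, producer surplus and
#' government tariff revenue, per region:
#' \itemize{
#'   \item dCS: closed-form Marshallian integral under each region's
#'     calibrated composite demand curve;
#'   \item dPS: change in profit over variable cost under the calibrated
#'     constant-elasticity supply curve, `p q / (1 + eps_s)` per market;
#'   \item dGov: change in ad-valorem wedge revenue on the region's imports.
#' }
#' `total = delta_cs + delta_ps + delta_gov` exactly. Relative shares use
#' the region's GDP and a baseline agri-food welfare denominator
#' (consumption expenditure + baseline producer surplus + baseline tariff
#' revenue; the unbounded Marshallian consumer surplus of inelastic demand
#' makes expenditure the natural finite proxy).
#'
#' @param model A `ps_model`.
#' @param eq A `ps_equilibrium` solved from `model`.
#' @return A `ps_welfare` tibble, one row per region, in the value units of
#'   `price x quantity` (thousand EUR for kt and EUR/t inputs).
#' @export
welfare_account <- function(model, eq) {
  stopifnot(inherits(model, "ps_model"), inherits(eq, "ps_equilibrium"))
  arr <- model$arr
  it <- eq$internal
  dCS_mat <- cs_closed_form(model$PC0, model$PC0 * it$PCt, arr$D0, arr$ED)
  dCS_mat[arr$D0 == 0] <- 0
  dPS_mat <- ps_level(arr$P0 * it$Pt, it$Q, arr$ES) -
    ps_level(arr$P0, arr$Q0, arr$ES)
  gov1 <- gov0 <- numeric(arr$R)
  for (k in seq_len(arr$C)) {
    p1 <- arr$P0[, k] * it$Pt[, k]
    tau_k <- matrix(arr$TAU[, , k], arr$R, arr$R)
    gov1 <- gov1 + colSums(tau_k * matrix(it$M[, , k], arr$R, arr$R) * p1)
    gov0 <- gov0 + colSums(tau_k * matrix(arr$M0[, , k], arr$R, arr$R) *
                             arr$P0[, k])

  }
  base_ps <- rowSums(ps_level(arr$P0, arr$Q0, arr$ES))
  base_exp <- rowSums(model$PC0 * arr$D0)
  out <- tibble(
    region_id = arr$regions,
    delta_cs = unname(rowSums(dCS_mat)),
    delta_ps = unname(rowSums(dPS_mat)),
    delta_gov = unname(gov1 - gov0)) |>
    mutate(total = .data$delta_cs + .data$delta_ps + .data$delta_gov,
           baseline_welfare = unname(base_exp + base_ps + gov0),
           gdp = model$baseline$regions$gdp[
             match(.data$region_id, model$baseline$regions$region_id)],
           share_of_baseline_welfare = .data$total / .data$baseline_welfare,
           share_of_gdp = .data$total / .data$gdp)
  class(out) <- c("ps_welfare", class(out))
  out
}

#' Producer surplus change by region
#'
#' @inheritParams welfare_account
#' @return Tibble `(region_id, delta_ps)`.
#' @export
producer_surplus_change <- function(model, eq) {
  select(welfare_account(model, eq), "region_id", "delta_ps")
}

#' Tariff (wedge) revenue change by importing region
#'
#' @inheritParams welfare_account
#' @return Tibble `(region_id, delta_gov)`.
#' @export
government_revenue_change <- function(model, eq) {
  select(welfare_account(model, eq), "region_id", "delta_gov")
}

#' Aggregate welfare accounts over a partition of regions
#'
#' Component-wise sums over non-overlapping blocs; adding-up
#' (`total = dCS + dPS + dGov`) is preserved exactly. Shares are recomputed
#' from the aggregated denominators.
#'
#' @param accounts A `ps_welfare` tibble from [welfare_account()].
#' @param blocs Tibble `(region_id, bloc)`; a region in two blocs is an
#'   error (use separate calls for nested blocs such as EU within Europe).
#' @param per_hectare Optional tibble `(bloc, dependent_area)` adding a
#'   per-hectare normalisation of the total.
#' @return Tibble, one row per bloc.
#' @export
aggregate_welfare <- function(accounts, blocs, per_hectare = NULL) {
  blocs <- as_tibble(blocs)
  assert_columns(blocs, c("region_id", "bloc"), "blocs")
  if (anyDuplicated(blocs$region_id) > 0) {
    stop_bad_input("overlapping blocs: a region is assigned twice")
  }
  out <- accounts |>
    inner_join(blocs, by = "region_id") |>
    group_by(.data$bloc) |>
    summarise(across(c("delta_cs", "delta_ps", "delta_gov", "total",
                       "baseline_welfare", "gdp"), sum),
              n_regions = n(), .groups = "drop") |>
    mutate(share_of_baseline_welfare = .data$total / .data$baseline_welfare,
           share_of_gdp = .data$total / .data$gdp)
  if (!is.null(per_hectare)) {
    out <- out |>
      left_join(as_tibble(per_hectare), by = "bloc") |>
      mutate(total_per_hectare = .data$total / .data$dependent_area)
  }
  out
}

#' Standard bloc aggregates (EU, Europe, extra-Europe, world)
#'
#' Convenience wrapper running [aggregate_welfare()] once per (possibly
#' nested) standard bloc defined by the baseline region flags.
#'
#' @param accounts A `ps_welfare` tibble.
#' @param regions The baseline `regions` tibble (with `in_europe`, `in_eu`).
#' @return Tibble with one row per bloc: eu, europe, extra_europe, world.
#' @export
bloc_welfare <- function(accounts, regions) {
  regions <- as_tibble(regions)
  one <- function(ids, name) {
    if (length(ids) == 0) return(NULL)
    aggregate_welfare(accounts, tibble(region_id = ids, bloc = name))
  }
  bind_rows(
    one(regions$region_id[regions$in_eu], "eu"),
    one(regions$region_id[regions$in_europe], "europe"),
    one(regions$region_id[!regions$in_europe], "extra_europe"),
    one(regions$region_id, "world"))
}

#' Willingness-to-pay extrapolation
#'
#' Total annual non-market value from a per-household annual
#' willingness-to-pay and a household count. Report in billions via
#' [euro_billion()].
#'
#' @param wtp_per_household Annual willingness-to-pay per household (EUR).
#' @param households Number of households.
#' @return Total annual value (EUR).
#' @examples
#' euro_billion(wtp_extrapolation(113.5, 193e6)) # 21.9
#' @export
wtp_extrapolation <- function(wtp_per_household, households) {
  if (any(wtp_per_household < 0) || any(households < 0)) {
    stop_bad_input("inputs must be >= 0")
  }
  wtp_per_household * households
}

#' @rdname wtp_extrapolation
#' @param x Value in EUR.
#' @param digits Decimals (half-up) in the billion-EUR report.
#' @export
euro_billion <- function(x, digits = 1) {
  round_half_up(x / 1e9, digits)
}

#' Honeybee-colony replacement cost
#'
#' Cost range of substituting the lost wild-pollination service with
#' additional managed honeybee colonies, total and per hectare of
#' pollination-dependent cropland.
#'
#' @param colonies_added Number of additional colonies.
#' @param cost_per_colony_low,cost_per_colony_high Annual unit cost range
#'   (EUR per colony).
#' @param dependent_area Hectares of pollination-dependent crops (optional;
#'   required for the per-hectare output, and must be > 0 then).
#' @return One-row tibble with `total_low`, `total_high` and, if an area is
#'   given, `per_hectare_low`, `per_hectare_high`.
#' @export
replacement_cost <- function(colonies_added, cost_per_colony_low,
                             cost_per_colony_high, dependent_area = NULL) {
  if (any(c(colonies_added, cost_per_colony_low, cost_per_colony_high) < 0)) {
    stop_bad_input("inputs must be >= 0")
  }
  if (cost_per_colony_low > cost_per_colony_high) {
    stop_bad_input("cost range must be ordered low <= high")
  }
  out <- tibble(total_low = colonies_added * cost_per_colony_low,
                total_high = colonies_added * cost_per_colony_high)
  if (!is.null(dependent_area)) {
    if (dependent_area <= 0) {
      stop_bad_input("dependent_area must be > 0 for per-hectare output")
    }
    out$per_hectare_low <- out$total_low / dependent_area
    out$per_hectare_high <- out$total_high / dependent_area
  }
  out
}

#' Relative change of an alternative versus a reference (percent)
#'
#' `100 * (reference - alternative) / reference`, rounded half-up; e.g. a
#' loss of 27.3 against a reference loss of 34.4 is 20.6% lower.
#'
#' @param reference Reference value (non-zero).
#' @param alternative Alternative value.
#' @param digits Decimals (half-up), default 1; `Inf` disables rounding.
#' @return Percent difference.
#' @examples
#' relative_change(34.4, 27.3) # 20.6
#' @export
relative_change <- function(reference, alternative, digits = 1) {
  if (any(reference == 0)) stop_bad_input("reference must be non-zero")
  pct <- 100 * (reference - alternative) / reference
  if (is.finite(digits)) round_half_up(pct, digits) else pct
}
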