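#' Crop-to-commodity production value shares
#'
#' Converts a region x commodity x crop table of production values into the
#' value shares used to aggregate crop-level pollination dependence up to
#' commodity-level productivity shocks. Within each (region, commodity) cell
#' the member-crop shares are normalised to sum to one.
#'
#' @param production_values Data frame with columns `region_id`,
#'   `commodity_id`, `crop_id`, `value` (production value, any common
#'   currency unit, non-negative).
#' @return A tibble `(region_id, commodity_id, crop_id, share)` with shares
#'   in `[0, 1]` summing to one within each (region, commodity).
#'   Region-commodity cells whose total value is zero are dropped with a
#'   warning.
#' @examples
#' pv <- tibble::tibble(
#'   region_id = "EU1", commodity_id = "othfruit",
#'   crop_id = c("cherry", "plum"), value = c(60, 40)
#' )
#' map_crops_to_commodities(pv)
#' @export
map_crops_to_commodities <- function(production_values) {
  pv <- as_tibble(production_values)
  assert_columns(pv, c("region_id", "commodity_id", "crop_id", "value"),
                 "production_values")
  if (any(!is.finite(pv$value)) || any(pv$value < 0)) {
    stop_bad_input("production values must be finite and non-negative")
  }
  multi <- pv |>
    distinct(.data$crop_id, .data$commodity_id) |>
    count(.data$crop_id) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_bad_input("crop(s) mapped to more than one commodity: %s",
                   paste(multi$crop_id, collapse = ", "))
  }
  shares <- pv |>
    group_by(.data$region_id, .data$commodity_id) |>
    mutate(total = sum(.data$value)) |>
    ungroup()
  zero <- shares |>
    filter(.data$total == 0) |>
    distinct(.data$region_id, .data$commodity_id)
  if (nrow(zero) > 0) {
    warn(sprintf(
      "dropping %d region-commodity cell(s) with zero total production value",
      nrow(zero)))
    shares <- filter(shares, .data$total > 0)
  }
  shares |>
    mutate(share = .data$value / .data$total) |>
    select("region_id", "commodity_id", "crop_id", "share")
}

#' Commodity-level mean productivity shock
#'
#' Aggregates crop-level dependence ratios `D_i` and the commodity's
#' wild-pollinator contribution `phi_c` into the mean productivity shock
#' `s = min(cap, sum_i share_i * phi_c * D_i)` per (region, commodity).
#' The associated yield multiplier is `1 - s`. Full (100%) dependence is
#' capped at a 99.9% shock so post-collapse output stays strictly positive.
#'
#' @param shares Value-share tibble from [map_crops_to_commodities()].
#' @param phi Data frame `(commodity_id, phi)`: share of animal-mediated
#'   pollination delivered by wild (vs managed) pollinators, in `[0, 1]`.
#' @param dependence Data frame with at least `(crop_id, D_mean)`; `D_mean`
#'   is the fraction of the crop's yield attributable to animal pollination.
#' @param cap Maximum emitted shock (default 0.999).
#' @return Tibble `(region_id, commodity_id, s_mean, multiplier_mean)`.
#' @export
compute_commodity_shock <- function(shares, phi, dependence, cap = 0.999) {
  shares <- as_tibble(shares)
  assert_columns(shares, c("region_id", "commodity_id", "crop_id", "share"),
                 "shares")
  assert_columns(phi, c("commodity_id", "phi"), "phi")
  assert_columns(dependence, c("crop_id", "D_mean"), "dependence")
  assert_fraction(phi$phi, "phi")
  assert_fraction(dependence$D_mean, "D_mean")
  assert_fraction(shares$share, "share")

  joined <- shares |>
    inner_join(select(dependence, "crop_id", "D_mean"), by = "crop_id") |>
    left_join(select(as_tibble(phi), "commodity_id", "phi"),
              by = "commodity_id")
  missing_phi <- joined |>
    filter(is.na(.data$phi), .data$D_mean > 0) |>
    distinct(.data$commodity_id)
  if (nrow(missing_phi) > 0) {
    stop_bad_input(
      "no wild-pollinator contribution (phi) for dependent commodity: %s",
      paste(missing_phi$commodity_id, collapse = ", "))
  }
  joined |>
    mutate(phi = ifelse(is.na(.data$phi), 0, .data$phi)) |>
    group_by(.data$region_id, .data$commodity_id) |>
    summarise(
      s_mean = min(cap, sum(.data$share * .data$phi * .data$D_mean)),
      .groups = "drop") |>
    mutate(multiplier_mean = 1 - .data$s_mean)
}

#' Triangular distribution quantile and CDF
#'
#' Closed-form quantile of the triangular distribution with support
#' `[lower, upper]` and mode `mode`; used to put 95% confidence bounds on
#' dependence ratios reported as (min, mean, max) triples.
#'
#' @param p Probability (vector) in `[0, 1]`.
#' @param lower,mode,upper Distribution parameters, `lower <= mode <= upper`.
#' @return Quantile value(s); `triangular_cdf()` returns probabilities.
#' @examples
#' triangular_quantile(0.025, 0, 0.5, 1) # 0.1118
#' @export
triangular_quantile <- function(p, lower, mode, upper) {
  if (any(lower > upper)) stop_bad_input("triangular: lower > upper")
  if (any(mode < lower | mode > upper)) {
    stop_bad_input("triangular: mode outside [lower, upper]")
  }
  assert_fraction(p, "p")
  n <- max(length(p), length(lower), length(mode), length(upper))
  p <- rep_len(p, n); a <- rep_len(lower, n)
  c_ <- rep_len(mode, n); b <- rep_len(upper, n)
  out <- numeric(n)
  degenerate <- (b - a) == 0
  out[degenerate] <- a[degenerate]
  i <- !degenerate
  fc <- (c_[i] - a[i]) / (b[i] - a[i])
  low_branch <- p[i] <= fc
  qi <- numeric(sum(i))
  qi[low_branch] <- a[i][low_branch] +
    sqrt(p[i][low_branch] * (b[i] - a[i])[low_branch] *
           (c_[i] - a[i])[low_branch])
  qi[!low_branch] <- b[i][!low_branch] -
    sqrt((1 - p[i][!low_branch]) * (b[i] - a[i])[!low_branch] *
           (b[i] - c_[i])[!low_branch])
  out[i] <- qi
  out
}

#' @rdname triangular_quantile
#' @param q Quantile (vector) at which to evaluate the CDF.
#' @export
triangular_cdf <- function(q, lower, mode, upper) {
  if (any(lower > upper)) stop_bad_input("triangular: lower > upper")
  n <- max(length(q), length(lower), length(mode), length(upper))
  q <- rep_len(q, n); a <- rep_len(lower, n)
  c_ <- rep_len(mode, n); b <- rep_len(upper, n)
  out <- numeric(n)
  out[q <= a] <- 0
  out[q >= b] <- 1
  mid <- q > a & q < b
  lowb <- mid & q <= c_
  upb <- mid & q > c_
  out[lowb] <- (q[lowb] - a[lowb])^2 / ((b[lowb] - a[lowb]) * (c_[lowb] - a[lowb]))
  out[upb] <- 1 - (b[upb] - q[upb])^2 / ((b[upb] - a[upb]) * (b[upb] - c_[upb]))
  out
}

#' Confidence bounds on commodity shocks
#'
#' Derives low/high shock components for a `coverage` confidence interval by
#' replacing each crop's dependence ratio with the triangular quantiles at
#' `(1 - coverage)/2` and `(1 + coverage)/2` (mode at `D_mean`), then
#' aggregating with the mean-shock formula. The aggregation is comonotone:
#' every crop sits at the same quantile, yielding a single low/mean/high
#' scenario triple. Crops without usable (min, max) bounds (`D_min`/`D_max`
#' missing, or `fallback = TRUE`) contribute their mean contribution scaled
#' by `1 -/+ fallback_pct` instead.
#'
#' @inheritParams compute_commodity_shock
#' @param dependence Data frame `(crop_id, D_mean, D_min, D_max)`; optional
#'   logical column `fallback` forces the proportional fallback for a crop.
#' @param coverage Central interval coverage, in (0, 1); default 0.95.
#' @param fallback_pct Proportional variation for crops without bounds
#'   (default 0.5, i.e. +/-50% of the mean contribution).
#' @return Tibble `(region_id, commodity_id, s_mean, s_low, s_high,
#'   multiplier_mean, multiplier_low, multiplier_high)`.
#' @export
derive_shock_bounds <- function(shares, phi, dependence, coverage = 0.95,
                                fallback_pct = 0.5, cap = 0.999) {
  if (!is.finite(coverage) || coverage < 0 || coverage >= 1) {
    stop_bad_input("coverage must lie in [0, 1)")
  }
  dep <- as_tibble(dependence)
  assert_columns(dep, c("crop_id", "D_mean"), "dependence")
  if (!"D_min" %in% names(dep)) dep$D_min <- NA_real_
  if (!"D_max" %in% names(dep)) dep$D_max <- NA_real_
  if (!"fallback" %in% names(dep)) dep$fallback <- FALSE
  dep <- mutate(dep,
    fallback = .data$fallback | is.na(.data$D_min) | is.na(.data$D_max))
  with_bounds <- filter(dep, !.data$fallback)
  if (nrow(with_bounds) > 0) {
    ok <- with_bounds$D_min <= with_bounds$D_mean &
      with_bounds$D_mean <= with_bounds$D_max
    if (any(!ok)) {
      stop_bad_input("dependence bounds must satisfy D_min <= D_mean <= D_max")
    }
  }
  p_lo <- (1 - coverage) / 2
  p_hi <- (1 + coverage) / 2
  dep <- dep |>
    mutate(
      D_lo = ifelse(.data$fallback, .data$D_mean * (1 - fallback_pct),
                    triangular_quantile(p_lo,
                                        ifelse(.data$fallback, 0, .data$D_min),
                                        .data$D_mean,
                                        ifelse(.data$fallback, 1, .data$D_max))),
      D_hi = ifelse(.data$fallback, .data$D_mean * (1 + fallback_pct),
                    triangular_quantile(p_hi,
                                        ifelse(.data$fallback, 0, .data$D_min),
                                        .data$D_mean,
                                        ifelse(.data$fallback, 1, .data$D_max))))

  s_of <- function(col) {
    compute_commodity_shock(shares, phi,
                            rename(select(dep, "crop_id", all_of(col)),
                                   D_mean = all_of(col)),
                            cap = cap)
  }
  mean_tbl <- s_of("D_mean")
  low_tbl <- rename(select(s_of("D_lo"), -"multiplier_mean"),
                    s_low = "s_mean")
  high_tbl <- rename(select(s_of("D_hi"), -"multiplier_mean"),
                     s_high = "s_mean")
  mean_tbl |>
    left_join(low_tbl, by = c("region_id", "commodity_id")) |>
    left_join(high_tbl, by = c("region_id", "commodity_id")) |>
    mutate(
      # the interval always contains the point estimate: comonotone
      # quantile aggregation can cross the mean when a dependence mode sits
      # at the edge of its support
      s_low = pmin(.data$s_low, .data$s_mean),
      s_high = pmax(.data$s_high, .data$s_mean),
      s_high = pmin(cap, .data$s_high),
      multiplier_low = 1 - .data$s_low,
      multiplier_high = 1 - .data$s_high) |>
    select("region_id", "commodity_id", "s_mean", "s_low", "s_high",
           "multiplier_mean", "multiplier_low", "multiplier_high")
}

#' Annualised population decline rate
#'
#' Converts a cumulative population decline over `n_periods` years into the
#' constant annual rate `1 - (1 - cumulative_decline)^(1/n_periods)`. A 90%
#' collapse over the 14-year 2017-2030 horizon corresponds to 15.2% per year.
#'
#' @param cumulative_decline Total fractional decline, in `[0, 1)`.
#' @param n_periods Number of years (>= 1).
#' @return Annual decline rate as a fraction.
#' @examples
#' annual_decline_rate(0.90, 14) # 0.1516...
#' @export
annual_decline_rate <- function(cumulative_decline, n_periods) {
  if (any(cumulative_decline < 0 | cumulative_decline >= 1)) {
    stop_bad_input("cumulative_decline must lie in [0, 1)")
  }
  if (any(n_periods < 1)) stop_bad_input("n_periods must be >= 1")
  1 - (1 - cumulative_decline)^(1 / n_periods)
}

#' @rdname annual_decline_rate
#' @return `decline_spec()` returns a one-row tibble with the cumulative
#'   decline, horizon and implied annual rate.
#' @export
decline_spec <- function(cumulative_decline, n_periods = 14) {
  tibble(
    cumulative_decline = cumulative_decline,
    n_periods = n_periods,
    annual_rate = annual_decline_rate(cumulative_decline, n_periods))
}

#' Region-resolved commodity shock table
#'
#' Builds the full region x commodity shock table for a collapse scenario
#' confined to Europe: European regions receive the shocks implied by the
#' dependence source, all other regions receive zero shocks. Swapping the
#' dependence table (e.g. an older alternative source) changes values only,
#' never the schema.
#'
#' @inheritParams derive_shock_bounds
#' @param regions Data frame `(region_id, in_europe)` classifying every
#'   region that may appear in `shares`; unclassified regions are an error.
#' @param extra_regions Optional character vector of additional (typically
#'   non-European) region ids absent from `shares` that should still appear
#'   with zero shocks.
#' @return Tibble with one row per region x commodity carrying
#'   `s_mean, s_low, s_high` and the three multipliers.
#' @export
build_shock_table <- function(shares, phi, dependence, regions,
                              coverage = 0.95, fallback_pct = 0.5,
                              cap = 0.999, extra_regions = NULL) {
  regions <- as_tibble(regions)
  assert_columns(regions, c("region_id", "in_europe"), "regions")
  share_regions <- unique(as_tibble(shares)$region_id)
  unclassified <- setdiff(share_regions, regions$region_id)
  if (length(unclassified) > 0) {
    stop_bad_input("region(s) not classified as European or not: %s",
                   paste(unclassified, collapse = ", "))
  }
  europe_ids <- regions$region_id[regions$in_europe]
  eur_shares <- filter(as_tibble(shares), .data$region_id %in% europe_ids)
  shocked <- if (nrow(eur_shares) > 0) {
    derive_shock_bounds(eur_shares, phi, dependence, coverage = coverage,
                        fallback_pct = fallback_pct, cap = cap)
  } else {
    tibble(region_id = character(), commodity_id = character(),
           s_mean = numeric(), s_low = numeric(), s_high = numeric(),
           multiplier_mean = numeric(), multiplier_low = numeric(),
           multiplier_high = numeric())
  }
  commodities <- unique(c(shocked$commodity_id,
                          as_tibble(shares)$commodity_id))
  zero_ids <- union(setdiff(regions$region_id, europe_ids),
                    extra_regions %||% character())
  zeros <- tidyr::expand_grid(region_id = zero_ids,
                              commodity_id = commodities) |>
    mutate(s_mean = 0, s_low = 0, s_high = 0,
           multiplier_mean = 1, multiplier_low = 1, multiplier_high = 1)
  bind_rows(shocked, zeros) |>
    arrange(.data$region_id, .data$commodity_id)
}

#' Format a shock fraction as a report percentage
#'
#' Shocks are stored as fractions; reports print them as percentages rounded
#' half-up to one decimal (so 0.0795 prints as 8.0).
#'
#' @param s Shock fraction(s).
#' @param digits Decimals in the printed percent (default 1).
#' @return Numeric percentage(s).
#' @export
shock_percent <- function(s, digits = 1) {
  round_half_up(100 * s, digits)
}
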