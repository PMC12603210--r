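#' Synthetic study configuration
#'
#' Configuration for the seeded synthetic-data generator that emulates the
#' structure of the production/market databases the analysis consumes:
#' right-skewed production values, inelastic demand, globally balanced
#' bilateral trade, Europe holding roughly a tenth of the world's
#' pollination-dependent production value.
#'
#' @param seed Integer RNG seed (mandatory; all generation is deterministic
#'   given it).
#' @param n_regions_europe,n_regions_eu,n_regions_extra Region counts; EU
#'   regions are a subset of the European ones.
#' @param n_commodities,n_pollination_dependent Commodity counts.
#' @param europe_dependent_value_share Europe's target share of the global
#'   production value of pollination-dependent commodities (default 0.10).
#' @param value_sdlog Log-scale dispersion of production quantities
#'   (right-skew; default 0.6).
#' @param full_dependence_crop Add one crop with a dependence ratio of 1.0
#'   to exercise the 99.9% shock cap (default `TRUE`).
#' @return A validated `ps_synth_config` list.
#' @export
synth_config <- function(seed,
                         n_regions_europe = 3, n_regions_eu = 2,
                         n_regions_extra = 3,
                         n_commodities = 6, n_pollination_dependent = 3,
                         europe_dependent_value_share = 0.10,
                         value_sdlog = 0.6,
                         full_dependence_crop = TRUE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
        !is.finite(seed)) {
    stop_bad_input("a single finite numeric seed is mandatory")
  }
  cfg <- list(seed = as.integer(seed),
              n_regions_europe = as.integer(n_regions_europe),
              n_regions_eu = as.integer(n_regions_eu),
              n_regions_extra = as.integer(n_regions_extra),
              n_commodities = as.integer(n_commodities),
              n_pollination_dependent = as.integer(n_pollination_dependent),
              europe_dependent_value_share = europe_dependent_value_share,
              value_sdlog = value_sdlog,
              full_dependence_crop = isTRUE(full_dependence_crop))
  if (cfg$n_regions_europe < 1 || cfg$n_regions_extra < 1) {
    stop_bad_input("need at least one European and one extra-European region")
  }
  if (cfg$n_regions_eu > cfg$n_regions_europe || cfg$n_regions_eu < 0) {
    stop_bad_input("EU regions must be a subset of the European regions")
  }
  if (cfg$n_pollination_dependent < 1 ||
        cfg$n_pollination_dependent > cfg$n_commodities) {
    stop_bad_input("dependent commodities must be between 1 and the total")
  }
  if (cfg$europe_dependent_value_share <= 0 ||
        cfg$europe_dependent_value_share >= 1) {
    stop_bad_input("europe_dependent_value_share must lie in (0, 1)")
  }
  structure(cfg, class = "ps_synth_config")
}

#' Generate a balanced synthetic baseline market dataset
#'
#' Draws a complete base-year market state: log-normal (right-skewed)
#' production, bilateral trade flows balanced by construction (demand is
#' derived as domestic use plus imports), ad-valorem wedges, and inelastic
#' demand elasticities. European production of pollination-dependent
#' commodities is rescaled so Europe's share of their world production value
#' matches the configured target exactly. The result passes
#' [validate_baseline()] unmodified.
#'
#' @param config A [synth_config()].
#' @return A `ps_baseline` object.
#' @export
generate_market_dataset <- function(config) {
  stopifnot(inherits(config, "ps_synth_config"))
  set.seed(config$seed)
  n_eur <- config$n_regions_europe
  n_eu <- config$n_regions_eu
  n_ext <- config$n_regions_extra
  region_id <- c(
    if (n_eu > 0) sprintf("EU%02d", seq_len(n_eu)),
    if (n_eur - n_eu > 0) sprintf("EUR%02d", seq_len(n_eur - n_eu)),
    sprintf("ROW%02d", seq_len(n_ext)))
  in_europe <- c(rep(TRUE, n_eur), rep(FALSE, n_ext))
  in_eu <- c(rep(TRUE, n_eu), rep(FALSE, n_eur - n_eu), rep(FALSE, n_ext))
  R <- length(region_id)

  n_dep <- config$n_pollination_dependent
  C <- config$n_commodities
  dep_groups <- rep(c("vegetables_fruits", "oilseeds"), length.out = n_dep)
  ind_groups <- rep(c("cereals", "other"), length.out = C - n_dep)
  commodities <- tibble(
    commodity_id = c(sprintf("dep%d", seq_len(n_dep)),
                     sprintf("ind%d", seq_len(C - n_dep))),
    group = c(dep_groups, ind_groups),
    pollination_dependent = c(rep(TRUE, n_dep), rep(FALSE, C - n_dep)))

  # extra-European regions are larger on average so Europe stays a modest
  # share of world production; dependent-value share is then hit exactly
  size <- ifelse(in_europe, 1, 3)
  Q0 <- matrix(rlnorm(R * C, meanlog = log(500), sdlog = config$value_sdlog),
               R, C) * size
  P0 <- matrix(rlnorm(R * C, meanlog = log(400), sdlog = 0.3), R, C)
  dep_idx <- seq_len(n_dep)
  dep_val_eur <- sum(Q0[in_europe, dep_idx] * P0[in_europe, dep_idx])
  dep_val_row <- sum(Q0[!in_europe, dep_idx] * P0[!in_europe, dep_idx])
  target <- config$europe_dependent_value_share
  # scale European dependent quantities: s.t. eur/(eur+row) = target
  scale_eur <- target * dep_val_row / ((1 - target) * dep_val_eur)
  Q0[in_europe, dep_idx] <- Q0[in_europe, dep_idx] * scale_eur

  yield <- matrix(rlnorm(R * C, meanlog = log(4), sdlog = 0.3), R, C)
  A0 <- Q0 / yield

  # bilateral trade: each origin exports a drawn fraction of production,
  # allocated across other destinations by size-weighted random gravity
  trade <- list()
  for (k in seq_len(C)) {
    xfrac <- runif(R, 0.05, 0.35)
    wt <- runif(R, 0.2, 1) * size
    for (o in seq_len(R)) {
      dests <- setdiff(seq_len(R), o)
      alloc <- wt[dests] / sum(wt[dests])
      trade[[length(trade) + 1]] <- tibble(
        origin = region_id[o], destination = region_id[dests],
        commodity_id = commodities$commodity_id[k],
        qty = Q0[o, k] * xfrac[o] * alloc)
    }
  }
  trade <- bind_rows(trade)

  wedges <- trade |>
    select("origin", "destination", "commodity_id") |>
    mutate(tau = runif(n(), 0, 0.3))

  exports <- trade |>
    group_by(.data$origin, .data$commodity_id) |>
    summarise(exports = sum(.data$qty), .groups = "drop")
  imports <- trade |>
    group_by(.data$destination, .data$commodity_id) |>
    summarise(imports = sum(.data$qty), .groups = "drop")

  market <- tidyr::expand_grid(region_id = region_id,
                               commodity_id = commodities$commodity_id) |>
    mutate(production = as.vector(t(Q0)),
           producer_price = as.vector(t(P0)),
           area = as.vector(t(A0))) |>
    left_join(exports, by = c(region_id = "origin", "commodity_id")) |>
    left_join(imports, by = c(region_id = "destination", "commodity_id")) |>
    mutate(exports = ifelse(is.na(.data$exports), 0, .data$exports),
           imports = ifelse(is.na(.data$imports), 0, .data$imports),
           demand = .data$production - .data$exports + .data$imports) |>
    select(-"exports", -"imports")

  # consumer composite price: trade-weighted landed price per destination
  landed <- trade |>
    left_join(wedges, by = c("origin", "destination", "commodity_id")) |>
    left_join(select(market, "region_id", "commodity_id",
                     op = "producer_price"),
              by = c(origin = "region_id", "commodity_id")) |>
    mutate(value = .data$qty * .data$op * (1 + .data$tau)) |>
    group_by(region_id = .data$destination, .data$commodity_id) |>
    summarise(import_qty = sum(.data$qty), import_value = sum(.data$value),
              .groups = "drop")
  market <- market |>
    left_join(landed, by = c("region_id", "commodity_id")) |>
    left_join(exports, by = c(region_id = "origin", "commodity_id")) |>
    mutate(
      exports = ifelse(is.na(.data$exports), 0, .data$exports),
      import_qty = ifelse(is.na(.data$import_qty), 0, .data$import_qty),
      import_value = ifelse(is.na(.data$import_value), 0, .data$import_value),
      domestic_use = .data$production - .data$exports,
      consumer_price = (.data$domestic_use * .data$producer_price +
                          .data$import_value) /
        (.data$domestic_use + .data$import_qty)) |>
    select("region_id", "commodity_id", "production", "demand",
           "producer_price", "consumer_price", "area")

  elasticities <- tidyr::expand_grid(
    region_id = region_id, commodity_id = commodities$commodity_id) |>
    mutate(eps_supply = runif(n(), 0.3, 0.8),
           eta_yield = runif(n(), 0.1, 0.25),
           eps_demand = -runif(n(), 0.2, 0.9),
           sigma_top = runif(n(), 1.5, 3),
           sigma_origin = runif(n(), 2, 5))

  regions <- tibble(
    region_id = region_id,
    name = region_id,
    in_europe = in_europe,
    in_eu = in_eu,
    gdp = rowSums(Q0 * P0) * runif(R, 15, 30),
    population = round(rowSums(Q0) * runif(R, 8, 15)),
    households = NA_real_,
    land_endowment = rowSums(A0) * 1.15,
    lambda_land = runif(R, 0.05, 0.3))
  regions$households <- round(regions$population / runif(R, 2, 3))

  ps_baseline(regions, commodities, market, trade, wedges, elasticities)
}

#' Generate synthetic dependence, contribution and value-share tables
#'
#' Emulates the schema of crop-level dependence reviews and wild-pollinator
#' contribution studies: each pollination-dependent commodity carries one
#' to three member crops with ordered dependence bounds
#' (`D_min <= D_mean <= D_max`), one crop at full dependence (`D = 1`) to
#' exercise the 99.9% shock cap, and a per-commodity wild contribution
#' share. Crop production values (right-skewed) yield normalised
#' region-specific value shares.
#'
#' @param config A [synth_config()].
#' @param baseline The `ps_baseline` the tables must attach to.
#' @return List with `dependence`, `phi`, `crop_values` and `shares`
#'   tibbles.
#' @export
generate_dependence_tables <- function(config, baseline) {
  stopifnot(inherits(config, "ps_synth_config"),
            inherits(baseline, "ps_baseline"))
  set.seed(config$seed + 1L)
  dep_comms <- baseline$commodities$commodity_id[
    baseline$commodities$pollination_dependent]
  n_crops_per <- sample(1:3, length(dep_comms), replace = TRUE)
  crops <- purrr::map2(dep_comms, n_crops_per, function(cm, k) {
    tibble(commodity_id = cm,
           crop_id = sprintf("%s_crop%d", cm, seq_len(k)))
  }) |>
    bind_rows()
  n <- nrow(crops)
  D_mean <- runif(n, 0.1, 0.9)
  if (config$full_dependence_crop) D_mean[1] <- 1.0
  dependence <- crops |>
    mutate(D_mean = D_mean,
           D_min = .data$D_mean * runif(n, 0.3, 0.9),
           D_max = .data$D_mean + (1 - .data$D_mean) * runif(n, 0.1, 0.7),
           # full dependence is certain dependence: degenerate bounds
           D_min = ifelse(.data$D_mean == 1, 1, .data$D_min),
           source_tag = "synthetic")
  phi <- tibble(commodity_id = dep_comms,
                phi = runif(length(dep_comms), 0.1, 0.9),
                is_average_imputed = FALSE)
  region_id <- baseline$regions$region_id
  crop_values <- tidyr::expand_grid(region_id = region_id,
                                    crop_id = crops$crop_id) |>
    left_join(crops, by = "crop_id") |>
    mutate(value = rlnorm(n(), meanlog = log(100),
                          sdlog = config$value_sdlog)) |>
    select("region_id", "commodity_id", "crop_id", "value")
  shares <- map_crops_to_commodities(crop_values)
  list(dependence = dependence, phi = phi, crop_values = crop_values,
       shares = shares)
}

#' Generate a synthetic nutrient coefficient table
#'
#' Calories are spread across all commodities; vitamin A and folate density
#' is concentrated on the vegetables-and-fruits group (an order of
#' magnitude higher), reproducing the qualitative pattern that
#' micronutrient availability is more exposed to pollination losses than
#' calories.
#'
#' @param config A [synth_config()].
#' @param commodities The baseline `commodities` tibble.
#' @return Tibble `(commodity_id, kcal_per_ton, vitA_per_ton,
#'   folate_per_ton)`.
#' @export
generate_nutrient_table <- function(config, commodities) {
  stopifnot(inherits(config, "ps_synth_config"))
  set.seed(config$seed + 2L)
  commodities <- as_tibble(commodities)
  vf <- commodities$group == "vegetables_fruits"
  n <- nrow(commodities)
  tibble(
    commodity_id = commodities$commodity_id,
    kcal_per_ton = rlnorm(n, log(2.5e6), 0.4),
    vitA_per_ton = rlnorm(n, log(1e5), 0.4) * ifelse(vf, 10, 1),
    folate_per_ton = rlnorm(n, log(5e4), 0.4) * ifelse(vf, 8, 1))
}

#' Generate the complete synthetic study
#'
#' One-call wrapper producing everything the pipeline consumes: the
#' balanced baseline, the dependence/contribution/value-share tables, the
#' nutrient coefficients, and the derived shock table with confidence
#' bounds.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `baseline`, `dependence`, `phi`, `shares`,
#'   `crop_values`, `nutrients` and `shocks`.
#' @export
generate_synthetic_study <- function(config) {
  baseline <- generate_market_dataset(config)
  dep <- generate_dependence_tables(config, baseline)
  nutrients <- generate_nutrient_table(config, baseline$commodities)
  shocks <- build_shock_table(dep$shares, dep$phi, dep$dependence,
                              baseline$regions)
  list(config = config, baseline = baseline, dependence = dep$dependence,
       phi = dep$phi, shares = dep$shares, crop_values = dep$crop_values,
       nutrients = nutrients, shocks = shocks)
}
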