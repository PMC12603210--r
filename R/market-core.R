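#' Assemble and validate a baseline market dataset
#'
#' Bundles the observed base-year tables into a `ps_baseline` object and
#' checks its accounting identities. The model is calibrated to this state,
#' so the data must already be an equilibrium: for every region and
#' commodity, demand = domestic use + imports, production = domestic use +
#' exports, and world exports equal world imports (which holds by
#' construction when trade is given as bilateral flows).
#'
#' @param regions Tibble `(region_id, name, in_europe, in_eu, gdp,
#'   population, households, land_endowment, lambda_land)`. `lambda_land` is
#'   the region's aggregate cropland supply elasticity with respect to the
#'   area-weighted crop return index.
#' @param commodities Tibble `(commodity_id, group, pollination_dependent)`.
#' @param market Tibble `(region_id, commodity_id, production, demand,
#'   producer_price, area)`; quantities in kt, prices in EUR/t, area in kha.
#'   An optional `consumer_price` column is checked against the
#'   trade-weighted landed price and otherwise derived.
#' @param trade Tibble `(origin, destination, commodity_id, qty)` of
#'   bilateral flow quantities (kt); origin != destination.
#' @param wedges Tibble `(origin, destination, commodity_id, tau)` of
#'   ad-valorem price-transmission wedges (tariffs and equivalent barriers).
#' @param elasticities Tibble `(region_id, commodity_id, eps_supply,
#'   eta_yield, eps_demand, sigma_top, sigma_origin)`: supply own-price
#'   elasticity (> 0), price-responsive yield elasticity (>= 0), demand
#'   own-price elasticity (< 0), and the two Armington substitution
#'   elasticities (domestic vs import composite; among origins).
#' @return A validated `ps_baseline` list.
#' @export
ps_baseline <- function(regions, commodities, market, trade, wedges,
                        elasticities) {
  bl <- structure(
    list(regions = as_tibble(regions),
         commodities = as_tibble(commodities),
         market = as_tibble(market),
         trade = as_tibble(trade),
         wedges = as_tibble(wedges),
         elasticities = as_tibble(elasticities)),
    class = "ps_baseline")
  validate_baseline(bl)
  bl
}

#' @rdname ps_baseline
#' @param baseline A `ps_baseline` object.
#' @export
validate_baseline <- function(baseline) {
  assert_columns(baseline$regions,
                 c("region_id", "in_europe", "in_eu", "gdp", "population",
                   "households", "land_endowment", "lambda_land"), "regions")
  assert_columns(baseline$commodities,
                 c("commodity_id", "group", "pollination_dependent"),
                 "commodities")
  assert_columns(baseline$market,
                 c("region_id", "commodity_id", "production", "demand",
                   "producer_price", "area"), "market")
  assert_columns(baseline$trade,
                 c("origin", "destination", "commodity_id", "qty"), "trade")
  assert_columns(baseline$wedges,
                 c("origin", "destination", "commodity_id", "tau"), "wedges")
  assert_columns(baseline$elasticities,
                 c("region_id", "commodity_id", "eps_supply", "eta_yield",
                   "eps_demand", "sigma_top", "sigma_origin"), "elasticities")
  rg <- baseline$regions
  if (any(rg$in_eu & !rg$in_europe)) {
    stop_bad_input("region flags inconsistent: in_eu implies in_europe")
  }
  mk <- baseline$market
  if (any(mk$producer_price <= 0)) stop_bad_input("producer prices must be > 0")
  if (any(mk$production < 0 | mk$demand < 0 | mk$area <= 0)) {
    stop_bad_input("market quantities must be non-negative and area > 0")
  }
  el <- baseline$elasticities
  if (any(el$eps_supply <= 0)) stop_bad_input("eps_supply must be > 0")
  if (any(el$eta_yield < 0)) stop_bad_input("eta_yield must be >= 0")
  if (any(el$eps_demand >= 0)) stop_bad_input("eps_demand must be < 0")
  if (any(el$sigma_top <= 0) || any(el$sigma_origin <= 0)) {
    stop_bad_input("Armington elasticities must be > 0")
  }
  if (any(baseline$trade$qty < 0)) stop_bad_input("trade flows must be >= 0")
  if (any(baseline$trade$origin == baseline$trade$destination)) {
    stop_bad_input("bilateral trade rows must have origin != destination")
  }
  if (any(baseline$wedges$tau < 0)) stop_bad_input("wedges must be >= 0")

  # accounting: production covers domestic use + exports; demand is met
  flows <- baseline$trade |>
    group_by(.data$origin, .data$commodity_id) |>
    summarise(exports = sum(.data$qty), .groups = "drop")
  chk <- mk |>
    left_join(flows, by = c(region_id = "origin", "commodity_id")) |>
    mutate(exports = ifelse(is.na(.data$exports), 0, .data$exports))
  if (any(chk$exports > chk$production + 1e-9 * pmax(chk$production, 1))) {
    stop_bad_input("exports exceed production for some region-commodity")
  }
  imps <- baseline$trade |>
    group_by(.data$destination, .data$commodity_id) |>
    summarise(imports = sum(.data$qty), .groups = "drop")
  chk <- chk |>
    left_join(imps, by = c(region_id = "destination", "commodity_id")) |>
    mutate(imports = ifelse(is.na(.data$imports), 0, .data$imports),
           resid = .data$production - .data$exports + .data$imports -
             .data$demand)
  bad <- abs(chk$resid) > 1e-6 * pmax(chk$demand, 1)
  if (any(bad)) {
    rep <- chk[bad, c("region_id", "commodity_id", "resid")]
    stop_bad_input(
      "baseline not balanced (demand != domestic use + imports) for %d cells, e.g. %s/%s (residual %.3g)",
      sum(bad), rep$region_id[1], rep$commodity_id[1], rep$resid[1])
  }
  invisible(baseline)
}

# Internal: dense array representation of the baseline.
# Quantities kt, prices EUR/t, so value cells are in thousand EUR.
baseline_arrays <- function(baseline) {
  regions <- baseline$regions$region_id
  comms <- baseline$commodities$commodity_id
  R <- length(regions); C <- length(comms)
  mat <- function(df, col, default = 0) {
    m <- matrix(default, R, C, dimnames = list(regions, comms))
    i <- cbind(match(df$region_id, regions), match(df$commodity_id, comms))
    m[i] <- df[[col]]
    m
  }
  Q0 <- mat(baseline$market, "production")
  D0 <- mat(baseline$market, "demand")
  P0 <- mat(baseline$market, "producer_price", default = 1)
  A0 <- mat(baseline$market, "area", default = 1e-12)
  ES <- mat(baseline$elasticities, "eps_supply", default = 0.5)
  ETA <- mat(baseline$elasticities, "eta_yield")
  ED <- mat(baseline$elasticities, "eps_demand", default = -0.5)
  S1 <- mat(baseline$elasticities, "sigma_top", default = 2)
  S2 <- mat(baseline$elasticities, "sigma_origin", default = 2)
  M0 <- array(0, c(R, R, C), dimnames = list(regions, regions, comms))
  i <- cbind(match(baseline$trade$origin, regions),
             match(baseline$trade$destination, regions),
             match(baseline$trade$commodity_id, comms))
  M0[i] <- baseline$trade$qty
  TAU <- array(0, c(R, R, C), dimnames = list(regions, regions, comms))
  j <- cbind(match(baseline$wedges$origin, regions),
             match(baseline$wedges$destination, regions),
             match(baseline$wedges$commodity_id, comms))
  TAU[j] <- baseline$wedges$tau
  lambda <- setNames(baseline$regions$lambda_land, regions)
  list(regions = regions, comms = comms, R = R, C = C,
       Q0 = Q0, D0 = D0, P0 = P0, A0 = A0,
       ES = ES, ETA = ETA, ED = ED, S1 = S1, S2 = S2,
       M0 = M0, TAU = TAU, lambda = lambda)
}

#' Calibrate the partial-equilibrium model to a baseline
#'
#' Chooses the CES share and scale parameters so the observed baseline is an
#' exact model equilibrium (share-form calibration: all behavioural
#' functions are expressed in ratios to the base year, so the zero-shock
#' solution reproduces the baseline identically). Derived baseline objects
#' (bilateral value shares, nest shares, consumer composite prices, area
#' weights) are precomputed and stored.
#'
#' @param baseline A validated [ps_baseline()] object.
#' @return A `ps_model` object. `calibration_residual` holds the maximum
#'   relative deviation of a zero-shock solve from the baseline.
#' @export
calibrate_baseline <- function(baseline) {
  validate_baseline(baseline)
  arr <- baseline_arrays(baseline)
  R <- arr$R; C <- arr$C
  exports0 <- apply(arr$M0, c(1, 3), sum)
  imports0 <- apply(arr$M0, c(2, 3), sum)
  DU0 <- arr$Q0 - exports0
  if (any(DU0 < -1e-9)) stop_bad_input("negative domestic use at baseline")
  DU0 <- pmax(DU0, 0)

  # landed values and bilateral import value shares per destination
  PL0 <- arr$M0 # placeholder shape
  for (k in seq_len(C)) {
    PL0[, , k] <- outer(arr$P0[, k], rep(1, R)) *
      (1 + matrix(arr$TAU[, , k], R, R))
  }
  V0 <- arr$M0 * PL0
  IV0 <- apply(V0, c(2, 3), sum)                 # import value by dest
  W2 <- V0
  for (k in seq_len(C)) {
    denom <- IV0[, k]
    W2[, , k] <- sweep(matrix(V0[, , k], R, R), 2,
                       ifelse(denom > 0, denom, 1), "/")
  }
  DV0 <- DU0 * arr$P0                            # domestic-use value
  wdom <- ifelse(DV0 + IV0 > 0, DV0 / (DV0 + IV0), 1)
  PC0 <- ifelse(DU0 + imports0 > 0,
                (DV0 + IV0) / (DU0 + imports0), arr$P0)
  aw <- arr$A0 / rowSums(arr$A0)                 # area weights for the index

  consumer_price_gap <- 0
  if ("consumer_price" %in% names(baseline$market)) {
    given <- baseline_arrays_col(baseline, "consumer_price")
    consumer_price_gap <- max(abs(given - PC0) / pmax(PC0, 1e-12))
  }

  model <- structure(
    list(baseline = baseline, arr = arr,
         exports0 = exports0, imports0 = imports0, DU0 = DU0,
         W2 = W2, wdom = wdom, PC0 = PC0, aw = aw,
         consumer_price_gap = consumer_price_gap,
         calibration_residual = NA_real_),
    class = "ps_model")
  eq0 <- solve_equilibrium(model, shocks = NULL)
  model$calibration_residual <- max(
    abs(eq0$internal$Q - arr$Q0) / pmax(arr$Q0, 1e-12),
    abs(eq0$internal$p_tilde - 1))
  model
}

baseline_arrays_col <- function(baseline, col) {
  regions <- baseline$regions$region_id
  comms <- baseline$commodities$commodity_id
  m <- matrix(0, length(regions), length(comms),
              dimnames = list(regions, comms))
  df <- baseline$market
  m[cbind(match(df$region_id, regions), match(df$commodity_id, comms))] <-
    df[[col]]
  m
}

#' Solver settings
#'
#' @param tolerance Maximum relative market-clearing residual (and price
#'   change) accepted as converged. Default `1e-6`.
#' @param damping Step damping for the log-price fixed-point update.
#'   Default 0.5.
#' @param max_iter Iteration cap (default 500).
#' @return A `ps_solver_control` list.
#' @export
solver_control <- function(tolerance = 1e-6, damping = 0.5, max_iter = 500L) {
  if (tolerance <= 0 || damping <= 0 || damping > 1 || max_iter < 1) {
    stop_bad_input("invalid solver control settings")
  }
  structure(list(tolerance = tolerance, damping = damping,
                 max_iter = as.integer(max_iter)),
            class = "ps_solver_control")
}

# Internal: shock tibble -> R x C matrix of s (fraction), missing pairs -> 0.
shock_matrix <- function(model, shocks, s_col = "s") {
  arr <- model$arr
  S <- matrix(0, arr$R, arr$C, dimnames = list(arr$regions, arr$comms))
  if (is.null(shocks)) return(S)
  shocks <- as_tibble(shocks)
  assert_columns(shocks, c("region_id", "commodity_id", s_col), "shocks")
  s <- shocks[[s_col]]
  assert_fraction(s, "shock s", lo = 0, hi = 0.999)
  keep <- shocks$region_id %in% arr$regions &
    shocks$commodity_id %in% arr$comms
  S[cbind(match(shocks$region_id[keep], arr$regions),
          match(shocks$commodity_id[keep], arr$comms))] <- s[keep]
  S
}

#' Pick one confidence level out of a shock table
#'
#' @param shock_table Output of [build_shock_table()].
#' @param level One of `"mean"`, `"low"`, `"high"`.
#' @return Tibble `(region_id, commodity_id, s)`.
#' @export
shocks_at_level <- function(shock_table, level = c("mean", "low", "high")) {
  level <- match.arg(level)
  col <- paste0("s_", level)
  assert_columns(shock_table, c("region_id", "commodity_id", col),
                 "shock_table")
  tibble(region_id = shock_table$region_id,
         commodity_id = shock_table$commodity_id,
         s = shock_table[[col]])
}

# Internal core: given price ratios (R x C), compute demand side.
demand_side <- function(model, Pt) {
  arr <- model$arr
  R <- arr$R; C <- arr$C
  PM <- matrix(1, R, C, dimnames = list(arr$regions, arr$comms))
  for (k in seq_len(C)) {
    s2 <- arr$S2[, k]                     # per destination
    w <- matrix(model$W2[, , k], R, R)    # origin x destination shares
    has_imp <- model$imports0[, k] > 0
    if (any(has_imp)) {
      E <- outer(log(Pt[, k]), 1 - s2)    # o x d: (1-s2[d]) * log p[o]
      base <- colSums(w * exp(E))
      pm <- ifelse(abs(1 - s2) > 1e-9, base^(1 / (1 - s2)),
                   exp(colSums(w * log(Pt[, k]))))
      PM[has_imp, k] <- pm[has_imp]
    }
  }
  wd <- model$wdom
  s1 <- arr$S1
  PCt <- ifelse(abs(1 - s1) > 1e-9,
                (wd * Pt^(1 - s1) + (1 - wd) * PM^(1 - s1))^(1 / (1 - s1)),
                exp(wd * log(Pt) + (1 - wd) * log(PM)))
  Dt <- PCt^arr$ED                        # composite demand ratio
  Dq <- arr$D0 * Dt
  DU <- model$DU0 * (Pt / PCt)^(-s1) * Dt
  Mtot <- model$imports0 * (PM / PCt)^(-s1) * Dt
  M <- arr$M0
  for (k in seq_len(arr$C)) {
    s2 <- arr$S2[, k]
    mrat <- ifelse(model$imports0[, k] > 0,
                   Mtot[, k] / model$imports0[, k], 0)
    rel <- exp(outer(log(Pt[, k]), -s2) - outer(rep(1, arr$R), -s2 * log(PM[, k])))
    M[, , k] <- matrix(arr$M0[, , k], arr$R, arr$R) * rel *
      outer(rep(1, arr$R), mrat)
  }
  list(PM = PM, PCt = PCt, Dq = Dq, DU = DU, Mtot = Mtot, M = M)
}

# Internal core: supply quantities, land and yields at price ratios Pt.
supply_side <- function(model, Pt, S) {
  arr <- model$arr
  Pbar <- exp(rowSums(model$aw * log(Pt)))          # region crop-return index
  land_exp <- Pbar^arr$lambda
  Q <- arr$Q0 * (1 - S) * Pt^arr$ES * land_exp
  yield_mult <- (1 - S) * Pt^arr$ETA
  y0 <- ifelse(arr$A0 > 0, arr$Q0 / arr$A0, 0)
  A <- ifelse(yield_mult > 0 & y0 > 0, Q / (y0 * yield_mult), arr$A0)
  list(Q = Q, A = A, yield_mult = yield_mult, Pbar = Pbar)
}

#' Supply response to prices and shocks
#'
#' Evaluates the calibrated supply block at given producer price ratios:
#' quantity `Q = Q0 * (1 - s) * (p/p0)^eps_supply * Pbar^lambda`, where
#' `Pbar` is the region's area-weighted crop price index (aggregate cropland
#' responds to it with elasticity `lambda`); realized yield is
#' `y0 * (1 - s) * (p/p0)^eta`, and land is the quantity/yield quotient.
#'
#' @param model A `ps_model`.
#' @param price_ratios Tibble `(region_id, commodity_id, price_ratio)`;
#'   missing cells default to 1 (baseline prices).
#' @param shocks Tibble `(region_id, commodity_id, s)` or `NULL`.
#' @return Tibble with supply, area, realized yield multiplier per cell.
#' @export
supply_response <- function(model, price_ratios = NULL, shocks = NULL) {
  stopifnot(inherits(model, "ps_model"))
  arr <- model$arr
  Pt <- matrix(1, arr$R, arr$C, dimnames = list(arr$regions, arr$comms))
  if (!is.null(price_ratios)) {
    pr <- as_tibble(price_ratios)
    assert_columns(pr, c("region_id", "commodity_id", "price_ratio"),
                   "price_ratios")
    if (any(pr$price_ratio <= 0)) stop_bad_input("price ratios must be > 0")
    Pt[cbind(match(pr$region_id, arr$regions),
             match(pr$commodity_id, arr$comms))] <- pr$price_ratio
  }
  S <- shock_matrix(model, shocks)
  sp <- supply_side(model, Pt, S)
  tidyr::expand_grid(region_id = arr$regions, commodity_id = arr$comms) |>
    mutate(
      supply = as.vector(t(sp$Q)),
      area = as.vector(t(sp$A)),
      yield_multiplier = as.vector(t(sp$yield_mult)))
}

#' Two-level Armington allocation (single market)
#'
#' Reference implementation of the CES import allocation for one
#' destination and commodity, in calibrated share form: given base value
#' shares and price ratios, new value shares follow
#' `w_i' proportional to w_i * r_i^(1 - sigma)` within each nest, and
#' quantities are consistent with the nest price indices. `sigma = 1` is
#' handled by the Cobb-Douglas (log-form) limit.
#'
#' @param total_demand Composite demand quantity (post-change level).
#' @param base_demand Composite demand quantity at the base point.
#' @param domestic_ratio Domestic price ratio (price / base price).
#' @param import_ratios Vector of origin landed-price ratios.
#' @param share_domestic Base value share of the domestic variety in total use.
#' @param import_shares Base value shares among origins (sum to 1).
#' @param sigma_top,sigma_origin Nest substitution elasticities.
#' @param base_domestic_qty,base_import_qty Base quantities of domestic use
#'   and of each origin's imports.
#' @return List with composite price ratios, new value shares, and the
#'   allocated domestic and bilateral import quantities.
#' @export
armington_allocate <- function(total_demand, base_demand, domestic_ratio,
                               import_ratios, share_domestic, import_shares,
                               sigma_top, sigma_origin,
                               base_domestic_qty, base_import_qty) {
  if (any(c(domestic_ratio, import_ratios) <= 0)) {
    stop_bad_input("prices must be > 0")
  }
  if (length(import_shares) != length(import_ratios)) {
    stop_bad_input("import_shares and import_ratios must align")
  }
  if (abs(sum(import_shares) - 1) > 1e-9 && sum(base_import_qty) > 0) {
    stop_bad_input("import value shares must sum to 1")
  }
  ces_index <- function(w, r, sigma) {
    if (abs(1 - sigma) > 1e-9) sum(w * r^(1 - sigma))^(1 / (1 - sigma))
    else exp(sum(w * log(r)))
  }
  pm <- if (sum(base_import_qty) > 0) {
    ces_index(import_shares, import_ratios, sigma_origin)
  } else 1
  pc <- ces_index(c(share_domestic, 1 - share_domestic),
                  c(domestic_ratio, pm), sigma_top)
  drat <- total_demand / base_demand
  dom_qty <- base_domestic_qty * (domestic_ratio / pc)^(-sigma_top) * drat
  mtot_rat <- (pm / pc)^(-sigma_top) * drat
  imp_qty <- base_import_qty * (import_ratios / pm)^(-sigma_origin) * mtot_rat
  w_imp <- import_shares * import_ratios^(1 - sigma_origin)
  w_imp <- if (sum(w_imp) > 0) w_imp / sum(w_imp) else import_shares
  list(price_index = pc, import_price_index = pm,
       import_value_shares = w_imp,
       domestic_qty = dom_qty, import_qty = imp_qty)
}

#' Landed price under ad-valorem price transmission
#'
#' @param origin_price Exporter price(s).
#' @param tau Ad-valorem wedge(s) (>= 0).
#' @return Tibble with landed price and the per-unit wedge revenue accruing
#'   to the destination government.
#' @export
apply_price_transmission <- function(origin_price, tau) {
  if (any(tau < 0)) stop_bad_input("tau must be >= 0")
  tibble(origin_price = origin_price, tau = tau,
         landed_price = origin_price * (1 + tau),
         wedge_revenue_per_unit = origin_price * tau)
}

#' Solve the post-shock market equilibrium
#'
#' Alternates the supply block and Armington demand/market-clearing block
#' with damped log-price updates until every region-commodity market clears
#' to within `control$tolerance` (relative residual), mirroring the
#' sequential supply/market iteration of large partial-equilibrium systems.
#' Deterministic for fixed inputs. Non-convergence is an error carrying the
#' residual trajectory; there is no silent partial result.
#'
#' @param model A `ps_model` from [calibrate_baseline()].
#' @param shocks Tibble `(region_id, commodity_id, s)` of productivity
#'   shocks (fractions; the yield multiplier is `1 - s`), or `NULL` for the
#'   reference run.
#' @param control A [solver_control()].
#' @return A `ps_equilibrium` object with per-cell prices, quantities,
#'   bilateral flows, land use and convergence diagnostics.
#' @export
solve_equilibrium <- function(model, shocks = NULL,
                              control = solver_control()) {
  stopifnot(inherits(model, "ps_model"))
  arr <- model$arr
  S <- shock_matrix(model, shocks)
  Pt <- matrix(1, arr$R, arr$C, dimnames = list(arr$regions, arr$comms))
  # effective excess-demand elasticity bound per origin good, for step size
  sig_max <- apply(pmax(arr$S1, arr$S2, abs(arr$ED)), 2, max)
  denom <- arr$ES + arr$ETA + rep(arr$lambda, arr$C) +
    matrix(sig_max, arr$R, arr$C, byrow = TRUE)
  gamma <- control$damping / denom
  trajectory <- numeric(0)
  converged <- FALSE
  iter <- 0L
  dem <- NULL; sup <- NULL
  active <- arr$Q0 > 0
  while (iter < control$max_iter) {
    iter <- iter + 1L
    dem <- demand_side(model, Pt)
    sup <- supply_side(model, Pt, S)
    TD <- dem$DU + apply(dem$M, c(1, 3), sum)
    ratio <- ifelse(active, TD / pmax(sup$Q, 1e-300), 1)
    resid <- max(abs(ratio - 1))
    trajectory <- c(trajectory, resid)
    if (resid < control$tolerance) {
      converged <- TRUE
      break
    }
    Pt <- Pt * exp(gamma * log(ratio))
  }
  if (!converged) {
    abort(sprintf(
      "equilibrium solver failed to converge in %d iterations (last residual %.3g)",
      control$max_iter, trajectory[length(trajectory)]),
      class = "pollishock_convergence_error",
      trajectory = trajectory)
  }
  TD <- dem$DU + apply(dem$M, c(1, 3), sum)
  exports <- apply(dem$M, c(1, 3), sum)
  imports <- apply(dem$M, c(2, 3), sum)
  cells <- tidyr::expand_grid(region_id = arr$regions,
                              commodity_id = arr$comms)
  tv <- function(m) as.vector(t(m))
  state <- cells |>
    mutate(
      price_ratio = tv(Pt),
      producer_price = tv(arr$P0 * Pt),
      consumer_price_ratio = tv(dem$PCt),
      consumer_price = tv(model$PC0 * dem$PCt),
      supply = tv(sup$Q),
      demand = tv(dem$Dq),
      domestic_use = tv(dem$DU),
      exports = tv(exports),
      imports = tv(imports),
      area = tv(sup$A),
      yield_multiplier = tv(sup$yield_mult),
      shock = tv(S))
  flows <- as.data.frame.table(dem$M, responseName = "qty") |>
    as_tibble() |>
    rename(origin = "Var1", destination = "Var2", commodity_id = "Var3") |>
    mutate(across(c("origin", "destination", "commodity_id"), as.character)) |>
    filter(.data$qty > 0 | .data$origin != .data$destination)
  structure(
    list(state = state, flows = flows,
         land = tibble(region_id = arr$regions,
                       land_use = rowSums(sup$A),
                       land_baseline = rowSums(arr$A0)),
         diagnostics = list(iterations = iter,
                            max_residual = trajectory[length(trajectory)],
                            converged = TRUE,
                            trajectory = trajectory),
         internal = list(Pt = Pt, p_tilde = Pt, PCt = dem$PCt, PM = dem$PM,
                         Dq = dem$Dq, DU = dem$DU, M = dem$M, Q = sup$Q,
                         A = sup$A, S = S, Pbar = sup$Pbar)),
    class = "ps_equilibrium")
}

#' @export
print.ps_equilibrium <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<ps_equilibrium> %d regions x %d commodities; converged in %d iterations (max residual %.2e)\n",
    length(unique(x$state$region_id)),
    length(unique(x$state$commodity_id)), d$iterations, d$max_residual))
  invisible(x)
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf(
    "<ps_model> calibrated to %d regions x %d commodities; calibration residual %.2e\n",
    x$arr$R, x$arr$C, x$calibration_residual))
  invisible(x)
}

#' Trade openness indicators
#'
#' Self-sufficiency (production / demand), export intensity (exports /
#' production) and import penetration (imports / demand), in percent, per
#' region or per bloc of regions. For blocs, intra-bloc flows are excluded
#' so the indicators describe the bloc's trade with the rest of the world.
#' Undefined ratios (zero denominator) are `NA`, never 0.
#'
#' @param x A `ps_equilibrium` or `ps_baseline`/`ps_model`.
#' @param blocs Optional tibble `(region_id, bloc)` assigning regions to
#'   non-overlapping blocs; omitted regions are dropped.
#' @return Tibble per (region or bloc) x commodity of the three indicators.
#' @export
compute_trade_indicators <- function(x, blocs = NULL) {
  if (inherits(x, "ps_model")) x <- x$baseline
  if (inherits(x, "ps_baseline")) {
    flows <- rename(x$trade, qty = "qty")
    prod <- select(x$market, "region_id", "commodity_id", "production",
                   "demand")
  } else if (inherits(x, "ps_equilibrium")) {
    flows <- x$flows
    prod <- select(x$state, "region_id", "commodity_id",
                   production = "supply", "demand")
  } else {
    stop_bad_input("x must be a ps_baseline, ps_model or ps_equilibrium")
  }
  if (is.null(blocs)) {
    blocs <- tibble(region_id = unique(prod$region_id),
                    bloc = unique(prod$region_id))
  } else {
    blocs <- as_tibble(blocs)
    assert_columns(blocs, c("region_id", "bloc"), "blocs")
    if (anyDuplicated(blocs$region_id) > 0) {
      stop_bad_input("blocs must not overlap: a region appears twice")
    }
  }
  fl <- flows |>
    left_join(rename(blocs, bloc_o = "bloc"), by = c(origin = "region_id")) |>
    left_join(rename(blocs, bloc_d = "bloc"),
              by = c(destination = "region_id")) |>
    filter(!is.na(.data$bloc_o) | !is.na(.data$bloc_d))
  ex <- fl |>
    filter(!is.na(.data$bloc_o),
           is.na(.data$bloc_d) | .data$bloc_d != .data$bloc_o) |>
    group_by(bloc = .data$bloc_o, .data$commodity_id) |>
    summarise(exports = sum(.data$qty), .groups = "drop")
  im <- fl |>
    filter(!is.na(.data$bloc_d),
           is.na(.data$bloc_o) | .data$bloc_o != .data$bloc_d) |>
    group_by(bloc = .data$bloc_d, .data$commodity_id) |>
    summarise(imports = sum(.data$qty), .groups = "drop")
  prod |>
    inner_join(blocs, by = "region_id") |>
    group_by(.data$bloc, .data$commodity_id) |>
    summarise(production = sum(.data$production), demand = sum(.data$demand),
              .groups = "drop") |>
    left_join(ex, by = c("bloc", "commodity_id")) |>
    left_join(im, by = c("bloc", "commodity_id")) |>
    mutate(
      exports = ifelse(is.na(.data$exports), 0, .data$exports),
      imports = ifelse(is.na(.data$imports), 0, .data$imports),
      self_sufficiency = ifelse(.data$demand > 0,
                                100 * .data$production / .data$demand,
                                NA_real_),
      export_intensity = ifelse(.data$production > 0,
                                100 * .data$exports / .data$production,
                                NA_real_),
      import_penetration = ifelse(.data$demand > 0,
                                  100 * .data$imports / .data$demand,
                                  NA_real_))
}

#' Aggregate percentage changes by commodity group and region bloc
#'
#' Value-weighted (base production value) aggregation of yield, production
#' and producer-price changes, and physical-area aggregation of land-use
#' change, relative to the calibrated baseline.
#'
#' @param model The `ps_model` the equilibrium came from.
#' @param eq A `ps_equilibrium`.
#' @param blocs Tibble `(region_id, bloc)`; regions absent from it are
#'   dropped. Defaults to Europe / extra_europe from the baseline flags.
#' @param by_group Aggregate by commodity `group` (default) or across all
#'   commodities (`FALSE`).
#' @return Tibble of percent changes per bloc (x group).
#' @export
aggregate_outputs <- function(model, eq, blocs = NULL, by_group = TRUE) {
  stopifnot(inherits(model, "ps_model"), inherits(eq, "ps_equilibrium"))
  if (is.null(blocs)) {
    blocs <- tibble(
      region_id = model$baseline$regions$region_id,
      bloc = ifelse(model$baseline$regions$in_europe, "europe",
                    "extra_europe"))
  }
  base <- model$baseline$market |>
    select("region_id", "commodity_id", base_production = "production",
           base_price = "producer_price", base_area = "area") |>
    mutate(base_value = .data$base_production * .data$base_price)
  df <- eq$state |>
    inner_join(base, by = c("region_id", "commodity_id")) |>
    inner_join(as_tibble(blocs), by = "region_id") |>
    left_join(select(model$baseline$commodities, "commodity_id", "group"),
              by = "commodity_id")
  keys <- if (by_group) c("bloc", "group") else "bloc"
  out <- df |>
    group_by(across(all_of(keys))) |>
    summarise(
      yield_pct = 100 * (sum(.data$base_value * .data$yield_multiplier) /
                           sum(.data$base_value) - 1),
      production_pct = 100 * (sum(.data$base_value *
                                    (.data$supply / pmax(.data$base_production, 1e-12))) /
                                sum(.data$base_value) - 1),
      price_pct = 100 * (sum(.data$base_value * .data$price_ratio) /
                           sum(.data$base_value) - 1),
      land_pct = 100 * (sum(.data$area) / sum(.data$base_area) - 1),
      .groups = "drop")
  if (nrow(out) == 0) stop_bad_input("empty aggregation group")
  out
}
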