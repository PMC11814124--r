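#' Choke price from observed dive prices
#'
#' The choke price is the per-dive price at which demand falls to zero,
#' estimated as an upper percentile (default the 99th) of observed prices
#' using the nearest-rank definition.
#'
#' @param prices Positive price observations (>= 2 values).
#' @param percentile Percentile in (0, 100]; default 99.
#' @return Choke price in USD.
#' @export
choke_price <- function(prices, percentile = 99) {
  if (length(prices) < 2) stop("need at least 2 price observations",
                               call. = FALSE)
  stopifnot(percentile > 0, percentile <= 100)
  as.numeric(stats::quantile(prices, percentile / 100, type = 1, names = FALSE))
}

#' Linear demand curve from an observed market equilibrium
#'
#' With the market in equilibrium at `(Q*, P*)` and demand falling to zero
#' at the choke price `C`, the linear demand `Q(P) = a - b P` has slope
#' `b = Q* / (C - P*)` and intercept `a = Q* + b P*`, so that `Q(P*) = Q*`
#' and `Q(C) = 0`.
#'
#' @param q_star Equilibrium dives per year (>= 0).
#' @param p_star Equilibrium price per dive, USD (> 0 when `q_star > 0`).
#' @param c_choke Choke price, USD; must exceed `p_star`.
#' @return Tibble with `intercept` (a) and `slope` (b); zeros when
#'   `q_star = 0`.
#' @export
demand_from_equilibrium <- function(q_star, p_star, c_choke) {
  if (any(c_choke <= p_star)) {
    stop("choke price must exceed the equilibrium price", call. = FALSE)
  }
  b <- ifelse(q_star > 0, q_star / (c_choke - p_star), 0)
  tibble::tibble(intercept = q_star + b * p_star, slope = b)
}

#' Willingness-to-pay parameters
#'
#' Encodes the three demand shifters: the MPA "name effect" (divers pay 4%
#' more simply because a site is protected), and saturating responses to
#' relative biomass change (capped at +84% of the price) and to
#' biodiversity-score gain (capped at +82%). Both responses use a
#' Michaelis-Menten form `cap * x / (k + x)`; the half-saturation constants
#' set how fast the caps are approached and are a documented reconstruction.
#'
#' @param name_effect MPA name effect as a fraction of the price (default
#'   0.04).
#' @param biomass_cap,biodiversity_cap Response caps as fractions of the
#'   price (defaults 0.84 and 0.82).
#' @param biomass_halfsat Relative biomass change at half the biomass cap
#'   (default 1.0, i.e. a +100% biomass change).
#' @param biodiversity_halfsat Biodiversity-score gain at half the
#'   biodiversity cap (default 0.05).
#' @return A `wtp_params` list.
#' @export
wtp_params <- function(name_effect = 0.04, biomass_cap = 0.84,
                       biodiversity_cap = 0.82, biomass_halfsat = 1.0,
                       biodiversity_halfsat = 0.05) {
  if (any(c(name_effect, biomass_cap, biodiversity_cap, biomass_halfsat,
            biodiversity_halfsat) < 0)) {
    stop("WTP parameters must be nonnegative", call. = FALSE)
  }
  structure(list(name_effect = name_effect, biomass_cap = biomass_cap,
                 biodiversity_cap = biodiversity_cap,
                 biomass_halfsat = biomass_halfsat,
                 biodiversity_halfsat = biodiversity_halfsat),
            class = "wtp_params")
}

saturating <- function(x, cap, halfsat) {
  x <- pmax(x, 0)
  cap * x / (halfsat + x)
}

#' Willingness-to-pay shift from protection benefits
#'
#' Combines the MPA name effect with the saturating biomass and
#' biodiversity responses into a per-dive USD shift of the demand curve:
#' `WTP = P* * (name_effect * is_mpa + f_bio(dBiomass) + f_div(dScore))`.
#' Negative biological changes contribute 0 (divers do not pay extra for
#' losses).
#'
#' @param delta_biomass Relative biomass change (1.13 = +113%); >= -1.
#' @param delta_biodiversity Biodiversity-score gain (absolute, >= 0).
#' @param is_mpa Logical: does the site become/is it an MPA?
#' @param params [wtp_params()].
#' @param p_star Equilibrium price per dive, USD.
#' @return WTP shift per dive, USD (vectorised).
#' @export
wtp_shift <- function(delta_biomass, delta_biodiversity, is_mpa, params,
                      p_star) {
  stopifnot(inherits(params, "wtp_params"))
  if (any(delta_biomass < -1)) {
    stop("delta_biomass cannot be below -1 (a -100% change)", call. = FALSE)
  }
  if (any(delta_biodiversity < 0)) {
    stop("delta_biodiversity must be nonnegative", call. = FALSE)
  }
  p_star * (params$name_effect * as.numeric(is_mpa) +
              saturating(delta_biomass, params$biomass_cap,
                         params$biomass_halfsat) +
              saturating(delta_biodiversity, params$biodiversity_cap,
                         params$biodiversity_halfsat))
}

#' Change in dives from a WTP shift and a dive fee
#'
#' `dQ = Q* (WTP - F) / (C - P*)`. The post-change dive count `Q* + dQ` is
#' clamped at zero (with a warning) when a fee exceeds the choke margin.
#'
#' @param q_star,p_star,c_choke Equilibrium dives, price and choke price.
#' @param wtp WTP shift per dive, USD.
#' @param fee Dive fee per dive, USD.
#' @return Change in dives per year (vectorised).
#' @export
delta_dives <- function(q_star, p_star, c_choke, wtp, fee = 0) {
  if (any(c_choke <= p_star)) {
    stop("choke price must exceed the equilibrium price", call. = FALSE)
  }
  dq <- q_star * (wtp - fee) / (c_choke - p_star)
  clamped <- q_star + dq < 0
  if (any(clamped)) {
    warning(sprintf("fee exceeds choke margin in %d pixel(s); dives clamped at 0",
                    sum(clamped)), call. = FALSE)
    dq[clamped] <- -q_star[clamped]
  }
  dq
}

#' Change in dive-industry revenue
#'
#' The industry sells dives at the unchanged equilibrium price, so the
#' revenue change is `P* * dQ`.
#'
#' @param p_star Price per dive, USD.
#' @param delta_q Change in dives per year.
#' @return USD per year.
#' @export
delta_dive_revenue <- function(p_star, delta_q) p_star * delta_q

#' Dive-fee revenue
#'
#' `F * (Q* + dQ)`: the fee collected on every dive actually made.
#'
#' @param q_star Equilibrium dives per year.
#' @param delta_q Change in dives per year.
#' @param fee Fee per dive, USD (>= 0).
#' @return USD per year.
#' @export
fee_revenue <- function(q_star, delta_q, fee) {
  if (any(fee < 0)) stop("fee must be nonnegative", call. = FALSE)
  fee * (q_star + delta_q)
}

#' Change in consumer surplus
#'
#' `dCS = 0.5 (Q* + dQ)^2 (C - P*) / Q* - 0.5 Q* (C - P*)`: the change in
#' the triangle between the (shifted) demand curve and the effective price.
#' Defined as 0 where `Q* = 0`.
#'
#' @inheritParams delta_dives
#' @param delta_q Change in dives per year.
#' @return USD per year.
#' @export
delta_consumer_surplus <- function(q_star, p_star, c_choke, delta_q) {
  margin <- c_choke - p_star
  ifelse(q_star > 0 & delta_q != 0,
         0.5 * (q_star + delta_q)^2 * margin / q_star - 0.5 * q_star * margin,
         0)
}

#' Baseline dive-industry revenue and consumer surplus
#'
#' Revenue is `sum_i P*_i Q*_i`; baseline consumer surplus is the demand
#' triangle `sum_i 0.5 Q*_i (C_i - P*_i)`.
#'
#' @param pixels Pixel table with `dives`, `price_usd` and `choke_usd`
#'   columns (non-dive pixels contribute 0).
#' @return Tibble with `revenue_usd` and `consumer_surplus_usd`.
#' @export
baseline_surplus_and_revenue <- function(pixels) {
  assert_cols(pixels, c("dives", "price_usd"), "pixels")
  q <- pixels$dives
  p <- pixels$price_usd
  keep <- !is.na(q) & !is.na(p) & q > 0
  choke <- if ("choke_usd" %in% names(pixels)) {
    pixels$choke_usd
  } else {
    rep(NA_real_, nrow(pixels))
  }
  tibble::tibble(
    revenue_usd = sum(q[keep] * p[keep]),
    consumer_surplus_usd = sum(0.5 * q[keep] * (choke[keep] - p[keep]))
  )
}

#' Extrapolate the global number of recreational scuba dives
#'
#' Active divers split into casual divers making (on average) 4 dives per
#' year and core divers making 10; the marine share scales the total to
#' dives made in the ocean.
#'
#' @param active_divers Number of active divers worldwide (default 9e6).
#' @param casual_share Share of divers who are casual, in `[0, 1]` (default
#'   0.728).
#' @param casual_rate,core_rate Dives per year per casual/core diver
#'   (defaults 4 and 10).
#' @param marine_fraction Share of dives made in the marine environment
#'   (default 0.653).
#' @return Tibble with `total_dives` and `marine_dives` per year.
#' @export
estimate_global_dives <- function(active_divers = 9e6, casual_share = 0.728,
                                  casual_rate = 4, core_rate = 10,
                                  marine_fraction = 0.653) {
  assert_fraction(casual_share, "casual_share")
  assert_fraction(marine_fraction, "marine_fraction")
  total <- active_divers *
    (casual_share * casual_rate + (1 - casual_share) * core_rate)
  tibble::tibble(total_dives = total, marine_dives = total * marine_fraction)
}

#' Attribute the economic gain to its three WTP components
#'
#' The demand shift is linear in the WTP components, so the gain splits in
#' proportion to the biodiversity, biomass and name-effect contributions to
#' the total WTP. Returns zeros (flagged) when the total WTP is zero.
#'
#' @param delta_biomass Relative biomass change.
#' @param delta_biodiversity Biodiversity-score gain.
#' @param is_mpa Logical MPA flag.
#' @param params [wtp_params()].
#' @return Tibble with `biodiversity`, `biomass`, `name_effect` shares
#'   (summing to 1) and `defined` flag.
#' @export
attribute_components <- function(delta_biomass, delta_biodiversity, is_mpa,
                                 params) {
  c_bio <- saturating(delta_biomass, params$biomass_cap, params$biomass_halfsat)
  c_div <- saturating(delta_biodiversity, params$biodiversity_cap,
                      params$biodiversity_halfsat)
  c_name <- params$name_effect * as.numeric(is_mpa)
  tot <- c_bio + c_div + c_name
  if (sum(tot) == 0) {
    return(tibble::tibble(biodiversity = 0, biomass = 0, name_effect = 0,
                          defined = FALSE))
  }
  tibble::tibble(
    biodiversity = sum(c_div) / sum(tot),
    biomass = sum(c_bio) / sum(tot),
    name_effect = sum(c_name) / sum(tot),
    defined = TRUE
  )
}

#' Split consumer surplus into local and foreign shares per region
#'
#' @param pixel_surplus Tibble with `region_label` and `surplus_usd`.
#' @param foreign_fractions Tibble with `region_label` and
#'   `foreign_fraction` in `[0, 1]`; every region present in
#'   `pixel_surplus` must appear.
#' @return Tibble per region with `local_usd`, `foreign_usd`, `total_usd`.
#' @export
split_surplus_by_origin <- function(pixel_surplus, foreign_fractions) {
  assert_cols(pixel_surplus, c("region_label", "surplus_usd"), "pixel_surplus")
  assert_cols(foreign_fractions, c("region_label", "foreign_fraction"),
              "foreign_fractions")
  assert_fraction(foreign_fractions$foreign_fraction, "foreign_fraction")
  missing <- setdiff(unique(pixel_surplus$region_label),
                     foreign_fractions$region_label)
  if (length(missing) > 0) {
    stop(sprintf("no foreign-visitation fraction for region '%s'",
                 missing[[1]]), call. = FALSE)
  }
  pixel_surplus |>
    dplyr::group_by(.data$region_label) |>
    dplyr::summarise(total_usd = sum(.data$surplus_usd), .groups = "drop") |>
    dplyr::left_join(foreign_fractions, by = "region_label") |>
    dplyr::mutate(
      foreign_usd = .data$foreign_fraction * .data$total_usd,
      local_usd = .data$total_usd - .data$foreign_usd
    ) |>
    dplyr::select("region_label", "local_usd", "foreign_usd", "total_usd")
}
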