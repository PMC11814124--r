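#' Generate a complete synthetic world bundle
#'
#' Convenience constructor running the full synthetic-data chain: grid world
#' with MPA coverage, dive counts and price observations; fished stocks with
#' contiguous ranges and ground-truth traits; biodiversity species; trait
#' imputation (random forest fits on the stocks flagged empirical) and trait
#' resolution. Everything is a pure function of the configs and master seed.
#'
#' @param world_config [world_gen_config()].
#' @param stock_config [stock_gen_config()]; its seed defaults to the world
#'   seed.
#' @param n_species Number of biodiversity-scored species.
#' @param taxon_weights Taxon aggregate weight table.
#' @return A `dive_world_bundle` list with `pixels`, `coverage`,
#'   `price_obs`, `stocks`, `stock_ranges`, `species`, `species_ranges`,
#'   `traits`, trait models and `config`.
#' @export
generate_world_bundle <- function(world_config = world_gen_config(),
                                  stock_config = NULL,
                                  n_species = 200,
                                  taxon_weights = default_taxon_weights()) {
  if (is.null(stock_config)) {
    stock_config <- stock_gen_config(seed = world_config$seed)
  }
  world <- generate_world(world_config)
  st <- generate_stocks(stock_config, world)
  sp <- generate_species(n_species, taxon_weights, world,
                         seed = world_config$seed)

  stocks <- st$stocks
  hr_model <- pld_model <- NULL
  if (nrow(stocks) > 0) {
    emp <- stocks[stocks$is_empirical, ]
    if (nrow(emp) >= 10) {
      hr_model <- fit_trait_model(emp, "home_range_km2",
                                  seed = world_config$seed)
      emp_pld <- emp[!emp$is_elasmobranch, ]
      if (nrow(emp_pld) >= 10) {
        pld_model <- fit_trait_model(emp_pld, "pld_days",
                                     seed = world_config$seed)
      }
    }
    if (is.null(hr_model) || is.null(pld_model)) {
      # too few flagged empirical stocks to train: fall back to treating all
      # generated traits as observed
      stocks$is_empirical <- TRUE
    }
    traits <- resolve_traits(stocks, hr_model, pld_model)
  } else {
    traits <- tibble::tibble()
  }

  structure(
    list(pixels = world$pixels, coverage = world$coverage,
         price_obs = world$price_obs, stocks = stocks,
         stock_ranges = st$stock_ranges, species = sp$species,
         species_ranges = sp$species_ranges, traits = traits,
         hr_model = hr_model, pld_model = pld_model,
         config = list(world = unclass(world_config),
                       stock = unclass(stock_config),
                       n_species = n_species,
                       seed = world_config$seed)),
    class = "dive_world_bundle"
  )
}

#' @export
print.dive_world_bundle <- function(x, ...) {
  cat(sprintf(
    "<dive_world_bundle> %d pixels (%d ocean, %d dive), %d stocks, %d species\n",
    nrow(x$pixels), sum(x$pixels$is_ocean), sum(x$pixels$has_diving),
    nrow(x$stocks %||% tibble::tibble()),
    nrow(x$species %||% tibble::tibble())
  ))
  invisible(x)
}

check_bundle <- function(bundle) {
  required <- c("pixels", "stocks", "stock_ranges", "species",
                "species_ranges", "traits", "price_obs")
  missing <- required[!vapply(required, function(tb) {
    !is.null(bundle[[tb]]) && nrow(bundle[[tb]]) > 0
  }, logical(1))]
  if (length(missing) > 0) {
    stop("world bundle incomplete; missing or empty: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(bundle)
}

#' Attach prices, choke price and equilibrium dive counts to pixels
#'
#' @param bundle World bundle.
#' @param price_scheme Price allocation scheme (see [allocate_prices()]).
#' @param choke_percentile Percentile of price observations defining the
#'   choke price (default 99).
#' @param total_dives Optional total dives per year; dive counts are
#'   rescaled proportionally when given.
#' @return Pixel tibble with `price_usd`, `choke_usd` and (rescaled)
#'   `dives`.
#' @export
prepare_economy <- function(bundle, price_scheme = "global_median",
                            choke_percentile = 99, total_dives = NULL) {
  pixels <- allocate_prices(bundle$pixels, bundle$price_obs,
                            scheme = price_scheme)
  choke <- choke_price(bundle$price_obs$price_per_dive, choke_percentile)
  pixels$choke_usd <- ifelse(pixels$is_ocean, choke, NA_real_)
  bad <- pixels$has_diving & pixels$choke_usd <= pixels$price_usd
  if (any(bad, na.rm = TRUE)) {
    stop("choke price does not exceed the allocated price in some dive pixels",
         call. = FALSE)
  }
  if (!is.null(total_dives)) {
    cur <- sum(pixels$dives)
    if (cur > 0) pixels$dives <- pixels$dives * (total_dives / cur)
  }
  pixels
}

#' Equilibrium biomass change from protecting all dive pixels
#'
#' Runs the metapopulation model to the business-as-usual equilibrium (only
#' existing fully/highly protected pixels closed to fishing, everything
#' else held at the depletion density) and then to the protect-all
#' equilibrium (all dive pixels additionally closed), and summarises the
#' carrying-capacity-weighted percent biomass change over dive pixels.
#'
#' @param bundle World bundle.
#' @param n_iter Time steps per equilibration (default 100).
#' @param renormalize Renormalise larval kernel rows (default TRUE).
#' @return List with per-pixel `pct_change`, summary `mean`/`sd`, the two
#'   equilibrium states and the MPA pixel sets.
#' @export
evaluate_biomass <- function(bundle, n_iter = 100, renormalize = TRUE) {
  check_bundle(bundle)
  pixels <- bundle$pixels
  range_px <- sort(unique(bundle$stock_ranges$pixel_id))
  dist_km <- pixel_distances(pixels[match(range_px, pixels$pixel_id), ])
  prepared <- prepare_biology(bundle$stocks, bundle$stock_ranges,
                              bundle$traits, dist_km,
                              area_km2 = pixels$area_km2[1],
                              renormalize = renormalize)
  existing_mpa <- pixels$pixel_id[pixels$protection_status == "fully_highly"]
  dive_ids <- pixels$pixel_id[pixels$has_diving]
  all_mpa <- union(existing_mpa, dive_ids)

  bau_eq <- simulate_stocks_equilibrium(prepared, existing_mpa, n_iter)
  init <- split(bau_eq$biomass, bau_eq$stock_id) |>
    purrr::imap(function(b, sid) {
      ids <- bau_eq$pixel_id[bau_eq$stock_id == as.integer(sid)]
      stats::setNames(b, as.character(ids))
    })
  mpa_eq <- simulate_stocks_equilibrium(prepared, all_mpa, n_iter,
                                        init = init)
  chg <- percent_biomass_change(bau_eq, mpa_eq, bundle$stocks, dive_ids)
  list(per_pixel = chg$per_pixel, mean = chg$mean, sd = chg$sd,
       n_flagged = chg$n_flagged, bau_eq = bau_eq, mpa_eq = mpa_eq,
       existing_mpa = existing_mpa, all_mpa = all_mpa, dive_ids = dive_ids)
}

#' Biodiversity score under BAU and protect-all scenarios
#'
#' @param bundle World bundle.
#' @param taxon_weights Taxon aggregate weight table.
#' @param z Persistence exponent.
#' @return List with `score_bau`, `score_mpa`, `delta_score`.
#' @export
evaluate_biodiversity <- function(bundle,
                                  taxon_weights = default_taxon_weights(),
                                  z = 0.25) {
  pixels <- bundle$pixels
  existing_mpa <- pixels$pixel_id[pixels$protection_status == "fully_highly"]
  all_mpa <- union(existing_mpa, pixels$pixel_id[pixels$has_diving])
  species <- assign_species_weights(bundle$species, taxon_weights)
  score_bau <- biodiversity_score(species, bundle$species_ranges,
                                  existing_mpa, z = z)
  score_mpa <- biodiversity_score(species, bundle$species_ranges,
                                  all_mpa, z = z)
  list(score_bau = score_bau, score_mpa = score_mpa,
       delta_score = score_mpa - score_bau)
}

# biology = biomass + biodiversity, computed once and reused across fees
evaluate_biology <- function(bundle, n_iter = 100,
                             taxon_weights = default_taxon_weights(),
                             z = 0.25) {
  bio <- evaluate_biomass(bundle, n_iter = n_iter)
  div <- evaluate_biodiversity(bundle, taxon_weights = taxon_weights, z = z)
  c(bio, div)
}

# per-dive-pixel economics for one (policy, fee); biology precomputed
scenario_pixel_economics <- function(pixels, biology, policy, fee, wtp) {
  dp <- pixels[pixels$has_diving, ]
  dp <- dp[order(dp$pixel_id), ]
  out <- tibble::tibble(
    pixel_id = dp$pixel_id,
    region_label = dp$region_label,
    country_label = dp$country_label,
    q_star = dp$dives,
    p_star = dp$price_usd,
    choke_usd = dp$choke_usd
  )
  if (policy == "protect_all") {
    upgraded <- !(dp$pixel_id %in% biology$existing_mpa)
    pct <- biology$per_pixel$pct_change[
      match(dp$pixel_id, biology$per_pixel$pixel_id)]
    pct[is.na(pct)] <- 0
    out$delta_biomass <- ifelse(upgraded, pmax(pct / 100, -1), 0)
    out$delta_biodiversity <- ifelse(upgraded, biology$delta_score, 0)
    out$is_upgraded <- upgraded
  } else {
    out$delta_biomass <- 0
    out$delta_biodiversity <- 0
    out$is_upgraded <- FALSE
  }
  out$wtp_usd <- wtp_shift(out$delta_biomass, out$delta_biodiversity,
                           out$is_upgraded, wtp, out$p_star)
  out$fee_usd <- rep_len(fee, nrow(out))
  out$delta_q <- delta_dives(out$q_star, out$p_star, out$choke_usd,
                             out$wtp_usd, out$fee_usd)
  out$delta_industry_revenue_usd <- delta_dive_revenue(out$p_star, out$delta_q)
  out$fee_revenue_usd <- fee_revenue(out$q_star, out$delta_q, out$fee_usd)
  out$delta_consumer_surplus_usd <-
    delta_consumer_surplus(out$q_star, out$p_star, out$choke_usd, out$delta_q)
  out
}

aggregate_scenario <- function(px, wtp) {
  # linear attribution of the economic gain through the demand shift:
  # each pixel's dQ splits in proportion to its WTP components, weighted by
  # the pixel's demand slope Q*/(C - P*)
  w <- px$q_star / (px$choke_usd - px$p_star)
  c_bio <- saturating(px$delta_biomass, wtp$biomass_cap, wtp$biomass_halfsat) *
    px$p_star
  c_div <- saturating(px$delta_biodiversity, wtp$biodiversity_cap,
                      wtp$biodiversity_halfsat) * px$p_star
  c_name <- wtp$name_effect * as.numeric(px$is_upgraded) * px$p_star
  tot <- sum(w * (c_bio + c_div + c_name))
  tibble::tibble(
    total_dives_baseline = sum(px$q_star),
    delta_dives = sum(px$delta_q),
    pct_change_dives = if (sum(px$q_star) > 0) {
      100 * sum(px$delta_q) / sum(px$q_star)
    } else 0,
    delta_industry_revenue_usd = sum(px$delta_industry_revenue_usd),
    fee_revenue_usd = sum(px$fee_revenue_usd),
    delta_consumer_surplus_usd = sum(px$delta_consumer_surplus_usd),
    share_biodiversity = if (tot > 0) sum(w * c_div) / tot else 0,
    share_biomass = if (tot > 0) sum(w * c_bio) / tot else 0,
    share_name_effect = if (tot > 0) sum(w * c_name) / tot else 0
  )
}

#' Run one protection/fee scenario end to end
#'
#' Equilibrates the biology (for the protect-all policy), scores
#' biodiversity, maps the biological changes through willingness to pay into
#' the demand system, and aggregates per-pixel economics. Deterministic
#' given the bundle and configuration.
#'
#' @param bundle World bundle from [generate_world_bundle()] or
#'   [read_world()].
#' @param policy `"protect_all"` (upgrade every dive pixel to full/high
#'   protection) or `"bau"` (no upgrades; fees only).
#' @param fee Uniform dive fee, USD per dive.
#' @param wtp [wtp_params()].
#' @param price_scheme Price allocation scheme.
#' @param n_iter Biomass equilibration steps.
#' @param total_dives Optional rescaled total dives.
#' @param taxon_weights Taxon weight table for the biodiversity score.
#' @param biology Optional precomputed result of the internal biology
#'   evaluation (reused across fees by [fee_sweep()]).
#' @param pixels_prepared Optional precomputed [prepare_economy()] output.
#' @return A `scenario_result` with `pixels` (per-dive-pixel tibble),
#'   `summary` (one-row aggregate tibble), `biomass` and `biodiversity`
#'   summaries and the scenario settings.
#' @export
run_scenario <- function(bundle, policy = c("protect_all", "bau"), fee = 0,
                         wtp = wtp_params(), price_scheme = "global_median",
                         n_iter = 100, total_dives = NULL,
                         taxon_weights = default_taxon_weights(),
                         biology = NULL, pixels_prepared = NULL) {
  policy <- match.arg(policy)
  check_bundle(bundle)
  if (is.null(pixels_prepared)) {
    pixels_prepared <- prepare_economy(bundle, price_scheme,
                                       total_dives = total_dives)
  }
  if (is.null(biology)) {
    biology <- if (policy == "protect_all") {
      evaluate_biology(bundle, n_iter = n_iter, taxon_weights = taxon_weights)
    } else {
      existing <- bundle$pixels$pixel_id[
        bundle$pixels$protection_status == "fully_highly"]
      list(existing_mpa = existing, delta_score = 0,
           per_pixel = tibble::tibble(pixel_id = integer(0),
                                      pct_change = numeric(0)),
           mean = 0, sd = 0, score_bau = NA_real_, score_mpa = NA_real_)
    }
  }
  px <- scenario_pixel_economics(pixels_prepared, biology, policy, fee, wtp)
  structure(
    list(pixels = px,
         summary = aggregate_scenario(px, wtp),
         biomass = list(mean_pct_change = biology$mean %||% 0,
                        sd_pct_change = biology$sd %||% 0,
                        per_pixel = biology$per_pixel),
         biodiversity = list(score_bau = biology$score_bau,
                             score_mpa = biology$score_mpa,
                             delta_score = biology$delta_score %||% 0),
         policy = policy, fee = fee, wtp = wtp,
         price_scheme = price_scheme),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scenario_result> policy = %s, fee = $%.2f\n", x$policy, x$fee))
  cat(sprintf("  dives: %+.0f (%+.1f%%), industry revenue: %+.3g USD/yr\n",
              s$delta_dives, s$pct_change_dives, s$delta_industry_revenue_usd))
  cat(sprintf("  fee revenue: %.3g USD/yr, consumer surplus: %+.3g USD/yr\n",
              s$fee_revenue_usd, s$delta_consumer_surplus_usd))
  invisible(x)
}

default_fee_grid <- function(pixels_prepared, by = 1) {
  dp <- pixels_prepared[pixels_prepared$has_diving, ]
  margin <- stats::median(dp$choke_usd - dp$price_usd)
  seq(0, 2 * margin, by = by)
}

#' Sweep dive fees under both policies
#'
#' Evaluates aggregate fee revenue, industry revenue change, consumer
#' surplus change and dive change on a fee grid for the protect-all (MPA)
#' and BAU (no-MPA) branches. The biology is equilibrated once and reused.
#'
#' @inheritParams run_scenario
#' @param fees Nonnegative fee grid; default US$1 steps from 0 to twice the
#'   median choke margin.
#' @return A `dive_fee_sweep` tibble: one row per policy and fee.
#' @export
fee_sweep <- function(bundle, fees = NULL, wtp = wtp_params(),
                      price_scheme = "global_median", n_iter = 100,
                      total_dives = NULL,
                      taxon_weights = default_taxon_weights()) {
  check_bundle(bundle)
  pixels_prepared <- prepare_economy(bundle, price_scheme,
                                     total_dives = total_dives)
  if (is.null(fees)) fees <- default_fee_grid(pixels_prepared)
  if (is.unsorted(fees) || any(fees < 0)) {
    stop("fee grid must be sorted and nonnegative", call. = FALSE)
  }
  biology <- evaluate_biology(bundle, n_iter = n_iter,
                              taxon_weights = taxon_weights)
  rows <- purrr::map(c("protect_all", "bau"), function(pol) {
    purrr::map(fees, function(f) {
      px <- scenario_pixel_economics(pixels_prepared, biology, pol, f, wtp)
      dplyr::bind_cols(tibble::tibble(policy = pol, fee_usd = f),
                       aggregate_scenario(px, wtp))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("dive_fee_sweep", class(rows))
  rows
}

#' Per-pixel neutral fee and its dive-weighted mean
#'
#' The neutral fee equals the WTP shift in every pixel, so dives, industry
#' revenue and consumer surplus are unchanged pre- and post-MPA while fee
#' revenue `F_i * Q*_i` is collected. A verification pass asserts that the
#' implied dive changes vanish.
#'
#' @inheritParams run_scenario
#' @return A `neutral_fee` list: `per_pixel` (with `neutral_fee_usd`),
#'   `mean_fee_usd` (dive-weighted), `fee_revenue_usd`.
#' @export
neutral_fee <- function(bundle, wtp = wtp_params(),
                        price_scheme = "global_median", n_iter = 100,
                        total_dives = NULL,
                        taxon_weights = default_taxon_weights()) {
  check_bundle(bundle)
  pixels_prepared <- prepare_economy(bundle, price_scheme,
                                     total_dives = total_dives)
  biology <- evaluate_biology(bundle, n_iter = n_iter,
                              taxon_weights = taxon_weights)
  px <- scenario_pixel_economics(pixels_prepared, biology, "protect_all",
                                 fee = 0, wtp = wtp)
  px$neutral_fee_usd <- px$wtp_usd
  dq <- delta_dives(px$q_star, px$p_star, px$choke_usd, px$wtp_usd,
                    px$neutral_fee_usd)
  if (any(abs(dq) >= 1e-9)) {
    stop("neutral-fee verification failed: dive changes do not vanish",
         call. = FALSE)
  }
  mean_fee <- if (sum(px$q_star) > 0) {
    sum(px$q_star * px$neutral_fee_usd) / sum(px$q_star)
  } else 0
  structure(
    list(per_pixel = px, mean_fee_usd = mean_fee,
         fee_revenue_usd = sum(px$neutral_fee_usd * px$q_star)),
    class = "neutral_fee"
  )
}

#' Monte-Carlo replication over the uncertain global dive total
#'
#' Each run draws a total number of dives uniformly between the bounds,
#' rescales pixel dive counts proportionally, and records the fee-sweep
#' optima and zero-fee outcomes of both policy branches. Biology does not
#' depend on dive numbers and is equilibrated once.
#'
#' @inheritParams fee_sweep
#' @param n_runs Number of runs (default 500).
#' @param dive_bounds Lower/upper bounds for the dive total; default scales
#'   the bundle's baseline total by 17.1/33.1 and 54.0/33.1 (the global
#'   lower and upper marine-dive bounds relative to the central estimate).
#' @param seed Seed for the dive-total draws.
#' @return A `dive_monte_carlo` list: `runs` tibble (per-run outcomes) and
#'   `summary` (ensemble means and 2.5/50/97.5% quantiles of the
#'   MPA-minus-BAU fee-revenue difference and other outcomes).
#' @export
monte_carlo <- function(bundle, n_runs = 500, dive_bounds = NULL,
                        seed = bundle$config$seed %||% 1L, fees = NULL,
                        wtp = wtp_params(), price_scheme = "global_median",
                        n_iter = 100,
                        taxon_weights = default_taxon_weights()) {
  stopifnot(n_runs >= 1)
  check_bundle(bundle)
  pixels_prepared <- prepare_economy(bundle, price_scheme)
  base_total <- sum(pixels_prepared$dives)
  if (is.null(dive_bounds)) {
    dive_bounds <- base_total * c(17.1, 54.0) / 33.1
  }
  if (is.null(fees)) fees <- default_fee_grid(pixels_prepared)
  biology <- evaluate_biology(bundle, n_iter = n_iter,
                              taxon_weights = taxon_weights)
  totals <- withr::with_seed(sub_seed(seed, 3000), {
    stats::runif(n_runs, dive_bounds[1], dive_bounds[2])
  })
  runs <- purrr::map(seq_len(n_runs), function(i) {
    pp <- pixels_prepared
    if (base_total > 0) pp$dives <- pp$dives * totals[i] / base_total
    per_policy <- purrr::map(c("protect_all", "bau"), function(pol) {
      sweep_rev <- vapply(fees, function(f) {
        px <- scenario_pixel_economics(pp, biology, pol, f, wtp)
        sum(px$fee_revenue_usd)
      }, numeric(1))
      px0 <- scenario_pixel_economics(pp, biology, pol, 0, wtp)
      tibble::tibble(
        policy = pol,
        max_fee_revenue_usd = max(sweep_rev),
        argmax_fee_usd = fees[which.max(sweep_rev)],
        delta_dives_fee0 = sum(px0$delta_q),
        delta_industry_revenue_fee0 = sum(px0$delta_industry_revenue_usd),
        delta_consumer_surplus_fee0 = sum(px0$delta_consumer_surplus_usd)
      )
    }) |> dplyr::bind_rows()
    per_policy$run <- i
    per_policy$total_dives <- totals[i]
    per_policy
  }) |> dplyr::bind_rows()

  diff <- runs |>
    tidyr::pivot_wider(id_cols = c("run", "total_dives"),
                       names_from = "policy",
                       values_from = "max_fee_revenue_usd") |>
    dplyr::mutate(fee_revenue_advantage = .data$protect_all - .data$bau)
  qs <- stats::quantile(diff$fee_revenue_advantage, c(0.025, 0.5, 0.975))
  structure(
    list(runs = runs,
         differences = diff,
         summary = tibble::tibble(
           n_runs = n_runs,
           mean_advantage_usd = mean(diff$fee_revenue_advantage),
           q025_advantage_usd = qs[[1]],
           q500_advantage_usd = qs[[2]],
           q975_advantage_usd = qs[[3]],
           all_runs_mpa_dominant = all(diff$fee_revenue_advantage > 0)
         )),
    class = "dive_monte_carlo"
  )
}

#' Sensitivity of the maximum fee revenue to key assumptions
#'
#' Grid over the dive-total bounds, the price-allocation scheme and
#' alternative biodiversity weight tables; each row reports the protect-all
#' branch's maximum fee revenue and its argmax fee. Biomass equilibria are
#' shared across rows (they do not depend on any of the three axes).
#'
#' @inheritParams fee_sweep
#' @param dive_totals Named numeric vector of total-dive scenarios; default
#'   lower/central/upper = 17.1/33.1/54.0 scaled to the bundle total.
#' @param price_schemes Character vector of schemes to evaluate.
#' @param taxon_tables Named list of taxon weight tables.
#' @return Tibble with one row per combination.
#' @export
sensitivity_suite <- function(bundle, dive_totals = NULL,
                              price_schemes = c("global_median",
                                                "country_median",
                                                "interpolated"),
                              taxon_tables = list(
                                default = default_taxon_weights()),
                              fees = NULL, wtp = wtp_params(),
                              n_iter = 100) {
  check_bundle(bundle)
  base_total <- sum(bundle$pixels$dives)
  if (is.null(dive_totals)) {
    dive_totals <- c(lower = 17.1, central = 33.1, upper = 54.0) / 33.1 *
      base_total
  }
  bio <- evaluate_biomass(bundle, n_iter = n_iter)
  grid <- tidyr::expand_grid(
    dive_total = names(dive_totals),
    price_scheme = price_schemes,
    weights = names(taxon_tables)
  )
  purrr::pmap(grid, function(dive_total, price_scheme, weights) {
    div <- evaluate_biodiversity(bundle, taxon_weights = taxon_tables[[weights]])
    biology <- c(bio, div)
    pp <- prepare_economy(bundle, price_scheme,
                          total_dives = dive_totals[[dive_total]])
    fgrid <- if (is.null(fees)) default_fee_grid(pp) else fees
    rev <- vapply(fgrid, function(f) {
      sum(scenario_pixel_economics(pp, biology, "protect_all", f,
                                   wtp)$fee_revenue_usd)
    }, numeric(1))
    tibble::tibble(
      dive_total = dive_total, price_scheme = price_scheme,
      weights = weights,
      total_dives = dive_totals[[dive_total]],
      max_fee_revenue_usd = max(rev),
      argmax_fee_usd = fgrid[which.max(rev)]
    )
  }) |> dplyr::bind_rows()
}

#' Write a run summary as JSON
#'
#' @param result A `scenario_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  out <- c(
    list(policy = result$policy, fee_usd = result$fee,
         price_scheme = result$price_scheme),
    as.list(result$summary),
    list(biomass_mean_pct_change = result$biomass$mean_pct_change,
         biomass_sd_pct_change = result$biomass$sd_pct_change,
         biodiversity_score_bau = result$biodiversity$score_bau,
         biodiversity_score_mpa = result$biodiversity$score_mpa,
         biodiversity_delta_score = result$biodiversity$delta_score)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
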