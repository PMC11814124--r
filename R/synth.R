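#' Configuration for the synthetic world generator
#'
#' Defaults encode the study conditions the pipeline assumes: about 1.2% of
#' ocean pixels hold recreational diving, 67.35% of dive sites fall inside
#' MPAs with 15.48% in fully/highly protected ones, the global median price
#' per dive is US$58.75, and 33.1 million marine dives are made per year
#' (scaled to the number of dive pixels in the generated world relative to
#' the ~1,816 dive pixels a 50 km global grid implies).
#'
#' @param nrow,ncol Grid dimensions.
#' @param ocean_fraction Fraction of pixels that are ocean.
#' @param dive_fraction Fraction of ocean pixels with recreational diving.
#' @param mpa_target Fraction of dive pixels inside any MPA.
#' @param fully_target Fraction of dive pixels inside fully/highly protected
#'   MPAs (must not exceed `mpa_target`).
#' @param total_dives Total marine dives per year across the world; `NULL`
#'   scales 33.1e6 by the realized number of dive pixels / 1816.
#' @param price_median Median price per dive, USD.
#' @param price_sdlog Lognormal dispersion of price observations.
#' @param n_price_obs Number of dive-operator price observations.
#' @param dive_sdlog Lognormal dispersion of per-pixel dive counts
#'   (heavy-tailed allocation).
#' @param n_countries,n_regions Number of country / region bands.
#' @param seed Master seed; all world randomness derives from it.
#' @return A `world_gen_config` list.
#' @export
world_gen_config <- function(nrow = 40, ncol = 40,
                             ocean_fraction = 0.55,
                             dive_fraction = 0.012,
                             mpa_target = 0.6735,
                             fully_target = 0.1548,
                             total_dives = NULL,
                             price_median = 58.75,
                             price_sdlog = 0.25,
                             n_price_obs = 600,
                             dive_sdlog = 1.5,
                             n_countries = 6,
                             n_regions = 4,
                             seed = 1L) {
  assert_fraction(c(ocean_fraction, dive_fraction, mpa_target, fully_target),
                  "generator fractions")
  if (fully_target > mpa_target) {
    stop("fully_target must not exceed mpa_target", call. = FALSE)
  }
  if (dive_fraction > ocean_fraction) {
    stop("dive_fraction cannot exceed ocean_fraction", call. = FALSE)
  }
  structure(
    list(nrow = nrow, ncol = ncol, ocean_fraction = ocean_fraction,
         dive_fraction = dive_fraction, mpa_target = mpa_target,
         fully_target = fully_target, total_dives = total_dives,
         price_median = price_median, price_sdlog = price_sdlog,
         n_price_obs = n_price_obs, dive_sdlog = dive_sdlog,
         n_countries = n_countries, n_regions = n_regions,
         seed = as.integer(seed)),
    class = "world_gen_config"
  )
}

# deterministic sub-seeds: one master seed, fixed offsets per generator
sub_seed <- function(seed, offset) as.integer((seed + offset) %% .Machine$integer.max)

# 50 km spacing expressed in degrees on a 6371 km sphere
PIXEL_KM <- 50
DEG_KM <- 6371 * pi / 180

#' Round positive reals to integers preserving their sum (largest remainder)
#'
#' @param x Nonnegative numeric vector.
#' @param total Integer total the result must sum to; defaults to
#'   `round(sum(x))`.
#' @return Integer vector summing exactly to `total`.
#' @export
largest_remainder_round <- function(x, total = round(sum(x))) {
  if (length(x) == 0) return(integer(0))
  share <- if (sum(x) > 0) x / sum(x) * total else rep(total / length(x), length(x))
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(share - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# grid helpers: pixels indexed 0..(nrow*ncol-1), row-major
grid_neighbors <- function(idx, nrow, ncol) {
  r <- idx %/% ncol
  c <- idx %% ncol
  nb <- rbind(cbind(r - 1, c), cbind(r + 1, c), cbind(r, c - 1), cbind(r, c + 1))
  keep <- nb[, 1] >= 0 & nb[, 1] < nrow & nb[, 2] >= 0 & nb[, 2] < ncol
  nb[keep, 1] * ncol + nb[keep, 2]
}

# BFS distance (in grid steps) from a seed set over the full grid
grid_bfs_distance <- function(seeds, nrow, ncol) {
  n <- nrow * ncol
  dist <- rep(Inf, n)
  dist[seeds + 1] <- 0
  frontier <- seeds
  step <- 0
  while (length(frontier) > 0) {
    step <- step + 1
    nxt <- unique(unlist(lapply(frontier, grid_neighbors, nrow = nrow, ncol = ncol)))
    nxt <- nxt[dist[nxt + 1] == Inf]
    dist[nxt + 1] <- step
    frontier <- nxt
  }
  dist
}

#' Generate a synthetic gridded dive world
#'
#' Builds a coastal lattice: a land mass with a wiggly coastline, ocean
#' pixels, dive pixels clustered along the coast, MPA coverage hitting the
#' configured protection targets, heavy-tailed dive counts summing exactly to
#' the configured total, and lognormal dive-price observations whose sample
#' median tracks the configured median (stratified sampling).
#'
#' @param config A [world_gen_config()].
#' @return List with `pixels` (tibble incl. `dives` and `protection_status`),
#'   `coverage` (long MPA coverage), `price_obs` and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_gen_config"))
  withr::with_seed(sub_seed(config$seed, 0), {
    nr <- config$nrow; nc <- config$ncol
    n <- nr * nc
    ids <- 0:(n - 1)
    row <- ids %/% nc
    col <- ids %% nc

    # land strip on the west with a sinusoidal coastline
    land_cols <- (1 - config$ocean_fraction) * nc
    wiggle <- round(2 * sin(row / nr * 4 * pi))
    is_land <- col < pmax(0, land_cols + wiggle)
    is_ocean <- !is_land

    dlat <- PIXEL_KM / DEG_KM
    pixels <- tibble::tibble(
      pixel_id = ids,
      centroid_lon = col * dlat,
      centroid_lat = (row - nr / 2) * dlat,
      area_km2 = PIXEL_KM^2,
      is_ocean = is_ocean,
      has_diving = FALSE,
      region_label = paste0("region_", 1 + (row >= nr / 2) * 2 + (col >= nc / 2)),
      country_label = paste0("country_", 1 + (row * config$n_countries) %/% nr)
    )

    ocean_ids <- ids[is_ocean]
    n_dive <- round(config$dive_fraction * length(ocean_ids))
    dive_ids <- integer(0)
    if (n_dive > 0) {
      coast_dist <- grid_bfs_distance(ids[is_land], nr, nc)[ocean_ids + 1]
      if (all(!is.finite(coast_dist))) coast_dist <- rep(1, length(ocean_ids))
      w <- exp(-(coast_dist - 1) / 1.5)
      n_seeds <- max(1, round(n_dive / 6))
      seeds <- sample(ocean_ids, n_seeds, prob = w)
      seed_dist <- grid_bfs_distance(seeds, nr, nc)[ocean_ids + 1]
      w_cluster <- w * (1 + 5 * exp(-seed_dist / 2))
      dive_ids <- sort(sample(ocean_ids, n_dive, prob = w_cluster))
    }
    pixels$has_diving <- pixels$pixel_id %in% dive_ids

    # MPA coverage: exact counts among dive pixels hit the targets; the same
    # MPA density is applied to a sample of non-dive ocean pixels
    n_fh <- round(config$fully_target * n_dive)
    n_other <- round(config$mpa_target * n_dive) - n_fh
    shuffled <- sample(dive_ids)
    fh_px <- shuffled[seq_len(n_fh)]
    other_px <- shuffled[n_fh + seq_len(n_other)]
    non_dive_ocean <- setdiff(ocean_ids, dive_ids)
    n_bg <- min(length(non_dive_ocean),
                round(config$mpa_target * 0.2 * length(non_dive_ocean)))
    bg_px <- if (n_bg > 0) sample(non_dive_ocean, n_bg) else integer(0)
    other_classes <- c("less_unknown", "designated_unimplemented",
                       "proposed_committed")
    coverage <- dplyr::bind_rows(
      tibble::tibble(pixel_id = fh_px, status_class = "fully_highly",
                     fraction = stats::runif(length(fh_px), 0.5, 0.95)),
      tibble::tibble(pixel_id = other_px,
                     status_class = sample(other_classes, length(other_px),
                                           replace = TRUE,
                                           prob = c(0.7, 0.2, 0.1)),
                     fraction = stats::runif(length(other_px), 0.05, 0.9)),
      tibble::tibble(pixel_id = bg_px,
                     status_class = sample(c("fully_highly", other_classes),
                                           length(bg_px), replace = TRUE,
                                           prob = c(0.23, 0.54, 0.15, 0.08)),
                     fraction = stats::runif(length(bg_px), 0.05, 0.95))
    )
    coverage$fraction[coverage$status_class == "fully_highly" &
                        coverage$pixel_id %in% bg_px] <-
      stats::runif(sum(coverage$status_class == "fully_highly" &
                         coverage$pixel_id %in% bg_px), 0.5, 0.95)
    coverage$year <- sample(1975:2020, nrow(coverage), replace = TRUE)

    status <- classify_pixel_protection(coverage)
    pixels <- dplyr::left_join(pixels, status, by = "pixel_id")
    pixels$protection_status[is.na(pixels$protection_status)] <- "unprotected"

    # heavy-tailed dive counts summing exactly to the configured total
    total <- config$total_dives
    if (is.null(total)) total <- round(33.1e6 * n_dive / 1816)
    pixels$dives <- 0L
    if (n_dive > 0 && total > 0) {
      raw <- stats::rlnorm(n_dive, meanlog = 0, sdlog = config$dive_sdlog)
      pixels$dives[match(dive_ids, pixels$pixel_id)] <-
        largest_remainder_round(raw, total)
    }

    # price observations: stratified lognormal so the sample median tracks
    # the configured median closely even at moderate n
    n_obs <- config$n_price_obs
    price_obs <- tibble::tibble(operator_id = integer(0), pixel_id = integer(0),
                                price_per_dive = numeric(0))
    if (n_dive > 0 && n_obs > 0) {
      u <- (seq_len(n_obs) - stats::runif(n_obs)) / n_obs
      u <- sample(u)
      price <- exp(log(config$price_median) + config$price_sdlog * stats::qnorm(u))
      op_px <- sample(dive_ids, n_obs, replace = TRUE,
                      prob = pmax(pixels$dives[match(dive_ids, pixels$pixel_id)], 1))
      price_obs <- tibble::tibble(
        operator_id = seq_len(n_obs),
        pixel_id = op_px,
        price_per_dive = price
      )
    }

    list(pixels = pixels, coverage = coverage, price_obs = price_obs,
         config = config)
  })
}

#' Configuration for the synthetic stock generator
#'
#' Stocks carry the life-history features the trait models consume (intrinsic
#' growth rate, carrying capacity, body length, trophic level, an ordered
#' movement keyword and geographic range size) plus ground-truth home range
#' and pelagic larval duration generated from a log-linear model of those
#' features, so trait imputation has a recoverable truth.
#'
#' @param n_stocks Number of stocks.
#' @param empirical_fraction Fraction of stocks flagged as having empirical
#'   (observed) trait values; the rest must be imputed.
#' @param elasmobranch_fraction Fraction of stocks that are elasmobranchs
#'   (no pelagic larval stage, hence no PLD).
#' @param range_pixels_meanlog,range_pixels_sdlog Lognormal parameters of the
#'   contiguous range-blob size, in pixels.
#' @param depletion_min,depletion_max Business-as-usual biomass as a fraction
#'   of carrying capacity, drawn uniformly (B/K at BAU).
#' @param hr_coef,pld_coef Named coefficients of the log-linear trait model
#'   over `(intercept, log_r, log_k, log_length, trophic, movement,
#'   log_range_km2)`.
#' @param noise_sd Lognormal noise on generated traits (sd on the log scale).
#' @param seed Seed for the stock stream.
#' @return A `stock_gen_config` list.
#' @export
stock_gen_config <- function(n_stocks = 50,
                             empirical_fraction = 0.4,
                             elasmobranch_fraction = 0.12,
                             range_pixels_meanlog = log(40),
                             range_pixels_sdlog = 0.5,
                             depletion_min = 0.1,
                             depletion_max = 0.9,
                             hr_coef = c(intercept = -5, log_r = 0.3,
                                         log_k = 0.05, log_length = 1.8,
                                         trophic = 0.2, movement = 0.8,
                                         log_range_km2 = 0.15),
                             pld_coef = c(intercept = 1.2, log_r = -0.3,
                                          log_k = 0, log_length = 0.25,
                                          trophic = 0.1, movement = 0.05,
                                          log_range_km2 = 0.05),
                             noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_stocks >= 0, depletion_min > 0, depletion_max <= 1,
            depletion_min <= depletion_max)
  structure(
    list(n_stocks = n_stocks, empirical_fraction = empirical_fraction,
         elasmobranch_fraction = elasmobranch_fraction,
         range_pixels_meanlog = range_pixels_meanlog,
         range_pixels_sdlog = range_pixels_sdlog,
         depletion_min = depletion_min, depletion_max = depletion_max,
         hr_coef = hr_coef, pld_coef = pld_coef, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "stock_gen_config"
  )
}

# evaluate the log-linear trait model on stock features
trait_linear_predictor <- function(stocks, coef) {
  coef[["intercept"]] +
    coef[["log_r"]] * log(stocks$r) +
    coef[["log_k"]] * log(stocks$k) +
    coef[["log_length"]] * log(stocks$length_cm) +
    coef[["trophic"]] * stocks$trophic_level +
    coef[["movement"]] * stocks$movement_keyword +
    coef[["log_range_km2"]] * log(stocks$range_km2)
}

# grow a 4-connected blob of `size` ocean pixels from `start`
grow_blob <- function(start, size, is_ocean_by_id, nrow, ncol) {
  blob <- start
  frontier <- setdiff(grid_neighbors(start, nrow, ncol), blob)
  frontier <- frontier[is_ocean_by_id[frontier + 1]]
  while (length(blob) < size && length(frontier) > 0) {
    nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    blob <- c(blob, nxt)
    nb <- grid_neighbors(nxt, nrow, ncol)
    nb <- nb[is_ocean_by_id[nb + 1]]
    frontier <- setdiff(unique(c(frontier, nb)), blob)
  }
  sort(blob)
}

#' Generate synthetic fished stocks with ground-truth dispersal traits
#'
#' Each stock receives a contiguous (4-connected) geographic range blob that
#' intersects at least one dive pixel, life-history features, a BAU depletion
#' level, and ground-truth home range (km^2) and pelagic larval duration
#' (days) generated from the configured log-linear feature model plus
#' lognormal noise. A configurable fraction of stocks is flagged
#' `is_empirical`: their trait values are treated as observed and can train
#' the imputation models. Elasmobranch stocks carry no PLD.
#'
#' @param config A [stock_gen_config()].
#' @param world A world list from [generate_world()] (or any list with a
#'   `pixels` tibble).
#' @return List with `stocks` and `stock_ranges` tibbles.
#' @export
generate_stocks <- function(config, world) {
  stopifnot(inherits(config, "stock_gen_config"))
  pixels <- world$pixels
  # recover grid dims from the world config when available
  nrow_g <- world$config$nrow %||% round(sqrt(nrow(pixels)))
  ncol_g <- world$config$ncol %||% (nrow(pixels) %/% nrow_g)
  withr::with_seed(sub_seed(config$seed, 1000), {
    n <- config$n_stocks
    if (n == 0) {
      return(list(stocks = tibble::tibble(), stock_ranges = tibble::tibble()))
    }
    dive_ids <- pixels$pixel_id[pixels$has_diving]
    if (length(dive_ids) == 0) {
      stop("world has no dive pixels; stock ranges must intersect diving",
           call. = FALSE)
    }
    is_ocean_by_id <- pixels$is_ocean[order(pixels$pixel_id)]

    stocks <- tibble::tibble(
      stock_id = seq_len(n),
      r = stats::rlnorm(n, log(0.35), 0.5),
      k = stats::rlnorm(n, log(8000), 1),
      length_cm = stats::rlnorm(n, log(45), 0.6),
      trophic_level = stats::runif(n, 2, 4.5),
      movement_keyword = sample(1:4, n, replace = TRUE,
                                prob = c(0.3, 0.35, 0.25, 0.1)),
      is_elasmobranch = stats::runif(n) < config$elasmobranch_fraction,
      depletion = stats::runif(n, config$depletion_min, config$depletion_max),
      is_empirical = stats::runif(n) < config$empirical_fraction
    )

    sizes <- pmax(2, round(stats::rlnorm(n, config$range_pixels_meanlog,
                                         config$range_pixels_sdlog)))
    sizes <- pmin(sizes, sum(is_ocean_by_id))
    starts <- sample(dive_ids, n, replace = TRUE)
    ranges <- purrr::map2(starts, sizes, function(s, sz) {
      grow_blob(s, sz, is_ocean_by_id, nrow_g, ncol_g)
    })
    stock_ranges <- tibble::tibble(
      stock_id = rep(stocks$stock_id, lengths(ranges)),
      pixel_id = unlist(ranges)
    )
    stocks$range_km2 <- lengths(ranges) * PIXEL_KM^2

    noise <- function(m) stats::rnorm(m, 0, config$noise_sd)
    stocks$home_range_km2 <-
      exp(trait_linear_predictor(stocks, config$hr_coef) + noise(n))
    stocks$pld_days <-
      exp(trait_linear_predictor(stocks, config$pld_coef) + noise(n))
    stocks$pld_days[stocks$is_elasmobranch] <- NA_real_

    list(stocks = stocks, stock_ranges = stock_ranges)
  })
}

#' Default aggregate biodiversity weights per taxonomic group
#'
#' Aggregate weights reflecting extinction risk and functional/evolutionary
#' distinctiveness, dominated by elasmobranchs (34.0%), ray-finned fishes
#' (27.3%) and anthozoans (16.5%); entries sum to 1.
#'
#' @return Tibble with `taxon_group` and `aggregate_weight`.
#' @export
default_taxon_weights <- function() {
  tibble::tibble(
    taxon_group = c("Elasmobranchii", "Actinopterygii", "Anthozoa", "birds",
                    "mammals", "Malacostraca", "cephalopods", "other"),
    aggregate_weight = c(0.340, 0.273, 0.165, 0.052, 0.050, 0.038, 0.021, 0.061)
  )
}

#' Generate synthetic biodiversity-scored species
#'
#' Species are allotted to taxa by largest-remainder rounding of the taxon
#' aggregate weights (so the realized aggregate weight per taxon matches the
#' table), given contiguous native-range blobs biased toward dive pixels, and
#' an abatable-impact fraction (the share of the species' threat that MPAs
#' can remove).
#'
#' @param n_species Number of species.
#' @param taxon_weights Taxon aggregate weight table summing to 1 (default
#'   [default_taxon_weights()]).
#' @param world World list from [generate_world()].
#' @param seed Seed for the species stream; defaults to the world seed.
#' @return List with `species` and `species_ranges` tibbles.
#' @export
generate_species <- function(n_species, taxon_weights = default_taxon_weights(),
                             world, seed = world$config$seed %||% 1L) {
  assert_cols(taxon_weights, c("taxon_group", "aggregate_weight"),
              "taxon_weights")
  if (abs(sum(taxon_weights$aggregate_weight) - 1) > 1e-9) {
    stop("taxon aggregate weights must sum to 1", call. = FALSE)
  }
  if (n_species == 0) {
    return(list(species = tibble::tibble(species_id = integer(0),
                                         taxon_group = character(0),
                                         abatable_fraction = numeric(0)),
                species_ranges = tibble::tibble(species_id = integer(0),
                                                pixel_id = integer(0))))
  }
  pixels <- world$pixels
  nrow_g <- world$config$nrow %||% round(sqrt(nrow(pixels)))
  ncol_g <- world$config$ncol %||% (nrow(pixels) %/% nrow_g)
  withr::with_seed(sub_seed(seed, 2000), {
    counts <- largest_remainder_round(taxon_weights$aggregate_weight * n_species,
                                      n_species)
    taxa <- rep(taxon_weights$taxon_group, counts)
    is_ocean_by_id <- pixels$is_ocean[order(pixels$pixel_id)]
    dive_ids <- pixels$pixel_id[pixels$has_diving]
    ocean_ids <- pixels$pixel_id[pixels$is_ocean]
    starts <- ifelse(stats::runif(n_species) < 0.7 & length(dive_ids) > 0,
                     sample(dive_ids, n_species, replace = TRUE),
                     sample(ocean_ids, n_species, replace = TRUE))
    sizes <- pmax(3, round(stats::rlnorm(n_species, log(30), 0.6)))
    ranges <- purrr::map2(starts, sizes, function(s, sz) {
      grow_blob(s, min(sz, sum(is_ocean_by_id)), is_ocean_by_id, nrow_g, ncol_g)
    })
    species <- tibble::tibble(
      species_id = seq_len(n_species),
      taxon_group = taxa,
      abatable_fraction = stats::runif(n_species, 0.2, 0.9)
    )
    species_ranges <- tibble::tibble(
      species_id = rep(species$species_id, lengths(ranges)),
      pixel_id = unlist(ranges)
    )
    list(species = species, species_ranges = species_ranges)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
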