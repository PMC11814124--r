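#' Protection status levels, from highest to lowest protection
#'
#' The five-level classification used for marine protected areas (MPAs):
#' fully or highly protected (no fishing), less protected or unknown,
#' designated but unimplemented, proposed or committed, and unprotected.
#' The order of the returned vector is the rank order used whenever two
#' designations are compared.
#'
#' @return Character vector of the five status levels, highest first.
#' @export
protection_levels <- function() {
  c("fully_highly", "less_unknown", "designated_unimplemented",
    "proposed_committed", "unprotected")
}

# haversine on the 6371 km mean-radius sphere, in km
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

# internal: fail with the name of the first missing column
assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column '%s'", what, missing[[1]]),
         call. = FALSE)
  }
  invisible(df)
}

assert_fraction <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' Classify pixel protection status from MPA area coverage
#'
#' A pixel counts as fully/highly protected when at least `threshold` of its
#' area lies inside fully or highly protected MPAs. Otherwise the pixel takes
#' the highest-ranked designation class with any positive coverage, and
#' `unprotected` when it has none.
#'
#' @param coverage Data frame with columns `pixel_id`, `status_class`
#'   (one of [protection_levels()]) and `fraction` (area fraction in `[0, 1]`).
#'   Several rows per pixel are allowed (one per designation).
#' @param threshold Area fraction of fully/highly coverage required for the
#'   `fully_highly` classification (default 0.5).
#' @return Tibble with columns `pixel_id` and `protection_status` (factor
#'   with levels [protection_levels()]), one row per pixel present in
#'   `coverage`.
#' @export
classify_pixel_protection <- function(coverage, threshold = 0.5) {
  assert_cols(coverage, c("pixel_id", "status_class", "fraction"), "coverage")
  assert_fraction(coverage$fraction, "coverage$fraction")
  if (!all(coverage$status_class %in% protection_levels())) {
    stop("unknown status_class in coverage", call. = FALSE)
  }
  lv <- protection_levels()
  coverage |>
    dplyr::group_by(.data$pixel_id) |>
    dplyr::summarise(
      fh = sum(.data$fraction[.data$status_class == "fully_highly"]),
      # the best non-fully designation with positive coverage; sub-threshold
      # fully/highly coverage still puts the pixel inside an MPA, which
      # ranks at the less_unknown tier
      best = {
        present <- .data$status_class[.data$fraction > 0]
        present[present == "fully_highly"] <- "less_unknown"
        if (length(present) > 0) lv[min(match(present, lv))] else "unprotected"
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      protection_status = factor(
        ifelse(.data$fh >= threshold, "fully_highly", .data$best),
        levels = lv
      )
    ) |>
    dplyr::select("pixel_id", "protection_status")
}

#' Resolve a dive site's protection status from multiple designations
#'
#' When a site is covered by several protected-area designations, the
#' designation conferring the highest protection wins; among designations of
#' equal status, the oldest wins. An empty designation list means the site is
#' unprotected.
#'
#' @param designations Data frame with columns `status_class` and `year`
#'   (may have zero rows).
#' @return One-row tibble with `protection_status` and `designation_year`
#'   (`NA` when unprotected).
#' @export
classify_site_protection <- function(designations) {
  lv <- protection_levels()
  if (is.null(designations) || nrow(designations) == 0) {
    return(tibble::tibble(
      protection_status = factor("unprotected", levels = lv),
      designation_year = NA_integer_
    ))
  }
  assert_cols(designations, c("status_class", "year"), "designations")
  rank <- match(designations$status_class, lv)
  best <- which(rank == min(rank))
  oldest <- best[which.min(designations$year[best])]
  tibble::tibble(
    protection_status = factor(designations$status_class[oldest], levels = lv),
    designation_year = as.integer(designations$year[oldest])
  )
}

#' Great-circle distance matrix between pixel centroids
#'
#' Haversine distances on a sphere with mean Earth radius 6371 km.
#'
#' @param pixels Data frame with `pixel_id`, `centroid_lon`, `centroid_lat`.
#' @return Symmetric matrix of distances in km, dimnames = pixel ids.
#' @export
pixel_distances <- function(pixels) {
  assert_cols(pixels, c("pixel_id", "centroid_lon", "centroid_lat"), "pixels")
  pts <- cbind(pixels$centroid_lon, pixels$centroid_lat)
  d <- geosphere::distm(pts, fun = haversine_km)
  dimnames(d) <- list(pixels$pixel_id, pixels$pixel_id)
  d
}

#' Great-circle distance between two pixels
#'
#' @param pixels Pixel table (see [pixel_distances()]).
#' @param i,j Pixel ids.
#' @return Distance in km.
#' @export
pairwise_distance <- function(pixels, i, j) {
  idx <- match(c(i, j), pixels$pixel_id)
  if (anyNA(idx)) {
    stop(sprintf("unknown pixel id '%s'", c(i, j)[which(is.na(idx))[1]]),
         call. = FALSE)
  }
  p <- cbind(pixels$centroid_lon[idx], pixels$centroid_lat[idx])
  as.numeric(haversine_km(p[1, ], p[2, ]))
}

#' Allocate a per-dive price to every ocean pixel
#'
#' Three allocation schemes mirror common choices for spatially sparse price
#' data: a single global median, per-country medians (falling back to the
#' global median for countries without observations), and inverse-distance
#' interpolation of per-pixel medians.
#'
#' @param pixels Pixel table with `pixel_id`, `is_ocean`, `country_label`,
#'   `centroid_lon`, `centroid_lat`.
#' @param observations Price observations with `operator_id`, `pixel_id`,
#'   `price_per_dive` (USD, positive).
#' @param scheme One of `"global_median"`, `"country_median"`,
#'   `"interpolated"`.
#' @param idw_power Exponent for inverse-distance weights (interpolated
#'   scheme only).
#' @return `pixels` with a `price_usd` column filled for ocean pixels.
#' @export
allocate_prices <- function(pixels, observations,
                            scheme = c("global_median", "country_median",
                                       "interpolated"),
                            idw_power = 2) {
  scheme <- match.arg(scheme)
  assert_cols(pixels, c("pixel_id", "is_ocean"), "pixels")
  assert_cols(observations, c("operator_id", "pixel_id", "price_per_dive"),
              "observations")
  if (nrow(observations) == 0) stop("no price observations", call. = FALSE)
  if (any(observations$price_per_dive <= 0)) {
    stop("price_per_dive must be positive", call. = FALSE)
  }
  global_med <- stats::median(observations$price_per_dive)

  price <- rep(NA_real_, nrow(pixels))
  if (scheme == "global_median") {
    price[pixels$is_ocean] <- global_med
  } else if (scheme == "country_median") {
    assert_cols(pixels, "country_label", "pixels")
    obs <- dplyr::left_join(
      observations,
      dplyr::select(pixels, "pixel_id", "country_label"),
      by = "pixel_id"
    )
    med <- obs |>
      dplyr::group_by(.data$country_label) |>
      dplyr::summarise(med = stats::median(.data$price_per_dive),
                       .groups = "drop")
    m <- med$med[match(pixels$country_label, med$country_label)]
    m[is.na(m)] <- global_med
    price[pixels$is_ocean] <- m[pixels$is_ocean]
  } else {
    # median per observed pixel, then inverse-distance weighting to the rest
    px_med <- observations |>
      dplyr::group_by(.data$pixel_id) |>
      dplyr::summarise(med = stats::median(.data$price_per_dive),
                       .groups = "drop")
    src <- pixels[match(px_med$pixel_id, pixels$pixel_id), ]
    ocean <- which(pixels$is_ocean)
    d <- geosphere::distm(
      cbind(pixels$centroid_lon[ocean], pixels$centroid_lat[ocean]),
      cbind(src$centroid_lon, src$centroid_lat),
      fun = haversine_km
    )
    w <- 1 / pmax(d, 1e-6)^idw_power
    price[ocean] <- as.vector(w %*% px_med$med) / rowSums(w)
  }
  pixels$price_usd <- price
  pixels
}

#' Write a world bundle to a directory of delimited text files
#'
#' Persists the pixel table, MPA coverage, price observations, stocks and
#' their ranges, species and their ranges as CSV, and scalar configuration as
#' YAML. [read_world()] restores the bundle; round-tripping preserves
#' integer/enum fields exactly and reals to better than 1e-12.
#'
#' @param bundle A world bundle as produced by [generate_world_bundle()] (a
#'   list with at least `pixels`; other tables optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("pixels", "coverage", "price_obs", "stocks", "stock_ranges",
              "species", "species_ranges", "traits")
  for (tb in tables) {
    if (!is.null(bundle[[tb]])) {
      readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
    }
  }
  cfg <- bundle$config
  if (is.null(cfg)) cfg <- list()
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}

# schema: required columns per table; extra columns are preserved untouched
world_schemas <- function() {
  list(
    pixels = c("pixel_id", "centroid_lon", "centroid_lat", "area_km2",
               "is_ocean", "has_diving", "region_label", "country_label"),
    coverage = c("pixel_id", "status_class", "fraction", "year"),
    price_obs = c("operator_id", "pixel_id", "price_per_dive"),
    stocks = c("stock_id", "r", "k", "length_cm", "trophic_level",
               "movement_keyword", "is_elasmobranch", "depletion"),
    stock_ranges = c("stock_id", "pixel_id"),
    species = c("species_id", "taxon_group", "abatable_fraction"),
    species_ranges = c("species_id", "pixel_id")
  )
}

#' Read a world bundle written by [write_world()]
#'
#' @param dir Directory containing the CSV tables and `config.yml`.
#' @return World bundle list. Unknown extra columns in any table are kept.
#' @export
read_world <- function(dir) {
  schemas <- world_schemas()
  bundle <- list()
  for (tb in names(schemas)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(path)) {
      df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      assert_cols(df, schemas[[tb]], paste0(tb, ".csv"))
      bundle[[tb]] <- df
    }
  }
  traits_path <- file.path(dir, "traits.csv")
  if (file.exists(traits_path)) {
    bundle$traits <- readr::read_csv(traits_path, show_col_types = FALSE,
                                     progress = FALSE)
  }
  if (is.null(bundle$pixels)) stop("pixels.csv not found", call. = FALSE)
  bundle$pixels$protection_status <- NULL
  if (!is.null(bundle$coverage)) {
    st <- classify_pixel_protection(bundle$coverage)
    bundle$pixels <- dplyr::left_join(bundle$pixels, st, by = "pixel_id")
    bundle$pixels$protection_status[is.na(bundle$pixels$protection_status)] <-
      "unprotected"
  } else {
    bundle$pixels$protection_status <-
      factor("unprotected", levels = protection_levels())
  }
  cfg_path <- file.path(dir, "config.yml")
  bundle$config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  class(bundle) <- "dive_world_bundle"
  bundle
}
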