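# Shared fixtures, built in code and cached for the session.

.bundle_cache <- new.env(parent = emptyenv())

# A small but complete world bundle; dive_fraction raised so small grids
# still carry a usable number of dive pixels.
test_bundle <- function(seed = 7, nrow = 20, ncol = 20, dive_fraction = 0.06,
                        n_stocks = 15, n_species = 60) {
  key <- paste(seed, nrow, ncol, dive_fraction, n_stocks, n_species,
               sep = "_")
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- generate_world_bundle(
      world_gen_config(nrow = nrow, ncol = ncol,
                       dive_fraction = dive_fraction,
                       n_price_obs = 500, seed = seed),
      stock_gen_config(n_stocks = n_stocks, seed = seed),
      n_species = n_species
    )
  }
  .bundle_cache[[key]]
}

# Regular lattice of pixel centroids spaced `spacing_km` apart near the
# equator; ids are 0-based row-major.
make_grid_pixels <- function(nrow, ncol, spacing_km = 50) {
  step <- spacing_km / (6371 * pi / 180)
  ids <- 0:(nrow * ncol - 1)
  tibble::tibble(
    pixel_id = ids,
    centroid_lon = (ids %% ncol) * step,
    centroid_lat = (ids %/% ncol - nrow / 2) * step,
    area_km2 = spacing_km^2,
    is_ocean = TRUE,
    has_diving = FALSE,
    region_label = "region_1",
    country_label = "country_1"
  )
}

# independent sort-based median (oracle for allocate_prices)
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# independent geometric consumer-surplus oracle: triangle between the
# WTP-shifted demand curve and the effective price paid
cs_triangle_oracle <- function(q_star, p_star, c_choke, wtp, fee) {
  q_new <- q_star + q_star * (wtp - fee) / (c_choke - p_star)
  cs_after <- 0.5 * q_new * ((c_choke + wtp) - (p_star + fee))
  cs_before <- 0.5 * q_star * (c_choke - p_star)
  cs_after - cs_before
}
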