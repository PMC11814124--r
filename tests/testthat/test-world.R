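test_that("pixel protection classification follows the coverage threshold and rank rules", {
  cov <- function(...) {
    rows <- list(...)
    tibble::tibble(
      pixel_id = 1L,
      status_class = vapply(rows, `[[`, "", 1),
      fraction = vapply(rows, function(r) as.numeric(r[[2]]), 0)
    )
  }
  res <- classify_pixel_protection(cov(list("fully_highly", 0.5)))
  expect_equal(as.character(res$protection_status), "fully_highly")

  res <- classify_pixel_protection(cov(list("fully_highly", 0),
                                       list("less_unknown", 0)))
  expect_equal(as.character(res$protection_status), "unprotected")

  # below threshold, the highest-ranked designation present wins
  res <- classify_pixel_protection(cov(list("fully_highly", 0.49),
                                       list("less_unknown", 0.40)))
  expect_equal(as.character(res$protection_status), "less_unknown")

  expect_error(classify_pixel_protection(cov(list("fully_highly", 1.2))),
               "\\[0, 1\\]")
})

test_that("pixel classification is monotone in fully/highly coverage", {
  for (f in seq(0, 0.95, by = 0.05)) {
    lo <- classify_pixel_protection(tibble::tibble(
      pixel_id = 1L, status_class = c("fully_highly", "proposed_committed"),
      fraction = c(f, 0.3)
    ))$protection_status
    hi <- classify_pixel_protection(tibble::tibble(
      pixel_id = 1L, status_class = c("fully_highly", "proposed_committed"),
      fraction = c(f + 0.05, 0.3)
    ))$protection_status
    expect_lte(as.integer(hi), as.integer(lo)) # smaller level = higher status
  }
})

test_that("site protection takes the highest status, then the oldest designation", {
  d <- tibble::tibble(status_class = c("fully_highly", "less_unknown"),
                      year = c(2010, 1995))
  res <- classify_site_protection(d)
  expect_equal(as.character(res$protection_status), "fully_highly")
  expect_equal(res$designation_year, 2010L)

  res <- classify_site_protection(tibble::tibble(status_class = character(0),
                                                 year = numeric(0)))
  expect_equal(as.character(res$protection_status), "unprotected")
  expect_true(is.na(res$designation_year))

  d <- tibble::tibble(status_class = c("less_unknown", "less_unknown"),
                      year = c(2001, 1988))
  res <- classify_site_protection(d)
  expect_equal(as.character(res$protection_status), "less_unknown")
  expect_equal(res$designation_year, 1988L)
})

test_that("great-circle distances behave like spherical geometry", {
  px <- tibble::tibble(pixel_id = 0:2,
                       centroid_lon = c(0, 1, 180),
                       centroid_lat = c(0, 0, 0))
  expect_equal(pairwise_distance(px, 0, 0), 0)
  # 1 degree along the equator on a 6371 km sphere
  expect_equal(pairwise_distance(px, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  # antipodal limit
  expect_equal(pairwise_distance(px, 0, 2), pi * 6371, tolerance = 1e-6)
  expect_error(pairwise_distance(px, 0, 99), "unknown pixel")
})

test_that("distance matrix is symmetric, zero-diagonal and triangle-consistent", {
  px <- test_bundle()$pixels[1:40, ]
  d <- pixel_distances(px)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(px)))
  set.seed(1)
  for (k in 1:50) {
    ijk <- sample(nrow(px), 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("global-median price allocation is constant and matches a sort oracle", {
  b <- test_bundle()
  px <- allocate_prices(b$pixels, b$price_obs, "global_median")
  ocean_prices <- px$price_usd[px$is_ocean]
  expect_true(all(ocean_prices > 0))
  expect_equal(unique(ocean_prices), sort_median(b$price_obs$price_per_dive))
  expect_true(all(is.na(px$price_usd[!px$is_ocean])))
})

test_that("all price schemes agree given a single observation", {
  b <- test_bundle()
  obs <- b$price_obs[1, ]
  for (scheme in c("global_median", "country_median", "interpolated")) {
    px <- allocate_prices(b$pixels, obs, scheme)
    expect_equal(px$price_usd[px$is_ocean],
                 rep(obs$price_per_dive, sum(px$is_ocean)),
                 tolerance = 1e-9)
  }
  expect_error(allocate_prices(b$pixels, b$price_obs[0, ], "global_median"),
               "observations")
})

test_that("interpolated prices pull toward the nearer price cluster", {
  px <- make_grid_pixels(1, 3)
  obs <- tibble::tibble(operator_id = 1:2, pixel_id = c(0L, 2L),
                        price_per_dive = c(40, 100))
  out <- allocate_prices(px, obs, "interpolated")
  # middle pixel equidistant -> mean; end pixels near their own cluster
  expect_lt(out$price_usd[1], out$price_usd[2])
  expect_lt(out$price_usd[2], out$price_usd[3])
  expect_equal(out$price_usd[2], 70, tolerance = 1e-6)
})

test_that("country-median allocation falls back to the global median", {
  b <- test_bundle()
  # restrict observations to one country; other countries take the global median
  one_country <- b$pixels$country_label[match(b$price_obs$pixel_id,
                                              b$pixels$pixel_id)]
  obs <- b$price_obs[one_country == one_country[1], ]
  px <- allocate_prices(b$pixels, obs, "country_median")
  other <- px$is_ocean & px$country_label != one_country[1]
  expect_equal(unique(px$price_usd[other]),
               sort_median(obs$price_per_dive))
})

test_that("world bundles round-trip through CSV/YAML", {
  b <- test_bundle()
  dir <- withr::local_tempdir()
  write_world(b, dir)
  b2 <- read_world(dir)
  expect_equal(b2$pixels$pixel_id, b$pixels$pixel_id)
  expect_equal(b2$pixels$has_diving, b$pixels$has_diving)
  expect_equal(as.character(b2$pixels$protection_status),
               as.character(b$pixels$protection_status))
  expect_equal(b2$pixels$centroid_lat, b$pixels$centroid_lat,
               tolerance = 1e-12)
  expect_equal(b2$stocks$r, b$stocks$r, tolerance = 1e-12)
  expect_equal(b2$price_obs$price_per_dive, b$price_obs$price_per_dive,
               tolerance = 1e-12)
  expect_equal(as.data.frame(b2$species_ranges),
               as.data.frame(b$species_ranges), tolerance = 1e-12)
})

test_that("schema violations name the missing column; unknown columns survive", {
  b <- test_bundle()
  dir <- withr::local_tempdir()
  write_world(b, dir)
  px <- readr::read_csv(file.path(dir, "pixels.csv"), show_col_types = FALSE)
  px$extra_note <- "keep-me"
  readr::write_csv(px, file.path(dir, "pixels.csv"))
  b2 <- read_world(dir)
  expect_true(all(b2$pixels$extra_note == "keep-me"))

  px$area_km2 <- NULL
  readr::write_csv(px, file.path(dir, "pixels.csv"))
  expect_error(read_world(dir), "area_km2")
})
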