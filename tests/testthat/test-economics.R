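test_that("choke price is the nearest-rank percentile of observed prices", {
  expect_equal(choke_price(1:100, 99), 99)
  expect_equal(choke_price(1:100, 100), 100)
  expect_equal(choke_price(c(10, 20, 30), 50), 20)
  expect_error(choke_price(58.75), "at least 2")
  # degenerate: all prices equal -> choke equals the price and is rejected
  # downstream where C must exceed P*
  expect_equal(choke_price(rep(60, 10)), 60)
  expect_error(demand_from_equilibrium(100, 60, 60), "exceed")
})

test_that("demand curve reproduces the observed equilibrium and choke point", {
  d <- demand_from_equilibrium(1000, 58.75, 220)
  expect_equal(d$slope, 1000 / 161.25, tolerance = 1e-12)
  expect_equal(d$slope, 6.2016, tolerance = 1e-4)
  expect_equal(d$intercept, 1000 + d$slope * 58.75, tolerance = 1e-12)
  expect_equal(d$intercept, 1364.3, tolerance = 1e-4)
  # contracts: Q(P*) = Q*, Q(C) = 0
  expect_equal(d$intercept - d$slope * 58.75, 1000, tolerance = 1e-9)
  expect_equal(d$intercept - d$slope * 220, 0, tolerance = 1e-9)

  z <- demand_from_equilibrium(0, 58.75, 220)
  expect_equal(z$intercept, 0)
  expect_equal(z$slope, 0)
})

test_that("WTP shift combines name effect and saturating responses", {
  p <- wtp_params()
  expect_equal(wtp_shift(0, 0, TRUE, p, 58.75), 0.04 * 58.75)
  expect_equal(wtp_shift(0, 0, FALSE, p, 58.75), 0)
  # caps are asymptotes: huge changes approach but never exceed them
  expect_lt(wtp_shift(1e12, 0, FALSE, p, 1), 0.84)
  expect_equal(wtp_shift(1e12, 0, FALSE, p, 1), 0.84, tolerance = 1e-9)
  expect_equal(wtp_shift(0, 1e12, FALSE, p, 1), 0.82, tolerance = 1e-9)
  # monotone in both biological inputs
  expect_gt(wtp_shift(0.5, 0, FALSE, p, 1), wtp_shift(0.2, 0, FALSE, p, 1))
  expect_gt(wtp_shift(0, 0.1, FALSE, p, 1), wtp_shift(0, 0.02, FALSE, p, 1))
  expect_error(wtp_shift(-2, 0, FALSE, p, 1), "-1")
  expect_error(wtp_params(name_effect = -0.1), "nonnegative")
})

test_that("dive changes follow the linear demand shift", {
  expect_equal(delta_dives(1000, 58.75, 220, wtp = 53, fee = 53), 0)
  expect_equal(delta_dives(1000, 58.75, 220, wtp = 53, fee = 0),
               1000 * 53 / 161.25, tolerance = 1e-12)
  expect_equal(delta_dives(1000, 58.75, 220, wtp = 53, fee = 0), 328.68,
               tolerance = 1e-4)
  expect_equal(delta_dives(1000, 58.75, 220, wtp = 0, fee = 10), -62.02,
               tolerance = 1e-4)
  # a fee beyond the choke margin empties the site, with a warning
  expect_warning(dq <- delta_dives(1000, 58.75, 220, wtp = 0, fee = 300),
                 "clamped")
  expect_equal(dq, -1000)
})

test_that("revenue and fee identities hold", {
  dq <- 1000 * 53 / 161.25
  expect_equal(delta_dive_revenue(58.75, 0), 0)
  expect_equal(delta_dive_revenue(58.75, dq), 58.75 * dq, tolerance = 1e-12)
  expect_equal(delta_dive_revenue(58.75, dq), 19310, tolerance = 1e-3)
  expect_equal(sign(delta_dive_revenue(58.75, -5)), -1)

  expect_equal(fee_revenue(1000, 0, 0), 0)
  expect_equal(fee_revenue(1000, 0, 53), 53000)
  expect_error(fee_revenue(1000, 0, -1), "nonnegative")
})

test_that("fee revenue is a concave dome with the closed-form argmax", {
  q <- 1000; p <- 58.75; c <- 220; w <- 53
  margin <- c - p
  fees <- seq(0, margin + w, by = 0.01)
  rev <- vapply(fees, function(f) {
    fee_revenue(q, delta_dives(q, p, c, w, f), f)
  }, numeric(1))
  f_star <- (margin + w) / 2
  expect_equal(fees[which.max(rev)], f_star, tolerance = 0.011)
  # concavity: second differences nonpositive
  expect_true(all(diff(diff(rev)) < 1e-9))
})

test_that("consumer surplus change matches the printed quadratic form", {
  expect_equal(delta_consumer_surplus(1000, 58.75, 220, 0), 0)
  dq <- 1000 * 53 / 161.25
  expect_equal(delta_consumer_surplus(1000, 58.75, 220, dq), 61710,
               tolerance = 1e-4)
  # total surplus loss when the site empties
  expect_equal(delta_consumer_surplus(1000, 58.75, 220, -1000),
               -0.5 * 1000 * 161.25)
  expect_equal(delta_consumer_surplus(0, 58.75, 220, 0), 0)
})

test_that("consumer surplus equals the geometric triangle oracle", {
  set.seed(99)
  for (i in 1:200) {
    q <- stats::runif(1, 1, 1e5)
    p <- stats::runif(1, 20, 120)
    c <- p + stats::runif(1, 10, 300)
    w <- stats::runif(1, 0, 80)
    f <- stats::runif(1, 0, w + (c - p) * 0.9)
    dq <- delta_dives(q, p, c, w, f)
    expect_equal(delta_consumer_surplus(q, p, c, dq),
                 cs_triangle_oracle(q, p, c, w, f),
                 tolerance = 1e-9)
  }
})

test_that("baseline totals reproduce the global arithmetic", {
  # 33.1 million marine dives at the US$58.75 median -> US$1.94 billion
  px <- tibble::tibble(dives = 33.1e6, price_usd = 58.75, choke_usd = 220)
  base <- baseline_surplus_and_revenue(px)
  expect_equal(base$revenue_usd / 1e9, 1.94, tolerance = 0.005)

  toy <- tibble::tibble(dives = c(10, 20), price_usd = c(50, 60),
                        choke_usd = c(100, 100))
  expect_equal(baseline_surplus_and_revenue(toy)$revenue_usd, 1700)
  expect_equal(baseline_surplus_and_revenue(toy)$consumer_surplus_usd,
               0.5 * 10 * 50 + 0.5 * 20 * 40)
  empty <- tibble::tibble(dives = 0, price_usd = 58.75, choke_usd = 220)
  expect_equal(baseline_surplus_and_revenue(empty)$revenue_usd, 0)
})

test_that("global dive extrapolation matches the casual/core mix", {
  est <- estimate_global_dives()
  expect_equal(est$total_dives / 1e6, 50.7, tolerance = 0.001)
  expect_equal(est$marine_dives / 1e6, 33.1, tolerance = 0.002)

  all_casual <- estimate_global_dives(9e6, casual_share = 1)
  expect_equal(all_casual$total_dives, 36e6)

  # solve the mix: mean of 5.633 dives/yr over 9M divers -> 50.7M total
  share <- (10 - 5.633) / (10 - 4)
  expect_equal(share, 0.728, tolerance = 0.001)
  expect_equal(estimate_global_dives(9e6, share)$total_dives, 50.7e6,
               tolerance = 1e-3)
})

test_that("economic gains attribute proportionally to WTP components", {
  p <- wtp_params()
  only_name <- attribute_components(0, 0, TRUE, p)
  expect_equal(unlist(only_name[, 1:3]),
               c(biodiversity = 0, biomass = 0, name_effect = 1))

  # symmetric components -> equal thirds
  p_eq <- wtp_params(name_effect = 0.1, biomass_cap = 0.2,
                     biodiversity_cap = 0.2, biomass_halfsat = 1,
                     biodiversity_halfsat = 1)
  thirds <- attribute_components(1, 1, TRUE, p_eq)
  expect_equal(unlist(thirds[, 1:3]),
               c(biodiversity = 1, biomass = 1, name_effect = 1) / 3)

  none <- attribute_components(0, 0, FALSE, p)
  expect_false(none$defined)
  expect_equal(none$biomass + none$biodiversity + none$name_effect, 0)

  some <- attribute_components(0.9, 0.03, TRUE, p)
  expect_equal(some$biodiversity + some$biomass + some$name_effect, 1,
               tolerance = 1e-12)
})

test_that("surplus splits by origin conserve totals", {
  ps <- tibble::tibble(region_label = c("a", "a", "b"),
                       surplus_usd = c(100, 50, 200))
  fr <- tibble::tibble(region_label = c("a", "b"),
                       foreign_fraction = c(0, 0.61))
  out <- split_surplus_by_origin(ps, fr)
  expect_equal(out$foreign_usd[out$region_label == "a"], 0)
  expect_equal(out$foreign_usd[out$region_label == "b"], 0.61 * 200)
  expect_equal(out$local_usd + out$foreign_usd, out$total_usd,
               tolerance = 1e-9)
  expect_error(split_surplus_by_origin(
    ps, fr[fr$region_label == "a", ]), "region 'b'")
})
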