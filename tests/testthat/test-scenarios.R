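test_that("a BAU scenario with no fee changes nothing", {
  b <- test_bundle()
  res <- run_scenario(b, policy = "bau", fee = 0)
  expect_true(all(res$pixels$delta_q == 0))
  expect_true(all(res$pixels$delta_consumer_surplus_usd == 0))
  expect_equal(res$summary$delta_dives, 0)
  expect_equal(res$summary$fee_revenue_usd, 0)
  expect_equal(res$summary$delta_industry_revenue_usd, 0)
})

test_that("protect-all with zero fee raises dives in every dive pixel", {
  b <- test_bundle()
  res <- run_scenario(b, policy = "protect_all", fee = 0)
  upgraded <- res$pixels[res$pixels$is_upgraded & res$pixels$q_star > 0, ]
  expect_gt(nrow(upgraded), 0)
  expect_true(all(upgraded$delta_q > 0))
  expect_true(all(upgraded$wtp_usd > 0))
  # aggregates equal per-pixel sums
  expect_equal(res$summary$delta_dives, sum(res$pixels$delta_q),
               tolerance = 1e-9)
  expect_equal(res$summary$delta_consumer_surplus_usd,
               sum(res$pixels$delta_consumer_surplus_usd),
               tolerance = 1e-9)
  sh <- res$summary
  expect_equal(sh$share_biodiversity + sh$share_biomass +
                 sh$share_name_effect, 1, tolerance = 1e-9)
})

test_that("identical configuration and seed give identical results", {
  b1 <- test_bundle(seed = 31)
  b2 <- generate_world_bundle(
    world_gen_config(nrow = 20, ncol = 20, dive_fraction = 0.06,
                     n_price_obs = 500, seed = 31),
    stock_gen_config(n_stocks = 15, seed = 31),
    n_species = 60
  )
  r1 <- run_scenario(b1, "protect_all", fee = 10)
  r2 <- run_scenario(b2, "protect_all", fee = 10)
  expect_identical(r1$pixels, r2$pixels)
  expect_identical(r1$summary, r2$summary)
})

test_that("fee sweeps show MPA dominance and sensible endpoints", {
  b <- test_bundle()
  fs <- suppressWarnings(fee_sweep(b, fees = seq(0, 200, by = 5)))
  at0 <- fs[fs$fee_usd == 0, ]
  expect_equal(at0$fee_revenue_usd, c(0, 0))
  wide <- tidyr::pivot_wider(fs[, c("policy", "fee_usd", "fee_revenue_usd")],
                             names_from = "policy",
                             values_from = "fee_revenue_usd")
  expect_true(all(wide$protect_all >= wide$bau - 1e-9))
  # without an MPA any positive fee hurts dives, revenue and surplus
  bau_rows <- fs[fs$policy == "bau" & fs$fee_usd > 0, ]
  expect_true(all(bau_rows$delta_dives < 0))
  expect_true(all(bau_rows$delta_industry_revenue_usd < 0))
  expect_true(all(bau_rows$delta_consumer_surplus_usd < 0))
  expect_error(fee_sweep(b, fees = c(5, 1)), "sorted")
})

test_that("the neutral fee freezes the market and collects WTP as revenue", {
  b <- test_bundle()
  nf <- neutral_fee(b)
  px <- nf$per_pixel
  expect_equal(px$neutral_fee_usd, px$wtp_usd)
  dq <- delta_dives(px$q_star, px$p_star, px$choke_usd, px$wtp_usd,
                    px$neutral_fee_usd)
  expect_true(all(abs(dq) < 1e-9))
  dcs <- delta_consumer_surplus(px$q_star, px$p_star, px$choke_usd, dq)
  expect_true(all(abs(dcs) < 1e-6))
  expect_equal(nf$fee_revenue_usd, sum(px$wtp_usd * px$q_star),
               tolerance = 1e-12)
  expect_equal(nf$mean_fee_usd,
               sum(px$q_star * px$wtp_usd) / sum(px$q_star),
               tolerance = 1e-12)

  # zero WTP everywhere -> neutral fee 0
  zero <- wtp_params(name_effect = 0, biomass_cap = 0, biodiversity_cap = 0)
  nf0 <- neutral_fee(b, wtp = zero)
  expect_true(all(nf0$per_pixel$neutral_fee_usd == 0))
  expect_equal(nf0$mean_fee_usd, 0)
})

test_that("Monte-Carlo runs bracket the scenario and keep MPA dominance", {
  b <- test_bundle()
  mc <- suppressWarnings(
    monte_carlo(b, n_runs = 20, fees = seq(0, 150, by = 5), seed = 3)
  )
  expect_equal(nrow(mc$runs), 40) # two policies per run
  expect_true(mc$summary$all_runs_mpa_dominant)
  expect_true(all(mc$differences$fee_revenue_advantage > 0))

  # collapsed bounds at the central value reproduce a plain sweep
  total <- sum(prepare_economy(b)$dives)
  mc1 <- suppressWarnings(
    monte_carlo(b, n_runs = 1, dive_bounds = c(total, total),
                fees = seq(0, 150, by = 5), seed = 3)
  )
  fs <- suppressWarnings(fee_sweep(b, fees = seq(0, 150, by = 5)))
  best <- fs |>
    dplyr::group_by(.data$policy) |>
    dplyr::summarise(m = max(.data$fee_revenue_usd))
  for (pol in c("protect_all", "bau")) {
    expect_equal(
      mc1$runs$max_fee_revenue_usd[mc1$runs$policy == pol],
      best$m[best$policy == pol],
      tolerance = 1e-9
    )
  }
})

test_that("sensitivity rows respond only to their own axis", {
  b <- test_bundle()
  tw <- default_taxon_weights()
  uniform <- tibble::tibble(taxon_group = tw$taxon_group,
                            aggregate_weight = rep(1 / nrow(tw), nrow(tw)))
  sens <- suppressWarnings(sensitivity_suite(
    b, price_schemes = "global_median",
    taxon_tables = list(default = tw, uniform = uniform),
    fees = seq(0, 150, by = 5)
  ))
  # higher dive totals -> weakly higher maximum fee revenue
  by_w <- split(sens, sens$weights)
  for (s in by_w) {
    s <- s[order(s$total_dives), ]
    expect_true(all(diff(s$max_fee_revenue_usd) >= -1e-9))
  }
  # duplicated axis values give identical rows
  dup <- suppressWarnings(sensitivity_suite(
    b, dive_totals = c(a = 1e5, b = 1e5), price_schemes = "global_median",
    fees = seq(0, 150, by = 5)
  ))
  expect_equal(dup$max_fee_revenue_usd[1], dup$max_fee_revenue_usd[2])
  expect_equal(dup$argmax_fee_usd[1], dup$argmax_fee_usd[2])
})

test_that("run summaries serialise deterministically", {
  b <- test_bundle()
  res <- run_scenario(b, "protect_all", fee = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_run_summary(res, f1)
  write_run_summary(run_scenario(b, "protect_all", fee = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$policy, "protect_all")
  expect_equal(parsed$fee_usd, 5)
})

test_that("incomplete bundles are rejected with the missing tables named", {
  b <- test_bundle()
  b$stocks <- NULL
  expect_error(run_scenario(b, "bau"), "stocks")
})

test_that("tidy and glance methods expose results as tibbles", {
  b <- test_bundle()
  res <- run_scenario(b, "protect_all", fee = 0)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(all(c("pct_change_dives", "biomass_mean_pct_change") %in%
                    names(g)))
  m <- fit_trait_model(b$stocks, "home_range_km2", seed = 1)
  gm <- glance(m)
  expect_equal(gm$trait, "home_range_km2")
  ti <- tidy(m)
  expect_setequal(ti$feature, mpadive:::trait_features())
})
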