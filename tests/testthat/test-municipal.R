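test_that("the payoff-learning update moves and clamps as specified", {
  expect_equal(adjust_probability(0.5, 1000, 5000), 0.496)
  expect_equal(adjust_probability(0.5, 5000, 1000), 0.504)
  expect_equal(adjust_probability(0.2, 3000, 3000), 0.2)
  # clamping under adversarial payoff streams
  p <- 0.5
  set.seed(1)
  for (i in 1:500) {
    p <- adjust_probability(p, runif(1, -1e7, 1e7), runif(1, -1e7, 1e7))
    expect_true(p >= 0 && p <= 1)
  }
  expect_equal(adjust_probability(0.1, -1e9, 1e9), 0)
  expect_equal(adjust_probability(0.9, 1e9, -1e9), 1)
})

test_that("raw sludge matures to bags after the lag and sells at boundaries", {
  cfg <- municipal_config()
  st <- fsabm:::municipal_init_state(cfg)
  st$raw_tick <- 0L
  st$raw_vol <- 3
  st$legal_m3 <- 3
  at179 <- fsabm:::compost_step(st, 179L, cfg)
  expect_equal(at179$compost_bags, 0L)
  at180 <- fsabm:::compost_step(st, 180L, cfg)
  # 3 m3 * 0.5 yield / 0.05 m3 per bag = 30 bags, all bulk-sold on the
  # six-month boundary
  expect_equal(at180$matured_m3, 3)
  expect_equal(at180$bags_sold, 30L)
  expect_equal(at180$council_cash, 30 * 5000)
  expect_equal(at180$compost_bags, 0L)
})

test_that("the council cash series steps up at the first six-month boundary", {
  cfg <- municipal_config(p_legal_init = 1, p_farmer_attempt = 0,
                          multiplier = 0, p_guard_present = 0, n_ticks = 400)
  r <- run_municipal(cfg, seed = 4)
  s <- r$series
  # sludge arriving on days 1-180 matures by day 360, the first boundary
  # with stock; the sale is the only council income in this configuration
  expect_true(all(s$council_cash[s$tick < 360] == 0))
  expect_equal(s$council_cash[s$tick == 360] - s$council_cash[s$tick == 359],
               r$ledger$bulk_sales)
  expect_gt(r$ledger$bulk_sales, 0)
})

test_that("monthly permits bill every company at each month boundary", {
  cfg <- municipal_config(tariff_mode = "monthly_permit", permit_fee = 70000,
                          p_company_job = 0, p_farmer_attempt = 0, n_ticks = 60)
  r <- run_municipal(cfg, seed = 1)
  expect_equal(r$ledger$permits, 2 * 5 * 70000)
  # a 2000-tick run bills 66 renewals: the documented revenue bound
  cfg2 <- municipal_config(tariff_mode = "monthly_permit", permit_fee = 40000,
                           p_company_job = 0, p_farmer_attempt = 0,
                           n_ticks = 2000)
  r2 <- run_municipal(cfg2, seed = 1)
  expect_equal(r2$ledger$permits, 66 * 5 * 40000)
  # per-visit mode never bills permits
  r3 <- run_municipal(municipal_config(n_ticks = 100), seed = 1)
  expect_equal(r3$ledger$permits, 0)
})

test_that("money conservation and volume closure hold exactly per run", {
  for (s in 1:5) {
    cfg <- municipal_config(n_ticks = 500,
                            tariff_mode = if (s %% 2) "per_visit" else "monthly_permit")
    r <- run_municipal(cfg, seed = 100 + s)
    l <- r$ledger
    expect_equal(l$council_cash,
                 l$fees + l$fines_company + l$fines_farmer + l$permits +
                   l$bag_sales + l$bulk_sales)
    # volume closure: every m3 legally received is still raw, matured, or stolen
    expect_equal(l$legal_m3, l$raw_m3 + l$matured_m3 + l$stolen_m3,
                 tolerance = 1e-9)
    expect_true(l$stolen_m3 <= l$legal_m3 + 1e-9)
    p <- r$propensities
    expect_true(all(c(p$p_legal, p$p_steal, p$p_corrupt) >= 0))
    expect_true(all(c(p$p_legal, p$p_steal, p$p_corrupt) <= 1))
  }
})

test_that("the refurbished site eliminates theft in every repeat", {
  for (s in 1:15) {
    r <- run_municipal(municipal_config(refurbished = TRUE, n_ticks = 300),
                       seed = 200 + s)
    expect_equal(r$ledger$stolen_m3, 0)
  }
})

test_that("frozen propensities match the closed-form volume expectations", {
  # multiplier = 0: p_legal fixed at 0.5, so per tick each of 5 companies
  # ships 3 m3 with probability 0.2, half legal half illegal
  cfg <- municipal_config(multiplier = 0, p_legal_init = 0.5,
                          p_farmer_attempt = 0, n_ticks = 400)
  runs <- sapply(1:30, function(s) {
    r <- run_municipal(cfg, seed = 300 + s)
    c(r$ledger$legal_m3, r$ledger$illegal_m3)
  })
  expected <- 400 * 5 * 0.2 * 0.5 * 3  # 600 m3 each
  for (i in 1:2) {
    se <- sd(runs[i, ]) / sqrt(ncol(runs))
    expect_lt(abs(mean(runs[i, ]) - expected), 3 * se + 1e-9)
  }
  # propensities really are frozen
  r <- run_municipal(cfg, seed = 1)
  expect_equal(r$propensities$p_legal, rep(0.5, 5))
})

test_that("an empty system stays empty", {
  cfg <- municipal_config(p_company_job = 0, p_farmer_attempt = 0,
                          n_ticks = 400)
  r <- run_municipal(cfg, seed = 9)
  l <- r$ledger
  expect_equal(l$legal_m3 + l$illegal_m3 + l$stolen_m3, 0)
  expect_equal(l$council_cash, 0)
  expect_true(all(r$series$council_cash == 0))
})

test_that("municipal runs are reproducible and configs validate", {
  a <- run_municipal(municipal_config(n_ticks = 200), seed = 77)
  b <- run_municipal(municipal_config(n_ticks = 200), seed = 77)
  expect_identical(a$series, b$series)
  expect_error(municipal_config(p_guard_present = 2), "p_guard_present")
  expect_error(municipal_config(n_companies = 0), "n_companies")
  # refurbishment implies a full-time guard
  expect_equal(municipal_config(refurbished = TRUE)$p_guard_present, 1)
  # the bribe scenario multiplier scales the bribe
  expect_equal(municipal_config(bribe = 3000, bribe_multiplier = 8)$bribe, 24000)
})
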