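test_that("gross energy is the mass-weighted sum of macronutrient coefficients", {
  expect_equal(gross_energy(feed_spec(0.45, 0.25, 0.15)), 23.075)
  expect_equal(gross_energy(feed_spec(0, 0, 0)), 0)
  expect_error(feed_spec(0.7, 0.5, 0), class = "racewaysim_validation_error")
})

test_that("growth rate is sign-correct across feeding regimes", {
  p <- bioenergetic_params()
  # starvation: pure catabolism
  expect_lt(weight_derivative(100, 12, 0, p), 0)
  expect_lt(weight_derivative(500, 4, 0, p), 0)
  # balance point: intake chosen so anabolism equals catabolism
  bal <- uniroot(function(i) weight_derivative(100, 12, i, p),
                 c(0, max_ingestion(100, 12, p)))$root
  expect_equal(weight_derivative(100, 12, bal, p), 0, tolerance = 1e-9)
  # well above balance: positive growth
  expect_gt(weight_derivative(100, 12, 2 * bal, p), 0)
  expect_error(weight_derivative(-5, 12, 10, p),
               class = "racewaysim_domain_error")
})

test_that("ingestion cap is allometric and shuts down at the thermal maximum", {
  p <- bioenergetic_params(anab_exponent = 2 / 3)
  expect_equal(max_ingestion(100, p$anab_temp_max, p), 0)
  expect_equal(max_ingestion(200, 12, p) / max_ingestion(100, 12, p),
               2^(2 / 3))
  grid <- expand.grid(W = c(1, 50, 500), T = seq(0, 30, by = 2))
  expect_true(all(max_ingestion(grid$W, grid$T, p) >= 0))
})

test_that("respiration: feeding adds SDA, fasting scales with the allometry", {
  p <- bioenergetic_params()
  fast <- metabolic_outputs(150, 14, 0, p)
  fed <- metabolic_outputs(150, 14, 60, p)
  expect_gt(fed$respiration_mgO2_per_h, fast$respiration_mgO2_per_h)
  expect_gte(fast$tan_g_per_d, 0)
  expect_gte(fed$co2_g_per_d, 0)

  p1 <- bioenergetic_params(catab_exponent = 1)
  expect_equal(metabolic_outputs(200, 14, 0, p1)$respiration_mgO2_per_h,
               2 * metabolic_outputs(100, 14, 0, p1)$respiration_mgO2_per_h)

  tiny <- metabolic_outputs(1e-6, 14, 0, p)
  expect_lt(tiny$respiration_mgO2_per_h, 1e-4)
  expect_lt(tiny$tan_g_per_d, 1e-6)
})

test_that("respiration is non-decreasing in temperature up to the optimum", {
  p <- bioenergetic_params()
  temps <- seq(0, p$anab_temp_optimum, by = 0.5)
  resp <- vapply(temps, function(T)
    metabolic_outputs(150, T, 40, p)$respiration_mgO2_per_h, numeric(1))
  expect_true(all(diff(resp) >= 0))
})

test_that("growth integration covers the horizon and honours feeding", {
  co <- fish_cohort(1e5, 80, 16)
  fo <- daily_forcing(135)
  plan <- feed_plan(0:135, rep(2, 136), std_feed())
  tr <- integrate_growth(co, fo, plan, dt = 1)
  expect_equal(nrow(tr) - 1L, 135L)  # one output step per day
  expect_false(attr(tr, "starvation_collapse"))

  # zero-length horizon returns the initial state unchanged
  tr0 <- integrate_growth(co, fo, plan, dt = 1, horizon_d = 0)
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0$mean_weight_g, 80)
  expect_equal(tr0$count, 1e5)

  # ad libitum at the thermal optimum: strictly increasing weight, and the
  # sign of the budget agrees with the instantaneous derivative at each step
  p <- bioenergetic_params()
  fo_opt <- daily_forcing(30, T = p$anab_temp_optimum)
  plan_ad <- feed_plan(0:30, rep(50, 31), std_feed())
  tr_ad <- integrate_growth(fish_cohort(100, 60, 0), fo_opt, plan_ad, p)
  expect_true(all(diff(tr_ad$mean_weight_g) > 0))
  derivs <- weight_derivative(tr_ad$mean_weight_g, p$anab_temp_optimum,
                              50 * gross_energy(std_feed()), p)
  expect_true(all(derivs > 0))
})

test_that("energy is conserved over every integration step", {
  co <- fish_cohort(1000, 90, 10)
  fo <- forcing_series(0:60, 13 + 3 * sin((0:60) / 8), rep(10, 61),
                       rep(1.5e6, 61))
  plan <- feed_plan(c(0, 20, 40), c(1.5, 2.5, 0.5), std_feed())
  tr <- integrate_growth(co, fo, plan)
  p <- attr(tr, "params")
  gain_kJ <- diff(tr$mean_weight_g) * p$fish_energy_density
  net_kJ <- diff(tr$assim_kJ_cum) - diff(tr$catab_kJ_cum)
  expect_equal(gain_kJ, net_kJ, tolerance = 1e-6)
})

test_that("starvation with linear catabolism matches the exponential decay", {
  p <- bioenergetic_params(catab_exponent = 1)
  fo <- daily_forcing(30, T = 12)
  tr <- integrate_growth(fish_cohort(1, 100, 0), fo,
                         feed_plan(0, 0, std_feed()), p, dt = 1)
  k <- p$catab_coeff * exp(p$catab_temp_coeff * 12) / p$fish_energy_density
  expect_equal(tail(tr$mean_weight_g, 1), 100 * exp(-k * 30),
               tolerance = 1e-3)
})

test_that("a larger ration never produces a smaller fish", {
  fo <- daily_forcing(40, T = 12)
  for (r2 in c(0, 0.5, 1)) {
    tr1 <- integrate_growth(fish_cohort(1, 80, 0), fo,
                            feed_plan(0, r2 + 1, std_feed()))
    tr2 <- integrate_growth(fish_cohort(1, 80, 0), fo,
                            feed_plan(0, r2, std_feed()))
    expect_true(all(tr1$mean_weight_g >= tr2$mean_weight_g - 1e-9))
  }
})

test_that("mortality is applied before growth and tracked cumulatively", {
  fo <- daily_forcing(5)
  deaths <- data.frame(time_d = c(1, 3), deaths = c(10, 5))
  tr <- integrate_growth(fish_cohort(1000, 100, 0), fo,
                         feed_plan(0, 1.5, std_feed()), deaths = deaths)
  expect_equal(tail(tr$count, 1), 985)
  expect_equal(attr(tr, "deaths_cum"), 15)
})

test_that("prolonged starvation halts with a collapse flag", {
  fo <- daily_forcing(200, T = 20)
  tr <- integrate_growth(fish_cohort(10, 5, 0), fo,
                         feed_plan(0, 0, std_feed()))
  expect_true(attr(tr, "starvation_collapse"))
  expect_lt(nrow(tr), 201L)
  expect_equal(tail(tr$mean_weight_g, 1), 0)
})
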