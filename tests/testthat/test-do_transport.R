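test_that("saturation concentration matches published solubility values", {
  # Benson-Krause freshwater values at 1 atm (standard solubility table)
  expect_equal(csat(0), 14.621, tolerance = 1e-3)
  expect_equal(csat(10), 11.288, tolerance = 1e-3)
  expect_equal(csat(20), 9.092, tolerance = 1e-3)
  expect_equal(csat(25), 8.263, tolerance = 1e-3)
  # strictly decreasing in temperature
  expect_true(all(diff(csat(seq(0, 40, by = 0.5))) < 0))
  expect_gt(csat(5), csat(25))
  expect_error(csat(45), class = "racewaysim_domain_error")
  # reduced pressure lowers saturation
  expect_lt(csat(15, reaeration_params(pressure_atm = 0.9)), csat(15))
})

test_that("point source mass and concentration arithmetic closes", {
  src <- oxygen_source(2.4, gas_density_kg_m3 = 1.429, efficiency = 0.9)
  expect_equal(delivered_o2_kg_h(src), 3.08664)
  # 1 kg O2/h into 1e5 L/h: 10 mg/L at unit efficiency, 9 mg/L at 0.9
  full <- oxygen_source(1, gas_density_kg_m3 = 1, efficiency = 1)
  expect_equal(source_increment(full, 1e5), 10)
  expect_equal(source_increment(oxygen_source(1, 1, 0.9), 1e5), 9)
  expect_equal(source_increment(oxygen_source(0), 1e6), 0)
  expect_error(source_increment(src, 0), class = "racewaysim_domain_error")
})

test_that("uniform biomass distribution conserves total mass", {
  g <- std_geometry()
  b <- distribute_biomass(4000, "uniform", g)
  expect_equal(b$density_kg_m, 20)
  expect_equal(b$density_kg_m * g$length_m, 4000, tolerance = 1e-6)
  expect_equal(distribute_biomass(0, "uniform", g)$density_kg_m, 0)
  expect_error(distribute_biomass(-1, "uniform", g),
               class = "racewaysim_domain_error")
})

test_that("residence time is volume over flow in hours", {
  g <- std_geometry()  # 1600 m3
  expect_equal(residence_time(g, 1.6e6), 1)
  expect_equal(residence_time(g, 3.2e6), 0.5)
})

test_that("analytic steady profile: boundary, linear drop and fixed point", {
  g <- std_geometry()
  rp0 <- reaeration_params(k_rear_h = 0)
  # sink sized to 2 mg/L over the full length: R * M / Q = 2
  bio <- distribute_biomass(4000, "uniform", g,
                            specific_respiration = 2 * 1.5e6 / 4000)
  prof <- steady_state_profile(10, 1.5e6, g, bio, rp0,
                               x = c(0, 100, 200))
  expect_equal(prof, c(10, 9, 8))
  # zero biomass starting at saturation stays at saturation
  cs <- csat(15)
  prof2 <- steady_state_profile(cs, 1.5e6, g, distribute_biomass(0, "uniform", g),
                                reaeration_params(0.2), T_C = 15)
  expect_equal(prof2, rep(cs, 101), tolerance = 1e-12)
})

test_that("upwind solver reproduces the analytic steady states within 0.1%", {
  g <- std_geometry()
  fo <- const_forcing(12, T = 15, DO = 10, Q = 1.5e6)  # ~11 residence times
  # case 1: no reaeration, uniform sink -> linear profile
  rp0 <- reaeration_params(k_rear_h = 0)
  bio <- distribute_biomass(4000, "uniform", g, specific_respiration = 350)
  fld <- simulate_do(fo, bio, oxygen_source(0), rp0, g, dx = 2,
                     C_init = "inlet")
  an <- steady_state_profile(10, 1.5e6, g, bio, rp0, x = fld$x_m)
  expect_lt(max(abs(fld$C[, ncol(fld$C)] - an) / an), 1e-3)
  # case 2: zero biomass, exponential relaxation toward saturation
  rp <- reaeration_params(k_rear_h = 0.3)
  bio0 <- distribute_biomass(0, "uniform", g)
  fld2 <- simulate_do(fo, bio0, oxygen_source(0), rp, g, dx = 2,
                      C_init = "inlet")
  an2 <- steady_state_profile(10, 1.5e6, g, bio0, rp, T_C = 15, x = fld2$x_m)
  expect_lt(max(abs(fld2$C[, ncol(fld2$C)] - an2) / an2), 1e-3)
})

test_that("equilibrium inlet at saturation with no fish is a fixed point", {
  g <- std_geometry()
  cs <- csat(15)
  fo <- const_forcing(6, T = 15, DO = cs)
  fld <- simulate_do(fo, distribute_biomass(0, "uniform", g),
                     oxygen_source(0), reaeration_params(0.3), g)
  expect_equal(max(abs(fld$C - cs)), 0, tolerance = 1e-9)
})

test_that("DO is non-increasing downstream when the inlet is saturated", {
  g <- std_geometry()
  cs <- csat(16)
  fo <- forcing_series((0:24) / 24, rep(16, 25),
                       rep(cs, 25), 1.5e6 + 2e5 * sin((0:24) / 4))
  bio <- distribute_biomass(6000, "uniform", g, specific_respiration = 340)
  fld <- simulate_do(fo, bio, oxygen_source(0), reaeration_params(0.1), g)
  expect_true(all(apply(fld$C, 2, function(col) all(diff(col) <= 1e-9))))
})

test_that("global oxygen mass balance closes on randomised configurations", {
  set.seed(11)
  for (i in 1:8) {
    g <- raceway_geometry(runif(1, 100, 250), runif(1, 5, 10),
                          runif(1, 0.8, 1.5))
    Q <- runif(1, 5e5, 2e6)
    fo <- forcing_series((0:24) / 24,
                         14 + cumsum(rnorm(25, 0, 0.1)),
                         10 + cumsum(rnorm(25, 0, 0.05)),
                         rep(Q, 25))
    bio <- distribute_biomass(runif(1, 0, 8000), "uniform", g,
                              specific_respiration = runif(1, 100, 400))
    fld <- simulate_do(fo, bio, oxygen_source(runif(1, 0, 2)),
                       reaeration_params(runif(1, 0, 0.4)), g, dx = 4)
    expect_lt(oxygen_budget(fld)$relative_error, 0.005)
  }
})

test_that("halving the grid changes the outlet series by less than 1%", {
  g <- std_geometry()
  fo <- forcing_series((0:24) / 24, rep(15, 25),
                       10 + 0.5 * sin(2 * pi * (0:24) / 24), rep(1.5e6, 25))
  bio <- distribute_biomass(5000, "uniform", g, specific_respiration = 350)
  out <- function(dx) {
    fld <- simulate_do(fo, bio, oxygen_source(0.5), reaeration_params(), g,
                       dx = dx)
    fld$C[nrow(fld$C), ]
  }
  coarse <- out(4); fine <- out(2)
  expect_lt(max(abs(coarse - fine) / fine), 0.01)
})

test_that("a CFL-violating step is rejected naming the admissible step", {
  g <- std_geometry()
  fo <- const_forcing(3)
  bio <- distribute_biomass(1000, "uniform", g, specific_respiration = 300)
  err <- tryCatch(
    simulate_do(fo, bio, oxygen_source(0), reaeration_params(), g,
                dx = 2, dt = 0.5),
    error = identity)
  expect_s3_class(err, "racewaysim_config_error")
  expect_match(conditionMessage(err), "admissible")
})

test_that("anoxia clips at zero and is logged as an event, not an error", {
  g <- std_geometry()
  fo <- const_forcing(6, T = 15, DO = 4, Q = 4e5)
  bio <- distribute_biomass(20000, "uniform", g, specific_respiration = 400)
  fld <- simulate_do(fo, bio, oxygen_source(0), reaeration_params(0), g,
                     dx = 4, C_init = "inlet")
  expect_true(all(fld$C >= 0))
  expect_gt(nrow(fld$events), 0)
  expect_true(all(fld$events$type == "anoxia"))
})
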