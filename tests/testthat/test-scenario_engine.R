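test_that("synthetic forcing is reproducible and structurally sound", {
  spec <- synthetic_forcing_spec(seed = 99)
  f1 <- synthetic_forcing(spec, 5)
  f2 <- synthetic_forcing(spec, 5)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 5 * 24 + 1)

  # diurnal periodicity: lag-24h autocorrelation beats lag-17h
  detr <- f1$temperature_C - mean(f1$temperature_C)
  ac <- acf(detr, lag.max = 30, plot = FALSE)$acf
  expect_gt(ac[25], ac[18])
  ac_do <- acf(f1$inlet_DO_mgL - mean(f1$inlet_DO_mgL), lag.max = 30,
               plot = FALSE)$acf
  expect_gt(ac_do[25], ac_do[18])

  # zero amplitudes and noise give a constant series
  fc <- synthetic_forcing(synthetic_forcing_spec(seasonal_amp_C = 0,
                                                 diurnal_amp_C = 0,
                                                 do_diurnal_amp_mgL = 0,
                                                 noise_sd = 0,
                                                 do_mean_mgL = 10), 2)
  expect_equal(diff(range(fc$temperature_C)), 0)
  expect_equal(diff(range(fc$inlet_DO_mgL)), 0)

  # parameters driving DO negative are rejected
  expect_error(
    synthetic_forcing(synthetic_forcing_spec(do_mean_mgL = 0.2,
                                             do_diurnal_amp_mgL = 1,
                                             noise_sd = 0, seed = 1), 2),
    class = "racewaysim_validation_error")

  # seasonal decline toward winter from a post-peak summer start
  fl <- synthetic_forcing(synthetic_forcing_spec(noise_sd = 0,
                                                 diurnal_amp_C = 0,
                                                 seed = 1), 60)
  daily <- tapply(fl$temperature_C, floor(fl$time_d), mean)
  expect_lt(tail(daily, 1), head(daily, 1))
})

test_that("delayed transfers shift the event by exactly the delay", {
  cfg <- simulation_config(geometry = list(depth_m = 1),
                           fish = list(count = 136000, mean_weight_g = 200,
                                       sd_weight_g = 30),
                           seed = 5)
  rA <- run_scenario(scenario_definition("A", 30, transfer = transfer_rule()),
                     cfg)
  rB <- run_scenario(
    scenario_definition("B", 30, transfer = transfer_rule(delay_days = 7)),
    cfg)
  expect_false(is.null(rA$transfer_event))
  expect_equal(rB$transfer_event$time_d, rA$transfer_event$time_d + 7)

  # identical biomass until the first transfer; one-third removed at it
  pre <- rA$growth$time_d < rA$transfer_event$time_d
  expect_equal(rA$growth$biomass_kg[pre], rB$growth$biomass_kg[pre])
  at <- rA$growth$time_d == rA$transfer_event$time_d
  before <- rA$growth$time_d == rA$transfer_event$time_d - 1
  expect_lt(rA$growth$biomass_kg[at] / rA$growth$biomass_kg[before], 0.70)

  # utilization never reaches 100% up to and including scenario A's transfer
  uA <- rA$utilization
  expect_lte(max(uA$utilization_pct[uA$time_d <= rA$transfer_event$time_d]),
             100)
  # both runs log the transfer as a dated event
  expect_true("transfer" %in% rA$events$type)
})

test_that("an empty raceway at saturated inflow is a fixed point of the run", {
  cfg <- const_config(count = 0, mean_w = 200, T = 15, do_mean = csat(15))
  res <- run_scenario(scenario_definition("empty", 2, transfer = FALSE), cfg)
  expect_equal(max(abs(res$budget$outlet - res$budget$inlet)), 0,
               tolerance = 1e-9)
  expect_equal(max(res$field$inputs$M_total_kg), 0)
})

test_that("the DO solver sees exactly the growth module's daily biomass", {
  cfg <- const_config(count = 20000, mean_w = 150)
  res <- run_scenario(scenario_definition("cc", 4, transfer = FALSE), cfg)
  M_hourly <- res$field$inputs$M_total_kg
  for (d in 0:3) {
    expected <- res$growth$biomass_kg[res$growth$time_d == d]
    expect_equal(unique(M_hourly[(d * 24 + 1):((d + 1) * 24)]), expected)
  }
})

test_that("warm high-biomass runs show diurnal oscillation and downstream decay", {
  cfg <- simulation_config(geometry = list(depth_m = 1),
                           fish = list(count = 40000, mean_weight_g = 250,
                                       sd_weight_g = 0),
                           forcing = list(mean_temp_C = 17, seasonal_amp_C = 0,
                                          diurnal_amp_C = 1.5,
                                          do_mean_mgL = 9.8,
                                          do_diurnal_amp_mgL = 0.5,
                                          noise_sd = 0),
                           seed = 2)
  res <- run_scenario(scenario_definition("july", 10, transfer = FALSE), cfg)
  # monotone downstream decay at every hourly snapshot
  expect_true(all(apply(res$field$C, 2, function(col) all(diff(col) <= 1e-9))))
  # diurnal oscillation at the outlet
  outlet <- res$budget$outlet
  ac <- acf(outlet - mean(outlet), lag.max = 30, plot = FALSE)$acf
  expect_gt(ac[25], ac[18])
  expect_gt(diff(range(outlet)), 0.3)
})

test_that("budget decomposition components behave and close quasi-steadily", {
  # zero biomass: respiration component identically zero
  cfg0 <- const_config(count = 0)
  r0 <- run_scenario(scenario_definition("z", 2, transfer = FALSE), cfg0)
  expect_equal(max(abs(r0$budget$respiration)), 0)

  # inlet at saturation with no fish: reaeration component ~0
  cfgs <- const_config(count = 0, T = 15, do_mean = csat(15))
  rs <- run_scenario(scenario_definition("sat", 2, transfer = FALSE), cfgs)
  expect_equal(max(abs(rs$budget$reaeration)), 0, tolerance = 1e-6)

  # constant-forcing fed run: inlet + source + reaeration + respiration
  # reproduces the outlet within 2%
  cfg <- const_config(count = 25000, mean_w = 200)
  res <- run_scenario(scenario_definition("qs", 2,
                                          policy = control_policy("open_loop",
                                            schedule = supply_schedule(0, 2, 1.5)),
                                          transfer = FALSE), cfg)
  b <- res$budget[-(1:4), ]  # skip the start-up hours
  pred <- b$inlet + b$source + b$reaeration + b$respiration
  expect_lt(max(abs(pred - b$outlet) / b$outlet), 0.02)
  expect_true(all(b$respiration <= 0))
  expect_true(all(b$source >= 0))
})

test_that("exports are schema-stable, overwrite-safe and deterministic", {
  cfg <- const_config(count = 1000, mean_w = 150)
  res <- run_scenario(scenario_definition("expA", 2, transfer = FALSE), cfg)
  dir <- withr::local_tempdir()
  paths <- export_scenario(res, dir)
  expect_length(paths, 3)
  expect_setequal(basename(paths), c("expA_utilization.csv",
                                     "expA_do_field.csv", "expA_budget.csv"))
  b <- read.csv(file.path(dir, "expA_budget.csv"))
  expect_named(b, c("time", "inlet", "outlet", "source", "reaeration",
                    "respiration"))
  u <- read.csv(file.path(dir, "expA_utilization.csv"))
  expect_named(u, c("time", "utilization_pct", "scenario"))

  expect_error(export_scenario(res, dir), class = "racewaysim_io_error")
  expect_silent(export_scenario(res, dir, force = TRUE))

  # end-to-end determinism: identical config and seed, byte-identical files
  res2 <- run_scenario(scenario_definition("expA", 2, transfer = FALSE), cfg)
  dir2 <- withr::local_tempdir()
  export_scenario(res2, dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})
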