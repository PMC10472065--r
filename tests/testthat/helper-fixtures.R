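# Shared fixtures, built in code.

std_geometry <- function() raceway_geometry(200, 8, 1)

std_feed <- function() feed_spec(0.45, 0.25, 0.15)

# constant forcing at hourly cadence
const_forcing <- function(hours, T = 15, DO = 10, Q = 1.5e6) {
  forcing_series(time_d = (0:hours) / 24,
                 temperature_C = rep(T, hours + 1),
                 inlet_DO_mgL = rep(DO, hours + 1),
                 flow_Lh = rep(Q, hours + 1))
}

# constant forcing at daily cadence
daily_forcing <- function(days, T = 13, DO = 10, Q = 1.5e6) {
  forcing_series(time_d = 0:days,
                 temperature_C = rep(T, days + 1),
                 inlet_DO_mgL = rep(DO, days + 1),
                 flow_Lh = rep(Q, days + 1))
}

# a constant-conditions simulation config for engine tests
const_config <- function(count = 25000, mean_w = 200, sd_w = 0, T = 15,
                         do_mean = NULL, ...) {
  simulation_config(geometry = list(depth_m = 1),
                    fish = list(count = count, mean_weight_g = mean_w,
                                sd_weight_g = sd_w),
                    forcing = list(mean_temp_C = T, seasonal_amp_C = 0,
                                   diurnal_amp_C = 0, do_diurnal_amp_mgL = 0,
                                   noise_sd = 0, do_mean_mgL = do_mean),
                    ...)
}

write_forcing_fixture <- function(path, timestamp, temperature, inlet_DO, flow) {
  write.csv(data.frame(timestamp = timestamp, temperature = temperature,
                       inlet_DO = inlet_DO, flow = flow),
            path, row.names = FALSE)
}
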