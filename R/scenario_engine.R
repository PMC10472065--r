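# Scenario engine: couples growth, DO transport, management and control
# into dated runs, generates synthetic forcing, and exports CSV results.
#
# Coupling cadence: growth steps daily on daily-mean forcing; the DO solver
# and the control policy run hourly (matching the raceway residence time);
# biomass is held piecewise-constant within each day.

#' Synthetic forcing specification
#'
#' Parameters of the synthetic forcing generator, which emulates a summer
#' stream: a seasonal temperature cycle declining toward winter, a diurnal
#' temperature oscillation, inlet DO running near saturation with its own
#' diurnal oscillation, constant flow, and Gaussian noise.
#'
#' @param mean_temp_C Annual mean water temperature (degC).
#' @param seasonal_amp_C Seasonal (annual cosine) amplitude (degC).
#' @param diurnal_amp_C Diurnal (daily sine) amplitude (degC).
#' @param do_mean_mgL Mean inlet DO (mg/L); `NULL` ties the inlet to 98% of
#'   the temperature-dependent saturation concentration.
#' @param do_diurnal_amp_mgL Diurnal amplitude of inlet DO (mg/L).
#' @param flow_Lh Water flow rate (L/h), constant.
#' @param noise_sd Gaussian noise s.d. applied to temperature (degC) and
#'   inlet DO (mg/L).
#' @param seed Seed for reproducible noise.
#' @param start_doy Day of year of simulation start (default 184, early
#'   July).
#' @param peak_doy Day of year of the seasonal temperature peak.
#' @return An object of class `synthetic_forcing_spec`.
#' @export
synthetic_forcing_spec <- function(mean_temp_C = 13, seasonal_amp_C = 4,
                                   diurnal_amp_C = 1.5, do_mean_mgL = NULL,
                                   do_diurnal_amp_mgL = 0.6, flow_Lh = 1.5e6,
                                   noise_sd = 0.05, seed = NULL,
                                   start_doy = 184, peak_doy = 200) {
  if (seasonal_amp_C < 0 || diurnal_amp_C < 0 || do_diurnal_amp_mgL < 0)
    abort_validation("amplitudes must be non-negative")
  if (noise_sd < 0) abort_validation("'noise_sd' must be non-negative")
  if (flow_Lh <= 0) abort_validation("'flow_Lh' must be positive")
  structure(as.list(environment()), class = "synthetic_forcing_spec")
}

#' Generate a synthetic forcing series
#'
#' Hourly series over the requested horizon:
#' `T(t) = mean + seasonal * cos(2 pi (doy - peak)/365) +
#' diurnal * sin(2 pi (h - 9)/24) + noise`, and inlet DO analogous (tied to
#' 98% of `csat(T)` unless a mean is given, with its diurnal peak in the
#' late afternoon).  Reproducible for a fixed seed.
#'
#' @param spec A [synthetic_forcing_spec()].
#' @param days Horizon (days).
#' @return A [forcing_series()] at hourly cadence covering `days` days.
#' @export
synthetic_forcing <- function(spec, days) {
  if (!inherits(spec, "synthetic_forcing_spec"))
    abort_validation("'spec' must be a synthetic_forcing_spec")
  if (days <= 0) abort_validation("'days' must be positive")
  t_h <- seq(0, days * 24)
  t_d <- t_h / 24
  doy <- spec$start_doy + t_d
  with_seed(spec$seed, {
    temp <- spec$mean_temp_C +
      spec$seasonal_amp_C * cos(2 * pi * (doy - spec$peak_doy) / 365) +
      spec$diurnal_amp_C * sin(2 * pi * (t_h - 9) / 24) +
      rnorm(length(t_h), sd = spec$noise_sd)
    temp <- pmin(pmax(temp, -1), 40)
    do_base <- if (is.null(spec$do_mean_mgL)) {
      0.98 * csat(pmin(pmax(temp, 0), 40))
    } else {
      rep(spec$do_mean_mgL, length(t_h))
    }
    do <- do_base + spec$do_diurnal_amp_mgL * sin(2 * pi * (t_h - 15) / 24) +
      rnorm(length(t_h), sd = spec$noise_sd)
    if (any(do < 0))
      abort_validation("spec parameters produce negative inlet DO")
    forcing_series(time_d = t_d, temperature_C = temp, inlet_DO_mgL = do,
                   flow_Lh = rep(spec$flow_Lh, length(t_h)))
  })
}

#' Scenario definition
#'
#' Describes one dated scenario run: horizon, initial cohort, feeding,
#' forcing source, transfer rule and oxygen-supply policy.  Fields left
#' `NULL` are filled from the [simulation_config()] passed to
#' [run_scenario()].
#'
#' @param name Scenario label used in exports.
#' @param horizon_d Horizon (days), positive.
#' @param cohort A [fish_cohort()] or `NULL`.
#' @param forcing A [forcing_series()], a [synthetic_forcing_spec()], or
#'   `NULL` (synthetic from the config's forcing block).
#' @param policy A [control_policy()] or `NULL` (from the config).
#' @param transfer A [transfer_rule()], `FALSE` for no transfers, or `NULL`
#'   (from the config's management block).
#' @param ration_pct_bw Daily ration as percent body weight, or `NULL`
#'   (from the config's feed block).
#' @param start_date Calendar date of day 0 (`Date` or string), or `NULL`.
#' @return An object of class `scenario_definition`.
#' @export
scenario_definition <- function(name, horizon_d, cohort = NULL,
                                forcing = NULL, policy = NULL,
                                transfer = NULL, ration_pct_bw = NULL,
                                start_date = NULL) {
  if (horizon_d <= 0) abort_validation("'horizon_d' must be positive")
  structure(list(name = name, horizon_d = horizon_d, cohort = cohort,
                 forcing = forcing, policy = policy, transfer = transfer,
                 ration_pct_bw = ration_pct_bw, start_date = start_date),
            class = "scenario_definition")
}

# Daily growth path with an optional transfer event; ration is recomputed
# each day as a fraction of current mean body weight.  Forcing enters as
# daily means.
grow_path <- function(cohort, n_days, daily_T, ration_pct_bw, feed, params,
                      event = NULL) {
  ge <- gross_energy(feed)
  W <- c(mean = cohort$mean_weight_g,
         lo = max(cohort$mean_weight_g - cohort$sd_weight_g, 1e-3),
         hi = cohort$mean_weight_g + cohort$sd_weight_g)
  count <- cohort$count
  rows <- vector("list", n_days + 1L)
  for (d in 0:n_days) {
    if (!is.null(event) && !is.na(event$time_d) &&
        abs(event$time_d - d) < 0.5 && is.null(event$applied)) {
      count <- count * (1 - event$fraction)
      event$applied <- TRUE
    }
    intake <- ration_pct_bw / 100 * W[["mean"]] * ge
    rows[[d + 1L]] <- data.frame(
      time_d = d, mean_weight_g = W[["mean"]], lo_weight_g = W[["lo"]],
      hi_weight_g = W[["hi"]], count = count,
      biomass_kg = count * W[["mean"]] / 1000,
      intake_kJ_d = intake,
      temperature_C = daily_T[min(d + 1L, length(daily_T))])
    if (d < n_days) {
      Tday <- daily_T[d + 1L]
      for (nm in c("mean", "lo", "hi")) {
        intake_nm <- ration_pct_bw / 100 * W[[nm]] * ge
        inc <- rk4_growth_step(W[[nm]], d, 1, function(t) Tday,
                               function(t) intake_nm, params)
        W[[nm]] <- max(W[[nm]] + inc[1], 1e-3)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a coupled scenario
#'
#' Executes one scenario end to end: daily growth of the cohort, hourly
#' solution of the DO balance with the policy's oxygen supply, daily
#' evaluation of the transfer rule (planned from a forecast growth run),
#' and assembly of the DO-budget decomposition.  Transfers, supply cutoffs,
#' controller saturation and anoxia are logged as dated events; the run is
#' deterministic for a fixed forcing seed.
#'
#' @param defn A [scenario_definition()].
#' @param config A [simulation_config()].
#' @return An object of class `scenario_result`: `growth` (daily data
#'   frame), `utilization` (daily, percent), `field` (`do_field`, hourly),
#'   `budget` (hourly [budget_decomposition()]), `events` (data frame),
#'   plus the resolved definition.
#' @export
run_scenario <- function(defn, config) {
  if (!inherits(defn, "scenario_definition"))
    abort_validation("'defn' must be a scenario_definition")
  if (!inherits(config, "simulation_config"))
    abort_validation("'config' must be a simulation_config")
  geometry <- config$geometry_obj
  horizon <- defn$horizon_d
  rear <- reaeration_params(config$do_model$k_rear_h,
                            pressure_atm = config$do_model$pressure_atm)
  base_source <- oxygen_source(0, config$do_model$gas_density_kg_m3,
                               config$do_model$efficiency)
  policy <- defn$policy %||% control_policy(
    mode = config$control$mode, threshold_mgL = config$control$threshold_mgL,
    setpoint_mgL = config$control$setpoint_mgL, gain = config$control$gain,
    max_supply_m3h = config$control$max_supply_m3h)
  rule <- if (isFALSE(defn$transfer)) NULL else defn$transfer %||%
    transfer_rule(config$management$baseline_kg_m3,
                  config$management$transfer_fraction,
                  config$management$lead_days, config$management$delay_days)
  start_date <- as.Date(defn$start_date %||% config$start_date)

  forcing <- defn$forcing
  if (is.null(forcing))
    forcing <- do.call(synthetic_forcing_spec,
                       c(config$forcing, list(seed = config$seed)))
  if (inherits(forcing, "synthetic_forcing_spec"))
    forcing <- synthetic_forcing(forcing, horizon)
  if (!inherits(forcing, "forcing_series"))
    abort_validation("scenario forcing must be a forcing_series or spec")
  if (max(forcing$time_d) < horizon - 1e-9)
    abort_validation("forcing does not cover the scenario horizon")

  cohort <- defn$cohort %||% fish_cohort(config$fish$count,
                                         config$fish$mean_weight_g,
                                         config$fish$sd_weight_g)
  feed <- feed_spec(config$feed$protein_frac, config$feed$lipid_frac,
                    config$feed$carb_frac,
                    c(protein = config$feed$energy_protein_kJ_g,
                      lipid = config$feed$energy_lipid_kJ_g,
                      carbohydrate = config$feed$energy_carb_kJ_g))
  ration_pct <- defn$ration_pct_bw %||% config$feed$ration_pct_bw
  bio_params <- bioenergetic_params()

  # daily-mean temperature for the growth step
  day_bin <- pmin(floor(forcing$time_d), horizon - 1)
  daily_T <- as.numeric(tapply(forcing$temperature_C, day_bin, mean))

  events <- list()
  log_event <- function(time_d, type, detail) {
    events[[length(events) + 1L]] <<- data.frame(
      time_d = time_d, date = as.character(start_date + floor(time_d)),
      type = type, detail = detail)
  }

  forecast <- grow_path(cohort, horizon, daily_T, ration_pct, feed, bio_params)
  event <- NULL
  if (!is.null(rule)) {
    event <- plan_transfer(forecast[, c("time_d", "biomass_kg")], rule,
                           geometry$volume_m3)
    if (!is.null(event))
      log_event(event$time_d, "transfer",
                sprintf("transfer %.1f%% of biomass (predicted full utilization on day %g)",
                        100 * event$fraction, event$predicted_crossing_d))
  }
  growth <- grow_path(cohort, horizon, daily_T, ration_pct, feed, bio_params,
                      event = event)

  # --- hourly DO + control loop -------------------------------------------
  dx <- geometry$length_m / (config$time$spatial_cells - 1L)
  x <- seq(0, geometry$length_m, length.out = config$time$spatial_cells)
  u_max <- max(forcing$flow_Lh) / (1000 * geometry$cross_section_m2)
  dt_solver <- 0.9 * dx / u_max
  n_hours <- horizon * 24L
  times_d <- (0:n_hours) / 24

  bio_at <- function(j_hour) {
    # biomass of the day (piecewise constant), respiration at the hour's T
    day <- min(floor(times_d[j_hour + 1L]), horizon - 1)
    row <- growth[growth$time_d == day, ]
    Th <- forcing_at(forcing, times_d[j_hour + 1L])$temperature_C
    mo <- metabolic_outputs(row$mean_weight_g, min(max(Th, 0), 40),
                            row$intake_kJ_d, bio_params)
    r_spec <- if (row$biomass_kg > 0)
      mo$respiration_mgO2_per_h * 1000 / row$mean_weight_g else 0
    distribute_biomass(row$biomass_kg, "uniform", geometry,
                       specific_respiration = r_spec)
  }

  ctrl_state <- function(t_d, bio) {
    f <- forcing_at(forcing, t_d)
    list(C_in_mgL = f$inlet_DO_mgL, T_C = f$temperature_C, Q_Lh = f$flow_Lh,
         biomass = bio)
  }

  valve <- 0
  prev_supply <- NA_real_
  pick_supply <- function(j, bio, outlet_prev) {
    t_d <- times_d[j]
    switch(policy$mode,
      open_loop = list(supply_m3h = scheduled_supply(policy$schedule, t_d),
                       saturated = FALSE),
      green = green_supply(ctrl_state(t_d, bio), geometry, rear, base_source,
                           policy$max_supply_m3h, policy$tol_mgL),
      welfare = {
        # the supply holds for the coming control interval while water from
        # the previous one is still in transit: evaluate the requirement at
        # the interval endpoints and one step back, and keep the largest
        cand <- lapply(c(max(t_d - 1 / 24, 0), t_d, t_d + 1 / 24),
                       function(tt)
                         welfare_supply(ctrl_state(tt, bio), geometry, rear,
                                        base_source, policy$threshold_mgL,
                                        policy$max_supply_m3h, policy$tol_mgL))
        cand[[which.max(vapply(cand, `[[`, numeric(1), "supply_m3h"))]]
      },
      feedback = {
        valve <<- feedback_step(outlet_prev, policy$setpoint_mgL, valve,
                                policy$gain, policy$max_supply_m3h)
        list(supply_m3h = valve, saturated = valve >= policy$max_supply_m3h)
      })
  }

  C <- matrix(NA_real_, nrow = length(x), ncol = n_hours + 1L)
  bio0 <- bio_at(0L)
  f0 <- forcing_at(forcing, 0)
  sup0 <- pick_supply(1L, bio0, f0$inlet_DO_mgL)
  src0 <- base_source; src0$supply_m3_per_h <- sup0$supply_m3h
  C[, 1L] <- pmax(steady_state_profile(
    f0$inlet_DO_mgL + source_increment(src0, f0$flow_Lh), f0$flow_Lh,
    geometry, bio0, rear, T_C = min(max(f0$temperature_C, 0), 40), x = x), 0)

  supply_series <- numeric(n_hours)
  M_series <- numeric(n_hours)
  R_series <- numeric(n_hours)
  Cv <- C[, 1L]
  for (j in seq_len(n_hours)) {
    bio <- bio_at(j - 1L)
    sup <- pick_supply(j, bio, Cv[length(x)])
    if (isTRUE(sup$saturated))
      log_event(times_d[j], "saturation",
                sprintf("controller demand clamped at max supply %.2f m3/h",
                        policy$max_supply_m3h))
    if (!is.na(prev_supply) && prev_supply > 0 && sup$supply_m3h == 0)
      log_event(times_d[j], "supply_cutoff", "oxygen supply interrupted")
    prev_supply <- sup$supply_m3h
    src <- base_source; src$supply_m3_per_h <- sup$supply_m3h
    step <- do_interval(Cv, times_d[j] * 24, times_d[j + 1L] * 24,
                        forcing_at(forcing, times_d[j]),
                        forcing_at(forcing, times_d[j + 1L]),
                        src, bio, rear, geometry, dx, dt_solver)
    Cv <- step$C
    if (!is.null(step$events))
      for (i in seq_len(nrow(step$events)))
        log_event(step$events$time_h[i] / 24, "anoxia", step$events$detail[i])
    C[, j + 1L] <- Cv
    supply_series[j] <- sup$supply_m3h
    M_series[j] <- bio$M_total
    R_series[j] <- bio$specific_respiration_mgO2_kg_h
  }

  inputs <- list(forcing = forcing, geometry = geometry, params = rear,
                 source = base_source, dx = dx,
                 supply_m3h = supply_series, M_total_kg = M_series,
                 specific_respiration = R_series)
  field <- new_do_field(x_m = x, time_h = times_d * 24, C = C,
                        events = NULL, inputs = inputs)

  utilization <- data.frame(
    time_d = growth$time_d,
    date = as.character(start_date + growth$time_d),
    utilization_pct = 100 * growth$biomass_kg /
      (geometry$volume_m3 *
         (rule$baseline_kg_m3 %||% config$management$baseline_kg_m3)),
    scenario = defn$name)

  structure(list(name = defn$name, growth = growth,
                 utilization = utilization, field = field,
                 budget = budget_decomposition(field),
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(time_d = numeric(),
                                          date = character(),
                                          type = character(),
                                          detail = character()),
                 transfer_event = event, start_date = start_date,
                 policy = policy),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %d days, final biomass %.0f kg, DO range [%.2f, %.2f] mg/L, %d event(s)\n",
              x$name, max(x$growth$time_d), tail(x$growth$biomass_kg, 1),
              min(x$field$C), max(x$field$C), nrow(x$events)))
  invisible(x)
}

#' Decompose the DO budget of a simulated field
#'
#' Per reported time, the components of the dissolved-oxygen balance: DO at
#' the raceway inlet and outlet (point values), the point-source supply,
#' and the reaeration and respiration fractions accumulated along the
#' streamwise direction (distributed components, expressed per unit
#' through-flow in mg/L).  Respiration is a consumption and therefore a
#' negative component.  Under quasi-steady conditions
#' `outlet = inlet + source + reaeration + respiration` within a few
#' percent.
#'
#' @param field A `do_field` carrying its `inputs` record ([simulate_do()]
#'   or [run_scenario()] output).
#' @return A data frame of class `do_budget` with columns
#'   `time,inlet,outlet,source,reaeration,respiration` (`time` in hours).
#' @export
budget_decomposition <- function(field) {
  inp <- field$inputs
  if (is.null(inp)) abort_validation("field carries no inputs record")
  g <- inp$geometry
  n <- length(field$x_m)
  n_t <- length(field$time_h)
  f <- lapply(inp$forcing$time_d, function(t) forcing_at(inp$forcing, t))
  Q <- vapply(f, `[[`, numeric(1), "flow_Lh")
  Tw <- pmin(pmax(vapply(f, `[[`, numeric(1), "temperature_C"), 0), 40)
  Cs <- csat(Tw, inp$params)
  cellw <- diff(field$x_m)
  vol_L <- g$cross_section_m2 * cellw * 1000

  iv <- pmin(pmax(seq_len(n_t) - 1L, 1L), max(length(inp$supply_m3h), 1L))
  src <- inp$source
  source_mgL <- vapply(seq_len(n_t), function(j) {
    s <- src; s$supply_m3_per_h <- inp$supply_m3h[iv[j]]
    source_increment(s, Q[j])
  }, numeric(1))
  rear_mgL <- vapply(seq_len(n_t), function(j)
    sum(inp$params$k_rear_h * (Cs[j] - field$C[-1L, j]) * vol_L) / Q[j],
    numeric(1))
  resp_mgL <- -inp$specific_respiration[iv] * inp$M_total_kg[iv] / Q

  structure(data.frame(time = field$time_h,
                       inlet = vapply(f, `[[`, numeric(1), "inlet_DO_mgL"),
                       outlet = field$C[n, ],
                       source = source_mgL,
                       reaeration = rear_mgL,
                       respiration = resp_mgL),
            class = c("do_budget", "data.frame"))
}

#' Export a scenario run to CSV
#'
#' Writes `<name>_utilization.csv` (`time,utilization_pct,scenario`),
#' `<name>_do_field.csv` (`x_m,time,DO_mgL`, long format) and
#' `<name>_budget.csv` (`time,inlet,outlet,source,reaeration,respiration`)
#' into `directory`; a JSON-lines event log `<name>_events.jsonl` is added
#' when the run logged events.  Existing files are not overwritten unless
#' `force = TRUE`.
#'
#' @param result A `scenario_result`.
#' @param directory Output directory (created if missing).
#' @param force Overwrite existing files.
#' @return Invisibly, the paths written.
#' @export
export_scenario <- function(result, directory, force = FALSE) {
  if (!inherits(result, "scenario_result"))
    abort_validation("'result' must be a scenario_result")
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok) abort_io(sprintf("cannot create directory '%s'", directory))
  nm <- gsub("[^A-Za-z0-9_.-]", "_", result$name)
  paths <- file.path(directory, paste0(nm, c("_utilization.csv",
                                             "_do_field.csv", "_budget.csv")))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force)
    abort_io(sprintf("refusing to overwrite existing file(s): %s (use force = TRUE)",
                     paste(basename(existing), collapse = ", ")))
  util <- data.frame(time = result$utilization$time_d,
                     utilization_pct = result$utilization$utilization_pct,
                     scenario = result$utilization$scenario)
  write.csv(util, paths[1L], row.names = FALSE)
  write_field_csv(result$field, paths[2L])
  write.csv(as.data.frame(unclass(result$budget)), paths[3L],
            row.names = FALSE)
  written <- paths
  if (nrow(result$events) > 0) {
    ev_path <- file.path(directory, paste0(nm, "_events.jsonl"))
    if (file.exists(ev_path) && !force)
      abort_io(sprintf("refusing to overwrite existing file(s): %s (use force = TRUE)",
                       basename(ev_path)))
    con <- file(ev_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(result$events)))
      writeLines(jsonlite::toJSON(as.list(result$events[i, ]),
                                  auto_unbox = TRUE), con)
    written <- c(written, ev_path)
  }
  invisible(written)
}
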