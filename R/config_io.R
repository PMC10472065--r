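# Configuration, unit conventions and CSV I/O.
#
# Unit conventions, fixed at the package boundary and never converted inside
# the numerics: temperature degC, dissolved oxygen mg/L, water flow L/h,
# lengths m, individual weight g, biomass kg, energy kJ.  Time is fractional
# days from simulation start; calendar dates map through a configured start
# date.

#' Raceway geometry
#'
#' Physical domain of a single flow-through raceway basin.  The streamwise
#' coordinate runs from 0 at the inlet to `length_m` at the outlet; the
#' cross-sectional area `width_m * depth_m` converts the water flow rate into
#' a streamwise velocity.
#'
#' @param length_m Raceway length (m).
#' @param width_m Raceway width (m).
#' @param depth_m Water depth (m).  Site-specific; no universal default.
#' @return An object of class `raceway_geometry` with fields `length_m`,
#'   `width_m`, `depth_m`, `cross_section_m2` and `volume_m3`.
#' @examples
#' raceway_geometry(200, 8, 1)
#' @export
raceway_geometry <- function(length_m, width_m, depth_m) {
  for (nm in c("length_m", "width_m", "depth_m")) {
    v <- get(nm)
    stopifnot_scalar(v, nm)
    if (v <= 0) abort_validation(sprintf("'%s' must be strictly positive", nm))
  }
  structure(list(length_m = length_m, width_m = width_m, depth_m = depth_m,
                 cross_section_m2 = width_m * depth_m,
                 volume_m3 = length_m * width_m * depth_m),
            class = "raceway_geometry")
}

#' @export
print.raceway_geometry <- function(x, ...) {
  cat(sprintf("<raceway_geometry> %g m x %g m x %g m (A = %g m2, V = %g m3)\n",
              x$length_m, x$width_m, x$depth_m,
              x$cross_section_m2, x$volume_m3))
  invisible(x)
}

#' Forcing time series
#'
#' Time-indexed boundary conditions of the raceway: water temperature, inlet
#' dissolved-oxygen concentration (upstream of the point oxygen source) and
#' water flow rate.
#'
#' @param time_d Strictly increasing time points, fractional days from start.
#' @param temperature_C Water temperature (degC), within \[-1, 40\].
#' @param inlet_DO_mgL Dissolved oxygen at the inlet (mg/L), non-negative.
#' @param flow_Lh Water flow rate (L/h), strictly positive.
#' @return A data frame of class `forcing_series`.
#' @export
forcing_series <- function(time_d, temperature_C, inlet_DO_mgL, flow_Lh) {
  n <- length(time_d)
  if (n < 1L) abort_validation("forcing series must contain at least one row")
  if (length(temperature_C) != n || length(inlet_DO_mgL) != n ||
      length(flow_Lh) != n)
    abort_validation("forcing columns must all have the same length")
  if (anyNA(time_d) || any(diff(time_d) <= 0))
    abort_validation("forcing timestamps must be strictly increasing")
  if (anyNA(temperature_C) || any(temperature_C < -1 | temperature_C > 40))
    abort_validation("temperature must lie within [-1, 40] degC")
  if (anyNA(inlet_DO_mgL) || any(inlet_DO_mgL < 0))
    abort_validation("inlet DO must be non-negative")
  if (anyNA(flow_Lh) || any(flow_Lh <= 0))
    abort_validation("flow must be strictly positive")
  structure(data.frame(time_d = as.numeric(time_d),
                       temperature_C = as.numeric(temperature_C),
                       inlet_DO_mgL = as.numeric(inlet_DO_mgL),
                       flow_Lh = as.numeric(flow_Lh)),
            class = c("forcing_series", "data.frame"))
}

# Linear interpolation of the forcing at arbitrary times (constant
# extrapolation at the ends).
forcing_at <- function(forcing, t_d) {
  list(temperature_C = approx(forcing$time_d, forcing$temperature_C,
                              xout = t_d, rule = 2)$y,
       inlet_DO_mgL  = approx(forcing$time_d, forcing$inlet_DO_mgL,
                              xout = t_d, rule = 2)$y,
       flow_Lh       = approx(forcing$time_d, forcing$flow_Lh,
                              xout = t_d, rule = 2)$y)
}

#' Read a forcing CSV
#'
#' Reads sensor-export style forcing files with one header row and columns
#' `timestamp,temperature,inlet_DO,flow` (comma separated, dot decimal).
#' Timestamps are numeric in the cadence's native unit (hours for `"hourly"`,
#' days for `"daily"`).  Sub-cadence rows (e.g. 15-minute samples in an
#' hourly file) are aggregated to the cadence grid by their mean.  Gaps of up
#' to 3 grid steps are filled by linear interpolation; longer gaps are
#' rejected with a data-gap error naming the interval.
#'
#' @param path Path to the CSV file.
#' @param cadence `"hourly"` or `"daily"`.
#' @return A [forcing_series()] with time in fractional days.
#' @export
read_forcing_csv <- function(path, cadence = c("hourly", "daily")) {
  cadence <- match.arg(cadence)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temperature", "inlet_DO", "flow")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort_format(sprintf("forcing file lacks required column(s): %s",
                         paste(missing, collapse = ", ")))
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  if (anyNA(ts)) abort_format("timestamps must be numeric")
  if (any(diff(ts) <= 0))
    abort_validation("forcing timestamps must be strictly increasing")

  # Aggregate to the integer cadence grid by mean within each bin.
  bin <- floor(ts + 1e-9)
  agg <- function(v) as.numeric(tapply(v, bin, mean))
  grid_have <- sort(unique(bin))
  vals <- data.frame(timestamp = grid_have,
                     temperature = agg(raw$temperature),
                     inlet_DO = agg(raw$inlet_DO),
                     flow = agg(raw$flow))

  grid_full <- seq(min(grid_have), max(grid_have))
  gap_missing <- setdiff(grid_full, grid_have)
  if (length(gap_missing)) {
    runs <- split(gap_missing, cumsum(c(1, diff(gap_missing) != 1)))
    for (r in runs) {
      if (length(r) > 3L)
        abort_data_gap(sprintf(
          "data gap of %d steps between timestamps %g and %g exceeds 3 steps",
          length(r), min(r) - 1, max(r) + 1))
    }
    fill <- function(v) approx(vals$timestamp, v, xout = grid_full)$y
    vals <- data.frame(timestamp = grid_full,
                       temperature = fill(vals$temperature),
                       inlet_DO = fill(vals$inlet_DO),
                       flow = fill(vals$flow))
  }

  unit_d <- if (cadence == "hourly") 1 / 24 else 1
  forcing_series(time_d = vals$timestamp * unit_d,
                 temperature_C = vals$temperature,
                 inlet_DO_mgL = vals$inlet_DO,
                 flow_Lh = vals$flow)
}

#' Write / read a dissolved-oxygen field CSV
#'
#' Long-format export of a space-time DO field with columns
#' `x_m,time,DO_mgL` (`time` in hours), one row per (node, time) pair,
#' time-major.  `read_field_csv()` reverses the operation; a write/read
#' round trip reproduces every value.
#'
#' @param field A `do_field` as returned by [simulate_do()].
#' @param path Output path.
#' @return `write_field_csv()` invisibly returns `path`; `read_field_csv()`
#'   returns a bare `do_field` (grid and concentrations only).
#' @export
write_field_csv <- function(field, path) {
  if (!inherits(field, "do_field")) abort_validation("'field' must be a do_field")
  if (length(field$x_m) == 0L || length(field$time_h) == 0L)
    abort_validation("cannot export an empty DO field")
  df <- data.frame(x_m = rep(field$x_m, times = length(field$time_h)),
                   time = rep(field$time_h, each = length(field$x_m)),
                   DO_mgL = as.vector(field$C))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write field CSV to '%s'", path))
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- read.csv(path)
  need <- c("x_m", "time", "DO_mgL")
  if (!all(need %in% names(df)))
    abort_format("field CSV must have columns x_m,time,DO_mgL")
  x <- unique(df$x_m)
  times <- unique(df$time)
  C <- matrix(df$DO_mgL, nrow = length(x), ncol = length(times))
  new_do_field(x_m = x, time_h = times, C = C)
}

# ---------------------------------------------------------------------------
# Simulation configuration ---------------------------------------------------

# Single defaults table: every configurable value in the package and its
# default.  `geometry$depth_m` is deliberately NA: the water depth is
# site-specific and must always be supplied.
config_defaults <- function() {
  list(
    start_date = "2019-07-01",
    seed = 1L,
    time = list(growth_step_d = 1, do_step_h = 1, spatial_cells = 101L),
    geometry = list(length_m = 200, width_m = 8, depth_m = NA_real_),
    fish = list(count = 1e5, mean_weight_g = 80, sd_weight_g = 16),
    feed = list(protein_frac = 0.45, lipid_frac = 0.25, carb_frac = 0.15,
                energy_protein_kJ_g = 23.6, energy_lipid_kJ_g = 39.5,
                energy_carb_kJ_g = 17.2, ration_pct_bw = 1.5),
    do_model = list(k_rear_h = 0.1, pressure_atm = 1,
                    gas_density_kg_m3 = 1.429, efficiency = 0.9),
    control = list(mode = "open_loop", threshold_mgL = 9.5,
                   setpoint_mgL = 9, gain = 0.5, max_supply_m3h = 5,
                   schedule = list()),
    management = list(baseline_kg_m3 = 20, transfer_fraction = 1 / 3,
                      lead_days = 1, delay_days = 0, harvest_weight_g = 350,
                      min_feed_temp_C = 2),
    forcing = list(flow_Lh = 1.5e6, mean_temp_C = 13, seasonal_amp_C = 4,
                   diurnal_amp_C = 1.5, do_mean_mgL = NULL,
                   do_diurnal_amp_mgL = 0.6, noise_sd = 0.05),
    scenario = list(horizon_d = 30, variant = "A")
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) abort_validation(sprintf("block '%s' must be a mapping", block))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort_validation(sprintf("unknown key(s) in '%s': %s", block,
                             paste(unknown, collapse = ", ")))
  modifyList(defaults, user, keep.null = TRUE)
}

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a coupled run.  All
#' values default to the package's documented defaults table (see Details);
#' only the raceway water depth (`geometry$depth_m`) has no default and must
#' be supplied.  Unknown keys, at the top level or within a block, are
#' rejected by name.
#'
#' @details Blocks and defaults: `time` (growth step 1 d, DO reporting step
#'   1 h, 101 spatial cells), `geometry` (200 m x 8 m, depth required),
#'   `fish` (1e5 individuals, 80 +/- 16 g), `feed` (45/25/15 %
#'   protein/lipid/carbohydrate at 23.6/39.5/17.2 kJ/g, ration 1.5 %BW/d),
#'   `do_model` (k_rear 0.1 /h, 1 atm, gasified-oxygen density 1.429 kg/m3,
#'   gasification efficiency 0.9), `control` (open loop; welfare threshold
#'   9.5 mg/L; max supply 5 m3/h; proportional gain 0.5), `management`
#'   (baseline density 20 kg/m3, transfer fraction 1/3, lead 1 d, delay 0 d,
#'   harvest weight 350 g), `forcing` (flow 1.5e6 L/h, mean 13 degC,
#'   seasonal/diurnal amplitudes 4/1.5 degC, inlet DO tied to saturation
#'   unless `do_mean_mgL` is set), `scenario` (horizon 30 d, variant "A").
#'
#' @param ... Named blocks (`geometry`, `time`, `fish`, `feed`, `do_model`,
#'   `control`, `management`, `forcing`, `scenario`) and scalars
#'   (`start_date`, `seed`) overriding the defaults.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  user <- list(...)
  defs <- config_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    abort_validation(sprintf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", ")))
  cfg <- defs
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(defs[[nm]])) merge_block(defs[[nm]], user[[nm]], nm)
                 else user[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (is.na(g$depth_m))
    abort_validation("geometry$depth_m is required (no default raceway depth)")
  cfg$geometry_obj <- raceway_geometry(g$length_m, g$width_m, g$depth_m)
  if (cfg$time$do_step_h > cfg$time$growth_step_d * 24)
    abort_validation("DO time step must not exceed the growth time step")
  if (cfg$time$spatial_cells < 2L)
    abort_validation("at least 2 spatial cells are required")
  if (cfg$do_model$efficiency < 0 || cfg$do_model$efficiency > 1)
    abort_validation("do_model$efficiency must lie in [0, 1]")
  if (!cfg$control$mode %in% c("open_loop", "green", "welfare", "feedback"))
    abort_validation("control$mode must be open_loop, green, welfare or feedback")
  structure(cfg, class = "simulation_config")
}

#' Load / dump a configuration file
#'
#' `load_config()` reads a YAML or JSON document, fills every omitted value
#' from the defaults table of [simulation_config()] and validates the result;
#' unknown keys are rejected by name.  `dump_config()` writes a configuration
#' back to YAML; loading a dumped configuration yields an equal configuration.
#'
#' @param path Path to a YAML or JSON file.
#' @param config A `simulation_config`.
#' @return `load_config()` returns a `simulation_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc)) abort_format("configuration document must be a mapping")
  do.call(simulation_config, doc)
}

#' @rdname load_config
#' @export
dump_config <- function(config, path) {
  if (!inherits(config, "simulation_config"))
    abort_validation("'config' must be a simulation_config")
  out <- unclass(config)
  out$geometry_obj <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
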