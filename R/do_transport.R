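# One-dimensional dissolved-oxygen transport along the raceway.
#
# The streamwise DO balance is advection with a reaeration exchange term and
# a biomass-distributed respiration sink:
#
#   dC/dt = -(Q/A) dC/dx + k_rear (Csat - C) - (R/A) dM/dx
#
# with C in mg/L, Q the flow (L/h), A the cross-section (m2), k_rear the
# reaeration rate (1/h), R the specific respiration of the stock
# (mg O2 kg^-1 h^-1) and dM/dx the biomass density along x (kg/m).  A point
# oxygen source at the inlet raises the boundary concentration by
# supply * gas_density * efficiency / Q.  The solver is explicit first-order
# upwind on a node-centred grid over [0, length], stable under the CFL
# condition u dt / dx <= 1 with u = Q / (1000 A) in m/h.

#' Reaeration and saturation parameters
#'
#' @param k_rear_h Reaeration rate constant (1/h), non-negative.
#' @param csat_formula Name of the freshwater saturation formula; only
#'   `"benson-krause"` is implemented.
#' @param pressure_atm Barometric pressure (atm).
#' @return An object of class `reaeration_params`.
#' @export
reaeration_params <- function(k_rear_h = 0.1, csat_formula = "benson-krause",
                              pressure_atm = 1) {
  if (k_rear_h < 0) abort_validation("'k_rear_h' must be non-negative")
  if (!identical(csat_formula, "benson-krause"))
    abort_validation("unknown saturation formula; available: benson-krause")
  if (pressure_atm <= 0) abort_validation("'pressure_atm' must be positive")
  structure(list(k_rear_h = k_rear_h, csat_formula = csat_formula,
                 pressure_atm = pressure_atm),
            class = "reaeration_params")
}

#' Freshwater dissolved-oxygen saturation concentration
#'
#' Benson-Krause formulation for zero-salinity water in equilibrium with
#' water-saturated air, with the standard barometric pressure correction.
#' Strictly decreasing in temperature over the valid range.
#'
#' @param T Water temperature (degC), within \[0, 40\].
#' @param params A [reaeration_params()] (supplies the pressure).
#' @return Saturation concentration (mg/L).
#' @examples
#' csat(20)  # about 9.09 mg/L
#' @export
csat <- function(T, params = reaeration_params()) {
  if (any(!is.finite(T)) || any(T < 0 | T > 40))
    abort_domain("temperature outside the [0, 40] degC validity range")
  TK <- T + 273.15
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.243800e10 / TK^3 - 8.621949e11 / TK^4
  C1 <- exp(lnC)
  P <- params$pressure_atm
  if (identical(P, 1)) return(C1)
  # USGS pressure correction: Pwv vapour pressure (atm), theta second
  # virial-like coefficient.
  Pwv <- exp(11.8571 - 3840.70 / TK - 216961 / TK^2)
  theta <- 0.000975 - 1.426e-5 * T + 6.436e-8 * T^2
  C1 * P * ((1 - Pwv / P) * (1 - theta * P)) / ((1 - Pwv) * (1 - theta))
}

#' Point oxygen source
#'
#' Liquid-oxygen supply gasified at the raceway inlet.  `supply_m3_per_h` is
#' the gas-phase volume flow; the delivered oxygen mass per hour is
#' `supply * gas_density * efficiency`.
#'
#' @param supply_m3_per_h Gas-volume supply rate (m3/h), non-negative.
#' @param gas_density_kg_m3 Density of the gasified oxygen (kg/m3).
#' @param efficiency Gasification/transfer efficiency, in \[0, 1\].
#' @return An object of class `oxygen_source`.
#' @export
oxygen_source <- function(supply_m3_per_h, gas_density_kg_m3 = 1.429,
                          efficiency = 0.9) {
  if (supply_m3_per_h < 0) abort_validation("'supply_m3_per_h' must be non-negative")
  if (gas_density_kg_m3 <= 0) abort_validation("'gas_density_kg_m3' must be positive")
  if (efficiency < 0 || efficiency > 1)
    abort_validation("'efficiency' must lie in [0, 1]")
  structure(list(supply_m3_per_h = supply_m3_per_h,
                 gas_density_kg_m3 = gas_density_kg_m3,
                 efficiency = efficiency),
            class = "oxygen_source")
}

#' Delivered oxygen mass of a source
#'
#' @param source An [oxygen_source()].
#' @return Delivered mass flow (kg O2/h).
#' @export
delivered_o2_kg_h <- function(source) {
  source$supply_m3_per_h * source$gas_density_kg_m3 * source$efficiency
}

#' Concentration increment of the point source
#'
#' Delivered oxygen mass diluted into the through-flow:
#' `supply * gas_density * efficiency / Q`, closed to mg/L.
#'
#' @param source An [oxygen_source()].
#' @param Q_Lh Water flow rate (L/h), strictly positive.
#' @return Concentration increment at the inlet node (mg/L).
#' @export
source_increment <- function(source, Q_Lh) {
  if (any(Q_Lh <= 0)) abort_domain("flow must be strictly positive")
  delivered_o2_kg_h(source) * 1e6 / Q_Lh
}

#' Distribute biomass along the raceway
#'
#' Builds the streamwise biomass density dM/dx entering the respiration
#' sink.  Only a uniform distribution is provided: the fish are assumed
#' spread evenly over the full raceway length.
#'
#' @param M_total Total biomass (kg), non-negative.
#' @param mode Distribution mode; only `"uniform"`.
#' @param geometry A [raceway_geometry()].
#' @param specific_respiration Specific respiration of the stock
#'   (mg O2 kg^-1 h^-1).
#' @return An object of class `biomass_profile` with fields `density_kg_m`
#'   (uniform value), `M_total`, `specific_respiration_mgO2_kg_h`.
#' @export
distribute_biomass <- function(M_total, mode = "uniform", geometry,
                               specific_respiration = 0) {
  if (M_total < 0) abort_domain("biomass must be non-negative")
  mode <- match.arg(mode, "uniform")
  if (specific_respiration < 0)
    abort_validation("'specific_respiration' must be non-negative")
  structure(list(density_kg_m = M_total / geometry$length_m,
                 M_total = M_total,
                 specific_respiration_mgO2_kg_h = specific_respiration,
                 mode = mode),
            class = "biomass_profile")
}

#' Water residence time
#'
#' @param geometry A [raceway_geometry()].
#' @param Q_Lh Water flow rate (L/h), strictly positive.
#' @return Residence time (h), `volume / Q`.
#' @export
residence_time <- function(geometry, Q_Lh) {
  if (Q_Lh <= 0) abort_domain("flow must be strictly positive")
  geometry$volume_m3 * 1000 / Q_Lh
}

# Respiration sink in mg L^-1 h^-1 for a uniform biomass profile.
respiration_sink_mgL_h <- function(biomass, geometry) {
  biomass$specific_respiration_mgO2_kg_h * biomass$density_kg_m /
    (geometry$cross_section_m2 * 1000)
}

#' Analytic steady-state DO profile
#'
#' Closed-form solution of the streamwise balance at steady state with
#' constant inputs and uniform biomass, used as the independent oracle for
#' the numerical solver and as the one-residence-time predictor of the
#' closed-loop controllers.  With zero reaeration the profile is linear,
#' `C(x) = C0 - (R M / Q) (x / length)`; with reaeration it relaxes
#' exponentially toward `Csat - sink/k_rear` at rate `k_rear / u`.
#'
#' @param C0 Concentration at the inlet node, after any source (mg/L).
#' @param Q_Lh Water flow rate (L/h).
#' @param geometry A [raceway_geometry()].
#' @param biomass A [distribute_biomass()] profile.
#' @param params A [reaeration_params()].
#' @param T_C Water temperature (degC), used for the saturation value.
#' @param x Positions (m); defaults to 101 nodes over the raceway length.
#' @return Concentrations `C(x)` (mg/L) at `x`.
#' @export
steady_state_profile <- function(C0, Q_Lh, geometry, biomass,
                                 params = reaeration_params(), T_C = 15,
                                 x = NULL) {
  if (is.null(x)) x <- seq(0, geometry$length_m, length.out = 101L)
  u <- Q_Lh / (1000 * geometry$cross_section_m2)  # m/h
  s <- respiration_sink_mgL_h(biomass, geometry)
  k <- params$k_rear_h
  if (k == 0) return(C0 - s * x / u)
  Cs <- csat(T_C, params)
  Cinf <- Cs - s / k
  Cinf + (C0 - Cinf) * exp(-k * x / u)
}

new_do_field <- function(x_m, time_h, C, events = NULL, inputs = NULL) {
  structure(list(x_m = x_m, time_h = time_h, C = C,
                 events = if (is.null(events))
                   data.frame(time_h = numeric(), type = character(),
                              detail = character()) else events,
                 inputs = inputs),
            class = "do_field")
}

#' @export
print.do_field <- function(x, ...) {
  cat(sprintf("<do_field> %d nodes x %d times; DO range [%.2f, %.2f] mg/L; %d event(s)\n",
              length(x$x_m), length(x$time_h), min(x$C), max(x$C),
              nrow(x$events)))
  invisible(x)
}

# Advance the field over one reporting interval with explicit upwind
# substeps.  f0/f1 are the forcing at the interval endpoints (linearly
# interpolated in between); supply and biomass are held constant over the
# interval.  Returns the new concentration vector plus any anoxia events.
do_interval <- function(C, t0_h, t1_h, f0, f1, source, biomass, params,
                        geometry, dx, dt_solver) {
  span <- t1_h - t0_h
  n_sub <- max(1L, ceiling(span / dt_solver - 1e-9))
  dts <- span / n_sub
  A <- geometry$cross_section_m2
  k <- params$k_rear_h
  sink <- respiration_sink_mgL_h(biomass, geometry)
  n <- length(C)
  events <- NULL
  for (j in seq_len(n_sub)) {
    w1 <- (j - 1) / n_sub; w2 <- j / n_sub
    # forcing at substep start (for the advective state) and end (boundary)
    Tm <- f0$temperature_C * (1 - w1) + f1$temperature_C * w1
    Q  <- f0$flow_Lh * (1 - w1) + f1$flow_Lh * w1
    DOin <- f0$inlet_DO_mgL * (1 - w2) + f1$inlet_DO_mgL * w2
    u <- Q / (1000 * A)
    if (u * dts / dx > 1 + 1e-9)
      abort_config(sprintf(
        "CFL condition violated: maximal admissible solver step is %.4g h",
        dx / u))
    Cs <- csat(min(max(Tm, 0), 40), params)
    adv <- -u * dts / dx * (C[2:n] - C[1:(n - 1)])
    C[2:n] <- C[2:n] + adv + dts * (k * (Cs - C[2:n]) - sink)
    C[1] <- DOin + source_increment(source, Q)
    if (any(C < 0)) {
      events <- rbind(events, data.frame(
        time_h = t0_h + j * dts, type = "anoxia",
        detail = sprintf("DO clipped at 0 (unclipped minimum %.3f mg/L)",
                         min(C))))
      C[C < 0] <- 0
    }
  }
  list(C = C, events = events)
}

#' Simulate dissolved oxygen along the raceway
#'
#' Explicit first-order upwind solution of the streamwise DO balance over
#' the span of the forcing series, reported at the forcing timestamps.  The
#' inlet boundary is the forcing inlet DO plus the point-source increment;
#' the outflow boundary is free (upwind needs none).  Concentrations are
#' clipped at zero; any clipping is recorded as an anoxia event in the
#' result's event log rather than raised as an error.
#'
#' @param forcing A [forcing_series()]; its timestamps define the reporting
#'   grid.
#' @param biomass A [distribute_biomass()] profile, or a function of time
#'   (days) returning one.
#' @param source An [oxygen_source()]; its `supply_m3_per_h` may instead be
#'   driven by `supply`, a scalar, a [supply_schedule()], or a function of
#'   time (days) returning m3/h.
#' @param params A [reaeration_params()].
#' @param geometry A [raceway_geometry()].
#' @param dx Node spacing (m); default 2.
#' @param dt Solver substep (h); default `0.9 * dx / u_max` from the CFL
#'   condition.  A `dt` violating the CFL bound raises a configuration
#'   error stating the maximal admissible step.
#' @param supply Optional supply driver (see `source`).
#' @param C_init Initial concentration vector, or `"steady"` (default) for
#'   the quasi-steady profile at the first-timestamp conditions, or
#'   `"inlet"` for a flat profile at the inlet value.
#' @return A `do_field`: node positions `x_m`, report times `time_h`,
#'   concentration matrix `C` (nodes x times), event log, and an `inputs`
#'   record used by [budget_decomposition()] and [oxygen_budget()].
#' @export
simulate_do <- function(forcing, biomass, source, params = reaeration_params(),
                        geometry, dx = 2, dt = NULL, supply = NULL,
                        C_init = "steady") {
  if (!inherits(forcing, "forcing_series"))
    abort_validation("'forcing' must be a forcing_series")
  if (nrow(forcing) < 2L)
    abort_validation("forcing must contain at least two timestamps")
  if (dx <= 0 || dx > geometry$length_m)
    abort_validation("'dx' must be positive and at most the raceway length")

  # uniform node-centred grid; the spacing is rounded down so the outlet
  # node falls exactly on the raceway length
  n_cells <- max(2L, as.integer(ceiling(geometry$length_m / dx - 1e-9)))
  x <- seq(0, geometry$length_m, length.out = n_cells + 1L)
  dx <- x[2L] - x[1L]
  times_h <- forcing$time_d * 24
  n_t <- length(times_h)

  biomass_fun <- if (is.function(biomass)) biomass else function(t_d) biomass
  supply_fun <- if (is.null(supply)) {
    function(t_d) source$supply_m3_per_h
  } else if (is.function(supply)) {
    supply
  } else if (inherits(supply, "supply_schedule")) {
    function(t_d) scheduled_supply(supply, t_d)
  } else {
    function(t_d) supply
  }

  u_max <- max(forcing$flow_Lh) / (1000 * geometry$cross_section_m2)
  dt_max <- dx / u_max
  if (is.null(dt)) dt <- 0.9 * dt_max
  if (dt > dt_max + 1e-12)
    abort_config(sprintf(
      "CFL condition violated: maximal admissible solver step is %.4g h (requested %.4g h)",
      dt_max, dt))

  f_list <- lapply(forcing$time_d, function(t) forcing_at(forcing, t))
  src_at <- function(t_d) {
    s <- source; s$supply_m3_per_h <- max(0, supply_fun(t_d)); s
  }

  C <- matrix(NA_real_, nrow = length(x), ncol = n_t)
  f1 <- f_list[[1L]]
  src1 <- src_at(forcing$time_d[1L])
  bio1 <- biomass_fun(forcing$time_d[1L])
  C0_bnd <- f1$inlet_DO_mgL + source_increment(src1, f1$flow_Lh)
  C[, 1L] <- if (is.numeric(C_init)) {
    if (length(C_init) == 1L) rep(C_init, length(x)) else C_init
  } else if (identical(C_init, "inlet")) {
    rep(C0_bnd, length(x))
  } else {
    pmax(steady_state_profile(C0_bnd, f1$flow_Lh, geometry, bio1, params,
                              T_C = min(max(f1$temperature_C, 0), 40), x = x), 0)
  }

  events <- NULL
  supply_series <- numeric(n_t - 1L)
  M_series <- numeric(n_t - 1L)
  R_series <- numeric(n_t - 1L)
  Cv <- C[, 1L]
  for (j in seq_len(n_t - 1L)) {
    t_d <- forcing$time_d[j]
    bio <- biomass_fun(t_d)
    src <- src_at(t_d)
    supply_series[j] <- src$supply_m3_per_h
    M_series[j] <- bio$M_total
    R_series[j] <- bio$specific_respiration_mgO2_kg_h
    step <- do_interval(Cv, times_h[j], times_h[j + 1L],
                        f_list[[j]], f_list[[j + 1L]], src, bio, params,
                        geometry, dx, dt)
    Cv <- step$C
    events <- rbind(events, step$events)
    C[, j + 1L] <- Cv
  }

  inputs <- list(forcing = forcing, geometry = geometry, params = params,
                 source = source, dx = dx,
                 supply_m3h = supply_series, M_total_kg = M_series,
                 specific_respiration = R_series)
  new_do_field(x_m = x, time_h = times_h, C = C, events = events,
               inputs = inputs)
}

#' Global oxygen mass balance of a simulated field
#'
#' Independent budget accountant: recomputes, from the stored field and its
#' inputs only, the oxygen masses entering (inflow at the boundary node,
#' which includes the point source; reaeration along the raceway) and
#' leaving (outflow, respiration) plus the change in stored mass, using
#' trapezoidal quadrature over the reporting grid.  For a conservative
#' solver the closure error is a fraction of the total input.
#'
#' @param field A `do_field` from [simulate_do()] (or the scenario engine).
#' @return A list of budget terms (kg O2) and `relative_error`, the closure
#'   residual divided by total input.
#' @export
oxygen_budget <- function(field) {
  inp <- field$inputs
  if (is.null(inp)) abort_validation("field carries no inputs record")
  g <- inp$geometry
  x <- field$x_m
  t_h <- field$time_h
  n <- length(x)
  f <- lapply(inp$forcing$time_d, function(t) forcing_at(inp$forcing, t))
  Q <- vapply(f, `[[`, numeric(1), "flow_Lh")
  Tw <- vapply(f, `[[`, numeric(1), "temperature_C")
  Cs <- csat(pmin(pmax(Tw, 0), 40), inp$params)

  cellw <- diff(x)                      # cell owned by each interior node
  vol_L <- g$cross_section_m2 * cellw * 1000
  storage <- vapply(seq_along(t_h), function(j)
    sum(field$C[-1L, j] * vol_L), numeric(1)) / 1e6   # kg

  inflow_rate  <- Q * field$C[1L, ] / 1e6             # kg/h
  outflow_rate <- Q * field$C[n, ] / 1e6
  rear_rate <- vapply(seq_along(t_h), function(j)
    sum(inp$params$k_rear_h * (Cs[j] - field$C[-1L, j]) * vol_L),
    numeric(1)) / 1e6
  trapz_t <- function(r) sum(diff(t_h) * (head(r, -1) + tail(r, -1)) / 2)
  # respiration is an interval quantity (biomass held constant per interval):
  # total sink mass rate integrates to R_spec * M_total over the cells
  resp_kg <- sum(diff(t_h) * inp$specific_respiration * inp$M_total_kg) / 1e6
  terms <- list(inflow_kg = trapz_t(inflow_rate),
                outflow_kg = trapz_t(outflow_rate),
                reaeration_kg = trapz_t(rear_rate),
                respiration_kg = resp_kg,
                storage_change_kg = storage[length(t_h)] - storage[1L])
  residual <- terms$inflow_kg + terms$reaeration_kg - terms$outflow_kg -
    terms$respiration_kg - terms$storage_change_kg
  total_in <- terms$inflow_kg + max(terms$reaeration_kg, 0)
  c(terms, list(residual_kg = residual,
                relative_error = abs(residual) / max(total_in, 1e-12)))
}
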