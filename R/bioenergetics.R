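# Energy-budget growth model for rainbow trout.
#
# Weight change is the balance between assimilated energy intake (anabolism)
# and metabolic losses (catabolism), both modulated by water temperature:
#
#   dW/dt = (eps_A * fA(T) * min(I, k_I * W^m * fA(T))  -  k_C * e^(pk T) * W^n) / eps_W
#
# with W individual wet weight (g), I the supplied ration energy (kJ/d),
# fA(T) a unimodal anabolic temperature response that vanishes at T_max, and
# eps_W the energy density of fish tissue (kJ/g).  Respiration follows from
# the oxycalorific equivalent of catabolised energy plus the specific
# dynamic action of feeding; ammonia (TAN) and CO2 excretions follow from
# the protein share of catabolism and the respiratory quotient.

#' Feed specification
#'
#' Proximate composition of a feed and the gross-energy coefficients of the
#' three macronutrient classes.
#'
#' @param protein_frac,lipid_frac,carb_frac Mass fractions of crude protein,
#'   crude lipid and carbohydrate; each in \[0, 1\], summing to at most 1.
#' @param gross_energy_coeffs Named numeric vector of gross-energy
#'   coefficients (kJ/g) for `protein`, `lipid`, `carbohydrate`.
#' @return An object of class `feed_spec`.
#' @examples
#' gross_energy(feed_spec(0.45, 0.25, 0.15))  # 23.075 kJ/g
#' @export
feed_spec <- function(protein_frac, lipid_frac, carb_frac,
                      gross_energy_coeffs = c(protein = 23.6, lipid = 39.5,
                                              carbohydrate = 17.2)) {
  fr <- c(protein_frac, lipid_frac, carb_frac)
  if (any(!is.finite(fr)) || any(fr < 0 | fr > 1))
    abort_validation("feed fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-12)
    abort_validation(sprintf("feed fractions sum to %.3f > 1", sum(fr)))
  if (length(gross_energy_coeffs) != 3L || any(gross_energy_coeffs <= 0))
    abort_validation("gross_energy_coeffs must be three positive values")
  structure(list(protein_frac = protein_frac, lipid_frac = lipid_frac,
                 carb_frac = carb_frac,
                 gross_energy_coeffs = gross_energy_coeffs),
            class = "feed_spec")
}

#' Gross energy density of a feed
#'
#' Mass-weighted sum of the macronutrient gross-energy coefficients.
#'
#' @param feed A [feed_spec()].
#' @return Energy density (kJ/g feed).
#' @export
gross_energy <- function(feed) {
  if (!inherits(feed, "feed_spec")) abort_validation("'feed' must be a feed_spec")
  sum(c(feed$protein_frac, feed$lipid_frac, feed$carb_frac) *
        as.numeric(feed$gross_energy_coeffs))
}

#' Fish cohort state
#'
#' Population state of one raceway: number of individuals and the mean and
#' standard deviation of individual wet weight.
#'
#' @param count Number of individuals (>= 0).
#' @param mean_weight_g Mean individual weight (g), strictly positive.
#' @param sd_weight_g Standard deviation of individual weight (g).
#' @param deaths_cum Cumulative deaths.
#' @return An object of class `fish_cohort`.
#' @export
fish_cohort <- function(count, mean_weight_g, sd_weight_g = 0, deaths_cum = 0) {
  if (count < 0) abort_validation("'count' must be non-negative")
  if (mean_weight_g <= 0) abort_validation("'mean_weight_g' must be positive")
  if (sd_weight_g < 0) abort_validation("'sd_weight_g' must be non-negative")
  if (deaths_cum < 0) abort_validation("'deaths_cum' must be non-negative")
  structure(list(count = count, mean_weight_g = mean_weight_g,
                 sd_weight_g = sd_weight_g, deaths_cum = deaths_cum),
            class = "fish_cohort")
}

#' Bioenergetic parameter set
#'
#' Parameters of the trout energy budget.  The defaults were chosen once to
#' satisfy broad sanity envelopes for rainbow trout -- growth from fingerling
#' to commercial size within one season at 8-16 degC and a fed specific
#' respiration of roughly 300-400 mg O2/kg/h -- and are all overridable; they
#' are not a site calibration.
#'
#' @param anab_coeff Scale of the allometric ingestion cap (kJ g^-m d^-1).
#' @param anab_exponent Allometric exponent m of ingestion, in (0, 1.5\].
#' @param catab_coeff Scale of catabolism (kJ g^-n d^-1).
#' @param catab_exponent Allometric exponent n of catabolism, in (0, 1.5\].
#' @param catab_temp_coeff Exponential temperature coefficient of catabolism
#'   (1/degC); 0.06 corresponds to a Q10 of about 1.8.
#' @param anab_temp_optimum,anab_temp_max Optimum and upper lethal
#'   temperature of the anabolic response (degC); the response is 1 at the
#'   optimum and 0 at and above the maximum.
#' @param anab_temp_shape Shape exponent of the unimodal response.
#' @param assimilation_eff Fraction of capped intake energy assimilated.
#' @param fish_energy_density Energy density of fish tissue (kJ/g wet).
#' @param oxycal_coeff Oxygen consumed per unit metabolised energy
#'   (mg O2/kJ); default 1000/13.6 from the standard oxycalorific
#'   equivalent of 13.6 kJ per g O2.
#' @param sda_frac Specific dynamic action: fraction of intake energy
#'   respired as the cost of feeding.
#' @param protein_catab_frac Fraction of catabolised energy drawn from
#'   protein.
#' @param protein_energy_kJ_g Gross energy of protein (kJ/g), used to convert
#'   catabolised protein energy to protein mass.
#' @param tan_per_protein Total ammonia nitrogen excreted per g protein
#'   catabolised (g/g).
#' @param co2_per_O2 CO2 produced per g O2 respired (g/g); default from a
#'   respiratory quotient of 0.9.
#' @return An object of class `bioenergetic_params`.
#' @export
bioenergetic_params <- function(anab_coeff = 2.6,
                                anab_exponent = 2 / 3,
                                catab_coeff = 0.08,
                                catab_exponent = 0.8,
                                catab_temp_coeff = 0.06,
                                anab_temp_optimum = 16,
                                anab_temp_max = 25,
                                anab_temp_shape = 2,
                                assimilation_eff = 0.6,
                                fish_energy_density = 6,
                                oxycal_coeff = 1000 / 13.6,
                                sda_frac = 0.15,
                                protein_catab_frac = 0.5,
                                protein_energy_kJ_g = 23.6,
                                tan_per_protein = 0.092,
                                co2_per_O2 = 1.24) {
  p <- as.list(environment())
  if (p$anab_exponent <= 0 || p$anab_exponent > 1.5 ||
      p$catab_exponent <= 0 || p$catab_exponent > 1.5)
    abort_validation("allometric exponents must lie in (0, 1.5]")
  for (nm in c("assimilation_eff", "sda_frac", "protein_catab_frac")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      abort_validation(sprintf("'%s' must lie in [0, 1]", nm))
  }
  pos <- c("anab_coeff", "catab_coeff", "catab_temp_coeff", "fish_energy_density",
           "oxycal_coeff", "protein_energy_kJ_g", "tan_per_protein", "co2_per_O2")
  for (nm in pos) if (p[[nm]] <= 0)
    abort_validation(sprintf("'%s' must be strictly positive", nm))
  if (p$anab_temp_optimum >= p$anab_temp_max)
    abort_validation("anab_temp_optimum must be below anab_temp_max")
  structure(p, class = "bioenergetic_params")
}

# Unimodal anabolic temperature response: 1 at the optimum, 0 at and above
# T_max, smoothly declining toward cold temperatures.
temp_response <- function(T, params) {
  v <- (params$anab_temp_max - T) /
    (params$anab_temp_max - params$anab_temp_optimum)
  s <- params$anab_temp_shape
  out <- ifelse(v <= 0, 0, v^s * exp(s * (1 - v)))
  pmax(out, 0)
}

#' Maximum daily ingestion energy
#'
#' Allometric cap on ingestible energy, `anab_coeff * W^m`, scaled by the
#' anabolic temperature response (zero at and above `anab_temp_max`).  When
#' the supplied ration is smaller than this cap, the ration -- the amount of
#' feed the farmer actually provides -- is binding.
#'
#' @param W Individual weight (g), positive.
#' @param T Water temperature (degC).
#' @param params A [bioenergetic_params()].
#' @return Maximum ingestion (kJ/d).
#' @export
max_ingestion <- function(W, T, params = bioenergetic_params()) {
  if (any(W <= 0)) abort_domain("weight must be strictly positive")
  params$anab_coeff * W^params$anab_exponent * temp_response(T, params)
}

# Instantaneous energy fluxes (kJ/d) of one individual.
energy_rates <- function(W, T, intake_kJ_d, params) {
  cap <- params$anab_coeff * W^params$anab_exponent * temp_response(T, params)
  eff_intake <- pmin(intake_kJ_d, cap)
  assim <- params$assimilation_eff * temp_response(T, params) * eff_intake
  catab <- params$catab_coeff * exp(params$catab_temp_coeff * T) *
    W^params$catab_exponent
  list(assim_kJ_d = assim, catab_kJ_d = catab)
}

#' Individual growth rate
#'
#' Net energy budget divided by the tissue energy density:
#' `dW/dt = (anabolism - catabolism) / fish_energy_density` (g/d).  With no
#' intake the budget is pure catabolism and the rate is negative
#' (starvation); intake balancing catabolism gives zero growth.
#'
#' @inheritParams max_ingestion
#' @param intake_kJ_d Supplied ration energy (kJ/d).
#' @return Growth rate (g/d).
#' @export
weight_derivative <- function(W, T, intake_kJ_d, params = bioenergetic_params()) {
  if (any(W <= 0)) abort_domain("weight must be strictly positive")
  r <- energy_rates(W, T, intake_kJ_d, params)
  (r$assim_kJ_d - r$catab_kJ_d) / params$fish_energy_density
}

#' Respiration and metabolite excretion of one individual
#'
#' Oxygen consumption from the oxycalorific equivalent of catabolised energy
#' plus the specific dynamic action of the ration; total ammonia nitrogen
#' from the protein share of catabolism; CO2 from the respired oxygen mass
#' via the respiratory quotient.
#'
#' @inheritParams weight_derivative
#' @return An object of class `metabolic_outputs` with fields
#'   `respiration_mgO2_per_h`, `tan_g_per_d`, `co2_g_per_d` (per individual).
#' @export
metabolic_outputs <- function(W, T, intake_kJ_d, params = bioenergetic_params()) {
  if (any(W <= 0)) abort_domain("weight must be strictly positive")
  r <- energy_rates(W, T, intake_kJ_d, params)
  metab_kJ_d <- r$catab_kJ_d + params$sda_frac * pmin(intake_kJ_d,
    params$anab_coeff * W^params$anab_exponent * temp_response(T, params))
  resp_mg_h <- params$oxycal_coeff * metab_kJ_d / 24
  protein_g_d <- params$protein_catab_frac * r$catab_kJ_d /
    params$protein_energy_kJ_g
  structure(list(respiration_mgO2_per_h = resp_mg_h,
                 tan_g_per_d = params$tan_per_protein * protein_g_d,
                 co2_g_per_d = params$co2_per_O2 * resp_mg_h * 24 / 1000),
            class = "metabolic_outputs")
}

#' Feed plan
#'
#' Daily ration schedule with an attached feed composition.  The ration at
#' time t is the ration of the last plan row at or before t (step function).
#'
#' @param time_d Plan times (days from start), strictly increasing.
#' @param ration_g_per_fish Daily ration per individual (g/d).
#' @param feed A [feed_spec()] applying to all rows.
#' @return A data frame of class `feed_plan`.
#' @export
feed_plan <- function(time_d, ration_g_per_fish, feed) {
  if (length(time_d) != length(ration_g_per_fish))
    abort_validation("'time_d' and 'ration_g_per_fish' must have equal length")
  if (any(diff(time_d) <= 0))
    abort_validation("feed plan times must be strictly increasing")
  if (any(ration_g_per_fish < 0))
    abort_validation("rations must be non-negative")
  if (!inherits(feed, "feed_spec")) abort_validation("'feed' must be a feed_spec")
  structure(data.frame(time_d = time_d,
                       ration_g_per_fish = ration_g_per_fish,
                       intake_kJ_d = ration_g_per_fish * gross_energy(feed)),
            feed = feed, class = c("feed_plan", "data.frame"))
}

intake_at <- function(plan, t_d) {
  i <- findInterval(t_d + 1e-9, plan$time_d)
  ifelse(i < 1L, 0, plan$intake_kJ_d[pmax(i, 1L)])
}

# One classical fourth-order Runge-Kutta step of the augmented state
# (W, cumulative assimilated energy, cumulative catabolised energy).  The
# cumulative energies are integrated by the same quadrature as W, so the
# energy balance  dW * fish_energy_density = dE_assim - dE_catab  holds to
# machine precision over every step.
rk4_growth_step <- function(W, t_d, dt, temp_fun, intake_fun, params) {
  f <- function(t, w) {
    w <- max(w, 1e-9)
    r <- energy_rates(w, temp_fun(t), intake_fun(t), params)
    c((r$assim_kJ_d - r$catab_kJ_d) / params$fish_energy_density,
      r$assim_kJ_d, r$catab_kJ_d)
  }
  k1 <- f(t_d, W)
  k2 <- f(t_d + dt / 2, W + dt / 2 * k1[1])
  k3 <- f(t_d + dt / 2, W + dt / 2 * k2[1])
  k4 <- f(t_d + dt, W + dt * k3[1])
  dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)  # c(dW, dE_assim, dE_catab)
}

#' Integrate cohort growth over a forcing horizon
#'
#' Steps the individual energy budget with a fixed-step fourth-order
#' Runge-Kutta scheme.  Three weight trajectories are propagated -- from the
#' mean and the mean -/+ one standard deviation of the initial weight -- to
#' give the customary growth band; biomass is `count * mean weight`.
#' User-supplied daily mortalities are removed at the start of each step,
#' before growth.  If the mean weight reaches zero under prolonged
#' starvation the integration halts at that step and the returned trajectory
#' carries a `starvation_collapse` attribute.
#'
#' @param cohort A [fish_cohort()].
#' @param forcing A [forcing_series()] covering the horizon.
#' @param plan A [feed_plan()].
#' @param params A [bioenergetic_params()].
#' @param dt Step size (days); must not exceed the forcing cadence.
#' @param horizon_d Horizon (days); defaults to the forcing span.
#' @param deaths Optional data frame `time_d, deaths` of daily mortality
#'   counts.
#' @return A data frame of class `growth_trajectory` with one row per step:
#'   time, the three weights, count, biomass (kg), per-individual
#'   respiration/TAN/CO2, specific respiration of the population
#'   (mg O2/kg/h), and cumulative assimilated/catabolised energy (kJ, per
#'   mean individual).
#' @export
integrate_growth <- function(cohort, forcing, plan,
                             params = bioenergetic_params(), dt = 1,
                             horizon_d = NULL, deaths = NULL) {
  if (!inherits(cohort, "fish_cohort")) abort_validation("'cohort' must be a fish_cohort")
  if (!inherits(forcing, "forcing_series"))
    abort_validation("'forcing' must be a forcing_series")
  if (is.null(horizon_d)) horizon_d <- max(forcing$time_d) - min(forcing$time_d)
  if (horizon_d > max(forcing$time_d) - min(forcing$time_d) + 1e-9)
    abort_validation("forcing does not cover the requested horizon")
  cad <- if (nrow(forcing) > 1L) min(diff(forcing$time_d)) else Inf
  if (dt > cad + 1e-9)
    abort_validation("'dt' must not exceed the forcing cadence")

  temp_fun <- function(t) forcing_at(forcing, t)$temperature_C
  intake_fun <- function(t) intake_at(plan, t)
  death_at <- function(t) {
    if (is.null(deaths)) return(0)
    sum(deaths$deaths[abs(deaths$time_d - t) < dt / 2])
  }

  n_steps <- max(0L, round(horizon_d / dt))
  W <- c(mean = cohort$mean_weight_g,
         lo = max(cohort$mean_weight_g - cohort$sd_weight_g, 1e-3),
         hi = cohort$mean_weight_g + cohort$sd_weight_g)
  count <- cohort$count
  deaths_cum <- cohort$deaths_cum
  Ea <- 0; Ec <- 0
  collapse <- FALSE

  row_at <- function(t) {
    mo <- metabolic_outputs(max(W[["mean"]], 1e-9), temp_fun(t),
                            intake_fun(t), params)
    biomass <- count * W[["mean"]] / 1000
    data.frame(time_d = t, mean_weight_g = W[["mean"]],
               lo_weight_g = W[["lo"]], hi_weight_g = W[["hi"]],
               count = count, biomass_kg = biomass,
               respiration_mgO2_h = mo$respiration_mgO2_per_h,
               tan_g_d = mo$tan_g_per_d, co2_g_d = mo$co2_g_per_d,
               specific_respiration_mgO2_kg_h =
                 mo$respiration_mgO2_per_h * 1000 / W[["mean"]],
               assim_kJ_cum = Ea, catab_kJ_cum = Ec)
  }

  rows <- vector("list", n_steps + 1L)
  rows[[1L]] <- row_at(0)
  if (n_steps > 0L) for (i in seq_len(n_steps)) {
    t0 <- (i - 1L) * dt
    d <- death_at(t0)
    if (d > 0) { d <- min(d, count); count <- count - d; deaths_cum <- deaths_cum + d }
    inc <- rk4_growth_step(W[["mean"]], t0, dt, temp_fun, intake_fun, params)
    W[["mean"]] <- W[["mean"]] + inc[1]
    Ea <- Ea + inc[2]; Ec <- Ec + inc[3]
    for (nm in c("lo", "hi")) {
      W[[nm]] <- max(W[[nm]] +
        rk4_growth_step(W[[nm]], t0, dt, temp_fun, intake_fun, params)[1], 1e-3)
    }
    if (W[["mean"]] <= 0) {
      collapse <- TRUE
      W[["mean"]] <- 0
      rows[[i + 1L]] <- data.frame(time_d = i * dt, mean_weight_g = 0,
                                   lo_weight_g = W[["lo"]], hi_weight_g = W[["hi"]],
                                   count = count, biomass_kg = 0,
                                   respiration_mgO2_h = 0, tan_g_d = 0,
                                   co2_g_d = 0,
                                   specific_respiration_mgO2_kg_h = 0,
                                   assim_kJ_cum = Ea, catab_kJ_cum = Ec)
      rows <- rows[seq_len(i + 1L)]
      break
    }
    rows[[i + 1L]] <- row_at(i * dt)
  }
  out <- do.call(rbind, rows)
  structure(out, params = params, deaths_cum = deaths_cum,
            starvation_collapse = collapse,
            class = c("growth_trajectory", "data.frame"))
}
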