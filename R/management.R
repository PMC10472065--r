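# Stocking management: utilization factor, transfer planning and the
# intervention-proposal rules.
#
# The utilization factor is the current biomass density divided by a
# baseline transfer density (default 20 kg/m3, after common flow-through
# trout practice and FAO stocking recommendations).  When the forecast
# utilization reaches 100%, a configured fraction of the stock (default one
# third) is transferred to another basin, scheduled a configured lead time
# before the predicted crossing, optionally delayed.

#' Transfer rule
#'
#' @param baseline_kg_m3 Baseline transfer density (kg/m3), positive.
#' @param fraction Fraction of biomass moved per transfer, in (0, 1\].
#' @param lead_days Days before the predicted 100%-utilization crossing at
#'   which the transfer is scheduled.
#' @param delay_days Additional delay (days) applied after the lead; a
#'   one-week postponement variant uses 7.
#' @return An object of class `transfer_rule`.
#' @export
transfer_rule <- function(baseline_kg_m3 = 20, fraction = 1 / 3,
                          lead_days = 1, delay_days = 0) {
  if (baseline_kg_m3 <= 0) abort_validation("'baseline_kg_m3' must be positive")
  if (fraction <= 0 || fraction > 1)
    abort_validation("'fraction' must lie in (0, 1]")
  if (lead_days < 0) abort_validation("'lead_days' must be non-negative")
  if (delay_days < 0) abort_validation("'delay_days' must be non-negative")
  structure(list(baseline_kg_m3 = baseline_kg_m3, fraction = fraction,
                 lead_days = lead_days, delay_days = delay_days),
            class = "transfer_rule")
}

#' Stocking state
#'
#' Current cohort, biomass, density and utilization of one raceway.
#'
#' @param cohort A [fish_cohort()].
#' @param geometry A [raceway_geometry()].
#' @param baseline_kg_m3 Baseline transfer density (kg/m3).
#' @return An object of class `stocking_state`.
#' @export
stocking_state <- function(cohort, geometry, baseline_kg_m3 = 20) {
  biomass <- cohort$count * cohort$mean_weight_g / 1000
  density <- biomass / geometry$volume_m3
  structure(list(cohort = cohort, biomass_kg = biomass,
                 density_kg_m3 = density,
                 utilization = utilization_factor(density, baseline_kg_m3),
                 baseline_kg_m3 = baseline_kg_m3, geometry = geometry),
            class = "stocking_state")
}

#' Utilization factor
#'
#' Biomass density divided by the baseline transfer density; 1 (100%) marks
#' the stock-splitting point.
#'
#' @param density_kg_m3 Current biomass density (kg/m3), non-negative.
#' @param baseline_kg_m3 Baseline density (kg/m3), strictly positive.
#' @return Utilization as a fraction of baseline.
#' @export
utilization_factor <- function(density_kg_m3, baseline_kg_m3 = 20) {
  if (baseline_kg_m3 <= 0) abort_domain("baseline density must be positive")
  if (any(density_kg_m3 < 0)) abort_domain("density must be non-negative")
  density_kg_m3 / baseline_kg_m3
}

#' Plan a biomass transfer from a forecast
#'
#' Finds the first day the forecast utilization reaches 100% and schedules
#' a transfer of the rule's fraction `lead_days` before it (plus
#' `delay_days`).  Returns `NULL` when the forecast never crosses within its
#' horizon.  If the computed event date lies before the start of the
#' forecast (the crossing is already due), the event is scheduled for the
#' first forecast step with a warning.
#'
#' @param forecast Data frame with columns `time_d` and `biomass_kg`
#'   (typically a [integrate_growth()] trajectory).
#' @param rule A [transfer_rule()].
#' @param volume_m3 Raceway water volume (m3).
#' @return A list `(time_d, fraction, predicted_crossing_d)` or `NULL`.
#' @export
plan_transfer <- function(forecast, rule, volume_m3) {
  u <- forecast$biomass_kg / (volume_m3 * rule$baseline_kg_m3)
  idx <- which(u >= 1)
  if (!length(idx)) return(NULL)
  crossing <- forecast$time_d[idx[1L]]
  event <- crossing - rule$lead_days + rule$delay_days
  if (event < forecast$time_d[1L]) {
    warning(sprintf(
      "utilization crossing at day %g already due at planning time; transfer scheduled for the next step",
      crossing), call. = FALSE)
    event <- forecast$time_d[1L]
  }
  list(time_d = event, fraction = rule$fraction,
       predicted_crossing_d = crossing)
}

#' Apply a biomass transfer
#'
#' Removes a fraction of the stock by individuals: count and biomass scale
#' by `1 - fraction`, mean and sd of individual weight are unchanged, and
#' the utilization is recomputed.  No mass is created: removed plus
#' remaining biomass equals the prior biomass.
#'
#' @param state A [stocking_state()].
#' @param fraction Fraction of biomass moved, in \[0, 1\].
#' @return The updated `stocking_state`.
#' @export
apply_transfer <- function(state, fraction) {
  if (fraction < 0 || fraction > 1)
    abort_domain("'fraction' must lie in [0, 1]")
  cohort <- state$cohort
  cohort$count <- cohort$count * (1 - fraction)
  stocking_state(cohort, state$geometry, state$baseline_kg_m3)
}

#' Daily feed quantity
#'
#' Ration for the next day from a body-weight table: `count * mean weight *
#' ration fraction` for the cohort's weight class; zero below a minimum
#' feeding temperature.
#'
#' @param cohort A [fish_cohort()].
#' @param T Water temperature (degC).
#' @param feed_table Data frame with columns `min_weight_g`, `max_weight_g`,
#'   `ration_pct_bw` (percent body weight per day).
#' @param min_temp_C Minimum feeding temperature (degC).
#' @return Feed quantity (kg/d).
#' @export
daily_feed_quantity <- function(cohort, T, feed_table, min_temp_C = 2) {
  if (cohort$count == 0) return(0)
  row <- which(cohort$mean_weight_g >= feed_table$min_weight_g &
                 cohort$mean_weight_g < feed_table$max_weight_g)
  if (!length(row))
    abort_lookup(sprintf(
      "weight class for %.1f g is outside the feed table (covers %.0f-%.0f g)",
      cohort$mean_weight_g, min(feed_table$min_weight_g),
      max(feed_table$max_weight_g)))
  if (T < min_temp_C) return(0)
  cohort$count * cohort$mean_weight_g *
    feed_table$ration_pct_bw[row[1L]] / 100 / 1000
}

#' Illustrative feed table
#'
#' A three-class body-weight ration table.  Illustrative only: real rations
#' are feed- and site-specific.
#'
#' @return Data frame with `min_weight_g`, `max_weight_g`, `ration_pct_bw`.
#' @export
default_feed_table <- function() {
  data.frame(min_weight_g = c(0, 100, 250),
             max_weight_g = c(100, 250, 600),
             ration_pct_bw = c(2.0, 1.5, 1.2),
             feed_type = c("starter", "grower", "finisher"))
}

#' Propose management interventions
#'
#' Evaluates the rule set and returns zero or more proposals, each tied to
#' its trigger variable and execution cadence: harvest on fish weight
#' (yearly), transfer on biomass density (monthly/yearly), feed-type change
#' on weight class (monthly/yearly), next-day feed quantity on weight
#' (daily), next-hour oxygen supply on DO concentration (hourly).  At most
#' one proposal of each kind is emitted per call; rules lacking their
#' configuration are skipped with a warning.  Proposals are ordered
#' irreversible-first: harvest, transfer, feed change, feed quantity,
#' oxygen.
#'
#' @param state A [stocking_state()].
#' @param do_summary List with at least `min_mgL`, a summary of the current
#'   DO field.
#' @param config List of rule settings: `harvest_weight_g`, `feed_table`,
#'   `transfer_rule`, `forecast` (for the transfer rule), `do_setpoint_mgL`,
#'   `temperature_C`, `min_temp_C`.
#' @return A list of proposals, each a list with `kind`, `trigger_variable`,
#'   `cadence`, `detail`.
#' @export
propose_interventions <- function(state, do_summary, config) {
  proposals <- list()
  add <- function(kind, trigger, cadence, detail) {
    proposals[[length(proposals) + 1L]] <<-
      list(kind = kind, trigger_variable = trigger, cadence = cadence,
           detail = detail)
  }
  skip <- function(rule, what) {
    warning(sprintf("rule '%s' skipped: missing %s", rule, what),
            call. = FALSE)
  }

  if (is.null(config$harvest_weight_g)) {
    skip("harvest", "harvest_weight_g")
  } else if (state$cohort$mean_weight_g >= config$harvest_weight_g) {
    add("harvest", "fish_weight", "yearly",
        sprintf("mean weight %.0f g has reached harvest weight %.0f g",
                state$cohort$mean_weight_g, config$harvest_weight_g))
  }

  if (is.null(config$transfer_rule) || is.null(config$forecast)) {
    skip("transfer", "transfer_rule/forecast")
  } else {
    ev <- suppressWarnings(
      plan_transfer(config$forecast, config$transfer_rule,
                    state$geometry$volume_m3))
    if (!is.null(ev)) {
      add("transfer", "biomass_density", "monthly",
          sprintf("transfer %.0f%% of biomass on day %g (predicted 100%% utilization on day %g)",
                  100 * ev$fraction, ev$time_d, ev$predicted_crossing_d))
    }
  }

  if (is.null(config$feed_table)) {
    skip("change_feed", "feed_table")
  } else {
    cls <- which(state$cohort$mean_weight_g >= config$feed_table$min_weight_g &
                   state$cohort$mean_weight_g < config$feed_table$max_weight_g)
    if (length(cls) && !is.null(config$feed_table$feed_type)) {
      add("change_feed", "fish_weight", "monthly",
          sprintf("feed type for current weight class: %s",
                  config$feed_table$feed_type[cls[1L]]))
    }
  }

  if (is.null(config$feed_table) || is.null(config$temperature_C)) {
    skip("set_feed_quantity", "feed_table/temperature_C")
  } else {
    qty <- tryCatch(
      daily_feed_quantity(state$cohort, config$temperature_C,
                          config$feed_table,
                          min_temp_C = config$min_temp_C %||% 2),
      racewaysim_lookup_error = function(e) NULL)
    if (!is.null(qty)) {
      add("set_feed_quantity", "fish_weight", "daily",
          sprintf("feed %.1f kg over the next day", qty))
    }
  }

  if (is.null(config$do_setpoint_mgL) || is.null(do_summary$min_mgL)) {
    skip("set_oxygen_supply", "do_setpoint_mgL/do summary")
  } else if (do_summary$min_mgL < config$do_setpoint_mgL) {
    add("set_oxygen_supply", "DO_concentration", "hourly",
        sprintf("raise oxygen supply: minimum DO %.2f mg/L below setpoint %.2f mg/L",
                do_summary$min_mgL, config$do_setpoint_mgL))
  }

  proposals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
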