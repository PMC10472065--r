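# Oxygen-supply control policies.
#
# Open-loop: the supply follows a fixed schedule regardless of the DO state.
# Closed-loop policies invert the quasi-steady raceway model by bisection on
# the supply:
#   * "green"   -- smallest supply making the predicted outlet concentration
#                  equal to the inlet concentration, so the water returned to
#                  the stream carries the same DO it arrived with (supply
#                  nearly coincident with fish demand);
#   * "welfare" -- smallest supply keeping the predicted minimum along the
#                  raceway at or above a welfare threshold (default
#                  9.5 mg/L for trout); zero whenever the unforced minimum
#                  already satisfies it.
# A proportional error-feedback valve model is also provided.

#' Supply schedule
#'
#' Piecewise-constant open-loop oxygen supply: ordered, non-overlapping
#' segments of (start, end, supply).
#'
#' @param start_d,end_d Segment bounds (days from start).
#' @param supply_m3h Supply during each segment (m3/h), non-negative.
#' @return An object of class `supply_schedule`.
#' @export
supply_schedule <- function(start_d = numeric(), end_d = numeric(),
                            supply_m3h = numeric()) {
  n <- length(start_d)
  if (length(end_d) != n || length(supply_m3h) != n)
    abort_validation("schedule columns must have equal length")
  if (n > 0) {
    if (any(end_d <= start_d)) abort_validation("segments must have positive span")
    if (any(supply_m3h < 0)) abort_validation("supply must be non-negative")
    o <- order(start_d)
    start_d <- start_d[o]; end_d <- end_d[o]; supply_m3h <- supply_m3h[o]
    if (n > 1 && any(start_d[-1] < end_d[-n] - 1e-12))
      abort_validation("schedule segments must not overlap")
  }
  structure(data.frame(start_d = start_d, end_d = end_d,
                       supply_m3h = supply_m3h),
            class = c("supply_schedule", "data.frame"))
}

#' Scheduled supply at a time point
#'
#' @param schedule A [supply_schedule()].
#' @param t_d Time (days from start).
#' @return Supply (m3/h): the containing segment's value, else 0.
#' @export
scheduled_supply <- function(schedule, t_d) {
  hit <- which(schedule$start_d <= t_d & t_d < schedule$end_d)
  if (length(hit)) schedule$supply_m3h[hit[1L]] else 0
}

# Quasi-steady prediction of the DO profile for a candidate supply.  The
# steady profile equals the trajectory of a water parcel over one residence
# time, so it serves as the one-residence-time forward prediction that the
# controllers invert.
predict_profile <- function(supply, state, geometry, rear, source, x = NULL) {
  src <- source; src$supply_m3_per_h <- supply
  C0 <- state$C_in_mgL + source_increment(src, state$Q_Lh)
  steady_state_profile(C0, state$Q_Lh, geometry, state$biomass, rear,
                       T_C = min(max(state$T_C, 0), 40), x = x)
}

bisect_supply <- function(objective, max_supply, tol_supply = 1e-3) {
  # smallest s in [0, max_supply] with objective(s) >= 0 (objective monotone
  # non-decreasing in s)
  lo <- 0; hi <- max_supply
  if (objective(lo) >= 0) return(list(supply = 0, saturated = FALSE))
  if (objective(hi) < 0) return(list(supply = max_supply, saturated = TRUE))
  while (hi - lo > tol_supply) {
    mid <- (lo + hi) / 2
    if (objective(mid) >= 0) hi <- mid else lo <- mid
  }
  list(supply = hi, saturated = FALSE)
}

#' Green closed-loop supply
#'
#' Smallest non-negative supply for which the predicted outlet concentration
#' is no lower than the inlet concentration, clamped to
#' `[0, max_supply_m3h]`.  When reaeration alone lifts the outlet to the
#' inlet level the supply is zero; when the demand exceeds the valve
#' capacity the clamped value is returned with `saturated = TRUE`.
#'
#' @param state List describing the current conditions: `C_in_mgL` (inlet DO
#'   before the source), `T_C`, `Q_Lh`, and `biomass`, a
#'   [distribute_biomass()] profile.
#' @param geometry A [raceway_geometry()].
#' @param rear A [reaeration_params()].
#' @param source An [oxygen_source()] supplying the gas density and
#'   efficiency of the valve.
#' @param max_supply_m3h Valve capacity (m3/h).
#' @param tol_mgL Matching tolerance on the outlet concentration (mg/L).
#' @param tol_supply Bisection tolerance on the supply (m3/h).
#' @return List `(supply_m3h, saturated, predicted_outlet_mgL)`.
#' @export
green_supply <- function(state, geometry, rear = reaeration_params(),
                         source = oxygen_source(0), max_supply_m3h = 5,
                         tol_mgL = 0.05, tol_supply = 1e-3) {
  L <- geometry$length_m
  outlet <- function(s)
    predict_profile(s, state, geometry, rear, source, x = L)
  sol <- bisect_supply(function(s) outlet(s) - state$C_in_mgL,
                       max_supply_m3h, tol_supply)
  list(supply_m3h = sol$supply, saturated = sol$saturated,
       predicted_outlet_mgL = outlet(sol$supply))
}

#' Welfare closed-loop supply
#'
#' Smallest non-negative supply keeping the predicted minimum concentration
#' along the raceway at or above the welfare threshold; exactly zero when
#' the unforced minimum already satisfies it, and clamped with
#' `saturated = TRUE` when the threshold is unattainable within the valve
#' capacity.
#'
#' @inheritParams green_supply
#' @param threshold_mgL Welfare floor (mg/L); default 9.5 for trout.
#' @return List `(supply_m3h, saturated, predicted_min_mgL)`.
#' @export
welfare_supply <- function(state, geometry, rear = reaeration_params(),
                           source = oxygen_source(0), threshold_mgL = 9.5,
                           max_supply_m3h = 5, tol_mgL = 0.05,
                           tol_supply = 1e-3) {
  x <- seq(0, geometry$length_m, length.out = 101L)
  minC <- function(s)
    min(predict_profile(s, state, geometry, rear, source, x = x))
  sol <- bisect_supply(function(s) minC(s) - threshold_mgL,
                       max_supply_m3h, tol_supply)
  list(supply_m3h = sol$supply, saturated = sol$saturated,
       predicted_min_mgL = minC(sol$supply))
}

#' Proportional feedback valve step
#'
#' Error-feedback adjustment of the supply valve: the new opening is the
#' current one plus `gain * (setpoint - measured)`, clamped to
#' `[0, max_supply]`.  Zero error leaves the valve unchanged.  On the
#' simulated raceway the loop is stable for gains below
#' `2 * Q / (gas_density * efficiency * 1e6)` (m3/h per mg/L), the inverse
#' of the outlet's sensitivity to the supply.
#'
#' @param measured_mgL Measured DO (mg/L).
#' @param setpoint_mgL Desired DO (mg/L).
#' @param current_valve_m3h Current valve opening (m3/h).
#' @param gain Proportional gain (m3/h per mg/L), non-negative.
#' @param max_supply_m3h Valve capacity (m3/h).
#' @return New valve opening (m3/h).
#' @export
feedback_step <- function(measured_mgL, setpoint_mgL, current_valve_m3h,
                          gain, max_supply_m3h = 5) {
  if (gain < 0) abort_validation("'gain' must be non-negative")
  min(max(current_valve_m3h + gain * (setpoint_mgL - measured_mgL), 0),
      max_supply_m3h)
}

#' Control policy
#'
#' Bundle of control settings for the scenario engine.
#'
#' @param mode `"open_loop"`, `"green"`, `"welfare"` or `"feedback"`.
#' @param threshold_mgL Welfare floor (mg/L).
#' @param setpoint_mgL Feedback setpoint (mg/L).
#' @param max_supply_m3h Valve capacity (m3/h).
#' @param gain Proportional gain of the feedback mode.
#' @param schedule A [supply_schedule()] for the open-loop mode.
#' @param tol_mgL Controller tolerance (mg/L).
#' @return An object of class `control_policy`.
#' @export
control_policy <- function(mode = c("open_loop", "green", "welfare", "feedback"),
                           threshold_mgL = 9.5, setpoint_mgL = 9,
                           max_supply_m3h = 5, gain = 0.5,
                           schedule = supply_schedule(), tol_mgL = 0.05) {
  mode <- match.arg(mode)
  if (threshold_mgL <= 0) abort_validation("'threshold_mgL' must be positive")
  if (max_supply_m3h < 0) abort_validation("'max_supply_m3h' must be non-negative")
  if (gain < 0) abort_validation("'gain' must be non-negative")
  structure(list(mode = mode, threshold_mgL = threshold_mgL,
                 setpoint_mgL = setpoint_mgL,
                 max_supply_m3h = max_supply_m3h, gain = gain,
                 schedule = schedule, tol_mgL = tol_mgL),
            class = "control_policy")
}
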