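# Deterioration accrued during transport.  A casualty of class s riding an
# arc with one-way travel time t accrues 2 * t * p_s trauma-score units on
# the road leg (the factor 2 covers the vehicle round trip), and
# 2 * t * factor * p_s on the air leg, where factor (default 0.2) is the
# post-treatment slowdown.  In the multi-period model a casualty moved in
# period t additionally waits (t - 1) * dt hours before departure.

#' Pre-treatment deterioration accrued on a road arc
#'
#' @param travel_time_h One-way travel time in hours (non-negative).
#' @param sev A [severity_class()].
#' @return `2 * travel_time_h * p_s`.
#' @export
pre_rate <- function(travel_time_h, sev) {
  check_time(travel_time_h)
  2 * travel_time_h * sev$base_deterioration
}

#' Post-treatment deterioration accrued on an air arc
#'
#' @inheritParams pre_rate
#' @param factor Post-treatment slowdown in `(0, 1]` (default 0.2).
#' @return `2 * travel_time_h * factor * p_s`.
#' @export
post_rate <- function(travel_time_h, sev, factor = 0.2) {
  check_time(travel_time_h)
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]", call. = FALSE)
  2 * travel_time_h * factor * sev$base_deterioration
}

#' Deterioration on a road arc in period t of the dynamic model
#'
#' Casualties moved in period `t` have already waited `(t - 1) * dt` hours,
#' so the accrued deterioration is `p_s * ((t - 1) * dt + 2 * travel_time_h)`.
#' At `t = 1` this coincides with [pre_rate()].
#'
#' @inheritParams pre_rate
#' @param period Period index `t >= 1`.
#' @param dt Period length in hours (`> 0`, or 0 to drop the waiting term).
#' @return Accrued deterioration (non-negative).
#' @export
dynamic_pre_rate <- function(travel_time_h, sev, period, dt) {
  check_time(travel_time_h)
  if (period < 1) stop("period must be >= 1", call. = FALSE)
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  sev$base_deterioration * ((period - 1) * dt + 2 * travel_time_h)
}

#' Deterioration on an air arc in period t of the dynamic model
#'
#' `factor * p_s * ((t - 1) * dt + 2 * travel_time_h)`; at `t = 1` this
#' coincides with [post_rate()].
#'
#' @inheritParams dynamic_pre_rate
#' @param factor Post-treatment slowdown in `[0, 1]`.
#' @return Accrued deterioration (non-negative).
#' @export
dynamic_post_rate <- function(travel_time_h, sev, period, dt, factor = 0.2) {
  check_time(travel_time_h)
  if (period < 1) stop("period must be >= 1", call. = FALSE)
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (factor < 0 || factor > 1) stop("factor must lie in [0, 1]", call. = FALSE)
  factor * sev$base_deterioration * ((period - 1) * dt + 2 * travel_time_h)
}

check_time <- function(t) {
  if (any(t < 0)) stop("travel time must be >= 0", call. = FALSE)
  invisible(t)
}

#' Per-casualty objective coefficients of an instance
#'
#' Returns the weighted-deterioration cost of moving one casualty across each
#' arc: `road[i, j, s] = 2 * t_ij * p_s * w_s` (the pre-treatment component
#' F1) and `air[j, k, s] = 2 * t_jk * factor * p_s * w_s` (the
#' post-treatment component F2).
#'
#' @param inst An [evac_instance()].
#' @param period,dt Optional period index and period length; when given, the
#'   dynamic-model coefficients (waiting time included) are returned instead.
#' @return List with 3-d arrays `road` (areas x temps x severities) and
#'   `air` (temps x generals x severities).
#' @export
objective_terms <- function(inst, period = NULL, dt = NULL) {
  stopifnot(is.null(period) == is.null(dt))
  sevs <- inst$severities
  nI <- length(inst$areas); nJ <- length(inst$temp_hospitals)
  nK <- length(inst$general_hospitals)
  road <- array(0, c(nI, nJ, 2),
                dimnames = list(inst$areas, inst$temp_hospitals, SEVERITIES))
  air <- array(0, c(nJ, nK, 2),
               dimnames = list(inst$temp_hospitals, inst$general_hospitals,
                               SEVERITIES))
  for (s in SEVERITIES) {
    sv <- sevs[[s]]
    if (is.null(period)) {
      road[, , s] <- pre_rate(inst$road_times, sv) * sv$urgency_weight
      air[, , s] <- post_rate(inst$air_times, sv, inst$post_treatment_factor) *
        sv$urgency_weight
    } else {
      road[, , s] <- dynamic_pre_rate(inst$road_times, sv, period, dt) *
        sv$urgency_weight
      air[, , s] <- dynamic_post_rate(inst$air_times, sv, period, dt,
                                      inst$post_treatment_factor) *
        sv$urgency_weight
    }
  }
  list(road = road, air = air)
}
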