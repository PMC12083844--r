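# Budget-of-uncertainty robust counterpart.  Casualty counts live in
# symmetric intervals [q - q_hat, q + q_hat] with q_hat = variability * q;
# the per-area budget Gamma in [0, 1] scales how much of the deviation the
# plan must cover.  With uncertainty only on the demand right-hand side, the
# protection function of the interval set is maximised at its extreme point,
# so the robust counterpart collapses to demand inflation:
# coverage >= q + round(q_hat * Gamma), with ">=" replacing "=".

#' Uncertainty specification
#'
#' @param variability Fraction `delta` in `[0, 1]`: the maximum deviation is
#'   `delta * q` per (area, severity).
#' @param budget Either a scalar budget `Gamma` in `[0, 1]` broadcast to all
#'   areas, or a named vector over area ids.
#' @param rounding How the (generally fractional) deviation term
#'   `delta * q * Gamma` is made integral: `"ceil"` (default), `"half_up"`,
#'   or `"floor"`.  Ceiling is the default because casualty protection is
#'   conservative: any fractional casualty is planned for in full.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(variability, budget = 1,
                             rounding = c("ceil", "half_up", "floor")) {
  rounding <- match.arg(rounding)
  if (variability < 0 || variability > 1)
    stop("variability must lie in [0, 1]", call. = FALSE)
  if (any(budget < 0) || any(budget > 1))
    stop("budget must lie in [0, 1]", call. = FALSE)
  structure(list(variability = as.numeric(variability),
                 budget = budget, rounding = rounding),
            class = "uncertainty_spec")
}

round_rule <- function(x, rounding) {
  switch(rounding,
         ceil = ceiling(x),
         floor = floor(x),
         half_up = floor(x + 0.5))
}

#' Inflated (protected) demand for one nominal count
#'
#' `q + round(delta * q * Gamma)` under the chosen rounding rule; the
#' deviation term is rounded before being added to the integral nominal.
#'
#' @param q_nominal Non-negative nominal count(s).
#' @param delta Variability fraction in `[0, 1]`.
#' @param gamma Budget in `[0, 1]`.
#' @param rounding `"ceil"`, `"half_up"`, or `"floor"`.
#' @return Integer-valued inflated demand (vectorised).
#' @export
inflated_demand <- function(q_nominal, delta, gamma,
                            rounding = c("ceil", "half_up", "floor")) {
  rounding <- match.arg(rounding)
  if (any(q_nominal < 0)) stop("nominal counts must be >= 0", call. = FALSE)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  if (any(gamma < 0) || any(gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  q_nominal + round_rule(delta * q_nominal * gamma, rounding)
}

# Budget as a named vector over the instance's areas.
budget_by_area <- function(inst, unc) {
  b <- unc$budget
  if (length(b) == 1L && is.null(names(b)))
    return(stats::setNames(rep(as.numeric(b), length(inst$areas)), inst$areas))
  if (!all(inst$areas %in% names(b)))
    stop("budget vector must name every area", call. = FALSE)
  as.numeric(b[inst$areas])
}

#' Inflated demand matrix of an instance
#'
#' @param inst An [evac_instance()].
#' @param unc An [uncertainty_spec()].
#' @return Matrix (areas x severities) of protected demands.
#' @export
inflated_demand_matrix <- function(inst, unc) {
  gam <- budget_by_area(inst, unc)
  out <- inst$casualties
  for (s in SEVERITIES)
    out[, s] <- inflated_demand(inst$casualties[, s], unc$variability, gam,
                                unc$rounding)
  out
}

#' Build the robust counterpart MILP
#'
#' Identical to [build_static()] except that demand constraints take sense
#' `>=` with right-hand sides inflated by the rounded deviation term.  With
#' `budget = 0` the model has the same optimum as the deterministic one.
#'
#' @inheritParams build_static
#' @param unc An [uncertainty_spec()].
#' @return A [milp_model()].
#' @export
build_robust <- function(inst, unc,
                         formulation = c("aggregated", "per_vehicle")) {
  build_static(inst, demand_rhs = inflated_demand_matrix(inst, unc),
               formulation = match.arg(formulation), demand_sense = "ge")
}

#' Build, solve, and extract the robust plan
#'
#' @inheritParams build_robust
#' @param ... Passed to [solve_milp()].
#' @return A `static_solution` (or a stub with `solver_status` on failure,
#'   including a diagnostic naming the binding capacity when the inflated
#'   totals exceed what the system can hold).
#' @export
solve_robust <- function(inst, unc,
                         formulation = c("aggregated", "per_vehicle"), ...) {
  model <- build_robust(inst, unc, match.arg(formulation))
  raw <- solve_milp(model, ...)
  if (raw$status != "optimal") {
    diag <- infeasibility_diagnostic(inst, model$meta$demand_rhs)
    return(structure(list(solver_status = raw$status, objective = NA_real_,
                          diagnostic = diag), class = "static_solution"))
  }
  extract_static_solution(raw, inst, model)
}

infeasibility_diagnostic <- function(inst, demand) {
  msgs <- character(0)
  total <- sum(demand)
  if (total > sum(inst$capacities$temp))
    msgs <- c(msgs, sprintf(
      "inflated total %g exceeds pooled temporary capacity %g",
      total, sum(inst$capacities$temp)))
  for (s in SEVERITIES)
    if (sum(demand[, s]) > sum(inst$capacities$general[, s]))
      msgs <- c(msgs, sprintf(
        "inflated %s total %g exceeds pooled general capacity %g",
        s, sum(demand[, s]), sum(inst$capacities$general[, s])))
  if (total > inst$fleet$vehicles * inst$fleet$vehicle_capacity)
    msgs <- c(msgs, "inflated total exceeds road fleet seat capacity")
  if (total > inst$fleet$helicopters * inst$fleet$helicopter_capacity)
    msgs <- c(msgs, "inflated total exceeds helicopter seat capacity")
  if (!length(msgs)) msgs <- "no aggregate capacity is exceeded; infeasibility is combinatorial"
  msgs
}

#' Worst-case evaluation of a fixed plan
#'
#' Evaluates a plan against the single worst realization of the interval
#' uncertainty set, `q = nominal + round(deviation * Gamma)` per (area,
#' severity).  For right-hand-side-only uncertainty the protection function
#' is maximised at this extreme point, so exhaustive vertex enumeration
#' collapses to one evaluation.  Coverage holds when the plan's road flows
#' out of each area meet the realized demand.
#'
#' @param inst An [evac_instance()].
#' @param unc An [uncertainty_spec()].
#' @param plan A `static_solution`.
#' @return List with `feasible` (logical), `objective` (the plan's realized
#'   weighted trauma score), and `shortfall` (matrix of uncovered demand).
#' @export
worst_case_oracle <- function(inst, unc, plan) {
  realized <- inflated_demand_matrix(inst, unc)
  coverage <- apply(plan$flows_road, c(1, 3), sum)[inst$areas, SEVERITIES]
  shortfall <- pmax(realized - coverage, 0)
  list(feasible = all(shortfall <= 0),
       objective = plan$objective,
       shortfall = shortfall)
}
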