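# Computational study drivers: the budget/variability sensitivity sweep, the
# Monte-Carlo feasibility comparison of deterministic vs robust plans, and
# the hospital-capacity sweep.

#' Sensitivity sweep over uncertainty budgets and variabilities
#'
#' One robust solve per (budget, variability) pair; budget 0 collapses to a
#' single deterministic row because every variability gives the same model
#' there.  Rows report the objective split, the opened hospital sets, and
#' the solver status; per-cell failures are recorded and the sweep
#' continues.
#'
#' @param inst An [evac_instance()].
#' @param gammas Numeric vector of budgets in `[0, 1]`.
#' @param deltas Numeric vector of variabilities in `[0, 1]`.
#' @param rounding Deviation rounding rule (see [uncertainty_spec()]).
#' @param ... Passed to [solve_milp()].
#' @return A `data.frame` of class `sweep_result`, sorted by
#'   (gamma, delta), with columns `gamma`, `delta`, `F1`, `F2`, `objective`,
#'   `temp_open`, `general_open`, `status`.
#' @export
sensitivity_sweep <- function(inst, gammas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                              deltas = c(0.05, 0.15, 0.20),
                              rounding = "ceil", ...) {
  grid <- expand.grid(delta = sort(deltas), gamma = sort(gammas))[, 2:1]
  grid <- grid[!(grid$gamma == 0 & duplicated(grid$gamma)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid$gamma[r]; d <- grid$delta[r]
    sol <- tryCatch(
      solve_robust(inst, uncertainty_spec(d, g, rounding), ...),
      error = function(e) structure(list(solver_status = "error",
                                         objective = NA_real_),
                                    class = "static_solution"))
    data.frame(gamma = g, delta = if (g == 0) NA_real_ else d,
               F1 = sol$F1 %||% NA_real_, F2 = sol$F2 %||% NA_real_,
               objective = sol$objective,
               temp_open = paste(sol$temp_open %||% character(0), collapse = ","),
               general_open = paste(sol$general_open %||% character(0),
                                    collapse = ","),
               status = sol$solver_status)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

# Aggregate feasibility of serving realized demand q within a fixed opened
# configuration, allowing full reallocation (restricted recourse).  Because
# every area can reach every temporary hospital and every temporary hospital
# every general one, transportation feasibility reduces to the aggregate
# conditions: pooled opened temporary capacity, per-severity pooled opened
# general capacity, and fleet seats on both legs.
plan_covers <- function(inst, plan, q, mode = c("recourse", "frozen")) {
  mode <- match.arg(mode)
  if (mode == "frozen") {
    coverage <- apply(plan$flows_road, c(1, 3), sum)
    return(all(coverage >= q - 1e-9))
  }
  total <- sum(q)
  if (total > sum(inst$capacities$temp[plan$temp_open])) return(FALSE)
  for (s in SEVERITIES) {
    if (sum(q[, s]) >
        sum(inst$capacities$general[plan$general_open, s, drop = FALSE]))
      return(FALSE)
  }
  if (total > inst$fleet$vehicles * inst$fleet$vehicle_capacity) return(FALSE)
  if (total > inst$fleet$helicopters * inst$fleet$helicopter_capacity) return(FALSE)
  TRUE
}

# Realized cost of serving demand q optimally within the plan's opened
# hospitals: a transportation problem on the restricted arcs (continuous
# relaxation is integral for fixed openings in the aggregate sense used
# here; we re-solve the restricted MILP for exactness).
realized_objective <- function(inst, plan, q, ...) {
  restricted <- inst
  closed_t <- setdiff(inst$temp_hospitals, plan$temp_open)
  closed_g <- setdiff(inst$general_hospitals, plan$general_open)
  restricted$capacities$temp[closed_t] <- 0
  restricted$capacities$general[closed_g, ] <- 0
  restricted$casualties[] <- q
  sol <- solve_static(restricted, ...)
  sol$objective
}

#' Monte-Carlo feasibility comparison of deterministic and robust plans
#'
#' Solves the deterministic and robust plans once, then draws `n_samples`
#' casualty realizations ([perturb_realization()]) and checks whether each
#' plan can serve each realization within its opened hospitals (restricted
#' recourse by default: reallocation is allowed, openings are not revisited;
#' `mode = "frozen"` instead requires the plan's own flows to cover the
#' realization).  Mean realized objectives are averaged over the feasible
#' samples (recourse mode re-solves the restricted transportation problem;
#' to bound runtime this is done on at most `n_objective` samples).
#'
#' @param inst An [evac_instance()].
#' @param unc An [uncertainty_spec()].
#' @param n_samples Number of realizations.
#' @param seed Integer seed (realization r uses `seed + r`).
#' @param mode `"recourse"` or `"frozen"`.
#' @param n_objective Cap on the per-plan objective re-solves.
#' @param ... Passed to [solve_milp()].
#' @return A `data.frame` of class `feasibility_result` with one row:
#'   sample counts, feasible counts and mean realized objectives for both
#'   plans.
#' @export
feasibility_experiment <- function(inst, unc, n_samples = 10L, seed = 1L,
                                   mode = c("recourse", "frozen"),
                                   n_objective = 5L, ...) {
  mode <- match.arg(mode)
  det_plan <- solve_static(inst, ...)
  rob_plan <- solve_robust(inst, unc, ...)
  if (det_plan$solver_status != "optimal" || rob_plan$solver_status != "optimal")
    stop("both base plans must solve to optimality", call. = FALSE)
  det_ok <- logical(n_samples); rob_ok <- logical(n_samples)
  det_obj <- numeric(0); rob_obj <- numeric(0)
  for (r in seq_len(n_samples)) {
    q <- perturb_realization(inst, unc, seed + r)
    det_ok[r] <- plan_covers(inst, det_plan, q, mode)
    rob_ok[r] <- plan_covers(inst, rob_plan, q, mode)
    if (mode == "recourse") {
      if (det_ok[r] && length(det_obj) < n_objective)
        det_obj <- c(det_obj, realized_objective(inst, det_plan, q, ...))
      if (rob_ok[r] && length(rob_obj) < n_objective)
        rob_obj <- c(rob_obj, realized_objective(inst, rob_plan, q, ...))
    }
  }
  out <- data.frame(
    n_areas = length(inst$areas), n_temp = length(inst$temp_hospitals),
    n_general = length(inst$general_hospitals),
    gamma = if (length(unc$budget) == 1L) as.numeric(unc$budget) else NA_real_,
    delta = unc$variability, n_samples = n_samples,
    det_feasible = sum(det_ok), rob_feasible = sum(rob_ok),
    det_mean_objective = if (length(det_obj)) mean(det_obj) else NA_real_,
    rob_mean_objective = if (length(rob_obj)) mean(rob_obj) else NA_real_)
  attr(out, "det_feasible_mask") <- det_ok
  attr(out, "rob_feasible_mask") <- rob_ok
  class(out) <- c("feasibility_result", class(out))
  out
}

#' Objective response to hospital capacity
#'
#' Re-solves the robust model over a grid of temporary-hospital capacities
#' and general-hospital capacity scale factors; infeasible cells are
#' recorded as such.
#'
#' @param inst An [evac_instance()].
#' @param temp_caps Vector of pooled per-hospital temporary capacities.
#' @param general_scale Vector of multipliers applied to every general
#'   capacity.
#' @param unc An [uncertainty_spec()] (use budget 0 for the deterministic
#'   response).
#' @param ... Passed to [solve_milp()].
#' @return `data.frame` with columns `temp_capacity`, `general_scale`,
#'   `objective`, `status`.
#' @export
capacity_sweep <- function(inst, temp_caps, general_scale = 1, unc, ...) {
  grid <- expand.grid(temp_capacity = temp_caps,
                      general_scale = general_scale)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    modified <- inst
    modified$capacities$temp[] <- grid$temp_capacity[r]
    modified$capacities$general <-
      ceiling(inst$capacities$general * grid$general_scale[r])
    sol <- tryCatch(solve_robust(modified, unc, ...),
                    error = function(e) list(solver_status = "error",
                                             objective = NA_real_))
    data.frame(temp_capacity = grid$temp_capacity[r],
               general_scale = grid$general_scale[r],
               objective = sol$objective, status = sol$solver_status)
  })
  do.call(rbind, rows)
}
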