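# Multi-period dynamic location-transportation model.  Casualties moved in
# period t accrue waiting deterioration (t - 1) * dt on top of transport
# deterioration; opened-hospital sets may differ per period; vehicles and
# helicopters return to service one period after use, giving the fleet
# availability recursion avail[t + 1] = avail[t] - used[t] + used[t - 1].
# Fleet availability is tracked in seat units (count * per-tool capacity);
# there is no per-arc vehicle integer at this level.

#' Period structure of the dynamic model
#'
#' @param n_periods Number of periods `T >= 1`.
#' @param period_length Period length `dt` in hours (`> 0`).
#' @return An object of class `period_spec`.
#' @export
period_spec <- function(n_periods = 2L, period_length = 1) {
  n_periods <- as.integer(n_periods)
  if (is.na(n_periods) || n_periods < 1L) stop("n_periods must be >= 1", call. = FALSE)
  if (period_length <= 0) stop("period_length must be > 0", call. = FALSE)
  structure(list(n_periods = n_periods,
                 period_length = as.numeric(period_length)),
            class = "period_spec")
}

#' Fleet availability under the one-period-return recursion
#'
#' Tools used in period `t` are back in service in period `t + 2`:
#' `avail[1] = total`, `avail[t + 1] = avail[t] - usage[t] + usage[t - 1]`
#' (with `usage[0] = 0`).
#'
#' @param total Total fleet size.
#' @param usage Vector of per-period usage counts.
#' @return Availability vector of length `length(usage) + 1`.  Errors if any
#'   period's usage exceeds its availability.
#' @export
fleet_availability <- function(total, usage) {
  avail <- numeric(length(usage) + 1L)
  avail[1] <- total
  prev <- 0
  for (t in seq_along(usage)) {
    if (usage[t] > avail[t])
      stop(sprintf("usage %g in period %d exceeds availability %g",
                   usage[t], t, avail[t]), call. = FALSE)
    avail[t + 1L] <- avail[t] - usage[t] + prev
    prev <- usage[t]
  }
  avail
}

#' Build the two-stage dynamic MILP
#'
#' Monolithic multi-period model: period-gated and cumulative temporary
#' capacities, per-period seat availability with the fleet-return recursion,
#' total demand over periods (inflated when `unc` is given), per-period
#' outflow caps (deflated when `unc` is given), general-hospital gating and
#' cumulative caps, open-implies-served rules, per-period conservation at
#' each temporary hospital, and the waiting-time objective.
#'
#' When `unc` is given with a positive budget and `T = 1`, the total-demand
#' floor `q + dev` and the single period's outflow cap `q - dev` contradict
#' each other; the builder stops with a diagnostic in that case.
#'
#' @param inst An [evac_instance()].
#' @param periods A [period_spec()].
#' @param unc Optional [uncertainty_spec()] for the per-period budget.
#' @return A [milp_model()] with extraction metadata.
#' @export
build_two_stage <- function(inst, periods, unc = NULL) {
  rep <- validate_instance(inst)
  if (length(rep$errors))
    stop("instance fails validation:\n", format_report_items(rep$errors),
         call. = FALSE)
  I <- inst$areas; J <- inst$temp_hospitals; K <- inst$general_hospitals
  nI <- length(I); nJ <- length(J); nK <- length(K)
  TT <- periods$n_periods; dt <- periods$period_length
  eg <- inst$fleet$vehicle_capacity; eh <- inst$fleet$helicopter_capacity
  seats_road <- eg * inst$fleet$vehicles
  seats_air <- eh * inst$fleet$helicopters

  if (is.null(unc)) {
    dev <- matrix(0, nI, 2, dimnames = dimnames(inst$casualties))
  } else {
    dev <- inflated_demand_matrix(inst, unc) - inst$casualties
    if (TT == 1L && any(dev > 0))
      stop("with one period the robust total-demand floor (q + dev) and the ",
           "per-period cap (q - dev) are contradictory; use n_periods >= 2 ",
           "or budget 0", call. = FALSE)
  }
  dem_floor <- inst$casualties + dev
  period_cap <- inst$casualties - dev

  # blocks: x[i,j,s,t] | y[j,k,s,t] | U[j,t] | V[k,t]
  o_x <- 0L; o_y <- o_x + nI * nJ * 2L * TT
  o_U <- o_y + nJ * nK * 2L * TT; o_V <- o_U + nJ * TT
  nvar <- o_V + nK * TT
  ix <- function(i, j, s, t) o_x + (((t - 1L) * 2L + (s - 1L)) * nJ + (j - 1L)) * nI + i
  iy <- function(j, k, s, t) o_y + (((t - 1L) * 2L + (s - 1L)) * nK + (k - 1L)) * nJ + j
  iU <- function(j, t) o_U + (t - 1L) * nJ + j
  iV <- function(k, t) o_V + (t - 1L) * nK + k

  nm <- character(nvar); obj <- numeric(nvar)
  for (t in 1:TT) {
    ot <- objective_terms(inst, period = t, dt = dt)
    for (s in 1:2) for (j in 1:nJ) for (i in 1:nI) {
      nm[ix(i, j, s, t)] <- sprintf("x_%s_%s_%s_t%d", I[i], J[j], SEVERITIES[s], t)
      obj[ix(i, j, s, t)] <- ot$road[i, j, s]
    }
    for (s in 1:2) for (k in 1:nK) for (j in 1:nJ) {
      nm[iy(j, k, s, t)] <- sprintf("y_%s_%s_%s_t%d", J[j], K[k], SEVERITIES[s], t)
      obj[iy(j, k, s, t)] <- ot$air[j, k, s]
    }
    for (j in 1:nJ) nm[iU(j, t)] <- sprintf("U_%s_t%d", J[j], t)
    for (k in 1:nK) nm[iV(k, t)] <- sprintf("V_%s_t%d", K[k], t)
  }
  vtype <- rep("I", nvar); vtype[(o_U + 1L):nvar] <- "B"
  lb <- numeric(nvar); ub <- rep(Inf, nvar); ub[(o_U + 1L):nvar] <- 1

  cs <- list()
  add <- function(ind, val, sense, rhs, name)
    cs[[length(cs) + 1L]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                                   sense = sense, rhs = rhs, name = name)
  xs_jt <- function(j, t) c(outer(1:nI, 1:2, function(i, s) ix(i, j, s, t)))
  ys_kt <- function(k, t, s) vapply(1:nJ, function(j) iy(j, k, s, t), 1L)
  # temporary gating per period and cumulative cap
  for (j in 1:nJ) {
    for (t in 1:TT)
      add(c(xs_jt(j, t), iU(j, t)),
          c(rep(1, nI * 2), -inst$capacities$temp[[J[j]]]), "<=", 0,
          sprintf("gate_%s_t%d", J[j], t))
    ind <- unlist(lapply(1:TT, function(t) xs_jt(j, t)))
    add(ind, rep(1, length(ind)), "<=", inst$capacities$temp[[J[j]]],
        paste0("cum_cap_", J[j]))
  }
  # road seat availability: used[t] + used[t-1] <= total seats
  for (t in 1:TT) {
    ind <- unlist(lapply(1:nJ, function(j) xs_jt(j, t)))
    if (t > 1) ind <- c(ind, unlist(lapply(1:nJ, function(j) xs_jt(j, t - 1L))))
    add(ind, rep(1, length(ind)), "<=", seats_road,
        sprintf("seats_road_t%d", t))
  }
  # total demand over periods (>= floor), per-period outflow cap
  for (i in 1:nI) for (s in 1:2) {
    ind <- c(outer(1:nJ, 1:TT, function(j, t) ix(i, j, s, t)))
    add(ind, rep(1, length(ind)),
        if (is.null(unc)) "=" else ">=", dem_floor[i, s],
        sprintf("demand_%s_%s", I[i], SEVERITIES[s]))
    for (t in 1:TT)
      add(vapply(1:nJ, function(j) ix(i, j, s, t), 1L), rep(1, nJ),
          "<=", period_cap[i, s],
          sprintf("percap_%s_%s_t%d", I[i], SEVERITIES[s], t))
  }
  # general gating per (k, s, t) and cumulative per (k, s)
  for (k in 1:nK) for (s in 1:2) {
    for (t in 1:TT)
      add(c(ys_kt(k, t, s), iV(k, t)),
          c(rep(1, nJ), -inst$capacities$general[K[k], SEVERITIES[s]]),
          "<=", 0, sprintf("gate_%s_%s_t%d", K[k], SEVERITIES[s], t))
    ind <- c(outer(1:nJ, 1:TT, function(j, t) iy(j, k, s, t)))
    add(ind, rep(1, length(ind)), "<=",
        inst$capacities$general[K[k], SEVERITIES[s]],
        sprintf("cum_cap_%s_%s", K[k], SEVERITIES[s]))
  }
  # opened general hospitals receive at least one casualty in that period
  for (k in 1:nK) for (t in 1:TT) {
    ind <- c(outer(1:nJ, 1:2, function(j, s) iy(j, k, s, t)))
    add(c(ind, iV(k, t)), c(rep(1, length(ind)), -1), ">=", 0,
        sprintf("serve_%s_t%d", K[k], t))
  }
  # helicopter seat availability
  for (t in 1:TT) {
    ind <- unlist(lapply(1:nJ, function(j)
      c(outer(1:nK, 1:2, function(k, s) iy(j, k, s, t)))))
    if (t > 1) ind <- c(ind, unlist(lapply(1:nJ, function(j)
      c(outer(1:nK, 1:2, function(k, s) iy(j, k, s, t - 1L))))))
    add(ind, rep(1, length(ind)), "<=", seats_air,
        sprintf("seats_air_t%d", t))
  }
  # per-period conservation at each temporary hospital
  for (j in 1:nJ) for (s in 1:2) for (t in 1:TT)
    add(c(vapply(1:nI, function(i) ix(i, j, s, t), 1L),
          vapply(1:nK, function(k) iy(j, k, s, t), 1L)),
        c(rep(1, nI), rep(-1, nK)), "=", 0,
        sprintf("conserve_%s_%s_t%d", J[j], SEVERITIES[s], t))

  model <- milp_model(nm, lb, ub, vtype, obj, cs, "two_stage")
  model$meta <- list(type = "dynamic", n_periods = TT, dt = dt,
                     offsets = list(x = o_x, y = o_y, U = o_U, V = o_V),
                     dem_floor = dem_floor, period_cap = period_cap)
  model
}

#' Extract a structured solution from a solved dynamic model
#'
#' @param raw Result of [solve_milp()] with status `"optimal"`.
#' @param inst The instance.
#' @param model The built model.
#' @return An object of class `dynamic_solution`: per-period opened sets,
#'   4-d flow arrays, per-period seat usage and availability sequences
#'   (vehicle/helicopter counts via the seat capacity), `F1`, `F2`,
#'   `objective`.
#' @export
extract_dynamic_solution <- function(raw, inst, model) {
  if (raw$status != "optimal")
    stop("cannot extract a solution from status '", raw$status, "'",
         call. = FALSE)
  I <- inst$areas; J <- inst$temp_hospitals; K <- inst$general_hospitals
  nI <- length(I); nJ <- length(J); nK <- length(K)
  TT <- model$meta$n_periods; dt <- model$meta$dt
  off <- model$meta$offsets
  v <- raw$values
  flows_road <- array(v[(off$x + 1L):(off$x + nI * nJ * 2L * TT)],
                      c(nI, nJ, 2, TT),
                      dimnames = list(I, J, SEVERITIES, paste0("t", 1:TT)))
  flows_air <- array(v[(off$y + 1L):(off$y + nJ * nK * 2L * TT)],
                     c(nJ, nK, 2, TT),
                     dimnames = list(J, K, SEVERITIES, paste0("t", 1:TT)))
  U <- matrix(v[(off$U + 1L):(off$U + nJ * TT)], nJ, TT,
              dimnames = list(J, paste0("t", 1:TT)))
  V <- matrix(v[(off$V + 1L):(off$V + nK * TT)], nK, TT,
              dimnames = list(K, paste0("t", 1:TT)))
  F1 <- 0; F2 <- 0
  for (t in 1:TT) {
    ot <- objective_terms(inst, period = t, dt = dt)
    F1 <- F1 + sum(ot$road * flows_road[, , , t])
    F2 <- F2 + sum(ot$air * flows_air[, , , t])
  }
  if (abs(F1 + F2 - raw$objective) > 1e-4)
    stop("internal consistency error: recomputed dynamic objective mismatch",
         call. = FALSE)
  eg <- inst$fleet$vehicle_capacity; eh <- inst$fleet$helicopter_capacity
  road_use <- vapply(1:TT, function(t) sum(flows_road[, , , t]), 1)
  air_use <- vapply(1:TT, function(t) sum(flows_air[, , , t]), 1)
  # U_jt = 1 with zero intake is feasible (opening carries no cost term);
  # report only flow-bearing openings so the plan is well-defined under
  # solver degeneracy.
  structure(list(
    temp_open = lapply(1:TT, function(t) {
      intake <- apply(flows_road[, , , t, drop = FALSE], 2, sum)
      J[U[, t] > 0.5 & intake > 0]
    }),
    general_open = lapply(1:TT, function(t) K[V[, t] > 0.5]),
    flows_road = flows_road, flows_air = flows_air,
    seat_usage = list(road = road_use, air = air_use),
    fleet_avail = list(
      vehicles = fleet_availability(eg * inst$fleet$vehicles, road_use) / eg,
      helicopters = fleet_availability(eh * inst$fleet$helicopters, air_use) / eh),
    F1 = F1, F2 = F2, objective = F1 + F2,
    solver_status = raw$status),
    class = "dynamic_solution")
}

#' @export
print.dynamic_solution <- function(x, ...) {
  TT <- length(x$temp_open)
  cat(sprintf("dynamic evacuation plan over %d periods\n", TT))
  cat(sprintf("  objective %.4f = F1 %.4f + F2 %.4f\n", x$objective, x$F1, x$F2))
  for (t in 1:TT)
    cat(sprintf("  t=%d: temporary {%s}, general {%s}, %g casualties moved\n",
                t, paste(x$temp_open[[t]], collapse = ", "),
                paste(x$general_open[[t]], collapse = ", "),
                x$seat_usage$road[t]))
  invisible(x)
}

#' Build, solve, and extract the dynamic plan
#'
#' @inheritParams build_two_stage
#' @param ... Passed to [solve_milp()].
#' @return A `dynamic_solution` (or a stub with `solver_status`).
#' @export
solve_dynamic <- function(inst, periods = period_spec(), unc = NULL, ...) {
  model <- build_two_stage(inst, periods, unc)
  raw <- solve_milp(model, ...)
  if (raw$status != "optimal")
    return(structure(list(solver_status = raw$status, objective = NA_real_),
                     class = "dynamic_solution"))
  extract_dynamic_solution(raw, inst, model)
}
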