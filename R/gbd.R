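# Generalized Benders decomposition of the two-stage model.  The master
# problem carries the road leg (x, U, fleet recursion, demand) plus a scalar
# surrogate theta for the air-leg cost; the subproblem carries the air leg
# (y, V, helicopter recursion) with the road-side handover fixed.  The
# optimality cut is the constant bound theta >= SP optimum at the trial
# first stage, exactly as the source algorithm states it; because the cut
# carries no dependence on master variables the loop converges in very few
# iterations, and the monolithic model is the correctness anchor in tests.

#' Build the GBD master problem
#'
#' Road-leg model plus a non-negative surrogate `theta` for the air-leg
#' objective, with any accumulated constant optimality cuts
#' `theta >= cut value` and no-good cuts on opening patterns.
#'
#' @inheritParams build_two_stage
#' @param cuts Numeric vector of constant optimality cut values.
#' @param nogood List of incumbent `U` matrices to exclude (used after an
#'   infeasible subproblem).
#' @return A [milp_model()].
#' @export
build_master <- function(inst, periods, unc = NULL, cuts = numeric(0),
                         nogood = list()) {
  I <- inst$areas; J <- inst$temp_hospitals
  nI <- length(I); nJ <- length(J)
  TT <- periods$n_periods; dt <- periods$period_length
  seats_road <- inst$fleet$vehicle_capacity * inst$fleet$vehicles
  if (is.null(unc)) {
    dev <- matrix(0, nI, 2, dimnames = dimnames(inst$casualties))
  } else {
    dev <- inflated_demand_matrix(inst, unc) - inst$casualties
    if (TT == 1L && any(dev > 0))
      stop("robust per-period caps need n_periods >= 2", call. = FALSE)
  }
  dem_floor <- inst$casualties + dev
  period_cap <- inst$casualties - dev

  o_x <- 0L; o_U <- o_x + nI * nJ * 2L * TT
  o_th <- o_U + nJ * TT
  nvar <- o_th + 1L
  ix <- function(i, j, s, t) o_x + (((t - 1L) * 2L + (s - 1L)) * nJ + (j - 1L)) * nI + i
  iU <- function(j, t) o_U + (t - 1L) * nJ + j

  nm <- character(nvar); obj <- numeric(nvar)
  for (t in 1:TT) {
    ot <- objective_terms(inst, period = t, dt = dt)
    for (s in 1:2) for (j in 1:nJ) for (i in 1:nI) {
      nm[ix(i, j, s, t)] <- sprintf("x_%s_%s_%s_t%d", I[i], J[j], SEVERITIES[s], t)
      obj[ix(i, j, s, t)] <- ot$road[i, j, s]
    }
    for (j in 1:nJ) nm[iU(j, t)] <- sprintf("U_%s_t%d", J[j], t)
  }
  nm[o_th + 1L] <- "theta"; obj[o_th + 1L] <- 1
  vtype <- c(rep("I", o_U), rep("B", nJ * TT), "C")
  lb <- numeric(nvar)
  ub <- c(rep(Inf, o_U), rep(1, nJ * TT), Inf)

  cs <- list()
  add <- function(ind, val, sense, rhs, name)
    cs[[length(cs) + 1L]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                                   sense = sense, rhs = rhs, name = name)
  xs_jt <- function(j, t) c(outer(1:nI, 1:2, function(i, s) ix(i, j, s, t)))
  for (j in 1:nJ) {
    for (t in 1:TT)
      add(c(xs_jt(j, t), iU(j, t)),
          c(rep(1, nI * 2), -inst$capacities$temp[[J[j]]]), "<=", 0,
          sprintf("gate_%s_t%d", J[j], t))
    ind <- unlist(lapply(1:TT, function(t) xs_jt(j, t)))
    add(ind, rep(1, length(ind)), "<=", inst$capacities$temp[[J[j]]],
        paste0("cum_cap_", J[j]))
  }
  for (t in 1:TT) {
    ind <- unlist(lapply(1:nJ, function(j) xs_jt(j, t)))
    if (t > 1) ind <- c(ind, unlist(lapply(1:nJ, function(j) xs_jt(j, t - 1L))))
    add(ind, rep(1, length(ind)), "<=", seats_road, sprintf("seats_road_t%d", t))
  }
  for (i in 1:nI) for (s in 1:2) {
    ind <- c(outer(1:nJ, 1:TT, function(j, t) ix(i, j, s, t)))
    add(ind, rep(1, length(ind)), if (is.null(unc)) "=" else ">=",
        dem_floor[i, s], sprintf("demand_%s_%s", I[i], SEVERITIES[s]))
    for (t in 1:TT)
      add(vapply(1:nJ, function(j) ix(i, j, s, t), 1L), rep(1, nJ), "<=",
          period_cap[i, s], sprintf("percap_%s_%s_t%d", I[i], SEVERITIES[s], t))
  }
  for (ci in seq_along(cuts))
    add(o_th + 1L, 1, ">=", cuts[ci], sprintf("cut_%d", ci))
  for (gi in seq_along(nogood)) {
    Ust <- nogood[[gi]]  # nJ x TT 0/1 matrix
    ind <- c(outer(1:nJ, 1:TT, iU))
    val <- ifelse(c(Ust) > 0.5, -1, 1)
    add(ind, val, ">=", 1 - sum(Ust), sprintf("nogood_%d", gi))
  }
  model <- milp_model(nm, lb, ub, vtype, obj, cs, "gbd_master")
  model$meta <- list(type = "gbd_master", n_periods = TT, dt = dt,
                     offsets = list(x = o_x, U = o_U, theta = o_th))
  model
}

#' Build the GBD subproblem
#'
#' Air-leg model with the road-side handover fixed: for each (temporary
#' hospital, severity, period) the outflow to general hospitals must equal
#' the fixed road inflow `x_totals[j, s, t]`.
#'
#' @param x_totals 3-d array (temporary hospitals x severities x periods)
#'   of fixed road-leg inflows.
#' @inheritParams build_two_stage
#' @return A [milp_model()].
#' @export
build_subproblem <- function(x_totals, inst, periods) {
  J <- inst$temp_hospitals; K <- inst$general_hospitals
  nJ <- length(J); nK <- length(K)
  TT <- periods$n_periods; dt <- periods$period_length
  seats_air <- inst$fleet$helicopter_capacity * inst$fleet$helicopters

  o_y <- 0L; o_V <- o_y + nJ * nK * 2L * TT
  nvar <- o_V + nK * TT
  iy <- function(j, k, s, t) o_y + (((t - 1L) * 2L + (s - 1L)) * nK + (k - 1L)) * nJ + j
  iV <- function(k, t) o_V + (t - 1L) * nK + k
  nm <- character(nvar); obj <- numeric(nvar)
  for (t in 1:TT) {
    ot <- objective_terms(inst, period = t, dt = dt)
    for (s in 1:2) for (k in 1:nK) for (j in 1:nJ) {
      nm[iy(j, k, s, t)] <- sprintf("y_%s_%s_%s_t%d", J[j], K[k], SEVERITIES[s], t)
      obj[iy(j, k, s, t)] <- ot$air[j, k, s]
    }
    for (k in 1:nK) nm[iV(k, t)] <- sprintf("V_%s_t%d", K[k], t)
  }
  vtype <- c(rep("I", o_V), rep("B", nK * TT))
  lb <- numeric(nvar); ub <- c(rep(Inf, o_V), rep(1, nK * TT))
  cs <- list()
  add <- function(ind, val, sense, rhs, name)
    cs[[length(cs) + 1L]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                                   sense = sense, rhs = rhs, name = name)
  for (k in 1:nK) for (s in 1:2) {
    for (t in 1:TT)
      add(c(vapply(1:nJ, function(j) iy(j, k, s, t), 1L), iV(k, t)),
          c(rep(1, nJ), -inst$capacities$general[K[k], SEVERITIES[s]]),
          "<=", 0, sprintf("gate_%s_%s_t%d", K[k], SEVERITIES[s], t))
    ind <- c(outer(1:nJ, 1:TT, function(j, t) iy(j, k, s, t)))
    add(ind, rep(1, length(ind)), "<=",
        inst$capacities$general[K[k], SEVERITIES[s]],
        sprintf("cum_cap_%s_%s", K[k], SEVERITIES[s]))
  }
  for (k in 1:nK) for (t in 1:TT) {
    ind <- c(outer(1:nJ, 1:2, function(j, s) iy(j, k, s, t)))
    add(c(ind, iV(k, t)), c(rep(1, length(ind)), -1), ">=", 0,
        sprintf("serve_%s_t%d", K[k], t))
  }
  for (t in 1:TT) {
    ind <- unlist(lapply(1:nJ, function(j)
      c(outer(1:nK, 1:2, function(k, s) iy(j, k, s, t)))))
    if (t > 1) ind <- c(ind, unlist(lapply(1:nJ, function(j)
      c(outer(1:nK, 1:2, function(k, s) iy(j, k, s, t - 1L))))))
    add(ind, rep(1, length(ind)), "<=", seats_air, sprintf("seats_air_t%d", t))
  }
  for (j in 1:nJ) for (s in 1:2) for (t in 1:TT)
    add(vapply(1:nK, function(k) iy(j, k, s, t), 1L), rep(1, nK), "=",
        x_totals[j, s, t], sprintf("handover_%s_%s_t%d", J[j], SEVERITIES[s], t))
  model <- milp_model(nm, lb, ub, vtype, obj, cs, "gbd_subproblem")
  model$meta <- list(type = "gbd_subproblem", n_periods = TT, dt = dt,
                     offsets = list(y = o_y, V = o_V))
  model
}

#' Solve the two-stage model by generalized Benders decomposition
#'
#' Iterates master and subproblem with constant optimality cuts until the
#' bound gap closes: solve the master (lower bound), fix its road-leg plan,
#' solve the air-leg subproblem (upper bound = road cost + air cost), add
#' `theta >= air cost` and repeat.  An infeasible subproblem triggers a
#' no-good cut on the master's opening pattern (with a warning).
#'
#' @inheritParams build_two_stage
#' @param epsilon Absolute convergence tolerance on `UB - LB`.
#' @param max_iter Iteration cap.
#' @param ... Passed to [solve_milp()].
#' @return List with `solution` (a `dynamic_solution` assembled from the
#'   incumbent) and `trace` (a `gbd_trace`).
#' @export
gbd_solve <- function(inst, periods = period_spec(), unc = NULL,
                      epsilon = 1e-6, max_iter = 50L, ...) {
  stopifnot(epsilon >= 0)
  I <- inst$areas; J <- inst$temp_hospitals
  nI <- length(I); nJ <- length(J)
  TT <- periods$n_periods
  LB <- -Inf; UB <- Inf
  cuts <- numeric(0); nogood <- list()
  best <- NULL
  rows <- list()
  for (k in seq_len(max_iter)) {
    mp <- build_master(inst, periods, unc, cuts = cuts, nogood = nogood)
    mraw <- solve_milp(mp, ...)
    if (mraw$status != "optimal")
      stop("master problem not solved to optimality (status ",
           mraw$status, ")", call. = FALSE)
    LB <- mraw$objective
    off <- mp$meta$offsets
    xv <- array(mraw$values[(off$x + 1L):(off$x + nI * nJ * 2L * TT)],
                c(nI, nJ, 2, TT),
                dimnames = list(I, J, SEVERITIES, NULL))
    theta_val <- mraw$values[[off$theta + 1L]]
    F1x <- LB - theta_val
    x_totals <- apply(xv, c(2, 3, 4), sum)
    sp <- build_subproblem(x_totals, inst, periods)
    sraw <- solve_milp(sp, ...)
    if (sraw$status != "optimal") {
      warning("subproblem infeasible at iteration ", k,
              "; adding a no-good cut on the opening pattern")
      Ucur <- matrix(mraw$values[(off$U + 1L):(off$U + nJ * TT)], nJ, TT)
      nogood <- c(nogood, list(round(Ucur)))
      rows[[k]] <- data.frame(k = k, LB = LB, UB = UB, theta = theta_val,
                              SP_objective = NA_real_, cut_added = "nogood")
      next
    }
    F2y <- sraw$objective
    cand <- F1x + F2y
    if (cand < UB - 1e-12) {
      UB <- cand
      best <- list(xv = xv, sraw = sraw, sp = sp)
    }
    converged <- (UB - LB) <= epsilon
    rows[[k]] <- data.frame(k = k, LB = LB, UB = UB, theta = theta_val,
                            SP_objective = F2y,
                            cut_added = if (converged) "none" else "optimality")
    if (converged) break
    cuts <- c(cuts, F2y)
  }
  trace <- structure(list(
    iterations = do.call(rbind, rows),
    epsilon = epsilon,
    converged = is.finite(UB) && (UB - LB) <= epsilon,
    final_gap = UB - LB), class = "gbd_trace")
  solution <- if (!is.null(best))
    assemble_dynamic_solution(inst, periods, best$xv, best$sraw, best$sp)
  else NULL
  list(solution = solution, trace = trace)
}

assemble_dynamic_solution <- function(inst, periods, xv, sraw, sp) {
  J <- inst$temp_hospitals; K <- inst$general_hospitals
  nJ <- length(J); nK <- length(K)
  TT <- periods$n_periods; dt <- periods$period_length
  off <- sp$meta$offsets
  yv <- array(sraw$values[(off$y + 1L):(off$y + nJ * nK * 2L * TT)],
              c(nJ, nK, 2, TT),
              dimnames = list(J, K, SEVERITIES, paste0("t", 1:TT)))
  V <- matrix(sraw$values[(off$V + 1L):(off$V + nK * TT)], nK, TT)
  F1 <- 0; F2 <- 0
  for (t in 1:TT) {
    ot <- objective_terms(inst, period = t, dt = dt)
    F1 <- F1 + sum(ot$road * xv[, , , t])
    F2 <- F2 + sum(ot$air * yv[, , , t])
  }
  eg <- inst$fleet$vehicle_capacity; eh <- inst$fleet$helicopter_capacity
  road_use <- vapply(1:TT, function(t) sum(xv[, , , t]), 1)
  air_use <- vapply(1:TT, function(t) sum(yv[, , , t]), 1)
  dimnames(xv)[[4]] <- paste0("t", 1:TT)
  structure(list(
    temp_open = lapply(1:TT, function(t) {
      intake <- apply(xv[, , , t, drop = FALSE], 2, sum)
      J[intake > 0]
    }),
    general_open = lapply(1:TT, function(t) K[V[, t] > 0.5]),
    flows_road = xv, flows_air = yv,
    seat_usage = list(road = road_use, air = air_use),
    fleet_avail = list(
      vehicles = fleet_availability(eg * inst$fleet$vehicles, road_use) / eg,
      helicopters = fleet_availability(eh * inst$fleet$helicopters, air_use) / eh),
    F1 = F1, F2 = F2, objective = F1 + F2,
    solver_status = "optimal"), class = "dynamic_solution")
}

#' @export
print.gbd_trace <- function(x, ...) {
  cat(sprintf("GBD trace: %d iteration(s), converged = %s, final gap = %g\n",
              nrow(x$iterations), x$converged, x$final_gap))
  print(x$iterations, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.gbd_trace <- function(x, ...) x$iterations

#' Write a GBD trace to disk
#'
#' @param trace A `gbd_trace`.
#' @param path Output file.
#' @param format `"csv"` (one row per iteration) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(trace$iterations, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(iterations = trace$iterations, epsilon = trace$epsilon,
           converged = trace$converged, final_gap = trace$final_gap),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read back a GBD trace written by [write_trace()]
#'
#' @param path JSON trace file.
#' @return A `gbd_trace`.
#' @export
read_trace <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(iterations = as.data.frame(doc$iterations),
                 epsilon = doc$epsilon, converged = doc$converged,
                 final_gap = doc$final_gap), class = "gbd_trace")
}
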