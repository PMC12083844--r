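# Deterministic single-period location-allocation model.  Two interchangeable
# formulations:
#  * "aggregated" (default): identical vehicles on an arc are represented by
#    an integer arc count n_ij (m_jk for helicopters).  Objective-equivalent
#    to the per-vehicle model because vehicles are interchangeable and the
#    objective is linear in flows.
#  * "per_vehicle": one binary per (arc, vehicle) exactly as the model is
#    stated; kept for fidelity checks at small fleet sizes, where its index
#    symmetry is still tractable.

#' Vehicles needed to carry a flow
#'
#' Closed form of the load-limit plus non-emptiness constraints at
#' optimality: `ceiling(flow / capacity)`, 0 for zero flow.
#'
#' @param arc_flow Non-negative casualty count on an arc.
#' @param capacity Per-vehicle carrying capacity (`>= 1`).
#' @return Integer vehicle count (vectorised).
#' @export
vehicles_required <- function(arc_flow, capacity) {
  stopifnot(all(capacity >= 1))
  as.integer(ceiling(arc_flow / capacity))
}

#' Build the deterministic MILP
#'
#' Encodes the full single-period model: weighted-deterioration objective,
#' severity-pooled temporary capacities, per-severity general capacities,
#' fleet totals, per-vehicle load limits, non-empty-vehicle rules,
#' dispatch-only-from-open and at-least-one-dispatch-per-open hospital
#' rules, demand satisfaction, and road/air flow conservation at each
#' temporary hospital.
#'
#' @param inst An [evac_instance()]; must validate without errors.
#' @param demand_rhs Optional matrix (areas x severities) replacing the
#'   nominal casualty counts on the demand constraints (used by the robust
#'   counterpart).
#' @param formulation `"aggregated"` or `"per_vehicle"`.
#' @param demand_sense `"eq"` (deterministic, as stated) or `"ge"` (robust
#'   counterpart form).
#' @return A [milp_model()] carrying extraction metadata.
#' @export
build_static <- function(inst, demand_rhs = NULL,
                         formulation = c("aggregated", "per_vehicle"),
                         demand_sense = c("eq", "ge")) {
  formulation <- match.arg(formulation)
  demand_sense <- match.arg(demand_sense)
  rep <- validate_instance(inst)
  if (length(rep$errors))
    stop("instance fails validation:\n", format_report_items(rep$errors),
         call. = FALSE)
  if (is.null(demand_rhs)) demand_rhs <- inst$casualties
  demand_rhs <- demand_rhs[inst$areas, SEVERITIES, drop = FALSE]
  if (formulation == "aggregated")
    build_static_aggregated(inst, demand_rhs, demand_sense)
  else
    build_static_per_vehicle(inst, demand_rhs, demand_sense)
}

build_static_aggregated <- function(inst, demand_rhs, demand_sense) {
  I <- inst$areas; J <- inst$temp_hospitals; K <- inst$general_hospitals
  nI <- length(I); nJ <- length(J); nK <- length(K); nS <- 2L
  gam <- inst$fleet$vehicles; lam <- inst$fleet$helicopters
  eg <- inst$fleet$vehicle_capacity; eh <- inst$fleet$helicopter_capacity

  # variable blocks: x[i,j,s] | y[j,k,s] | n[i,j] | m[j,k] | U[j] | V[k]
  o_x <- 0L; o_y <- o_x + nI * nJ * nS; o_n <- o_y + nJ * nK * nS
  o_m <- o_n + nI * nJ; o_U <- o_m + nJ * nK; o_V <- o_U + nJ
  nvar <- o_V + nK
  ix <- function(i, j, s) o_x + ((s - 1L) * nJ + (j - 1L)) * nI + i
  iy <- function(j, k, s) o_y + ((s - 1L) * nK + (k - 1L)) * nJ + j
  im_n <- function(i, j) o_n + (j - 1L) * nI + i
  im_m <- function(j, k) o_m + (k - 1L) * nJ + j
  iU <- function(j) o_U + j
  iV <- function(k) o_V + k

  nm <- character(nvar)
  obj <- numeric(nvar)
  ot <- objective_terms(inst)
  for (s in 1:2) for (j in 1:nJ) for (i in 1:nI) {
    nm[ix(i, j, s)] <- paste("x", I[i], J[j], SEVERITIES[s], sep = "_")
    obj[ix(i, j, s)] <- ot$road[i, j, s]
  }
  for (s in 1:2) for (k in 1:nK) for (j in 1:nJ) {
    nm[iy(j, k, s)] <- paste("y", J[j], K[k], SEVERITIES[s], sep = "_")
    obj[iy(j, k, s)] <- ot$air[j, k, s]
  }
  for (j in 1:nJ) for (i in 1:nI) nm[im_n(i, j)] <- paste("n", I[i], J[j], sep = "_")
  for (k in 1:nK) for (j in 1:nJ) nm[im_m(j, k)] <- paste("m", J[j], K[k], sep = "_")
  for (j in 1:nJ) nm[iU(j)] <- paste0("U_", J[j])
  for (k in 1:nK) nm[iV(k)] <- paste0("V_", K[k])

  vtype <- rep("I", nvar); vtype[(o_U + 1L):nvar] <- "B"
  lb <- numeric(nvar); ub <- rep(Inf, nvar); ub[(o_U + 1L):nvar] <- 1

  cs <- list()
  add <- function(ind, val, sense, rhs, name)
    cs[[length(cs) + 1L]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                                   sense = sense, rhs = rhs, name = name)
  # temporary-hospital pooled capacity
  for (j in 1:nJ)
    add(c(outer(1:nI, 1:2, function(i, s) ix(i, j, s))), rep(1, nI * 2),
        "<=", inst$capacities$temp[[J[j]]], paste0("cap_temp_", J[j]))
  # general-hospital per-severity capacity
  for (k in 1:nK) for (s in 1:2)
    add(vapply(1:nJ, function(j) iy(j, k, s), 1L), rep(1, nJ),
        "<=", inst$capacities$general[K[k], SEVERITIES[s]],
        paste0("cap_gen_", K[k], "_", SEVERITIES[s]))
  # fleet totals
  add((o_n + 1L):(o_n + nI * nJ), rep(1, nI * nJ), "<=", gam, "fleet_vehicles")
  add((o_m + 1L):(o_m + nJ * nK), rep(1, nJ * nK), "<=", lam, "fleet_helicopters")
  # arc load limit, non-emptiness, dispatch-from-open (road)
  for (j in 1:nJ) for (i in 1:nI) {
    xij <- c(ix(i, j, 1), ix(i, j, 2))
    add(c(xij, im_n(i, j)), c(1, 1, -eg), "<=", 0,
        paste0("load_", I[i], "_", J[j]))
    add(c(im_n(i, j), xij), c(1, -1, -1), "<=", 0,
        paste0("nonempty_", I[i], "_", J[j]))
    add(c(im_n(i, j), iU(j)), c(1, -gam), "<=", 0,
        paste0("open_", I[i], "_", J[j]))
  }
  # same for air arcs
  for (k in 1:nK) for (j in 1:nJ) {
    yjk <- c(iy(j, k, 1), iy(j, k, 2))
    add(c(yjk, im_m(j, k)), c(1, 1, -eh), "<=", 0,
        paste0("load_", J[j], "_", K[k]))
    add(c(im_m(j, k), yjk), c(1, -1, -1), "<=", 0,
        paste0("nonempty_", J[j], "_", K[k]))
    add(c(im_m(j, k), iV(k)), c(1, -lam), "<=", 0,
        paste0("open_", J[j], "_", K[k]))
  }
  # at least one tool serves every opened hospital
  for (j in 1:nJ)
    add(c(vapply(1:nI, function(i) im_n(i, j), 1L), iU(j)),
        c(rep(1, nI), -1), ">=", 0, paste0("serve_", J[j]))
  for (k in 1:nK)
    add(c(vapply(1:nJ, function(j) im_m(j, k), 1L), iV(k)),
        c(rep(1, nJ), -1), ">=", 0, paste0("serve_", K[k]))
  # demand satisfaction
  sense <- if (demand_sense == "eq") "=" else ">="
  for (i in 1:nI) for (s in 1:2)
    add(vapply(1:nJ, function(j) ix(i, j, s), 1L), rep(1, nJ),
        sense, demand_rhs[i, s], paste0("demand_", I[i], "_", SEVERITIES[s]))
  # flow conservation at temporary hospitals
  for (j in 1:nJ) for (s in 1:2)
    add(c(vapply(1:nI, function(i) ix(i, j, s), 1L),
          vapply(1:nK, function(k) iy(j, k, s), 1L)),
        c(rep(1, nI), rep(-1, nK)), "=", 0,
        paste0("conserve_", J[j], "_", SEVERITIES[s]))

  model <- milp_model(nm, lb, ub, vtype, obj, cs, "aggregated")
  model$meta <- list(type = "static", formulation = "aggregated",
                     inst_dims = c(nI, nJ, nK),
                     offsets = list(x = o_x, y = o_y, n = o_n, m = o_m,
                                    U = o_U, V = o_V),
                     demand_rhs = demand_rhs, demand_sense = demand_sense)
  model
}

build_static_per_vehicle <- function(inst, demand_rhs, demand_sense) {
  I <- inst$areas; J <- inst$temp_hospitals; K <- inst$general_hospitals
  nI <- length(I); nJ <- length(J); nK <- length(K)
  gam <- inst$fleet$vehicles; lam <- inst$fleet$helicopters
  eg <- inst$fleet$vehicle_capacity; eh <- inst$fleet$helicopter_capacity

  # blocks: X[i,j,g] | x[i,j,g,s] | Y[j,k,h] | y[j,k,h,s] | U[j] | V[k]
  o_X <- 0L; o_x <- o_X + nI * nJ * gam
  o_Y <- o_x + nI * nJ * gam * 2L
  o_y <- o_Y + nJ * nK * lam
  o_U <- o_y + nJ * nK * lam * 2L; o_V <- o_U + nJ
  nvar <- o_V + nK
  iX <- function(i, j, g) o_X + ((g - 1L) * nJ + (j - 1L)) * nI + i
  ixf <- function(i, j, g, s) o_x + (((s - 1L) * gam + (g - 1L)) * nJ + (j - 1L)) * nI + i
  iY <- function(j, k, h) o_Y + ((h - 1L) * nK + (k - 1L)) * nJ + j
  iyf <- function(j, k, h, s) o_y + (((s - 1L) * lam + (h - 1L)) * nK + (k - 1L)) * nJ + j
  iU <- function(j) o_U + j
  iV <- function(k) o_V + k

  nm <- character(nvar); obj <- numeric(nvar)
  ot <- objective_terms(inst)
  for (g in 1:gam) for (j in 1:nJ) for (i in 1:nI)
    nm[iX(i, j, g)] <- sprintf("X_%s_%s_g%d", I[i], J[j], g)
  for (s in 1:2) for (g in 1:gam) for (j in 1:nJ) for (i in 1:nI) {
    nm[ixf(i, j, g, s)] <- sprintf("x_%s_%s_g%d_%s", I[i], J[j], g, SEVERITIES[s])
    obj[ixf(i, j, g, s)] <- ot$road[i, j, s]
  }
  for (h in 1:lam) for (k in 1:nK) for (j in 1:nJ)
    nm[iY(j, k, h)] <- sprintf("Y_%s_%s_h%d", J[j], K[k], h)
  for (s in 1:2) for (h in 1:lam) for (k in 1:nK) for (j in 1:nJ) {
    nm[iyf(j, k, h, s)] <- sprintf("y_%s_%s_h%d_%s", J[j], K[k], h, SEVERITIES[s])
    obj[iyf(j, k, h, s)] <- ot$air[j, k, s]
  }
  for (j in 1:nJ) nm[iU(j)] <- paste0("U_", J[j])
  for (k in 1:nK) nm[iV(k)] <- paste0("V_", K[k])

  vtype <- rep("I", nvar)
  vtype[(o_X + 1L):o_x] <- "B"
  vtype[(o_Y + 1L):o_y] <- "B"
  vtype[(o_U + 1L):nvar] <- "B"
  lb <- numeric(nvar); ub <- rep(Inf, nvar)
  ub[vtype == "B"] <- 1

  cs <- list()
  add <- function(ind, val, sense, rhs, name)
    cs[[length(cs) + 1L]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                                   sense = sense, rhs = rhs, name = name)
  for (j in 1:nJ) {
    ind <- c(outer(1:nI, 1:(gam * 2), function(i, gs)
      ixf(i, j, (gs - 1L) %% gam + 1L, (gs - 1L) %/% gam + 1L)))
    add(ind, rep(1, length(ind)), "<=", inst$capacities$temp[[J[j]]],
        paste0("cap_temp_", J[j]))
  }
  for (k in 1:nK) for (s in 1:2) {
    ind <- c(outer(1:nJ, 1:lam, function(j, h) iyf(j, k, h, s)))
    add(ind, rep(1, length(ind)), "<=",
        inst$capacities$general[K[k], SEVERITIES[s]],
        paste0("cap_gen_", K[k], "_", SEVERITIES[s]))
  }
  add((o_X + 1L):o_x, rep(1, nI * nJ * gam), "<=", gam, "fleet_vehicles")
  add((o_Y + 1L):o_y, rep(1, nJ * nK * lam), "<=", lam, "fleet_helicopters")
  for (g in 1:gam) {
    for (j in 1:nJ) for (i in 1:nI) {
      xs <- c(ixf(i, j, g, 1), ixf(i, j, g, 2))
      add(c(xs, iX(i, j, g)), c(1, 1, -eg), "<=", 0,
          sprintf("load_%s_%s_g%d", I[i], J[j], g))
      add(c(iX(i, j, g), xs), c(1, -1, -1), "<=", 0,
          sprintf("nonempty_%s_%s_g%d", I[i], J[j], g))
    }
    ind <- c(outer(1:nI, 1:nJ, function(i, j) iX(i, j, g)))
    add(ind, rep(1, length(ind)), "<=", 1, sprintf("onearc_g%d", g))
  }
  for (h in 1:lam) {
    for (k in 1:nK) for (j in 1:nJ) {
      ys <- c(iyf(j, k, h, 1), iyf(j, k, h, 2))
      add(c(ys, iY(j, k, h)), c(1, 1, -eh), "<=", 0,
          sprintf("load_%s_%s_h%d", J[j], K[k], h))
      add(c(iY(j, k, h), ys), c(1, -1, -1), "<=", 0,
          sprintf("nonempty_%s_%s_h%d", J[j], K[k], h))
    }
    ind <- c(outer(1:nJ, 1:nK, function(j, k) iY(j, k, h)))
    add(ind, rep(1, length(ind)), "<=", 1, sprintf("onearc_h%d", h))
  }
  # dispatch only from opened hospitals, per tool
  for (j in 1:nJ) for (g in 1:gam)
    add(c(vapply(1:nI, function(i) iX(i, j, g), 1L), iU(j)),
        c(rep(1, nI), -1), "<=", 0, sprintf("open_%s_g%d", J[j], g))
  for (k in 1:nK) for (h in 1:lam)
    add(c(vapply(1:nJ, function(j) iY(j, k, h), 1L), iV(k)),
        c(rep(1, nJ), -1), "<=", 0, sprintf("open_%s_h%d", K[k], h))
  # opened hospitals are served by at least one tool
  for (j in 1:nJ) {
    ind <- c(outer(1:nI, 1:gam, function(i, g) iX(i, j, g)))
    add(c(ind, iU(j)), c(rep(1, length(ind)), -1), ">=", 0,
        paste0("serve_", J[j]))
  }
  for (k in 1:nK) {
    ind <- c(outer(1:nJ, 1:lam, function(j, h) iY(j, k, h)))
    add(c(ind, iV(k)), c(rep(1, length(ind)), -1), ">=", 0,
        paste0("serve_", K[k]))
  }
  sense <- if (demand_sense == "eq") "=" else ">="
  for (i in 1:nI) for (s in 1:2) {
    ind <- c(outer(1:nJ, 1:gam, function(j, g) ixf(i, j, g, s)))
    add(ind, rep(1, length(ind)), sense, demand_rhs[i, s],
        paste0("demand_", I[i], "_", SEVERITIES[s]))
  }
  for (j in 1:nJ) for (s in 1:2) {
    indx <- c(outer(1:nI, 1:gam, function(i, g) ixf(i, j, g, s)))
    indy <- c(outer(1:nK, 1:lam, function(k, h) iyf(j, k, h, s)))
    add(c(indx, indy), c(rep(1, length(indx)), rep(-1, length(indy))),
        "=", 0, paste0("conserve_", J[j], "_", SEVERITIES[s]))
  }

  model <- milp_model(nm, lb, ub, vtype, obj, cs, "per_vehicle")
  model$meta <- list(type = "static", formulation = "per_vehicle",
                     inst_dims = c(nI, nJ, nK), fleet = c(gam, lam),
                     offsets = list(X = o_X, x = o_x, Y = o_Y, y = o_y,
                                    U = o_U, V = o_V),
                     demand_rhs = demand_rhs, demand_sense = demand_sense)
  model
}

#' Extract a structured solution from a solved static model
#'
#' Aggregates per-vehicle variables where necessary, recomputes the F1/F2
#' objective split from the flows and the instance's objective coefficients,
#' and cross-checks the recomputation against the solver's objective value.
#'
#' @param raw Result of [solve_milp()] with status `"optimal"`.
#' @param inst The instance the model was built from.
#' @param model The built model (carries extraction metadata).
#' @return An object of class `static_solution`: opened hospital sets,
#'   road/air flow arrays, vehicle/helicopter counts per arc, `F1`, `F2`,
#'   `objective`, `solver_status`.
#' @export
extract_static_solution <- function(raw, inst, model) {
  if (raw$status != "optimal")
    stop("cannot extract a solution from status '", raw$status, "'",
         call. = FALSE)
  I <- inst$areas; J <- inst$temp_hospitals; K <- inst$general_hospitals
  nI <- length(I); nJ <- length(J); nK <- length(K)
  v <- raw$values
  off <- model$meta$offsets
  flows_road <- array(0, c(nI, nJ, 2), dimnames = list(I, J, SEVERITIES))
  flows_air <- array(0, c(nJ, nK, 2), dimnames = list(J, K, SEVERITIES))
  if (model$meta$formulation == "aggregated") {
    flows_road[] <- v[(off$x + 1L):(off$x + nI * nJ * 2L)]
    flows_air[] <- v[(off$y + 1L):(off$y + nJ * nK * 2L)]
    vehicles <- matrix(v[(off$n + 1L):(off$n + nI * nJ)], nI, nJ,
                       dimnames = list(I, J))
    helis <- matrix(v[(off$m + 1L):(off$m + nJ * nK)], nJ, nK,
                    dimnames = list(J, K))
  } else {
    gam <- model$meta$fleet[1]; lam <- model$meta$fleet[2]
    xf <- array(v[(off$x + 1L):(off$x + nI * nJ * gam * 2L)],
                c(nI, nJ, gam, 2))
    yf <- array(v[(off$y + 1L):(off$y + nJ * nK * lam * 2L)],
                c(nJ, nK, lam, 2))
    flows_road[] <- apply(xf, c(1, 2, 4), sum)
    flows_air[] <- apply(yf, c(1, 2, 4), sum)
    Xb <- array(v[(off$X + 1L):(off$X + nI * nJ * gam)], c(nI, nJ, gam))
    Yb <- array(v[(off$Y + 1L):(off$Y + nJ * nK * lam)], c(nJ, nK, lam))
    vehicles <- apply(Xb, c(1, 2), sum); dimnames(vehicles) <- list(I, J)
    helis <- apply(Yb, c(1, 2), sum); dimnames(helis) <- list(J, K)
  }
  temp_open <- J[v[off$U + 1:nJ] > 0.5]
  general_open <- K[v[off$V + 1:nK] > 0.5]
  ot <- objective_terms(inst)
  F1 <- sum(ot$road * flows_road)
  F2 <- sum(ot$air * flows_air)
  if (abs(F1 + F2 - raw$objective) > 1e-4)
    stop(sprintf("internal consistency error: recomputed F1+F2 = %.6f but solver objective = %.6f",
                 F1 + F2, raw$objective), call. = FALSE)
  structure(list(temp_open = temp_open, general_open = general_open,
                 flows_road = flows_road, flows_air = flows_air,
                 vehicles_used = vehicles, helicopters_used = helis,
                 F1 = F1, F2 = F2, objective = F1 + F2,
                 solver_status = raw$status),
            class = "static_solution")
}

#' @export
print.static_solution <- function(x, ...) {
  cat("static evacuation plan\n")
  cat(sprintf("  objective %.4f = F1 %.4f (road) + F2 %.4f (air)\n",
              x$objective, x$F1, x$F2))
  cat("  temporary hospitals opened:", paste(x$temp_open, collapse = ", "), "\n")
  cat("  general hospitals opened:  ", paste(x$general_open, collapse = ", "), "\n")
  cat(sprintf("  vehicles used: %d, helicopters used: %d\n",
              sum(x$vehicles_used), sum(x$helicopters_used)))
  invisible(x)
}

#' Build, solve, and extract the deterministic plan
#'
#' @inheritParams build_static
#' @param ... Passed to [solve_milp()] (backend, gap, time limit).
#' @return A `static_solution`, or a list with `solver_status` when the
#'   model is not solved to optimality.
#' @export
solve_static <- function(inst, demand_rhs = NULL,
                         formulation = c("aggregated", "per_vehicle"),
                         demand_sense = c("eq", "ge"), ...) {
  model <- build_static(inst, demand_rhs, match.arg(formulation),
                        match.arg(demand_sense))
  raw <- solve_milp(model, ...)
  if (raw$status != "optimal")
    return(structure(list(solver_status = raw$status, objective = NA_real_),
                     class = "static_solution"))
  extract_static_solution(raw, inst, model)
}
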