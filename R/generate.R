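# Seeded generator of synthetic instances with the structural properties the
# models assume: complete travel-time matrices at millihour precision,
# integer casualty counts, and capacity/fleet policies sized from the drawn
# totals so the nominal instance is feasible with slack.

#' Generator parameters
#'
#' Defaults mirror the embedded case study: serious counts 5--70 and
#' moderate counts 23--153 per area, road legs 0.4--2.5 h, air legs
#' 0.55--0.75 h.  The capacity policy gives every temporary hospital
#' `ceiling(slack * total / n_temp)` pooled places and every general
#' hospital `ceiling(slack * total_s / n_general)` per-severity places; the
#' fleet policy sizes each fleet to `slack` times the seats needed plus one
#' tool per arc-side to absorb ceiling losses on split flows.
#'
#' @param n_areas,n_temp,n_general Index-set sizes (`>= 1`).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param casualty_range List with integer ranges `serious` and `moderate`.
#' @param road_time_range,air_time_range Hour intervals for uniform draws.
#' @param capacity_slack,fleet_slack Multipliers (`>= 1`) applied by the
#'   capacity and fleet policies.
#' @param vehicle_capacity,helicopter_capacity Per-tool seat counts.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_areas, n_temp, n_general, seed = 1L,
                             casualty_range = list(serious = c(5L, 70L),
                                                   moderate = c(23L, 153L)),
                             road_time_range = c(0.4, 2.5),
                             air_time_range = c(0.55, 0.75),
                             capacity_slack = 1.2, fleet_slack = 1.2,
                             vehicle_capacity = 6L, helicopter_capacity = 12L) {
  stopifnot(n_areas >= 1, n_temp >= 1, n_general >= 1,
            all(road_time_range > 0), all(air_time_range > 0),
            capacity_slack >= 1, fleet_slack >= 1)
  structure(list(n_areas = as.integer(n_areas), n_temp = as.integer(n_temp),
                 n_general = as.integer(n_general), seed = as.integer(seed),
                 casualty_range = casualty_range,
                 road_time_range = road_time_range,
                 air_time_range = air_time_range,
                 capacity_slack = capacity_slack, fleet_slack = fleet_slack,
                 vehicle_capacity = as.integer(vehicle_capacity),
                 helicopter_capacity = as.integer(helicopter_capacity)),
            class = "generator_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic instance
#'
#' @param params A [generator_params()].
#' @return An [evac_instance()] that passes validation with no errors and is
#'   feasible at nominal demand by construction of the policies.
#' @export
generate_instance <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, {
    nI <- params$n_areas; nJ <- params$n_temp; nK <- params$n_general
    areas <- paste0("I", 1:nI); temps <- paste0("J", 1:nJ)
    gens <- paste0("K", 1:nK)
    rint <- function(n, r) sample(seq.int(r[1], r[2]), n, replace = TRUE)
    casualties <- cbind(
      serious = rint(nI, params$casualty_range$serious),
      moderate = rint(nI, params$casualty_range$moderate))
    rownames(casualties) <- areas
    road <- matrix(round(stats::runif(nI * nJ, params$road_time_range[1],
                                      params$road_time_range[2]), 3),
                   nI, nJ, dimnames = list(areas, temps))
    air <- matrix(round(stats::runif(nJ * nK, params$air_time_range[1],
                                     params$air_time_range[2]), 3),
                  nJ, nK, dimnames = list(temps, gens))
    total <- sum(casualties)
    C <- ceiling(params$capacity_slack * total / nJ)
    Q <- sapply(SEVERITIES, function(s)
      rep(ceiling(params$capacity_slack * sum(casualties[, s]) / nK), nK))
    rownames(Q) <- gens
    eg <- params$vehicle_capacity; eh <- params$helicopter_capacity
    gam <- ceiling(params$fleet_slack * total / eg) + nI * nJ
    lam <- ceiling(params$fleet_slack * total / eh) + nJ * nK
    evac_instance(areas, temps, gens, casualties, road, air,
                  fleet = fleet_spec(gam, lam, eg, eh),
                  temp_capacity = C, general_capacity = Q)
  })
}

#' Draw one realization of the uncertain casualty counts
#'
#' Each realized count is drawn independently and uniformly from the integer
#' interval `[q - round(q_hat), q + round(q_hat)]` with
#' `q_hat = variability * q` (rounded under the spec's rule), the full
#' uncertainty interval the robust model protects against.
#'
#' @param inst An [evac_instance()].
#' @param unc An [uncertainty_spec()] (its `variability` and `rounding` are
#'   used; realizations span the whole interval regardless of the budget).
#' @param seed Integer seed.
#' @return Matrix (areas x severities) of realized integer counts.
#' @export
perturb_realization <- function(inst, unc, seed) {
  with_seed(seed, {
    q <- inst$casualties
    qhat <- round_rule(unc$variability * q, unc$rounding)
    lo <- pmax(q - qhat, 0)
    hi <- q + qhat
    out <- q
    out[] <- lo + vapply(c(hi - lo) + 1L, function(w)
      sample.int(w, 1L) - 1L, 1L)
    out
  })
}
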