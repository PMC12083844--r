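test_that("vehicles_required is ceiling division with a zero case", {
  expect_identical(vehicles_required(202, 6), 34L)
  expect_identical(vehicles_required(0, 6), 0L)
  expect_identical(vehicles_required(6, 6), 1L)
  expect_identical(vehicles_required(c(7, 12, 1), 6), c(2L, 2L, 1L))
  expect_error(vehicles_required(5, 0))
})

test_that("the nominal case-study plan satisfies every structural invariant", {
  inst <- lushan_instance()
  sol <- expect_optimal(lushan_nominal_solution())
  # objective split is an identity
  expect_equal(sol$F1 + sol$F2, sol$objective)
  # demand: every (area, severity) fully served
  expect_equal(apply(sol$flows_road, c(1, 3), sum), inst$casualties,
               ignore_attr = TRUE)
  # conservation at each (temporary hospital, severity)
  expect_equal(apply(sol$flows_road, c(2, 3), sum),
               apply(sol$flows_air, c(1, 3), sum))
  # capacities
  intake <- apply(sol$flows_road, 2, sum)
  expect_true(all(intake <= inst$capacities$temp + 1e-9))
  expect_true(all(apply(sol$flows_air, c(2, 3), sum) <=
                    inst$capacities$general + 1e-9))
  # nothing routed through a closed hospital
  closed_t <- setdiff(inst$temp_hospitals, sol$temp_open)
  expect_true(all(sol$flows_road[, closed_t, ] == 0))
  closed_g <- setdiff(inst$general_hospitals, sol$general_open)
  expect_true(all(sol$flows_air[, closed_g, ] == 0))
  # tool counts respect load limits and the fleet
  expect_true(all(apply(sol$flows_road, c(1, 2), sum) <=
                    6 * sol$vehicles_used))
  expect_lte(sum(sol$vehicles_used), inst$fleet$vehicles)
  expect_lte(sum(sol$helicopters_used), inst$fleet$helicopters)
  # at optimality arc tool counts are exactly the ceiling of the arc load
  expect_equal(sol$vehicles_used,
               matrix(vehicles_required(apply(sol$flows_road, c(1, 2), sum), 6),
                      nrow(sol$vehicles_used), dimnames = dimnames(sol$vehicles_used)))
})

test_that("aggregated and per-vehicle formulations have equal optima", {
  for (seed in 1:6) {
    inst <- small_random_instance(seed)
    agg <- solve_static(inst, formulation = "aggregated")
    pv <- solve_static(inst, formulation = "per_vehicle")
    expect_optimal(agg); expect_optimal(pv)
    expect_equal(pv$objective, agg$objective, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("zero demand yields an empty zero-cost plan", {
  inst <- tiny_instance()
  zero <- matrix(0, 2, 2, dimnames = dimnames(inst$casualties))
  sol <- solve_static(inst, demand_rhs = zero)
  expect_optimal(sol)
  expect_equal(sol$objective, 0)
  expect_true(all(sol$flows_road == 0) && all(sol$flows_air == 0))
  expect_length(sol$temp_open, 0)
  expect_length(sol$general_open, 0)
})

test_that("a fleet too small for the demand makes the model infeasible", {
  inst <- single_chain_instance(qs = 30, qm = 30)
  inst$fleet <- fleet_spec(5, 10, 6, 12)  # 30 road seats < 60 casualties
  sol <- solve_static(inst)
  expect_identical(sol$solver_status, "infeasible")
})

test_that("extraction cross-checks the recomputed objective", {
  inst <- tiny_instance()
  model <- build_static(inst)
  raw <- solve_milp(model)
  tampered <- raw
  tampered$objective <- raw$objective + 1
  expect_error(extract_static_solution(tampered, inst, model),
               "consistency")
  expect_error(extract_static_solution(list(status = "infeasible"), inst,
                                       model), "status")
})
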