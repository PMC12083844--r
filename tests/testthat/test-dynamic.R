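test_that("fleet availability follows the one-period-return recursion", {
  expect_equal(fleet_availability(150, c(40, 30)), c(150, 110, 120))
  expect_equal(fleet_availability(150, c(0, 0, 0)), c(150, 150, 150, 150))
  expect_error(fleet_availability(150, c(150, 150)), "period 2")
  # tools used in period t are all back by period t + 2
  expect_equal(fleet_availability(10, c(10, 0, 5))[4], 5)
})

test_that("one period with no uncertainty reduces to the static model", {
  for (inst in list(tiny_instance(), small_random_instance(21))) {
    st <- solve_static(inst)
    dy <- solve_dynamic(inst, period_spec(1, 1))
    expect_optimal(st); expect_optimal(dy)
    expect_equal(dy$objective, st$objective, tolerance = 1e-6)
    expect_equal(dy$F1, st$F1, tolerance = 1e-4)
  }
})

test_that("multi-period plans conserve flow and respect cumulative caps", {
  inst <- lushan_instance()
  # shrink the road fleet so one period cannot carry everything; tools used
  # in period t only return in period t + 2, so three periods are needed
  inst$fleet <- fleet_spec(100L, 150L, 6L, 12L)  # 600 seats < 985
  sol <- solve_dynamic(inst, period_spec(3, 1))
  expect_optimal(sol)
  for (t in 1:3)
    expect_equal(apply(sol$flows_road[, , , t], c(2, 3), sum),
                 apply(sol$flows_air[, , , t], c(1, 3), sum),
                 info = paste("period", t))
  expect_true(all(apply(sol$flows_road, 2, sum) <=
                    inst$capacities$temp + 1e-9))
  expect_true(all(apply(sol$flows_air, c(2, 3), sum) <=
                    inst$capacities$general + 1e-9))
  # the forced split saturates period 1, idles period 2 while the vehicles
  # return, and finishes in period 3
  expect_equal(sum(sol$flows_road), 985)
  expect_equal(sol$seat_usage$road, c(600, 0, 385))
  expect_equal(sol$fleet_avail$vehicles, c(100, 0, 100, 100 - 385 / 6 + 0),
               tolerance = 1e-9)
  # waiting makes the split plan cost more than the unconstrained one
  expect_gt(sol$objective, lushan_nominal_solution()$objective)
})

test_that("per-period demand caps with a budget force spreading over periods", {
  inst <- lushan_instance()
  unc <- uncertainty_spec(0.15, 0.6)
  sol <- solve_dynamic(inst, period_spec(2, 1), unc)
  expect_optimal(sol)
  dem <- inflated_demand_matrix(inst, unc)
  dev <- dem - inst$casualties
  served <- apply(sol$flows_road, c(1, 3), sum)
  expect_true(all(served >= dem - 1e-9))
  for (t in 1:2)
    expect_true(all(apply(sol$flows_road[, , , t], c(1, 3), sum) <=
                      inst$casualties - dev + 1e-9),
                info = paste("period", t))
  # with one period those two constraint families contradict each other
  expect_error(build_two_stage(inst, period_spec(1, 1), unc), "contradictory")
})

test_that("dynamic objective is non-decreasing in budget and variability", {
  inst <- lushan_instance()
  p2 <- period_spec(2, 1)
  base <- solve_dynamic(inst, p2, uncertainty_spec(0.05, 0.2))$objective
  more_gamma <- solve_dynamic(inst, p2, uncertainty_spec(0.05, 0.8))$objective
  more_delta <- solve_dynamic(inst, p2, uncertainty_spec(0.20, 0.2))$objective
  nominal <- solve_dynamic(inst, p2)$objective
  expect_lte(nominal, base)
  expect_lte(base, more_gamma)
  expect_lte(base, more_delta)
})
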