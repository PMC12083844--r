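test_that("demand inflation applies the rounding rule to the deviation term", {
  expect_equal(inflated_demand(59, 0.20, 1.0, "half_up"), 71)  # 59 + round(11.8)
  expect_equal(inflated_demand(143, 0.05, 0.2, "half_up"), 144) # 143 + round(1.43)
  expect_equal(inflated_demand(143, 0.05, 0.2, "ceil"), 145)
  expect_equal(inflated_demand(143, 0.05, 0.2, "floor"), 144)
  expect_equal(inflated_demand(48, 0.16, 1, "ceil"), 48 + 8)   # 7.68 -> 8
  # budget zero is the nominal case under every rule
  for (r in c("ceil", "half_up", "floor"))
    expect_equal(inflated_demand(0:50, 0.2, 0, r), 0:50)
  expect_error(inflated_demand(10, 1.5, 1), "delta")
  expect_error(inflated_demand(10, 0.5, 2), "gamma")
})

test_that("inflation depends on delta and budget only through their product", {
  q <- lushan_instance()$casualties
  a <- inflated_demand(q, 0.20, 0.2, "ceil")
  b <- inflated_demand(q, 0.05, 0.8, "ceil")
  expect_equal(a, b)
})

test_that("budget zero reproduces the deterministic optimum", {
  inst <- tiny_instance()
  det <- solve_static(inst)
  rob <- solve_robust(inst, uncertainty_spec(0.20, 0))
  expect_equal(rob$objective, det$objective, tolerance = 1e-9)
})

test_that("robust optimum equals deterministic optimum at inflated demands", {
  # right-hand-side-only uncertainty collapses the counterpart to demand
  # inflation; the ">=" sense never binds below the floor because every
  # objective coefficient is positive
  for (seed in 7:12) {
    # generous capacity slack so the inflated demands remain servable on
    # these very small instances (per-cell ceiling adds up to one casualty
    # per (area, severity) on top of the 12% inflation)
    inst <- small_random_instance(seed, vehicles = 30L, helicopters = 30L,
                                  capacity_slack = 2)
    unc <- uncertainty_spec(0.20, 0.6)
    rob <- solve_robust(inst, unc)
    det_at_inflated <- solve_static(inst,
                                    demand_rhs = inflated_demand_matrix(inst, unc),
                                    demand_sense = "eq")
    expect_optimal(rob); expect_optimal(det_at_inflated)
    expect_equal(rob$objective, det_at_inflated$objective, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("per-area budgets inflate only the budgeted areas", {
  inst <- tiny_instance()
  b <- c(I1 = 1, I2 = 0)
  dm <- inflated_demand_matrix(inst, uncertainty_spec(0.5, b))
  expect_equal(dm["I2", ], inst$casualties["I2", ])
  expect_true(all(dm["I1", ] > inst$casualties["I1", ]))
})

test_that("the worst-case oracle validates robust plans and flags nominal ones", {
  inst <- lushan_instance()
  unc <- uncertainty_spec(0.20, 1)
  rob <- solve_robust(inst, unc)
  chk <- worst_case_oracle(inst, unc, rob)
  expect_true(chk$feasible)
  expect_true(all(chk$shortfall == 0))
  det <- lushan_nominal_solution()
  chk_det <- worst_case_oracle(inst, unc, det)
  expect_false(chk_det$feasible)
  expect_gt(sum(chk_det$shortfall), 0)
  # budget 0 collapses the oracle to nominal coverage
  chk0 <- worst_case_oracle(inst, uncertainty_spec(0.20, 0), det)
  expect_true(chk0$feasible)
})

test_that("an over-inflated instance reports the binding capacity", {
  inst <- single_chain_instance(qs = 40, qm = 45)
  inst$capacities$temp[] <- 90  # nominal fits exactly; any inflation does not
  sol <- solve_robust(inst, uncertainty_spec(0.20, 1))
  expect_identical(sol$solver_status, "infeasible")
  expect_true(any(grepl("temporary capacity", sol$diagnostic)))
})
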