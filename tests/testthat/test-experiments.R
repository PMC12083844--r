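test_that("the sensitivity sweep collapses budget 0 and stays sorted", {
  inst <- tiny_instance()
  sw <- sensitivity_sweep(inst, gammas = c(0, 0.5, 1), deltas = c(0.1, 0.3))
  expect_equal(nrow(sw), 1 + 2 * 2)
  expect_equal(sum(sw$gamma == 0), 1)
  expect_true(!is.unsorted(sw$gamma))
  # budget-0 row equals the plain deterministic solve
  det <- solve_static(inst)
  expect_equal(sw$objective[sw$gamma == 0], det$objective, tolerance = 1e-9)
  # monotone in budget at fixed variability, and in variability at fixed budget
  for (d in unique(stats::na.omit(sw$delta))) {
    col <- sw[is.na(sw$delta) | sw$delta == d, ]
    expect_true(all(diff(col$objective) >= -1e-9), info = paste("delta", d))
  }
  for (g in setdiff(unique(sw$gamma), 0)) {
    row <- sw[sw$gamma == g, ]
    expect_true(all(diff(row$objective[order(row$delta)]) >= -1e-9))
  }
})

test_that("equal delta-budget products give identical sweep rows", {
  inst <- tiny_instance()
  a <- solve_robust(inst, uncertainty_spec(0.30, 0.5))
  b <- solve_robust(inst, uncertainty_spec(0.15, 1.0))
  expect_equal(a$objective, b$objective, tolerance = 1e-9)
})

test_that("feasibility comparison favours the robust plan directionally", {
  inst <- lushan_instance()
  unc <- uncertainty_spec(0.20, 1)
  res <- feasibility_experiment(inst, unc, n_samples = 40, seed = 11,
                                n_objective = 2)
  # full-budget robust plan covers every realization in the interval set
  expect_equal(res$rob_feasible, res$n_samples)
  expect_lt(res$det_feasible, res$n_samples)
  expect_lte(res$det_feasible, res$rob_feasible)
  # zero variability: both plans cover everything
  res0 <- feasibility_experiment(inst, uncertainty_spec(0, 1),
                                 n_samples = 5, seed = 3, n_objective = 0)
  expect_equal(res0$det_feasible, 5)
  expect_equal(res0$rob_feasible, 5)
})

test_that("frozen-flow feasibility is stricter than restricted recourse", {
  inst <- lushan_instance()
  unc <- uncertainty_spec(0.20, 1)
  det_plan <- solve_static(inst)
  stricter <- 0L
  for (r in 1:20) {
    q <- perturb_realization(inst, unc, r)
    fr <- casevac:::plan_covers(inst, det_plan, q, "frozen")
    rc <- casevac:::plan_covers(inst, det_plan, q, "recourse")
    expect_true(rc >= fr)  # frozen feasible implies recourse feasible
    stricter <- stricter + (rc && !fr)
  }
  expect_gt(stricter, 0)
})

test_that("objective falls as hospital capacity grows, then plateaus", {
  inst <- lushan_instance()
  unc <- uncertainty_spec(0.05, 0.3)
  cs <- capacity_sweep(inst, temp_caps = c(400, 500, 700, 1300), unc = unc)
  expect_true(all(cs$status == "optimal"))
  expect_true(all(diff(cs$objective) <= 1e-9))
  # beyond total demand a single temporary hospital suffices: plateau
  cs2 <- capacity_sweep(inst, temp_caps = c(1300, 2000), unc = unc)
  expect_equal(cs2$objective[1], cs2$objective[2], tolerance = 1e-9)
})
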