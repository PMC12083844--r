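test_that("the master's surrogate is free until the first cut arrives", {
  inst <- tiny_instance()
  mp <- build_master(inst, period_spec(2, 1))
  raw <- solve_milp(mp)
  expect_identical(raw$status, "optimal")
  expect_equal(raw$values[["theta"]], 0)
  # master objective = road-leg cost + theta; no air variables exist
  expect_false(any(grepl("^y_|^V_", mp$var_names)))
  with_cut <- build_master(inst, period_spec(2, 1), cuts = 42)
  raw2 <- solve_milp(with_cut)
  expect_equal(raw2$values[["theta"]], 42)
  expect_equal(raw2$objective - raw$objective, 42, tolerance = 1e-9)
})

test_that("the subproblem prices the handed-over flows", {
  inst <- tiny_instance()
  periods <- period_spec(2, 1)
  # zero handover: zero cost, nothing opened
  x0 <- array(0, c(2, 2, 2))
  raw0 <- solve_milp(build_subproblem(x0, inst, periods))
  expect_equal(raw0$objective, 0)
  # handover equal to a feasible static plan's temporary intakes in period 1
  st <- solve_static(inst)
  x1 <- array(0, c(2, 2, 2))
  x1[, , 1] <- apply(st$flows_road, c(2, 3), sum)
  sp <- build_subproblem(x1, inst, periods)
  raw1 <- solve_milp(sp)
  expect_identical(raw1$status, "optimal")
  # the air leg re-optimised at fixed handover can be no worse than the
  # static plan's own air cost
  expect_lte(raw1$objective, st$F2 + 1e-9)
})

test_that("bounds are monotone and the loop converges with gap zero", {
  res <- gbd_solve(lushan_instance(), period_spec(2, 1))
  tr <- res$trace$iterations
  expect_true(res$trace$converged)
  expect_lte(res$trace$final_gap, 1e-6)
  expect_true(all(diff(tr$LB) >= -1e-9))
  expect_true(all(diff(tr$UB) <= 1e-9))
  expect_lte(nrow(tr), 3)  # constant cuts close the gap immediately
})

test_that("GBD matches the monolithic two-stage optimum", {
  # principal correctness anchor for the constant-cut scheme
  inst <- lushan_instance()
  mono <- solve_dynamic(inst, period_spec(2, 1))
  gbd <- gbd_solve(inst, period_spec(2, 1))
  expect_equal(gbd$solution$objective, mono$objective, tolerance = 1e-6)
  for (seed in 31:34) {
    si <- small_random_instance(seed)
    m <- solve_dynamic(si, period_spec(2, 1))
    g <- gbd_solve(si, period_spec(2, 1))
    expect_true(g$trace$converged)
    expect_equal(g$solution$objective, m$objective, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("trace serialization round-trips", {
  res <- gbd_solve(tiny_instance(), period_spec(2, 1))
  jf <- withr::local_tempfile(fileext = ".json")
  write_trace(res$trace, jf, "json")
  back <- read_trace(jf)
  expect_equal(back$iterations$LB, res$trace$iterations$LB)
  expect_equal(back$iterations$UB, res$trace$iterations$UB)
  expect_equal(back$converged, res$trace$converged)
  expect_equal(back$final_gap, res$trace$final_gap)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_trace(res$trace, cf, "csv")
  expect_equal(nrow(utils::read.csv(cf)), nrow(res$trace$iterations))
})
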