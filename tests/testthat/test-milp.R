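test_that("the aggregated static model has the expected shape", {
  model <- build_static(lushan_instance())
  # 90 road flows + 30 air flows + 45 + 15 arc counts + 5 + 3 binaries
  expect_equal(n_variables(model), 90 + 30 + 45 + 15 + 5 + 3)
  expect_equal(sum(model$vtype == "B"), 8)
  expect_equal(sum(model$vtype == "I"), 180)
  senses <- vapply(model$constraints, `[[`, "", "sense")
  # demand rows are equalities in the deterministic model
  dem <- grepl("^demand_", vapply(model$constraints, `[[`, "", "name"))
  expect_equal(sum(dem), 18)
  expect_true(all(senses[dem] == "="))
  # robust flag flips only the demand sense
  model_ge <- build_static(lushan_instance(), demand_sense = "ge")
  senses_ge <- vapply(model_ge$constraints, `[[`, "", "sense")
  expect_true(all(senses_ge[dem] == ">="))
  expect_equal(senses[!dem], senses_ge[!dem])
})

test_that("the per-vehicle model carries one binary per (arc, tool)", {
  inst <- tiny_instance(vehicles = 4L, helicopters = 3L)
  model <- build_static(inst, formulation = "per_vehicle")
  # X: 2*2*4, Y: 2*2*3, U: 2, V: 2 binaries
  expect_equal(sum(model$vtype == "B"), 16 + 12 + 2 + 2)
  # x: 2*2*4*2, y: 2*2*3*2 integer flows
  expect_equal(sum(model$vtype == "I"), 32 + 24)
})

test_that("LP and MPS exports are parseable text with the right counts", {
  model <- build_static(tiny_instance())
  lp <- withr::local_tempfile(fileext = ".lp")
  write_lp(model, lp)
  txt <- readLines(lp)
  expect_true(any(txt == "Minimize"))
  expect_true(any(txt == "Subject To"))
  expect_true(any(txt == "Binary"))
  # one line per constraint between Subject To and Bounds
  expect_equal(which(txt == "Bounds") - which(txt == "Subject To") - 1L,
               n_constraints(model))
  mps <- withr::local_tempfile(fileext = ".mps")
  write_mps(model, mps)
  mtxt <- readLines(mps)
  expect_equal(sum(grepl("^ [LGE] ", mtxt)), n_constraints(model))
  expect_true(any(grepl("INTORG", mtxt)))
  expect_identical(mtxt[length(mtxt)], "ENDATA")
})

test_that("constraint violation checking flags broken solutions", {
  model <- build_static(single_chain_instance())
  raw <- solve_milp(model)
  expect_length(casevac:::constraint_violations(model, raw$values), 0)
  broken <- raw$values
  broken[grep("^x_", model$var_names)[1]] <- broken[grep("^x_", model$var_names)[1]] + 5
  expect_gt(length(casevac:::constraint_violations(model, broken)), 0)
})
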