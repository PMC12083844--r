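test_that("the embedded case fixture matches the published tables", {
  inst <- lushan_instance()
  expect_length(inst$areas, 9)
  expect_length(inst$temp_hospitals, 5)
  expect_length(inst$general_hospitals, 3)
  # spot values from the printed tables
  expect_equal(inst$casualties["I6", "serious"], 70)
  expect_equal(inst$casualties["I1", "moderate"], 143)
  expect_equal(inst$road_times["I9", "J2"], 2.250)
  expect_equal(inst$road_times["I1", "J1"], 1.250)
  expect_equal(inst$air_times["J2", "K3"], 0.61)
  expect_equal(inst$capacities$general["K3", "moderate"], 500)
  expect_true(all(inst$capacities$temp == 500))
  # totals
  expect_equal(total_casualties(inst), 985)
  expect_equal(total_casualties(inst, "serious"), 255)
  expect_equal(total_casualties(inst, "moderate"), 730)
  # severity parameterisation
  expect_equal(inst$severities$serious$urgency_weight, 2)
  expect_equal(inst$severities$moderate$base_deterioration, 0.2)
  expect_equal(inst$post_treatment_factor, 0.2)
})

test_that("the fixture validates cleanly; capacity shortfalls warn not error", {
  inst <- lushan_instance()
  rep <- validate_instance(inst)
  expect_length(rep$errors, 0)
  expect_length(rep$warnings, 0)

  short <- inst
  short$capacities$temp[] <- 100
  rep2 <- validate_instance(short)
  expect_length(rep2$errors, 0)
  expect_true(any(vapply(rep2$warnings, `[[`, "", "code") ==
                    "temp_capacity_short"))
})

test_that("invariant violations are rejected at construction", {
  inst <- lushan_instance()
  bad <- inst$casualties; bad["I1", "serious"] <- -3
  expect_error(
    evac_instance(inst$areas, inst$temp_hospitals, inst$general_hospitals,
                  bad, inst$road_times, inst$air_times, inst$fleet,
                  inst$capacities$temp, inst$capacities$general),
    "casualty")
  expect_error(severity_class("serious", -1, 0.5), "urgency")
  expect_error(severity_class("moderate", 1, 0), "deterioration")
  expect_error(fleet_spec(0, 10), "fleet")
  shell <- validate_instance(list(areas = character(0)))
  expect_true(any(vapply(shell$errors, `[[`, "", "code") == "empty_set"))
})

test_that("JSON and CSV serialization round-trip losslessly", {
  inst <- lushan_instance()
  jf <- withr::local_tempfile(fileext = ".json")
  write_instance(inst, jf, "json")
  back <- load_instance(jf)
  for (f in c("areas", "temp_hospitals", "general_hospitals", "casualties",
              "road_times", "air_times", "post_treatment_factor"))
    expect_equal(back[[f]], inst[[f]], info = f)
  expect_equal(unclass(back$fleet), unclass(inst$fleet))
  expect_equal(back$capacities$temp, inst$capacities$temp)
  expect_equal(back$capacities$general, inst$capacities$general)
  expect_equal(back$severities$serious$base_deterioration, 0.8)

  cd <- withr::local_tempdir()
  write_instance(inst, cd, "csv")
  back2 <- load_instance(cd)
  expect_equal(back2$casualties, inst$casualties)
  expect_equal(back2$road_times, inst$road_times)
  expect_equal(back2$air_times, inst$air_times)
  expect_equal(unclass(back2$fleet), unclass(inst$fleet))
})

test_that("loading reports missing fields and incomplete matrices by name", {
  inst <- lushan_instance()
  jf <- withr::local_tempfile(fileext = ".json")
  doc <- jsonlite::read_json(write_instance(inst, jf, "json"))
  doc$road_times$I4$J2 <- NULL
  jf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, jf2, auto_unbox = TRUE)
  expect_error(load_instance(jf2), "road_times.*I4.*J2")
  doc$fleet <- NULL
  jsonlite::write_json(doc, jf2, auto_unbox = TRUE)
  expect_error(load_instance(jf2), "fleet")
  expect_error(load_instance(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("the installed extdata fixture equals the in-code fixture", {
  path <- system.file("extdata", "lushan.json", package = "casevac")
  expect_true(nzchar(path))
  inst <- load_instance(path)
  expect_equal(inst$casualties, lushan_instance()$casualties)
  expect_equal(inst$road_times, lushan_instance()$road_times)
})
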