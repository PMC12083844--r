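serious <- severity_class("serious", 2, 0.8)
moderate <- severity_class("moderate", 1, 0.2)

test_that("transport deterioration formulas match hand arithmetic", {
  # pre-treatment: 2 * t * p
  expect_equal(pre_rate(1.25, serious), 2.0)        # 2 * 1.25 * 0.8
  expect_equal(pre_rate(0.45, moderate), 0.18)      # 2 * 0.45 * 0.2
  expect_equal(pre_rate(0, serious), 0)
  # post-treatment: 2 * t * factor * p
  expect_equal(post_rate(0.61, serious, 0.2), 0.1952)
  expect_equal(post_rate(0.71, moderate, 0.2), 0.0568)
  expect_equal(post_rate(0.9, moderate, 1), pre_rate(0.9, moderate))
  expect_error(pre_rate(-1, serious), "travel time")
  expect_error(post_rate(1, serious, 0), "factor")
})

test_that("dynamic rates add waiting time and reduce to static at period 1", {
  expect_equal(dynamic_pre_rate(1.25, serious, period = 2, dt = 1),
               0.8 * (1 + 2.5))
  expect_equal(dynamic_post_rate(0.61, serious, period = 2, dt = 1, 0.2),
               0.2 * 0.8 * (1 + 1.22))
  for (t_h in c(0.45, 0.9, 2.25)) {
    expect_equal(dynamic_pre_rate(t_h, serious, 1, 5), pre_rate(t_h, serious))
    expect_equal(dynamic_post_rate(t_h, moderate, 1, 5, 0.2),
                 post_rate(t_h, moderate, 0.2))
  }
  # degenerate period length: no waiting contribution at any period
  expect_equal(dynamic_pre_rate(1, moderate, 7, 0), pre_rate(1, moderate))
  expect_equal(dynamic_post_rate(1, moderate, 3, 1, 0), 0)
  expect_error(dynamic_pre_rate(1, serious, 0, 1), "period")
})

test_that("rates are linear in time and ordered by severity", {
  ts <- seq(0.1, 3, by = 0.37)
  expect_equal(pre_rate(2 * ts, serious), 2 * pre_rate(ts, serious))
  expect_true(all(diff(pre_rate(ts, moderate)) > 0))
  expect_true(all(pre_rate(ts, serious) > pre_rate(ts, moderate)))
  expect_equal(post_rate(ts, serious, 0.2), 0.2 * pre_rate(ts, serious))
})

test_that("objective coefficients combine rate and urgency weight per arc", {
  inst <- lushan_instance()
  ot <- objective_terms(inst)
  # serious on (I1, J2): 2 * 0.8 h * 0.8 /h * weight 2
  expect_equal(ot$road["I1", "J2", "serious"], 2.56)
  # moderate road coefficient simplifies to 0.4 * t
  expect_equal(ot$road[, , "moderate"], 0.4 * inst$road_times,
               ignore_attr = TRUE)
  expect_equal(ot$air["J2", "K3", "serious"], 2 * 0.61 * 0.2 * 0.8 * 2)
  expect_true(all(ot$road > 0) && all(ot$air > 0))
  # dynamic coefficients at period 1 equal the static ones
  ot1 <- objective_terms(inst, period = 1, dt = 4)
  expect_equal(ot1$road, ot$road)
  expect_equal(ot1$air, ot$air)
})
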