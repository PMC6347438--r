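test_that("percent incorporation is the cell share of recovered activity", {
  run <- run_at(c(59, 36, 3, 2, 1))
  expect_equal(percent_incorporation(run), 59 / 101)
  expect_equal(round(percent_incorporation(run), 3), 0.584)

  none <- run_at(c(0, 36, 3))
  expect_equal(percent_incorporation(none), 0)

  expect_error(percent_incorporation(run_at(c(0, 0, 0))), "zero")
})

test_that("percent incorporation is invariant to a common measurement time", {
  base <- percent_incorporation(run_at(c(59, 36, 3, 2, 1), t_min = 0))
  for (t in c(15, 60, 120, 240)) {
    a <- c(59, 36, 3, 2, 1) * decay_factor(t, f18)
    expect_equal(percent_incorporation(run_at(a, t_min = t)), base,
                 tolerance = 1e-12)
  }
})

test_that("compartment fractions normalise to exactly one", {
  run <- run_at(c(59, 36, 3, 2, 1))
  fr <- wash_fractions(run)
  expect_equal(sum(fr), 1, tolerance = 1e-15)
  expect_equal(unname(round(fr, 4)),
               c(0.5842, 0.3564, 0.0297, 0.0198, 0.0099))
  single <- labeling_run(
    f18,
    data.frame(compartment = c("cells", "supernatant"),
               activity_mbq = c(5, 0), t_min = 0),
    initial_activity_mbq = 5.05
  )
  expect_equal(unname(wash_fractions(single)), c(1, 0))
  # positivity-agnostic normalisation property
  set.seed(7)
  for (i in 1:20) {
    a <- runif(5, 0.01, 50)
    expect_equal(sum(wash_fractions(run_at(a))), 1, tolerance = 1e-15)
  }
})

test_that("run validation enforces compartment structure and mass balance", {
  expect_error(labeling_run(f18, data.frame(compartment = "supernatant",
                                            activity_mbq = 1, t_min = 0), 2),
               "exactly one `cells`")
  expect_error(labeling_run(f18, data.frame(
    compartment = c("cells", "supernatant"),
    activity_mbq = c(100, 50), t_min = 0), initial_activity_mbq = 100),
    "mass balance")
  expect_error(labeling_run(f18, data.frame(compartment = "lumen",
                                            activity_mbq = 1, t_min = 0), 2),
               "unknown compartment")
})

test_that("two-point uptake fits solve the saturation ratio in closed form", {
  c0 <- 0.55
  m <- fit_uptake(c(60, 120), c(0.99 * c0, c0))
  expect_equal(m$k, log(99) / 60, tolerance = 1e-8)
  # fitted 30-min:2-h ratio lands near 0.90 for this rate constant
  r30 <- predict(m, 30) / predict(m, 120)
  expect_equal(round(r30, 2), 0.90)
})

test_that("uptake fitting recovers noiseless curves and rejects degenerate input", {
  t <- c(5, 10, 20, 30, 45, 60, 90, 120)
  y <- 0.6 * (1 - exp(-0.05 * t))
  m <- fit_uptake(t, y)
  expect_equal(m$f_inf, 0.6, tolerance = 1e-6)
  expect_equal(m$k, 0.05, tolerance = 1e-6)
  # fitted curve is nondecreasing
  expect_true(all(diff(predict(m, seq(0, 180, 5))) >= 0))
  expect_error(fit_uptake(c(30, 30), c(0.2, 0.3)), "identifiable")
})

test_that("leakage fits agree with a normal-equations oracle", {
  m <- fit_leakage(c(46, 76, 106), c(10.5, 19.4, 23.7))
  o <- ols_oracle(c(46, 76, 106), c(10.5, 19.4, 23.7))
  expect_equal(m$slope, 0.22, tolerance = 1e-12)
  expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(m$r_squared, o$r_squared, tolerance = 1e-10)

  set.seed(11)
  for (i in 1:20) {
    t <- sort(runif(sample(3:8, 1), 0, 200))
    y <- runif(length(t), 0, 40)
    m <- fit_leakage(t, y)
    o <- ols_oracle(t, y)
    expect_equal(m$slope, o$slope, tolerance = 1e-10)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(m$r_squared, o$r_squared, tolerance = 1e-10)
  }

  expect_equal(fit_leakage(c(10, 50), c(3, 9))$r_squared, 1)
  expect_error(fit_leakage(c(10, 10), c(3, 9)), "degenerate")
})

test_that("leakage prediction interpolates, warns on extrapolation, and clamps", {
  m <- fit_leakage(c(46, 76, 106), c(10.5, 19.4, 23.7))
  expect_equal(predict_leakage_at(m, 60), 14.3467, tolerance = 1e-4)
  expect_equal(predict_leakage_at(m, 76), m$intercept + m$slope * 76)
  flat <- fit_leakage(c(0, 100), c(7, 7))
  expect_equal(predict_leakage_at(flat, 50), 7)
  expect_warning(predict_leakage_at(m, 300), "outside the fitted window")
  expect_equal(suppressWarnings(predict_leakage_at(m, 1e5)), 100)
})

test_that("yield prediction composes incorporation with physical decay", {
  expect_equal(predict_yield(100, 0.4, 0, f18), 40)
  expect_equal(predict_yield(100, 0.5, 109.77, f18), 25, tolerance = 1e-9)
  expect_equal(predict_yield(740, 0.582, 65, f18), 285.7, tolerance = 1e-3)
})
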