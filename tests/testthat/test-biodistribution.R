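test_that("well-mixed dose fractions mirror blood volumes and sum to one", {
  tab <- blood_volume_table("heart_contents", 0.5)
  fr <- blood_pool_fractions(tab)
  expect_equal(fr, c(heart_contents = 0.5, rest_of_body = 0.5))

  tab10 <- blood_volume_table(paste0("organ_", 1:10), rep(0.05, 10))
  fr10 <- blood_pool_fractions(tab10)
  expect_equal(unname(fr10), c(rep(0.05, 10), 0.5))
  expect_equal(sum(fr10), 1, tolerance = 1e-15)

  expect_error(blood_volume_table(c("a", "b"), c(0.7, 0.6)), "sum")
  expect_error(blood_volume_table("rest_of_body", 0.1), "reserved")
})

test_that("the packaged blood-volume table round-trips and closes to one", {
  tab <- load_blood_volumes()
  raw <- read.csv(system.file("extdata", "icrp89_blood_volumes.csv",
                              package = "rbcdosim"), comment.char = "#")
  expect_equal(tab$organ, raw$organ)
  expect_equal(tab$fraction, raw$fraction)
  expect_equal(sum(blood_pool_fractions(tab)), 1, tolerance = 1e-15)
})

test_that("blood-pool residence time is the decayed static share", {
  scA <- scenario_full_retention()
  expect_equal(residence_time(1, f18, scA), 2.6394, tolerance = 1e-4)
  expect_equal(residence_time(0, f18, scA), 0)
  scB <- scenario_free_excretion(0.25)
  expect_equal(residence_time(0.5, f18, scB),
               0.75 * 0.5 * (109.77 / 60) / log(2), tolerance = 1e-12)
  # linearity in the dose fraction
  f <- runif(10)
  expect_equal(residence_time(f, f18, scA), f * residence_time(1, f18, scA))
})

test_that("scenario construction enforces the retained/excreted partition", {
  expect_error(scenario_spec(0.8, 0.25), "equal 1")
  sc <- read_scenario(system.file("extdata", "scenario_25pct_free.yaml",
                                  package = "rbcdosim"))
  expect_equal(sc$excreted_fraction, 0.25)
  expect_equal(sc$bladder_entry_halftime_min, 12)
  expect_equal(sc$voiding_interval_h, 3.5)
})

test_that("voiding-bladder residence matches a brute-force trapezoid oracle", {
  sc <- scenario_free_excretion(0.25)
  got <- bladder_residence(0.25, f18, sc)
  oracle <- bladder_oracle(0.25, f18, sc, dt = 0.02)
  expect_equal(got, oracle, tolerance = 1e-4)

  sc2 <- scenario_spec(0.6, 0.4, bladder_entry_halftime_min = 45,
                       voiding_interval_h = 2)
  expect_equal(bladder_residence(0.4, tc99m, sc2),
               bladder_oracle(0.4, tc99m, sc2, dt = 0.02),
               tolerance = 1e-4)
})

test_that("voiding-bladder limits reduce to pure decay in the bladder", {
  expect_equal(bladder_residence(0, f18, scenario_free_excretion(0.25)), 0)
  # instant entry + effectively-never voiding: everything decays in bladder
  sc_inf <- scenario_spec(0.75, 0.25, bladder_entry_halftime_min = 0,
                          voiding_interval_h = 1e6)
  expect_equal(bladder_residence(0.25, f18, sc_inf),
               0.25 * (109.77 / 60) / log(2), tolerance = 1e-9)
  # degenerate entry rate equal to the decay constant stays finite and sane
  sc_eq <- scenario_spec(0.75, 0.25,
                         bladder_entry_halftime_min = f18$half_life,
                         voiding_interval_h = 3.5)
  expect_equal(bladder_residence(0.25, f18, sc_eq),
               bladder_oracle(0.25, f18, sc_eq, dt = 0.02), tolerance = 1e-4)
})

test_that("bladder residence grows with voiding interval and half-life", {
  vals <- sapply(c(1, 2, 3.5, 6, 12), function(vi) {
    bladder_residence(0.25, f18,
                      scenario_spec(0.75, 0.25, 12, voiding_interval_h = vi))
  })
  expect_true(all(diff(vals) > 0))
  sc <- scenario_free_excretion(0.25)
  expect_gt(bladder_residence(0.25, tc99m, sc),
            bladder_residence(0.25, f18, sc))
})

test_that("full-retention activity coefficients conserve total decay", {
  tab <- make_blood_volume_table(paste0("o", 1:6), total_fraction = 0.8,
                                 seed = 3)
  tia <- tia_vector(tab, f18, scenario_full_retention())
  expect_equal(sum(tia$tia_h), (109.77 / 60) / log(2), tolerance = 1e-12)
  expect_true(all(tia$tia_h >= 0))
})

test_that("excretion scenarios never exceed the pure-decay bound", {
  bound <- (109.77 / 60) / log(2)
  tab <- make_blood_volume_table(paste0("o", 1:6), seed = 4)
  tia <- tia_vector(tab, f18, scenario_free_excretion(0.25))
  expect_lt(sum(tia$tia_h), bound)
  expect_true("urinary_bladder_contents" %in% tia$region)
  # equality recovered as voiding -> never and entry -> instant
  tia_lim <- tia_vector(tab, f18,
                        scenario_spec(0.75, 0.25, 0, voiding_interval_h = 1e6))
  expect_equal(sum(tia_lim$tia_h), bound, tolerance = 1e-9)
})
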