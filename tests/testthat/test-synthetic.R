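test_that("synthetic labeling runs are seeded, valid and noiseless-exact", {
  truth <- labeling_truth(0.582, calibrator_cv = 0, n_replicates = 2, seed = 1)
  runs <- make_labeling_run(truth)
  expect_length(runs, 2)
  for (r in runs) {
    expect_equal(percent_incorporation(r), 0.582, tolerance = 1e-12)
    fr <- wash_fractions(r)
    expect_equal(unname(fr),
                 c(0.582, 1 - 0.582 - 0.06, 0.03, 0.02, 0.01),
                 tolerance = 1e-12)
  }

  truth_custom <- labeling_truth(0.6, wash_carryover = c(0.03, 0.015, 0.005),
                                 calibrator_cv = 0, seed = 2)
  fr <- wash_fractions(make_labeling_run(truth_custom)[[1]])
  expect_equal(unname(fr), c(0.6, 0.35, 0.03, 0.015, 0.005),
               tolerance = 1e-12)

  zero <- labeling_truth(0, calibrator_cv = 0, seed = 3)
  run0 <- make_labeling_run(zero)[[1]]
  expect_equal(corrected_activities(run0)[["cells"]], 0)
})

test_that("generators are pure functions of their seed", {
  t1 <- labeling_truth(0.5, calibrator_cv = 0.05, n_replicates = 3, seed = 99)
  expect_identical(make_labeling_run(t1), make_labeling_run(t1))
  s1 <- make_leakage_series(0.22, 1.147, c(46, 76, 106), cv = 0.05, seed = 7)
  s2 <- make_leakage_series(0.22, 1.147, c(46, 76, 106), cv = 0.05, seed = 7)
  expect_identical(s1, s2)
  s3 <- make_leakage_series(0.22, 1.147, c(46, 76, 106), cv = 0.05, seed = 8)
  expect_false(identical(s1, s3))
  # generation does not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_labeling_run(t1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless leakage series round-trip through the fitter", {
  s <- make_leakage_series(0.22, 1.147, c(46, 76, 106), cv = 0, seed = 1)
  m <- fit_leakage(s$t_min, s$leaked_percent)
  expect_equal(m$slope, 0.22, tolerance = 1e-9)
  expect_equal(m$intercept, 1.147, tolerance = 1e-9)
  flat <- make_leakage_series(0, 5, c(10, 20, 30), cv = 0, seed = 1)
  expect_true(all(flat$leaked_percent == 5))
})

test_that("synthetic S-matrices are valid by construction and scale with mass", {
  ph <- synthetic_phantom()
  s <- make_smatrix(ph, f18)
  expect_s3_class(s, "svalue_matrix")  # construction already validates
  expect_true(all(s$values >= 0))
  for (org in s$sources) {
    expect_true(all(s$values[, org] <= s$values[org, org] + 1e-12))
  }

  # doubling a target's mass halves the electron component of its self S-value
  m1 <- c(a = 0.5, b = 1)
  ph1 <- synthetic_phantom(organ_masses_kg = m1, electron_energy = 0.2,
                           photon_energy = 0)
  ph2 <- synthetic_phantom(organ_masses_kg = c(a = 1, b = 1),
                           electron_energy = 0.2, photon_energy = 0)
  s1 <- make_smatrix(ph1, f18); s2 <- make_smatrix(ph2, f18)
  expect_equal(s2$values["a", "a"], s1$values["a", "a"] / 2)

  # no electron energy and no coupling: the matrix vanishes
  ph0 <- synthetic_phantom(organ_masses_kg = m1, electron_energy = 0,
                           photon_energy = 0.5,
                           coupling = matrix(0, 2, 2))
  expect_true(all(make_smatrix(ph0, f18)$values == 0))
})

test_that("synthetic blood-volume tables are valid partitions", {
  tab <- make_blood_volume_table(paste0("o", 1:8), total_fraction = 0.7,
                                 seed = 5)
  expect_s3_class(tab, "blood_volume_table")
  expect_equal(sum(tab$fraction), 0.7, tolerance = 1e-12)
  expect_identical(tab, make_blood_volume_table(paste0("o", 1:8), 0.7, seed = 5))
})
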