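smat <- function(vals, targets, sources = targets, phantom = "test") {
  dimnames(vals) <- list(targets, sources)
  svalue_matrix(vals, phantom_name = phantom)
}

test_that("the MIRD sum reproduces hand products and a double-loop oracle", {
  s <- smat(matrix(c(3, 0.5, 1, 4), 2, 2), c("a", "b"))
  d <- absorbed_doses(c(a = 1, b = 2), s)
  expect_equal(d, c(a = 5, b = 8.5))
  expect_equal(absorbed_doses(c(a = 0, b = 0), s), c(a = 0, b = 0))

  set.seed(5)
  for (i in 1:10) {
    organs <- paste0("org", 1:10)
    vals <- matrix(runif(100, 0, 0.02), 10, 10)
    diag(vals) <- apply(vals, 2, max) + runif(10, 0.01, 0.1)  # dominance
    s10 <- smat(vals, organs)
    a <- stats::setNames(runif(10, 0, 3), organs)
    expect_equal(absorbed_doses(a, s10), mird_oracle(a, s10),
                 tolerance = 1e-12)
  }
})

test_that("doses are linear in activity coefficients and S-values", {
  organs <- paste0("o", 1:4)
  vals <- matrix(runif(16, 0, 0.01), 4, 4); diag(vals) <- 0.1
  s <- smat(vals, organs)
  a <- stats::setNames(runif(4), organs)
  expect_equal(absorbed_doses(2 * a, s), 2 * absorbed_doses(a, s))
  s2 <- smat(2 * vals, organs)
  expect_equal(absorbed_doses(a, s2), 2 * absorbed_doses(a, s))
})

test_that("schema mismatches and invalid S-matrices are rejected by name", {
  s <- smat(matrix(c(3, 0.5, 1, 4), 2, 2), c("a", "b"))
  expect_error(absorbed_doses(c(a = 1, bladder = 2), s), "bladder")
  expect_error(smat(matrix(c(1, 2, 0.1, 3), 2, 2), c("a", "b")),
               "self-dose dominance")
  expect_error(smat(matrix(c(-1, 0, 0, 1), 2, 2), c("a", "b")),
               "non-negative")
})

test_that("S-matrix CSV round-trips through the documented layout", {
  organs <- c("heart_wall", "lungs", "rest_of_body")
  vals <- matrix(runif(9, 0, 0.01), 3, 3); diag(vals) <- 0.2
  s <- smat(vals, organs, phantom = "roundtrip")
  path <- tempfile(fileext = ".csv")
  write_smatrix(s, path)
  s2 <- read_smatrix(path)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(s2$targets, organs)
})

test_that("wall correction swaps the surface term for wall self-absorption", {
  doses <- c(gut_wall = 10, other = 1)
  tia <- c(gut_wall = 1)
  spec <- hollow_organ_spec("gut_wall", wall_mass_kg = 0.1,
                            contents_mass_kg = 0.2, delta_electron = 2)
  corrected <- wall_correction(doses, tia, spec)
  # surface term 0.5*2/0.2 = 5 removed; wall term 2/0.1 = 20 added
  expect_equal(corrected[["gut_wall"]], 10 - 5 + 20)
  expect_equal(corrected[["other"]], 1)  # only the named organ changes

  zero <- hollow_organ_spec("gut_wall", 0.1, 0.2, delta_electron = 0)
  expect_equal(wall_correction(doses, tia, zero), doses)

  expect_warning(
    out <- wall_correction(doses, tia,
                           hollow_organ_spec("absent", 0.1, 0.2, 1)),
    "no correction")
  expect_equal(out, doses)
})

test_that("equal masses and activities double the electron self-term", {
  tia <- c(bladder_wall = 0.7)
  spec <- hollow_organ_spec("bladder_wall", wall_mass_kg = 0.05,
                            contents_mass_kg = 0.05, delta_electron = 1.3)
  surface_term <- 0.5 * 0.7 * 1.3 / 0.05
  doses <- c(bladder_wall = surface_term)  # dose made of the electron term only
  corrected <- wall_correction(doses, tia, spec)
  expect_equal(corrected[["bladder_wall"]], 2 * surface_term)
  expect_gte(corrected[["bladder_wall"]], 0)
})

test_that("effective dose weights tissues per ICRP-60 and handles surrogates", {
  w <- load_tissue_weights()
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)

  organs <- c("testes", "colon", "lungs", "red_marrow", "stomach",
              "urinary_bladder", "breasts", "liver", "thymus", "thyroid",
              "skin", "bone_surfaces", w$remainder_organs)
  uniform <- stats::setNames(rep(0.03, length(organs)), organs)
  expect_equal(effective_dose(uniform, w), 0.03, tolerance = 1e-12)

  single <- uniform * 0
  single[["stomach"]] <- 1
  expect_equal(effective_dose(single, w), 0.12, tolerance = 1e-12)

  expect_error(effective_dose(uniform[names(uniform) != "thyroid"], w),
               "thyroid")
})

test_that("effective dose is linear in the dose vector", {
  w <- load_tissue_weights()
  organs <- c("testes", "colon", "lungs", "red_marrow", "stomach",
              "urinary_bladder", "breasts", "liver", "thymus", "thyroid",
              "skin", "bone_surfaces", w$remainder_organs)
  set.seed(9)
  d1 <- stats::setNames(runif(length(organs), 0, 0.1), organs)
  d2 <- stats::setNames(runif(length(organs), 0, 0.1), organs)
  expect_equal(effective_dose(0.3 * d1 + 0.7 * d2, w),
               0.3 * effective_dose(d1, w) + 0.7 * effective_dose(d2, w),
               tolerance = 1e-12)
})

test_that("administration limits follow the regulatory classes", {
  lim <- load_regulatory_limits()
  res <- admin_limits(c(heart_wall = 7.78e-2), effective = 3.90e-2,
                      activity_per_admin_mbq = 370, limits = lim)
  expect_equal(res$limiting_organ, "heart_wall")
  expect_equal(res$max_annual_admins, 5)
  expect_true(res$single_admin_ok)

  # restrictive class binds harder: same dose on red marrow caps at 50 mSv
  res_rm <- admin_limits(c(red_marrow = 7.78e-2), activity_per_admin_mbq = 370,
                         limits = lim)
  expect_equal(res_rm$max_annual_admins, floor(50 / (7.78e-2 * 370)))

  none <- admin_limits(c(a = 0, b = 0), activity_per_admin_mbq = 100,
                       limits = lim)
  expect_equal(none$limiting_organ, "none (no binding constraint)")
  expect_equal(none$max_annual_admins, Inf)

  # exactly at the single-admin limit: equality passes, at least one admin
  at_limit <- admin_limits(c(liver = 50 / 370), activity_per_admin_mbq = 370,
                           limits = lim)
  expect_true(at_limit$single_admin_ok)
  expect_gte(at_limit$max_annual_admins, 1)
})

test_that("more activity per administration never allows more administrations", {
  lim <- load_regulatory_limits()
  d <- c(heart_wall = 7.78e-2, lungs = 6.39e-2, red_marrow = 1.77e-2)
  acts <- seq(50, 1000, by = 50)
  admins <- sapply(acts, function(a) {
    admin_limits(d, activity_per_admin_mbq = a, limits = lim)$max_annual_admins
  })
  expect_true(all(diff(admins) <= 0))
})

test_that("total effective dose scales and rounds for reporting", {
  expect_equal(total_effective_dose(3.90e-2, c(185, 370)), c(7.2, 14.4))
  expect_equal(total_effective_dose(7.0e-3, 1110, digits = 2), 7.77)
  expect_equal(total_effective_dose(0.5, 0), 0)
})

test_that("agent comparison ratios behave as pure presentation", {
  a <- c(x = 1, y = 2, z = 4)
  cmp_same <- compare_agents(list(ref = a, alt = a))
  expect_true(all(cmp_same$ratio_alt == 1))
  cmp_scaled <- compare_agents(list(ref = a, alt = 2 * a))
  expect_true(all(cmp_scaled$ratio_alt == 2))
  expect_error(compare_agents(list(ref = c(x = 1), alt = c(q = 1))),
               "no organs")
})
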