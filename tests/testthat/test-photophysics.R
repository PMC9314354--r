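test_that("intensity is the linear free/bound mixture", {
  aff <- fix_triple_affinities(0, 0)
  comp <- composition(c(H1 = 1e-6), c(D1 = 1e-6))
  st <- solve_equilibrium(comp, aff)
  # no binding: all dye free
  expect_equal(intensity(st, dye_photophysics("D1", phi_free = 3), "D1"), 3e-6)
  # fully bound limit under huge Ka and host excess
  aff2 <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e13))
  st2 <- solve_equilibrium(composition(c(H1 = 1e-4), c(D1 = 1e-6)), aff2)
  expect_equal(intensity(st2, dye_photophysics("D1", phi_bound = 0.5), "D1"),
               0.5 * 1e-6, tolerance = 1e-4)
  # 50% bound, quench-type: half the free-dye intensity
  half <- st2
  half$free["D1"] <- 0.5e-6
  half$complexes["D1", "H1"] <- 0.5e-6
  expect_equal(intensity(half, dye_photophysics("D1"), "D1"), 0.5e-6)
  expect_error(intensity(st, dye_photophysics("D1"), "D9"), "unknown dye")
})

test_that("dye photophysics validates inputs and derives the mode", {
  expect_identical(dye_photophysics("D1", 1, 0)$mode, "quench")
  expect_identical(dye_photophysics("D1", 1, 10)$mode, "enhance")
  expect_error(dye_photophysics("D1", phi_free = 0), "phi_free")
  expect_error(dye_photophysics("D1", phi_bound = -1), "phi_bound")
})

test_that("response ratio obeys the trivial and limiting cases", {
  aff <- fix_triple_affinities(1e6, 1e7)
  unit <- fix_unit()
  ph <- dye_photophysics("D1")
  # zero dose and non-binding analyte leave the signal unchanged
  expect_equal(response_ratio(unit, c(A1 = 0), aff, ph), 1)
  aff0 <- fix_triple_affinities(1e6, 0)
  expect_equal(response_ratio(unit, c(A1 = 2e-6), aff0, ph), 1)
  # saturating competitor reaches the full-displacement ceiling D_t/[D]_free0
  st0 <- solve_equilibrium(composition(c(H1 = 1e-6), c(D1 = 1e-6)), aff,
                           tol = 1e-12)
  ceiling_ <- 1e-6 / st0$free[["D1"]]
  r_sat <- response_ratio(unit, c(A1 = 1e-3), aff, ph, tol = 1e-12)
  expect_equal(r_sat, ceiling_, tolerance = 1e-3)
  expect_lte(r_sat, ceiling_ * (1 + 1e-9))
})

test_that("quench and enhance dyes respond on opposite sides of 1", {
  aff <- fix_triple_affinities(1e6, 1e7)
  unit <- fix_unit()
  r_quench <- response_ratio(unit, c(A1 = 2e-6), aff, dye_photophysics("D1"))
  r_enh <- response_ratio(unit, c(A1 = 2e-6), aff,
                          dye_photophysics("D1", phi_free = 1, phi_bound = 10))
  expect_gt(r_quench, 1)
  expect_lt(r_enh, 1)
})

test_that("response ratio is scale-free in the emission coefficients", {
  aff <- fix_triple_affinities(1e6, 1e7)
  unit <- fix_unit()
  r1 <- response_ratio(unit, c(A1 = 2e-6), aff,
                       dye_photophysics("D1", phi_free = 1, phi_bound = 0.2))
  r2 <- response_ratio(unit, c(A1 = 2e-6), aff,
                       dye_photophysics("D1", phi_free = 7, phi_bound = 1.4))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate dark baseline raises an explicit error", {
  # essentially infinite binding of a nearly dark dye: the baseline
  # intensity underflows to exactly zero and the ratio is undefined
  aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e304))
  unit <- sensor_unit("u", c(H1 = 1e-3), "D1", 1e-9)
  expect_error(response_ratio(unit, c(A1 = 1e-6), aff,
                              dye_photophysics("D1", phi_free = 1e-300)),
               "degenerate baseline")
})

test_that("direct titration of a quench dye is non-increasing and convex-limited", {
  aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e7))
  ph <- dye_photophysics("D1")
  ramp <- seq(0, 5e-6, length.out = 21)
  curve <- direct_titration(c(H1 = 1), ramp, "D1", 1e-6, aff, ph)
  expect_s3_class(curve, "titration_curve")
  expect_identical(attr(curve, "kind"), "direct")
  expect_true(all(diff(curve$intensity) <= 1e-15))
  expect_equal(curve$intensity[1], 1e-6)  # no host: all dye free
  # randomized quench-mode panels stay monotone
  set.seed(47)
  for (i in 1:10) {
    ka <- 10^runif(1, 5, 9)
    affr <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = ka))
    cv <- direct_titration(c(H1 = 1), ramp, "D1", 1e-6, affr, ph)
    expect_true(all(diff(cv$intensity) <= 1e-15))
  }
})

test_that("flat ramps and empty ramps behave as specified", {
  aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e7))
  ph <- dye_photophysics("D1")
  expect_error(direct_titration(c(H1 = 1), numeric(0), "D1", 1e-6, aff, ph),
               "empty")
  expect_error(direct_titration(c(H1 = 1), c(1e-6, 1e-6), "D1", 1e-6, aff, ph),
               "strictly increasing")
})

test_that("titration midpoint matches the closed-form inversion", {
  ka <- 1e7; gt <- 1e-6
  # host total at which half the dye is bound, from the analytic pair formula
  f <- function(ht) closed_form_pair(ht, gt, ka) / gt - 0.5
  ht_half_analytic <- uniroot(f, c(1e-8, 1e-3), tol = 1e-15)$root
  aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = ka))
  g <- function(ht) {
    st <- solve_equilibrium(composition(c(H1 = ht), c(D1 = gt)), aff, tol = 1e-12)
    st$complexes["D1", "H1"] / gt - 0.5
  }
  ht_half_solver <- uniroot(g, c(1e-8, 1e-3), tol = 1e-15)$root
  expect_equal(ht_half_solver, ht_half_analytic, tolerance = 1e-8)
})

test_that("competitive titration recovers signal and separates reporter ratios", {
  aff <- fix_triple_affinities(1e6, 1e7)
  ph <- dye_photophysics("D1")
  ramp <- seq(0, 1e-5, length.out = 11)
  # non-binding analyte: flat curve
  aff0 <- fix_triple_affinities(1e6, 0)
  flat <- competitive_titration(fix_unit(), "A1", ramp, aff0, ph)
  expect_lt(diff(range(flat$intensity)), 1e-18)
  # quench dye: displacement recovers intensity monotonically
  cv <- competitive_titration(fix_unit(), "A1", ramp, aff, ph)
  expect_identical(attr(cv, "kind"), "competitive")
  expect_true(all(diff(cv$intensity) >= -1e-15))
  # the two reporter ratios 4:5 and 7:5 give unequal fluorescence changes
  dose <- 2e-6
  dI <- vapply(c(4 / 5, 7 / 5), function(r) {
    u <- sensor_unit("u", c(H1 = r * 1e-6), "D1", 1e-6)
    c0 <- competitive_titration(u, "A1", c(0, dose), aff, ph)
    diff(c0$intensity)
  }, numeric(1))
  expect_gt(abs(dI[1] - dI[2]), 1e-12)
  # asymptote equals the full-displacement ceiling of the response ratio
  r_inf <- response_ratio(fix_unit(), c(A1 = 1e-2), aff, ph, tol = 1e-12)
  st0 <- solve_equilibrium(composition(c(H1 = 1e-6), c(D1 = 1e-6)), aff,
                           tol = 1e-12)
  expect_equal(r_inf, 1e-6 / st0$free[["D1"]], tolerance = 1e-4)
})

test_that("titration curves write as two-column text", {
  aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e7))
  curve <- direct_titration(c(H1 = 1), c(0, 1e-6, 2e-6), "D1", 1e-6, aff,
                            dye_photophysics("D1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_curve(curve, path)
  back <- utils::read.csv(path)
  expect_equal(back$conc_M, curve$conc, tolerance = 1e-14)
  expect_equal(back$intensity, curve$intensity, tolerance = 1e-14)
})
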