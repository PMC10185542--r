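test_that("Moens wave speed matches hand evaluation and scalings", {
  # hand evaluation: sqrt(346e3 * 0.002 / (1000 * 0.0218 * 0.75)) = 6.5057
  expect_equal(moens_pwv(346e3, 0.002, 1000, 0.0218, 0.5), 6.51,
               tolerance = 0.01 / 6.51)
  v1 <- moens_pwv(2e5, 0.002, 1000, 0.02, 0.5)
  expect_equal(moens_pwv(8e5, 0.002, 1000, 0.02, 0.5), 2 * v1)
  expect_equal(moens_pwv(2e5, 0.002, 1000, 0.08, 0.5), v1 / 2)
  expect_error(moens_pwv(2e5, 0.002, 1000, 0.02, 1), "nu")
  expect_error(moens_pwv(-1, 0.002, 1000, 0.02), "positive")
})

test_that("forward and inverse Moens relations are exact mutual inverses", {
  set.seed(42)
  for (i in 1:25) {
    E <- runif(1, 5e4, 2e6)
    h <- runif(1, 5e-4, 5e-3)
    rho <- runif(1, 900, 1100)
    D <- runif(1, 0.005, 0.04)
    nu <- runif(1, 0, 0.5)
    v <- moens_pwv(E, h, rho, D, nu)
    expect_equal(moens_inverse_e(v, h, rho, D, nu), E, tolerance = 1e-12)
    expect_equal(moens_pwv(moens_inverse_e(v, h, rho, D, nu), h, rho, D, nu),
                 v, tolerance = 1e-12)
  }
})

test_that("inverse Moens at the target wave speed recovers the design modulus", {
  E <- moens_inverse_e(6.54, 0.002, 1000, 0.0218, 0.5)
  expect_equal(E, 350e3, tolerance = 0.01)
  # at the measured 6.58 m/s the modulus lies within a few percent of the
  # bench zero-strain value 346 kPa
  expect_equal(moens_inverse_e(6.58, 0.002, 1000, 0.0218, 0.5), 346e3,
               tolerance = 0.03)
})

test_that("effective modulus interpolates the bench softening knots", {
  m <- standard_wall_material()
  expect_identical(effective_modulus(m, 0), 346e3)
  expect_equal(effective_modulus(m, 10), 248e3, tolerance = 1e-9)
  expect_equal(effective_modulus(m, 20), 80e3, tolerance = 1e-9)
  e5 <- effective_modulus(m, 5)
  e15 <- effective_modulus(m, 15)
  expect_true(e5 < 346e3 && e5 > 248e3)
  expect_true(e15 < 248e3 && e15 > 80e3)
  # monotone non-increasing across the modelled range, clamped beyond
  tp <- seq(0, 25, by = 0.5)
  ee <- vapply(tp, function(x) effective_modulus(m, x), numeric(1))
  expect_true(all(diff(ee) <= 1e-9))
  expect_equal(effective_modulus(m, 25), 80e3, tolerance = 1e-9)
  expect_error(effective_modulus(m, -1), "not modelled")
})

test_that("softening table construction validates its knots", {
  expect_error(softening_curve_from_table(cbind(c(5, 10), c(3e5, 2e5))),
               "tp = 0")
  expect_error(softening_curve_from_table(cbind(c(0, 10), c(2e5, 3e5))),
               "non-increasing")
  single <- softening_curve_from_table(cbind(0, 3e5))
  expect_identical(effective_modulus(single, 12), 3e5)
  two <- softening_curve_from_table(cbind(c(0, 10), c(3e5, 2e5)))
  expect_equal(effective_modulus(two, 5), 2.5e5)
})

test_that("Laplace-law fixed point softens a curve-defined material", {
  soft <- wall_material(E0 = 346e3, behavior = "strain_softening",
                        softening_curve = function(eps) 346e3 / (1 + 8 * eps))
  expect_identical(effective_modulus(soft, 0), 346e3)
  e10 <- effective_modulus(soft, 10, diameter = 0.0218,
                           wall_thickness = 0.002)
  e20 <- effective_modulus(soft, 20, diameter = 0.0218,
                           wall_thickness = 0.002)
  expect_true(e20 < e10 && e10 < 346e3)
  # self-consistency: strain from the returned modulus maps back to it
  sigma <- mmhg_to_pa(10) * 0.0109 / 0.002
  expect_equal(346e3 / (1 + 8 * sigma / e10), e10, tolerance = 1e-6)
})

test_that("material constructor enforces its invariants", {
  expect_error(wall_material(-1), "positive")
  expect_error(wall_material(3e5, poisson_ratio = 0.7), "0.5")
  expect_error(wall_material(3e5, behavior = "strain_softening",
                             softening_curve = function(e) 3e5 * (1 + e)),
               "non-increasing")
  expect_error(wall_material(3e5, behavior = "strain_softening",
                             softening_curve = function(e) 2e5 - 0 * e),
               "equal E0")
})

test_that("chamber pressures keep the transmural identity exactly", {
  cp <- chamber_pressures(95, 80)
  expect_identical(cp$tp, 15)
  expect_identical(chamber_pressures(80)$tp, 0)
  lv <- chamber_pressures(40, 40)
  expect_identical(lv$tp, 0)
})

test_that("the mmHg/Pa boundary uses the single conversion constant", {
  expect_equal(mmhg_to_pa(1), 133.322)
  expect_equal(pa_to_mmhg(mmhg_to_pa(77.3)), 77.3, tolerance = 1e-12)
})
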