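test_that("end-effect correction matches hand-evaluated values and limits", {
  # nu(2) = 0.312 + 0.565/2 - 0.100/4
  expect_equal(end_correction(2), 0.5695, tolerance = 1e-12)
  # nu(67/3) evaluated by hand: 0.312 + 0.565*3/67 - 0.100*9/4489
  expect_equal(end_correction(67 / 3), 0.3370980174, tolerance = 1e-8)
  # constant term dominates at large p
  expect_equal(end_correction(1e9), 0.312, tolerance = 1e-8)
  expect_error(end_correction(0.5), "axial ratio")
})

test_that("nu stays within its bounded range over the validity domain", {
  p <- seq(2, 30, by = 0.25)
  nu <- end_correction(p)
  expect_true(all(nu > 0.312))
  expect_true(all(nu <= 0.570))
})

test_that("forward rod model reproduces the regime boundary and printed range", {
  # L = 2d: the sphere/rod boundary, ~1.04e-10 m^2/s for d = 3 nm in RT water
  expect_equal(rod_diffusion(6, 3), 1.04e-10, tolerance = 0.02)
  # L = 67 nm evaluates at the low end of the measured wire range (~0.25e-10)
  expect_equal(rod_diffusion(67, 3), 2.522e-11, tolerance = 1e-3)
  # D is inversely proportional to viscosity
  thick <- solvent_conditions(viscosity_Pa_s = 2 * 8.90e-4)
  expect_equal(rod_diffusion(20, 3, thick), rod_diffusion(20, 3) / 2,
               tolerance = 1e-12)
  expect_error(rod_diffusion(5, 3), "sphere_diffusion")
  expect_warning(rod_diffusion(100, 3), "validity")
})

test_that("rod diffusion is strictly decreasing in length at fixed diameter", {
  L <- seq(6, 90, by = 0.5)  # p in [2, 30]
  D <- rod_diffusion(L, 3)
  expect_true(all(diff(D) < 0))
})

test_that("rod inversion is the exact inverse of the forward model", {
  for (L in c(6, 20, 50, 90)) {
    D <- rod_diffusion(L, 3)
    expect_equal(invert_rod_diffusion(D, 3)$length_nm, L, tolerance = 1e-6)
  }
})

test_that("rod inversion agrees with a dense grid-search oracle", {
  grid <- seq(6, 120, by = 0.01)  # deliberately spans past p = 30
  Dgrid <- suppressWarnings(rod_diffusion(grid, 3))
  for (dt in c(0.33e-10, 0.44e-10, 0.25e-10)) {
    oracle <- grid[which.min(abs(Dgrid - dt))]
    expect_lt(abs(invert_rod_diffusion(dt, 3)$length_nm - oracle), 0.011)
  }
})

test_that("inversion flags out-of-validity lengths and rejects fast species", {
  slow <- rod_diffusion(93.1, 3) |> suppressWarnings()  # p = 31.03
  inv <- invert_rod_diffusion(slow, 3)
  expect_gt(inv$axial_ratio, 30)
  expect_match(inv$flags, "validity", all = FALSE)
  # short wires carry no flag
  expect_length(invert_rod_diffusion(0.33e-10, 3)$flags, 0)
  # diffusion above the boundary cannot be a rod
  expect_error(invert_rod_diffusion(1.2e-10, 3), "sphere")
})

test_that("Stokes-Einstein sphere model and its closed-form inverse agree", {
  # R = 1 nm at defaults: kB*298.15/(6*pi*8.9e-4*1e-9)
  expect_equal(sphere_diffusion(1), 2.4537e-10, tolerance = 1e-4)
  # the fast dimeric building block (D_t = 1.55e-10) is a ~1.6 nm sphere
  expect_equal(invert_sphere_diffusion(1.55e-10), 1.583, tolerance = 1e-3)
  for (R in c(0.5, 1.6, 5)) {
    expect_equal(invert_sphere_diffusion(sphere_diffusion(R)), R,
                 tolerance = 1e-12)
  }
})

test_that("regime classification separates wires, building blocks and overlong rods", {
  expect_identical(classify_regime(0.33e-10, 3), "rod")
  expect_identical(classify_regime(1.55e-10, 3), "sphere")
  d31 <- suppressWarnings(rod_diffusion(93, 3))  # L/d = 31
  expect_identical(classify_regime(d31, 3), "out_of_validity")
})

test_that("the classifier boundary equals the forward model at L = 2d", {
  b <- regime_boundary(3)
  expect_identical(b, rod_diffusion(6, 3))
  expect_identical(classify_regime(b, 3), "sphere")
  expect_identical(classify_regime(b * 0.999, 3), "rod")
})

test_that("solvent conditions validate their inputs", {
  expect_error(solvent_conditions(-1), "temperature")
  expect_error(solvent_conditions(298, 0), "viscosity")
})
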