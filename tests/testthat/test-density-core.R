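test_that("water density table is exact at anchors and interpolates between", {
  expect_equal(water_density_at(20), 0.9982)
  expect_equal(water_density_at(30), 0.9957)
  expect_equal(water_density_at(4), 1.0000)
  # linear between anchors
  expect_equal(water_density_at(25), (0.9982 + 0.9957) / 2)
  expect_error(water_density_at(-1), "range")
  expect_error(water_density_at(41), "range")
})

test_that("gravity <-> density conversions scale by water density and invert", {
  expect_equal(density_from_gravity(1.0, 0.9982), 0.9982)
  expect_equal(density_from_gravity(0.2, 0.9982), 0.19964)
  # moving from 20 to 30 degrees C shifts Db by Gb * (-0.0025)
  expect_equal(density_from_gravity(0.2, 0.9957) - density_from_gravity(0.2, 0.9982),
               -0.0005)
  expect_equal(gravity_from_density(0.9982, 0.9982), 1.0)
  expect_equal(gravity_from_density(0.19964, 0.9982), 0.2)
  expect_equal(gravity_from_density(0.530, 0.9982), 0.530 / 0.9982)
  # roundtrip on a grid
  gb <- seq(0.05, 1.0, by = 0.05)
  expect_equal(gravity_from_density(density_from_gravity(gb), 0.9982), gb)
  expect_error(density_from_gravity(0), "positive")
  expect_error(gravity_from_density(-0.1), "positive")
})

test_that("ambient density from gravity follows the shrinkage model and is continuous", {
  expect_equal(density_at_moisture(0.5, 50), 0.75)          # no shrink branch
  expect_equal(density_at_moisture(0.5, 30), 0.65)          # boundary, both branches
  expect_equal(density_at_moisture(0.5, 0), 0.5 / (1 - 0.265 * 0.5))
  # continuity at the fiber-saturation point for a sweep of gravities
  for (gb in seq(0.1, 1.0, by = 0.1)) {
    below <- density_at_moisture(gb, 30 - 1e-9)
    above <- density_at_moisture(gb, 30 + 1e-9)
    expect_equal(below, above, tolerance = 1e-7)
    expect_equal(density_at_moisture(gb, 30), gb * 1.3)
  }
  expect_error(density_at_moisture(1.2, 10), "Gb")
  expect_error(density_at_moisture(0.5, 250), "200")
})

test_that("published and derivation-consistent conversions differ by 29466/29946", {
  expect_equal(round(basic_from_ambient(0.5, 12, params_published), 3), 0.409)
  expect_equal(basic_from_ambient(0.5, 12, params_derivation),
               eq1_literal(0.5, 12, numerator = 29946))
  grid <- expand.grid(Dw = seq(0.05, 1.2, by = 0.05), w = 0:30)
  pub <- basic_from_ambient(grid$Dw, grid$w, params_published)
  der <- basic_from_ambient(grid$Dw, grid$w, params_derivation)
  expect_equal(pub, eq1_literal(grid$Dw, grid$w), tolerance = 1e-12)
  expect_equal(pub / der, rep(29466 / 29946, nrow(grid)), tolerance = 1e-12)
})

test_that("piecewise moisture model applies the exact no-shrink inverse from the boundary up", {
  p_pub_pw <- conversion_params(moisture_model = "piecewise_fiber_saturation")
  # boundary value is the same in both numerator modes under piecewise
  expect_equal(basic_from_ambient(0.65, 30, p_pub_pw), 0.9982 * 0.65 / 1.3)
  expect_equal(basic_from_ambient(0.65, 30, params_exact_piecewise),
               0.9982 * 0.65 / 1.3)
  expect_equal(basic_from_ambient(0.75, 50, params_exact_piecewise),
               0.9982 * 0.75 / 1.5)
  # below the boundary the closed form applies
  expect_equal(basic_from_ambient(0.5, 12, params_exact_piecewise),
               basic_from_ambient(0.5, 12, params_derivation))
})

test_that("forward model then conversion recovers Gb * water density to 1e-10", {
  grid <- expand.grid(gb = seq(0.05, 0.95, by = 0.05),
                      w = c(0, 1, 5, 12, 29.9, 30, 45, 90, 150, 200))
  dw <- density_at_moisture(grid$gb, grid$w)
  back <- basic_from_ambient(dw, grid$w, params_exact_piecewise)
  expect_equal(back, grid$gb * 0.9982, tolerance = 1e-10)
})

test_that("bisection oracle matches the closed form", {
  expect_equal(solve_basic_by_bisection(0.75, 50), 0.9982 * 0.75 / 1.5,
               tolerance = 1e-8)
  expect_equal(solve_basic_by_bisection(0.5, 12),
               basic_from_ambient(0.5, 12, params_derivation),
               tolerance = 1e-8)
  w0_dw <- 0.5 / (1 - 0.265 * 0.5)   # ambient density of Gb = 0.5 oven dry
  expect_equal(solve_basic_by_bisection(w0_dw, 0), 0.5 * 0.9982,
               tolerance = 1e-8)
  withr::with_seed(42, {
    dw <- runif(1000, 0.05, 1.2)
    w <- runif(1000, 0, 200)
  })
  expect_equal(solve_basic_by_bisection(dw, w),
               basic_from_ambient(dw, w, params_exact_piecewise),
               tolerance = 1e-8)
  expect_error(solve_basic_by_bisection(5, 0), "bracket")
})

test_that("basic density is monotone in ambient density and in moisture", {
  w <- 12
  dw <- seq(0.05, 1.6, by = 0.05)
  db <- basic_from_ambient(dw, w, params_derivation)
  expect_true(all(diff(db) > 0))
  # decreasing in w while 3 - 10 * s * Dw stays positive (Dw < 1.13)
  for (dwi in c(0.1, 0.5, 1.0, 1.12)) {
    db_w <- basic_from_ambient(dwi, seq(0, 30, by = 1), params_derivation)
    expect_true(all(diff(db_w) < 0))
  }
})

test_that("slope sensitivity reproduces the printed figures and ignores water density", {
  expect_equal(round(slope_sensitivity(0.1, 12, 1.2), 1), -0.3)
  expect_equal(round(slope_sensitivity(1.6, 12, 1.2), 1), -3.6)
  expect_equal(slope_sensitivity(0.7, 25, 1.0), 0)
  for (rho in c(0.9957, 0.9982, 1.0)) {
    p <- conversion_params(water_density = rho)
    expect_equal(slope_sensitivity(0.1, 12, 1.2, p),
                 slope_sensitivity(0.1, 12, 1.2), tolerance = 1e-12)
    expect_equal(slope_sensitivity(1.6, 12, 1.2, p),
                 slope_sensitivity(1.6, 12, 1.2), tolerance = 1e-12)
  }
  expect_error(slope_sensitivity(0.5, 12, 0), "positive")
})

test_that("conversion parameters validate their domains", {
  expect_error(conversion_params(shrinkage_slope = 1.2), "shrinkage_slope")
  expect_error(conversion_params(water_density = 0.5), "water_density")
  expect_error(conversion_params(fiber_saturation_pct = -1),
               "fiber_saturation_pct")
  expect_s3_class(conversion_params(), "conversion_params")
})
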