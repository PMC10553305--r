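test_that("surface turbulent velocity reproduces the published wind pairs", {
  expect_equal(surface_turbulent_velocity(wind_forcing(0.80)), 0.0288,
               tolerance = 1e-12)
  expect_equal(round(surface_turbulent_velocity(wind_forcing(0.80)), 2),
               0.03)
  expect_equal(round(surface_turbulent_velocity(wind_forcing(1.12)), 2),
               0.04)
  expect_identical(surface_turbulent_velocity(wind_forcing(0)), 0)
  p <- turbulence_params(w0 = 0.03)
  expect_identical(surface_turbulent_velocity(wind_forcing(5), p), 0.03)
  expect_error(wind_forcing(-1), "non-negative")
})

test_that("k = w^2 and its round-trip inverse hold", {
  expect_equal(tke_from_w(0.03), 9e-4)
  expect_identical(tke_from_w(0), 0)
  w <- stats::runif(20, 0, 0.2)
  expect_equal(sqrt(tke_from_w(w)), w, tolerance = 1e-14)
})

test_that("dissipation closure scales cubically and hits the surface value", {
  expect_equal(dissipation_rate(0.03), 1e-4, tolerance = 1e-3)
  expect_identical(dissipation_rate(0), 0)
  expect_equal(dissipation_rate(0.06) / dissipation_rate(0.03), 8,
               tolerance = 1e-12)
})

test_that("profiles decay exponentially to near zero at the bottom", {
  prof <- turbulence_profile(wind_forcing(0.8, "June"))
  expect_equal(prof$z, seq(0, 1.5, by = 0.01))
  expect_true(all(diff(prof$w) < 0))
  expect_true(all(diff(prof$k) < 0))
  expect_true(all(diff(prof$eps) < 0))
  expect_true(all(prof$w >= 0))
  n <- nrow(prof)
  expect_lt(prof$w[n], 0.05 * prof$w[1])
  # log w is affine in z with slope -1/lambda
  slopes <- diff(log(prof$w)) / diff(prof$z)
  expect_equal(slopes, rep(-1 / 0.25, n - 1), tolerance = 1e-9)
  expect_equal(prof$w[n] / prof$w[1], exp(-1.5 / 0.25), tolerance = 1e-12)
})

test_that("stronger wind dominates pointwise and zero wind is identically zero", {
  p1 <- turbulence_profile(wind_forcing(0.8))
  p2 <- turbulence_profile(wind_forcing(1.12))
  expect_true(all(p2$w >= p1$w))
  expect_true(all(p2$k >= p1$k))
  expect_true(all(p2$eps >= p1$eps))
  p0 <- turbulence_profile(wind_forcing(0))
  expect_true(all(p0$w == 0) && all(p0$k == 0) && all(p0$eps == 0))
})

test_that("parameter validation catches bad grids and values", {
  expect_error(turbulence_params(alpha_w = 0), "positive")
  expect_error(turbulence_profile(wind_forcing(1),
                                  turbulence_params(dz = 2, z_max = 1.5)),
               "grid")
})
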