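chae <- swimmer("chaetognath", 0.04, 0.02)
luc <- swimmer("luciferid", 0.016, 0.02)

test_that("stationary-prey limit is the swept-cylinder rate pi R^2 N y", {
  fld <- particle_field(13500)
  expect_identical(gs_rate(chae, fld), pi * 0.02^2 * 13500 * 0.04)
  expect_identical(gs_rate(luc, fld), pi * 0.02^2 * 13500 * 0.016)
  # published chaetognath / luciferid surface rates at the June mean
  expect_equal(per_hour(gs_rate(chae, fld)), 2442.902, tolerance = 1e-6)
  expect_equal(per_hour(gs_rate(luc, fld)), 977.161, tolerance = 1e-6)
})

test_that("symmetric-speed closed form is (4/3) pi R^2 N v", {
  for (v in c(0.01, 0.04, 0.3)) {
    sw <- swimmer("s", v, 0.015)
    fld <- particle_field(5000, speed = v)
    expect_equal(gs_rate(sw, fld), 4 / 3 * pi * 0.015^2 * 5000 * v,
                 tolerance = 1e-12)
  }
})

test_that("the general bracket is continuous across the stationary tolerance", {
  fld_just_moving <- particle_field(13500, speed = 2e-12)
  fld_still <- particle_field(13500, speed = 1e-13)
  expect_equal(gs_rate(chae, fld_just_moving), gs_rate(chae, fld_still),
               tolerance = 1e-9)
})

test_that("rates are linear in N and quadratic in R", {
  base <- gs_rate(chae, particle_field(1000))
  expect_identical(gs_rate(chae, particle_field(2000)), 2 * base)
  big <- swimmer("big", 0.04, 0.04)
  expect_equal(gs_rate(big, particle_field(1000)), 4 * base,
               tolerance = 1e-12)
  expect_identical(gs_rate(chae, particle_field(0)), 0)
})

test_that("degenerate and invalid inputs are rejected", {
  still <- swimmer("still", 0, 0.02)
  expect_error(gs_rate(still, particle_field(100)), "degenerate")
  expect_identical(gs_rate(still, particle_field(0)), 0)
  expect_error(swimmer("a", -1, 0.02), "non-negative")
  expect_error(swimmer("a", 0.1, 0), "positive")
  expect_error(particle_field(-5), "non-negative")
  expect_error(effective_speed(-0.1, 0), "non-negative")
})

test_that("effective speed follows the Pythagorean substitution", {
  expect_equal(effective_speed(0.03, 0.04), 0.05)
  expect_identical(effective_speed(0.07, 0), 0.07)
  expect_identical(effective_speed(0, 0.02), 0.02)
})

test_that("RO rate dominates GS, reduces to it at w = 0, and is continuous", {
  fld <- particle_field(13500)
  expect_identical(ro_rate(chae, fld, w = 0), gs_rate(chae, fld))
  for (w in c(1e-12, 1e-4, 0.01, 0.03, 0.1))
    expect_gte(ro_rate(chae, fld, w), gs_rate(chae, fld))
  expect_equal(ro_rate(chae, fld, w = 1e-12), gs_rate(chae, fld),
               tolerance = 1e-9)
})

test_that("turbulence multiplier matches direct RO/GS evaluation", {
  expect_equal(turbulence_multiplier(y = 0.04, w = 0.03), 1.4,
               tolerance = 1e-6)
  expect_equal(turbulence_multiplier(y = 0.016, w = 0.03), 2.676471,
               tolerance = 1e-6)
  expect_equal(turbulence_multiplier(y = 0.062, w = 0.03), 1.181166,
               tolerance = 1e-6)
  expect_identical(turbulence_multiplier(y = 0.05, x = 0.01, w = 0), 1)
  fld <- particle_field(4200)
  expect_equal(turbulence_multiplier(y = 0.016, w = 0.04),
               ro_rate(luc, fld, 0.04) / gs_rate(luc, fld),
               tolerance = 1e-12)
})

test_that("multiplier is invariant under R and N and monotone in w", {
  set.seed(99)
  ref <- turbulence_multiplier(y = 0.03, x = 0.005, w = 0.02)
  for (i in 1:25) {
    R <- stats::runif(1, 1e-4, 0.1); N <- stats::runif(1, 1, 1e5)
    sw <- swimmer("s", 0.03, R); fld <- particle_field(N, 0.005)
    expect_equal(ro_rate(sw, fld, 0.02) / gs_rate(sw, fld), ref,
                 tolerance = 1e-10)
  }
  ws <- seq(0, 0.1, by = 0.005)
  mults <- vapply(ws, function(w) turbulence_multiplier(y = 0.04, w = w),
                  numeric(1))
  expect_true(all(diff(mults) >= 0))
  expect_true(all(mults >= 1))
})

test_that("taxon registry holds the three taxa with published parameters", {
  reg <- taxon_registry()
  expect_named(reg, c("copepod", "chaetognath", "luciferid"))
  expect_equal(reg$chaetognath$speed, 0.04)
  expect_equal(reg$chaetognath$radius, 0.02)
  expect_equal(reg$luciferid$speed, 0.016)
  expect_equal(reg$luciferid$radius, 0.02)
  expect_equal(reg$copepod$radius, 4e-4)
  expect_equal(reg$copepod$speed, 0.062)
  expect_equal(taxon_registry(copepod_speed = "literal")$copepod$speed,
               0.0062)
  expect_error(get_taxon("krill"), "unknown taxon")
})

test_that("unit conversions are exact", {
  expect_identical(per_hour(0.5), 1800)
  expect_identical(to_density(13.5), 13500)
  expect_identical(to_density(0), 0)
  expect_error(to_density(-1), "non-negative")
})
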