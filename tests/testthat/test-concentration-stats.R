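chae <- swimmer("chaetognath", 0.04, 0.02)
rate_fn <- function(N) per_hour(gs_rate(chae, particle_field(N)))

test_that("station tables load, validate, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,particles_per_L", "A,5"), f)
  st <- load_stations(f)
  expect_s3_class(st, "station_set")
  expect_equal(st$concentrations, 5)

  ten <- station_set(c(7, 8, 9, 11, 12, 13, 14, 16, 19, 26), "june-like")
  write_stations(ten, f)
  back <- load_stations(f)
  expect_equal(back$concentrations, ten$concentrations)
  expect_equal(back$station_ids, ten$station_ids)

  writeLines("station_id,particles_per_L", f)
  expect_error(load_stations(f), "no station rows")
  writeLines(c("station_id,conc", "A,5"), f)
  expect_error(load_stations(f), "particles_per_L")
  writeLines(c("station_id,particles_per_L", "A,5", "B,-2", "C,x"), f)
  expect_error(load_stations(f), "line\\(s\\) 2, 3")
  expect_error(station_set(numeric(0)), "non-empty")
  expect_error(station_set(c(1, -1)), "non-negative")
})

test_that("bootstrap of a constant station set is exact with zero SD", {
  st <- station_set(rep(4, 6))
  res <- bootstrap_rate(st, rate_fn, bootstrap_config(n_reps = 50, seed = 1))
  expect_equal(res$mean_rate, rate_fn(4000))
  expect_identical(res$sd_rate, 0)
})

test_that("bootstrap is reproducible under seed and differs across seeds", {
  st <- station_set(c(7, 9, 14, 21, 26))
  a <- bootstrap_rate(st, rate_fn, bootstrap_config(200, seed = 7))
  b <- bootstrap_rate(st, rate_fn, bootstrap_config(200, seed = 7))
  expect_identical(a$rates, b$rates)
  d <- bootstrap_rate(st, rate_fn, bootstrap_config(200, seed = 8))
  expect_false(identical(a$rates, d$rates))
  expect_gt(a$sd_rate, 0)
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  invisible(bootstrap_rate(station_set(c(1, 2, 3)), rate_fn,
                           bootstrap_config(50, seed = 5)))
  expect_identical(stats::runif(1), before)
})

test_that("for a linear rate the bootstrap mean converges to the rate at the sample mean", {
  st <- station_set(c(7, 8, 10, 12, 13, 14, 15, 17, 19, 20))
  res <- bootstrap_rate(st, rate_fn, bootstrap_config(1e4, seed = 3))
  expect_equal(res$mean_rate, rate_fn(to_density(mean(st$concentrations))),
               tolerance = 0.01)
})

test_that("scaling all concentrations scales a linear bootstrap mean", {
  st1 <- station_set(c(2, 5, 9, 11))
  st3 <- station_set(3 * c(2, 5, 9, 11))
  cfg <- bootstrap_config(500, seed = 11)
  r1 <- bootstrap_rate(st1, rate_fn, cfg)
  r3 <- bootstrap_rate(st3, rate_fn, cfg)
  expect_equal(r3$mean_rate, 3 * r1$mean_rate, tolerance = 1e-12)
})

test_that("single-draw mode keeps the mean but inflates the SD", {
  st <- station_set(c(1, 5, 9, 13, 22))
  mean_mode <- bootstrap_rate(st, rate_fn, bootstrap_config(5000, seed = 2))
  single <- bootstrap_rate(st, rate_fn,
                           bootstrap_config(5000, seed = 2, mode = "single"))
  expect_equal(single$mean_rate, mean_mode$mean_rate, tolerance = 0.05)
  expect_gt(single$sd_rate, mean_mode$sd_rate)
})

test_that("configuration validation rejects nonsense", {
  expect_error(bootstrap_config(n_reps = 0), "positive")
  expect_error(bootstrap_config(resample_size = 0), "positive")
})
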