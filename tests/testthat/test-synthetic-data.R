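test_that("generated sets honour the requested summaries and range", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    lo <- stats::runif(1, 0, 5)
    hi <- lo + stats::runif(1, 5, 30)
    m <- stats::runif(1, lo + 0.35 * (hi - lo), hi - 0.35 * (hi - lo))
    s <- stats::runif(1, 0.05, 0.35) * (hi - lo)
    spec <- station_spec(n, m, s, lo, hi, seed = i)
    st <- generate_stations(spec)
    expect_length(st$concentrations, n)
    expect_true(all(st$concentrations >= lo - 1e-12))
    expect_true(all(st$concentrations <= hi + 1e-12))
    expect_lte(abs(mean(st$concentrations) - m), 0.05 * m)
    expect_lte(abs(stats::sd(st$concentrations) - s), 0.15 * s)
  }
})

test_that("generation is deterministic under seed and varies across seeds", {
  spec1 <- station_spec(10, 13.5, 7.1, 7, 26, seed = 5)
  expect_identical(generate_stations(spec1)$concentrations,
                   generate_stations(spec1)$concentrations)
  spec2 <- station_spec(10, 13.5, 7.1, 7, 26, seed = 6)
  expect_false(identical(generate_stations(spec1)$concentrations,
                         generate_stations(spec2)$concentrations))
})

test_that("alternative base distributions also meet the tolerances", {
  for (d in c("scaled-beta", "integer-uniform-adjusted")) {
    st <- generate_stations(station_spec(12, 10, 4, 0, 25,
                                         distribution = d, seed = 3))
    expect_lte(abs(mean(st$concentrations) - 10), 0.5)
    expect_lte(abs(stats::sd(st$concentrations) - 4), 0.6)
  }
})

test_that("degenerate and infeasible specs are detected, not looped on", {
  st <- generate_stations(station_spec(5, 3, 0, 3, 3, seed = 1))
  expect_equal(st$concentrations, rep(3, 5))
  expect_no_error(station_spec(5, 3, 1, 3, 3))  # constructible ...
  expect_error(generate_stations(station_spec(5, 3, 1, 3, 3)),
               "degenerate range")  # ... but infeasible to generate
  # SD larger than any arrangement in [0, 10] with mean 5 can achieve
  expect_error(generate_stations(station_spec(10, 5, 8, 0, 10)),
               "infeasible")
  expect_error(station_spec(1, 5, 1, 0, 10), "n_stations")
  expect_error(station_spec(5, 11, 1, 0, 10), "min_val <= target_mean")
})

test_that("packaged fixtures match the published season summaries", {
  fx <- packaged_fixtures()
  expect_named(fx, c("june", "october"))
  sj <- summary(fx$june)
  expect_equal(sj[["n"]], 10)
  expect_gte(sj[["mean"]], 12.8); expect_lte(sj[["mean"]], 14.2)
  expect_lte(abs(sj[["sd"]] - 7.1), 0.15 * 7.1)
  expect_gte(sj[["min"]], 7); expect_lte(sj[["max"]], 26)
  so <- summary(fx$october)
  expect_equal(so[["n"]], 7)
  expect_lte(abs(so[["mean"]] - 2), 0.1)
  expect_gte(so[["min"]], 0); expect_lte(so[["max"]], 6)
})

test_that("fixtures round-trip through the station reader unchanged", {
  fx <- packaged_fixtures()
  f <- withr::local_tempfile(fileext = ".csv")
  write_stations(fx$june, f)
  expect_equal(load_stations(f)$concentrations, fx$june$concentrations)
})
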