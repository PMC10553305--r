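#' Specification of a synthetic station concentration set
#'
#' The surveys report only summary statistics of the per-station
#' microplastic concentrations (n, mean, SD, range), not the station
#' values themselves. A station spec describes such a summary so that
#' [generate_stations()] can draw a concrete, reproducible station set
#' consistent with it.
#'
#' @param n_stations Number of stations (>= 2).
#' @param target_mean Target sample mean, particles L\eqn{^{-1}}.
#' @param target_sd Target sample SD, particles L\eqn{^{-1}}.
#' @param min_val,max_val Admissible concentration range (min >= 0,
#'   min <= mean <= max).
#' @param distribution Base distribution drawn before moment adjustment:
#'   \code{"truncated-normal"} (default), \code{"scaled-beta"}, or
#'   \code{"integer-uniform-adjusted"}.
#' @param seed Integer seed.
#' @return An object of class \code{"station_spec"}.
#' @export
station_spec <- function(n_stations, target_mean, target_sd, min_val,
                         max_val,
                         distribution = c("truncated-normal", "scaled-beta",
                                          "integer-uniform-adjusted"),
                         seed = 42) {
  distribution <- match.arg(distribution)
  if (n_stations < 2) stop("'n_stations' must be >= 2", call. = FALSE)
  if (min_val < 0) stop("'min_val' must be >= 0", call. = FALSE)
  if (min_val > target_mean || target_mean > max_val)
    stop("need min_val <= target_mean <= max_val", call. = FALSE)
  if (target_sd < 0) stop("'target_sd' must be >= 0", call. = FALSE)
  structure(list(n_stations = as.integer(n_stations),
                 target_mean = target_mean, target_sd = target_sd,
                 min_val = min_val, max_val = max_val,
                 distribution = distribution, seed = as.integer(seed)),
            class = "station_spec")
}

# Largest sample SD attainable for n values in [lo, hi] with the given
# mean: put mass at the two endpoints. Used for feasibility screening.
.max_sd_in_range <- function(n, mean, lo, hi) {
  if (hi == lo) return(0)
  p <- (mean - lo) / (hi - lo)
  # population bound scaled to sample-SD (divisor n-1) convention
  sqrt(p * (1 - p)) * (hi - lo) * sqrt(n / (n - 1))
}

#' Generate a synthetic station concentration set
#'
#' Draws \code{n_stations} non-negative concentrations whose sample mean
#' is within 5\% of \code{target_mean} and sample SD within 15\% of
#' \code{target_sd}, all inside \code{[min_val, max_val]}. Strategy:
#' draw from the base distribution, affine-adjust to the exact target
#' moments, clip to the range, and accept if the clipped sample still
#' meets the tolerances; otherwise redraw, up to \code{max_attempts}
#' times. Deterministic under \code{spec$seed}.
#'
#' @param spec A [station_spec()].
#' @param max_attempts Rejection-loop cap (default 1000).
#' @return A [station_set()] labelled with the spec's distribution/seed.
#' @examples
#' generate_stations(station_spec(10, 13.5, 7.1, 7, 26, seed = 1))
#' @export
generate_stations <- function(spec, max_attempts = 1000) {
  stopifnot(inherits(spec, "station_spec"))
  n <- spec$n_stations
  lo <- spec$min_val; hi <- spec$max_val
  if (lo == hi) {
    if (spec$target_sd > 0)
      stop("infeasible spec: degenerate range [", lo, ", ", hi,
           "] cannot achieve sd > 0", call. = FALSE)
    return(station_set(rep(lo, n), season_label = "synthetic",
                       station_ids = sprintf("SYN%02d", seq_len(n))))
  }
  if (spec$target_sd > .max_sd_in_range(n, spec$target_mean, lo, hi))
    stop("infeasible spec: target_sd = ", spec$target_sd,
         " exceeds the maximum SD attainable for n = ", n,
         " values in [", lo, ", ", hi, "] with mean ", spec$target_mean,
         " (", signif(.max_sd_in_range(n, spec$target_mean, lo, hi), 4), ")",
         call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)

  draw <- switch(spec$distribution,
    "truncated-normal" = function() {
      x <- stats::rnorm(n, spec$target_mean, max(spec$target_sd, 1e-12))
      pmin(pmax(x, lo), hi)
    },
    "scaled-beta" = function() {
      m <- (spec$target_mean - lo) / (hi - lo)
      v <- min((spec$target_sd / (hi - lo))^2, m * (1 - m) * 0.99)
      conc <- m * (1 - m) / max(v, 1e-8) - 1
      lo + (hi - lo) * stats::rbeta(n, m * conc, (1 - m) * conc)
    },
    "integer-uniform-adjusted" = function() {
      sample(seq(floor(lo), ceiling(hi)), n, replace = TRUE)
    })

  for (attempt in seq_len(max_attempts)) {
    x <- draw()
    s <- stats::sd(x)
    if (s > 0)  # affine-adjust to the exact target moments, then clip
      x <- spec$target_mean + (x - mean(x)) * spec$target_sd / s
    x <- pmin(pmax(x, lo), hi)
    ok_mean <- abs(mean(x) - spec$target_mean) <= 0.05 * spec$target_mean
    ok_sd <- if (spec$target_sd == 0) stats::sd(x) < 1e-9 else
      abs(stats::sd(x) - spec$target_sd) <= 0.15 * spec$target_sd
    if (ok_mean && ok_sd)
      return(station_set(x, season_label = "synthetic",
                         station_ids = sprintf("SYN%02d", seq_len(n))))
  }
  stop("could not generate a station set meeting the spec within ",
       max_attempts, " attempts (target mean ", spec$target_mean, " +/- 5%, ",
       "sd ", spec$target_sd, " +/- 15%, range [", lo, ", ", hi, "]); ",
       "the spec is likely near-infeasible", call. = FALSE)
}

#' Published survey summaries behind the packaged fixtures
#'
#' The June survey found microplastics at all 10 stations, 7-26
#' particles/L (mean 13.5, SD 7.1); the October survey retained 7 intact
#' samples, 0-6 particles/L (mean 2, SD 1.7).
#'
#' @return Named list of [station_spec()]s for \code{"june"} and
#'   \code{"october"}.
#' @export
season_specs <- function() {
  list(
    june = station_spec(10, target_mean = 13.5, target_sd = 7.1,
                        min_val = 7, max_val = 26, seed = 2018L),
    october = station_spec(7, target_mean = 2, target_sd = 1.7,
                           min_val = 0, max_val = 6, seed = 2019L)
  )
}

#' Packaged synthetic station fixtures
#'
#' Two frozen station sets shipped with the package
#' (\code{inst/extdata/june_stations_synthetic.csv},
#' \code{october_stations_synthetic.csv}). They are synthetic: generated
#' once by [generate_stations()] from the published summaries in
#' [season_specs()], since the surveys' per-station values were never
#' published. All default configurations and tests use them.
#'
#' @return Named list of [station_set()]s: \code{june} (n = 10) and
#'   \code{october} (n = 7).
#' @export
packaged_fixtures <- function() {
  files <- c(june = "june_stations_synthetic.csv",
             october = "october_stations_synthetic.csv")
  out <- lapply(names(files), function(season) {
    path <- system.file("extdata", files[[season]], package = "mpencounter",
                        mustWork = TRUE)
    load_stations(path, season_label = season)
  })
  names(out) <- names(files)
  out
}
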