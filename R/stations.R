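#' Per-station microplastic concentrations for one season
#'
#' The resampling population for the bootstrap: the set of surface
#' microplastic concentrations measured at the sampling stations of one
#' survey, in particles per liter.
#'
#' @param concentrations Numeric vector of per-station concentrations,
#'   particles L\eqn{^{-1}}; all >= 0, length >= 1.
#' @param season_label Free-text label.
#' @param station_ids Optional character vector of station labels.
#' @return An object of class \code{"station_set"}.
#' @examples
#' station_set(c(7, 10, 26), "demo")
#' @export
station_set <- function(concentrations, season_label = "",
                        station_ids = NULL) {
  if (!is.numeric(concentrations) || length(concentrations) < 1L)
    stop("'concentrations' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("all concentrations must be finite and non-negative", call. = FALSE)
  if (is.null(station_ids))
    station_ids <- sprintf("S%02d", seq_along(concentrations))
  if (length(station_ids) != length(concentrations))
    stop("'station_ids' must match 'concentrations' in length", call. = FALSE)
  structure(list(season_label = season_label,
                 concentrations = as.numeric(concentrations),
                 station_ids = as.character(station_ids)),
            class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<station_set> %s: n = %d stations, %g-%g part/L (mean %.3g, sd %.3g)\n",
    if (nzchar(x$season_label)) x$season_label else "unlabelled",
    s[["n"]], s[["min"]], s[["max"]], s[["mean"]], s[["sd"]]))
  invisible(x)
}

#' @export
summary.station_set <- function(object, ...) {
  c(n = length(object$concentrations),
    mean = mean(object$concentrations),
    sd = stats::sd(object$concentrations),
    min = min(object$concentrations),
    max = max(object$concentrations))
}

#' Read a station concentration table
#'
#' Expects a delimited text file with a header containing at least the
#' columns \code{station_id} and \code{particles_per_L} (extra columns
#' such as \code{lat}/\code{lon} are ignored). Malformed values are
#' reported with their line numbers.
#'
#' @param path Path to the file.
#' @param season_label Label to attach; defaults to the file name.
#' @param sep Field separator (default comma).
#' @return A [station_set()].
#' @export
load_stations <- function(path, season_label = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("station_id", "particles_per_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("'", path, "' contains no station rows", call. = FALSE)
  conc <- suppressWarnings(as.numeric(df$particles_per_L))
  bad <- which(!is.finite(conc) | conc < 0)
  if (length(bad))
    stop("'", path, "' has invalid particles_per_L values on data line(s) ",
         paste(bad, collapse = ", "),
         " (file line(s) ", paste(bad + 1L, collapse = ", "),
         "): values must be non-negative numbers", call. = FALSE)
  station_set(conc,
              season_label = if (is.null(season_label))
                tools::file_path_sans_ext(basename(path)) else season_label,
              station_ids = as.character(df$station_id))
}

#' Write a station concentration table
#'
#' Inverse of [load_stations()]: writes the standard two-column CSV.
#'
#' @param stations A [station_set()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_stations <- function(stations, path) {
  stopifnot(inherits(stations, "station_set"))
  df <- data.frame(station_id = stations$station_ids,
                   particles_per_L = stations$concentrations)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bootstrap configuration
#'
#' @param n_reps Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed for the pseudo-random stream (default 42).
#' @param resample_size Stations drawn per repetition; defaults to the
#'   number of observed stations (classical bootstrap).
#' @param mode \code{"mean"} (default): each repetition resamples
#'   \code{resample_size} stations with replacement and the rate is
#'   evaluated at the resample's mean density. \code{"single"}: each
#'   repetition draws one station and the rate is evaluated at that
#'   station's density (same mean for linear rates, larger SD).
#' @return An object of class \code{"bootstrap_config"}.
#' @export
bootstrap_config <- function(n_reps = 1000, seed = 42, resample_size = NULL,
                             mode = c("mean", "single")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1)
    stop("'n_reps' must be a positive integer", call. = FALSE)
  if (!is.null(resample_size) &&
      (!is.numeric(resample_size) || resample_size < 1))
    stop("'resample_size' must be a positive integer", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 resample_size = resample_size, mode = mode),
            class = "bootstrap_config")
}

#' Bootstrap resample densities
#'
#' Draws the bootstrap replicate densities that [bootstrap_rate()] and the
#' profile pipeline consume: \code{n_reps} densities (particles
#' m\eqn{^{-3}}), each the mean of a with-replacement resample of the
#' station concentrations (or a single station draw, depending on
#' \code{cfg$mode}), converted via [to_density()]. Reproducible under
#' \code{cfg$seed}; the caller's RNG state is left untouched.
#'
#' @param stations A [station_set()].
#' @param cfg A [bootstrap_config()].
#' @return Numeric vector of length \code{cfg$n_reps}.
#' @export
bootstrap_densities <- function(stations, cfg = bootstrap_config()) {
  stopifnot(inherits(stations, "station_set"),
            inherits(cfg, "bootstrap_config"))
  conc <- stations$concentrations
  m <- if (is.null(cfg$resample_size)) length(conc) else
    as.integer(cfg$resample_size)
  if (cfg$mode == "single") m <- 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(cfg$seed)
  idx <- matrix(sample.int(length(conc), cfg$n_reps * m, replace = TRUE),
                nrow = cfg$n_reps)
  to_density(rowMeans(matrix(conc[idx], nrow = cfg$n_reps)))
}

#' Bootstrap an encounter rate over station concentrations
#'
#' Repeatedly resamples the station set with replacement, evaluates the
#' supplied rate function at each resample's mean particle density, and
#' summarises the replicate rates by their mean and standard deviation
#' (population SD over the replicate set).
#'
#' @param stations A [station_set()].
#' @param rate_fn Function mapping density (particles m\eqn{^{-3}}) to a
#'   rate (any units; typically encounters h\eqn{^{-1}}). May be linear or
#'   nonlinear; must be vectorised over density or accept a vector.
#' @param cfg A [bootstrap_config()].
#' @return An object of class \code{"bootstrap_result"}: list with
#'   \code{mean_rate}, \code{sd_rate}, \code{n_reps}, \code{seed},
#'   \code{rates} (the replicate values).
#' @examples
#' st <- station_set(c(7, 12, 26), "demo")
#' chae <- swimmer("chaetognath", 0.04, 0.02)
#' bootstrap_rate(st, function(N) per_hour(gs_rate(chae, particle_field(N))),
#'                bootstrap_config(n_reps = 200, seed = 1))
#' @export
bootstrap_rate <- function(stations, rate_fn, cfg = bootstrap_config()) {
  stopifnot(is.function(rate_fn))
  dens <- bootstrap_densities(stations, cfg)
  rates <- vapply(dens, rate_fn, numeric(1))
  structure(list(mean_rate = mean(rates),
                 sd_rate = .pop_sd(rates),
                 n_reps = cfg$n_reps, seed = cfg$seed, rates = rates),
            class = "bootstrap_result")
}

# population SD: divisor n, matching "mean and SD of the repetition set"
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> mean = %.4g, sd = %.4g (%d reps, seed %d)\n",
              x$mean_rate, x$sd_rate, x$n_reps, x$seed))
  invisible(x)
}
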