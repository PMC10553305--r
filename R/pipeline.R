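#' Season scenario: stations + wind + turbulence settings
#'
#' Bundles everything one survey season contributes to the encounter
#' calculation. Bundled defaults exist for \code{"june"} (wind 0.80 m/s,
#' surface turbulent velocity pinned at 0.03 m/s) and \code{"october"}
#' (wind 1.12 m/s, 0.04 m/s), each with its packaged synthetic station
#' fixture.
#'
#' @param label Season label; \code{"june"} and \code{"october"} get
#'   bundled defaults, any other label requires explicit arguments.
#' @param stations A [station_set()]; default the packaged fixture.
#' @param U Mean wind speed, m s\eqn{^{-1}}; default 0.80 (June) or 1.12
#'   (October).
#' @param params A [turbulence_params()]; default pins \code{w0} at the
#'   published surface turbulent velocity for the bundled seasons.
#' @return An object of class \code{"season_scenario"}.
#' @examples
#' season_scenario("june")
#' @export
season_scenario <- function(label, stations = NULL, U = NULL, params = NULL) {
  key <- tolower(label)
  defaults <- list(june = list(U = 0.80, w0 = 0.03),
                   october = list(U = 1.12, w0 = 0.04))
  if (key %in% names(defaults)) {
    if (is.null(U)) U <- defaults[[key]]$U
    if (is.null(params)) params <- turbulence_params(w0 = defaults[[key]]$w0)
    if (is.null(stations)) stations <- packaged_fixtures()[[key]]
  }
  if (is.null(stations) || is.null(U))
    stop("scenario '", label, "' has no bundled defaults; supply 'stations'",
         " and 'U' explicitly", call. = FALSE)
  if (is.null(params)) params <- turbulence_params()
  stopifnot(inherits(stations, "station_set"),
            inherits(params, "turbulence_params"))
  structure(list(label = label, stations = stations,
                 forcing = wind_forcing(U, label), params = params),
            class = "season_scenario")
}

#' @export
print.season_scenario <- function(x, ...) {
  cat(sprintf("<season_scenario> %s: U = %g m/s, w0 = %.4g m/s, %d stations\n",
              x$label, x$forcing$U,
              surface_turbulent_velocity(x$forcing, x$params),
              length(x$stations$concentrations)))
  invisible(x)
}

#' Bootstrap encounter-rate depth profile for one taxon/season/model
#'
#' The package's central computation. For each depth on the turbulence
#' grid it evaluates the encounter rate of the taxon against the
#' bootstrap-resampled particle densities and records the mean and SD
#' over repetitions, in encounters per hour. Under the GS (calm) model
#' the profile is constant with depth (particle concentration is assumed
#' depth-independent and there is no turbulence term); under the RO model
#' the rate is boosted near the surface by the wind-induced turbulent
#' velocity \eqn{w(z)} and converges to the GS profile at depth as
#' \eqn{w \to 0}.
#'
#' One bootstrap draw sequence is shared across depths, so the profile is
#' smooth and the RO/GS ratio at each depth is free of resampling noise;
#' set \code{redraw_per_depth = TRUE} to redraw independently at every
#' depth instead.
#'
#' @param scenario A [season_scenario()] (or a season label with bundled
#'   defaults, e.g. \code{"june"}).
#' @param taxon Taxon label resolved through [taxon_registry()], or a
#'   [swimmer()].
#' @param model \code{"GS"} (calm) or \code{"RO"} (turbulent).
#' @param cfg A [bootstrap_config()].
#' @param redraw_per_depth Redraw the bootstrap at each depth (default
#'   FALSE).
#' @param ... Passed to [taxon_registry()] when \code{taxon} is a label
#'   (e.g. \code{copepod_speed}).
#' @return An object of class \code{"encounter_profile"}: list with
#'   \code{taxon}, \code{season}, \code{model}, \code{z} (depths, m),
#'   \code{mean} and \code{sd} (rates, h\eqn{^{-1}}), \code{w} (turbulent
#'   velocity used at each depth), and the bootstrap settings.
#' @examples
#' prof <- encounter_profile("june", "chaetognath", "GS",
#'                           bootstrap_config(n_reps = 200, seed = 7))
#' prof$mean[1]  # surface mean rate, particles per individual per hour
#' @export
encounter_profile <- function(scenario, taxon, model = c("GS", "RO"),
                              cfg = bootstrap_config(),
                              redraw_per_depth = FALSE, ...) {
  model <- match.arg(model)
  if (is.character(scenario)) scenario <- season_scenario(scenario)
  stopifnot(inherits(scenario, "season_scenario"))
  sw <- if (inherits(taxon, "swimmer")) taxon else get_taxon(taxon, ...)

  turb <- turbulence_profile(scenario$forcing, scenario$params)
  z <- turb$z
  w <- if (model == "GS") rep(0, length(z)) else turb$w

  dens <- bootstrap_densities(scenario$stations, cfg)
  rate_at <- function(dens_vec, wz) {
    # linear in N: evaluate the per-unit-density rate once
    unit <- .gs_rate_num(sw$radius, 1, effective_speed(0, wz),
                         effective_speed(sw$speed, wz))
    per_hour(unit * dens_vec)
  }
  mean_z <- numeric(length(z)); sd_z <- numeric(length(z))
  for (i in seq_along(z)) {
    if (redraw_per_depth) {
      cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
      dens_i <- bootstrap_densities(scenario$stations, cfg_i)
    } else dens_i <- dens
    rates <- rate_at(dens_i, w[i])
    mean_z[i] <- mean(rates); sd_z[i] <- .pop_sd(rates)
  }
  structure(list(taxon = sw$name, season = scenario$label, model = model,
                 z = z, mean = mean_z, sd = sd_z, w = w,
                 n_reps = cfg$n_reps, seed = cfg$seed,
                 stations = scenario$stations),
            class = "encounter_profile")
}

#' @export
print.encounter_profile <- function(x, ...) {
  cat(sprintf(
    "<encounter_profile> %s / %s / %s: surface %.4g +/- %.3g part ind^-1 h^-1 (%d depths, %d bootstrap reps)\n",
    x$season, x$taxon, x$model, x$mean[1], x$sd[1], length(x$z), x$n_reps))
  invisible(x)
}

#' @export
summary.encounter_profile <- function(object, ...) {
  data.frame(season = object$season, taxon = object$taxon,
             model = object$model,
             surface_mean = object$mean[1], surface_sd = object$sd[1],
             bottom_mean = object$mean[length(object$mean)],
             stringsAsFactors = FALSE)
}

#' @export
plot.encounter_profile <- function(x, ...) {
  graphics::matplot(cbind(x$mean, x$mean - x$sd, x$mean + x$sd), -x$z,
                    type = "l", lty = c(1, 3, 3), col = 1,
                    xlab = sprintf("encounter rate (part %s^-1 h^-1)",
                                   x$taxon),
                    ylab = "depth (m)",
                    main = sprintf("%s, %s (%s)", x$taxon, x$season,
                                   x$model), ...)
  invisible(x)
}

#' Study configuration
#'
#' Defaults reproduce the published study design: both bundled seasons,
#' all three taxa, both models, 1000 bootstrap repetitions.
#'
#' @param seasons Character vector of season labels (with bundled
#'   defaults) or a named list of [season_scenario()]s.
#' @param taxa Character vector of taxon labels.
#' @param n_reps Bootstrap repetitions.
#' @param seed Bootstrap seed.
#' @param copepod_speed Passed to [taxon_registry()].
#' @param redraw_per_depth Passed to [encounter_profile()].
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(seasons = c("june", "october"),
                         taxa = c("copepod", "chaetognath", "luciferid"),
                         n_reps = 1000, seed = 42,
                         copepod_speed = "corrected",
                         redraw_per_depth = FALSE) {
  structure(list(seasons = seasons, taxa = taxa, n_reps = n_reps,
                 seed = seed, copepod_speed = copepod_speed,
                 redraw_per_depth = redraw_per_depth),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [study_config()]; unknown keys
#' are rejected. Seasons may be given as labels or as nested maps with
#' \code{U}, \code{w0}, and \code{stations} (path to a station CSV).
#'
#' @param path YAML file path.
#' @return A \code{"study_config"}.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$seasons) && is.list(raw$seasons) &&
      !is.null(names(raw$seasons))) {
    raw$seasons <- lapply(names(raw$seasons), function(lab) {
      s <- raw$seasons[[lab]]
      season_scenario(
        lab,
        stations = if (!is.null(s$stations)) load_stations(s$stations),
        U = s$U,
        params = if (!is.null(s$w0)) turbulence_params(w0 = s$w0))
    }) |> stats::setNames(names(raw$seasons))
  }
  do.call(study_config, raw)
}

#' Run the full encounter-rate study
#'
#' Computes all taxon x season x model encounter-rate depth profiles
#' (12 under the default design) and the summary table of surface rates
#' and turbulence multipliers.
#'
#' @param config A [study_config()].
#' @return An object of class \code{"encounter_study"}: list with
#'   \code{profiles} (named list of [encounter_profile()] results),
#'   \code{summary} (data.frame of surface rates and RO/GS multipliers),
#'   and \code{config}.
#' @examples
#' \donttest{
#' study <- run_full_study(study_config(n_reps = 200))
#' summary(study)
#' }
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  scen <- config$seasons
  if (is.character(scen)) {
    scen <- lapply(scen, season_scenario)
    names(scen) <- config$seasons
  }
  cfg <- bootstrap_config(n_reps = config$n_reps, seed = config$seed)
  profiles <- list()
  for (season in names(scen)) for (taxon in config$taxa)
    for (model in c("GS", "RO")) {
      key <- paste(season, taxon, tolower(model), sep = "_")
      profiles[[key]] <- tryCatch(
        encounter_profile(scen[[season]], taxon, model, cfg,
                          redraw_per_depth = config$redraw_per_depth,
                          copepod_speed = config$copepod_speed),
        error = function(e) stop("scenario failed: ", key, " (",
                                 conditionMessage(e), ")", call. = FALSE))
    }
  smry <- do.call(rbind, lapply(names(scen), function(season) {
    do.call(rbind, lapply(config$taxa, function(taxon) {
      gs <- profiles[[paste(season, taxon, "gs", sep = "_")]]
      ro <- profiles[[paste(season, taxon, "ro", sep = "_")]]
      data.frame(season = season, taxon = taxon,
                 surface_gs = gs$mean[1], surface_ro = ro$mean[1],
                 multiplier = ro$mean[1] / gs$mean[1],
                 surface_gs_sd = gs$sd[1], surface_ro_sd = ro$sd[1],
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(profiles = profiles, summary = smry, config = config),
            class = "encounter_study")
}

# published-style rounding: >= 100 to 3 significant figures, < 10 to one
# decimal, in between 3 significant figures; multipliers to one decimal
.format_rate <- function(r) {
  ifelse(r >= 100, signif(r, 3), ifelse(r < 10, round(r, 1), signif(r, 3)))
}

#' @export
print.encounter_study <- function(x, ...) {
  cat(sprintf("<encounter_study> %d profiles, %d bootstrap reps, seed %d\n",
              length(x$profiles), x$config$n_reps, x$config$seed))
  print(summary(x))
  invisible(x)
}

#' @export
summary.encounter_study <- function(object, ...) {
  s <- object$summary
  data.frame(season = s$season, taxon = s$taxon,
             surface_gs = .format_rate(s$surface_gs),
             surface_ro = .format_rate(s$surface_ro),
             multiplier = round(s$multiplier, 1),
             stringsAsFactors = FALSE)
}

#' @export
plot.encounter_study <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3)); on.exit(graphics::par(old))
  for (season in unique(x$summary$season))
    for (taxon in unique(x$summary$taxon)) {
      gs <- x$profiles[[paste(season, taxon, "gs", sep = "_")]]
      ro <- x$profiles[[paste(season, taxon, "ro", sep = "_")]]
      graphics::matplot(cbind(gs$mean, ro$mean), -gs$z, type = "l",
                        lty = c(2, 1), col = 1,
                        xlab = "rate (h^-1)", ylab = "depth (m)",
                        main = paste(taxon, season))
    }
  invisible(x)
}

#' Write study profiles and a run manifest to disk
#'
#' One CSV per profile (\code{z_m, mean_rate_per_h, sd_rate_per_h}, 12
#' significant digits, named \code{{season}_{taxon}_{model}.csv}) plus a
#' \code{manifest.json} recording parameters, seeds and package version.
#'
#' @param study An [run_full_study()] result, or a list of
#'   [encounter_profile()]s.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_profiles <- function(study, out_dir) {
  profiles <- if (inherits(study, "encounter_study")) study$profiles else
    study
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  if (length(profiles) == 0L)
    warning("no profiles to write; emitting manifest only")
  paths <- character(0)
  for (p in profiles) {
    stopifnot(inherits(p, "encounter_profile"))
    f <- file.path(out_dir, sprintf("%s_%s_%s.csv", p$season, p$taxon,
                                    tolower(p$model)))
    df <- data.frame(z_m = signif(p$z, 12),
                     mean_rate_per_h = signif(p$mean, 12),
                     sd_rate_per_h = signif(p$sd, 12))
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = NA),
                     f, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  manifest <- list(
    package = "mpencounter",
    version = as.character(utils::packageVersion("mpencounter")),
    n_profiles = length(profiles),
    profiles = lapply(profiles, function(p)
      list(season = p$season, taxon = p$taxon, model = p$model,
           n_reps = p$n_reps, seed = p$seed,
           stations = p$stations$concentrations)))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mf))
}
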