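#' Wind forcing for a season
#'
#' @param U Mean wind speed at the surface, m s\eqn{^{-1}} (>= 0).
#' @param season_label Free-text label.
#' @return An object of class \code{"wind_forcing"}.
#' @export
wind_forcing <- function(U, season_label = "") {
  if (!is.numeric(U) || length(U) != 1L || is.na(U) || U < 0)
    stop("'U' must be a single non-negative wind speed (m/s)", call. = FALSE)
  structure(list(U = U, season_label = season_label), class = "wind_forcing")
}

#' Turbulence submodel parameters
#'
#' Parameters of the wind-forced vertical turbulence closure used here:
#' surface turbulent velocity \eqn{w_0 = \alpha_w U} decaying
#' exponentially with depth with e-folding scale \code{lambda_decay},
#' turbulent kinetic energy \eqn{k = w^2}, and dissipation rate
#' \eqn{\varepsilon = w^3 / l_{mix}}. Defaults are calibrated so that
#' winds of 0.80 and 1.12 m/s give surface turbulent velocities of about
#' 0.03 and 0.04 m/s, surface dissipation on the order of 1e-4
#' m\eqn{^2} s\eqn{^{-3}}, and near-zero turbulence at the 1.5 m lagoon
#' bottom.
#'
#' @param alpha_w Dimensionless surface-velocity coefficient (default 0.036).
#' @param lambda_decay E-folding depth of turbulent velocity, m (default 0.25).
#' @param l_mix Mixing length in the dissipation closure, m (default 0.27).
#' @param z_max Maximum depth of the grid, m (default 1.5, the lagoon depth).
#' @param dz Depth grid step, m (default 0.01).
#' @param w0 Optional direct override of the surface turbulent velocity,
#'   m s\eqn{^{-1}}; when supplied the wind speed is ignored.
#' @return An object of class \code{"turbulence_params"}.
#' @export
turbulence_params <- function(alpha_w = 0.036, lambda_decay = 0.25,
                              l_mix = 0.27, z_max = 1.5, dz = 0.01,
                              w0 = NULL) {
  vals <- c(alpha_w = alpha_w, lambda_decay = lambda_decay, l_mix = l_mix,
            z_max = z_max, dz = dz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all turbulence parameters must be strictly positive", call. = FALSE)
  if (!is.null(w0) && (!is.numeric(w0) || length(w0) != 1L || w0 < 0))
    stop("'w0' override must be a single non-negative number", call. = FALSE)
  structure(list(alpha_w = alpha_w, lambda_decay = lambda_decay,
                 l_mix = l_mix, z_max = z_max, dz = dz, w0 = w0),
            class = "turbulence_params")
}

#' Surface turbulent velocity from wind speed
#'
#' \eqn{w_0 = \alpha_w U}, or the explicit \code{w0} override if the
#' parameter set carries one.
#'
#' @param forcing A [wind_forcing()].
#' @param params A [turbulence_params()].
#' @return Surface turbulent velocity, m s\eqn{^{-1}}.
#' @examples
#' surface_turbulent_velocity(wind_forcing(0.8))   # ~0.03 m/s
#' surface_turbulent_velocity(wind_forcing(1.12))  # ~0.04 m/s
#' @export
surface_turbulent_velocity <- function(forcing, params = turbulence_params()) {
  stopifnot(inherits(forcing, "wind_forcing"),
            inherits(params, "turbulence_params"))
  if (!is.null(params$w0)) params$w0 else params$alpha_w * forcing$U
}

#' Turbulent kinetic energy from turbulent velocity
#'
#' The turbulent velocity is taken as the root-mean-square of the
#' turbulent kinetic energy, so \eqn{k = w^2}.
#'
#' @param w Turbulent velocity, m s\eqn{^{-1}} (>= 0). Vectorised.
#' @return \eqn{k}, m\eqn{^2} s\eqn{^{-2}}.
#' @export
tke_from_w <- function(w) {
  if (any(w < 0)) stop("'w' must be non-negative", call. = FALSE)
  w^2
}

#' Dissipation rate from turbulent velocity
#'
#' Mixing-length closure \eqn{\varepsilon = w^3 / l_{mix}}, dimensionally
#' m\eqn{^2} s\eqn{^{-3}}.
#'
#' @param w Turbulent velocity, m s\eqn{^{-1}} (>= 0). Vectorised.
#' @param params A [turbulence_params()] (supplies \code{l_mix}).
#' @return \eqn{\varepsilon}, m\eqn{^2} s\eqn{^{-3}}.
#' @examples
#' dissipation_rate(0.03)  # 1e-4
#' @export
dissipation_rate <- function(w, params = turbulence_params()) {
  stopifnot(inherits(params, "turbulence_params"))
  if (any(w < 0)) stop("'w' must be non-negative", call. = FALSE)
  w^3 / params$l_mix
}

#' Build a vertical turbulence profile
#'
#' Depth-gridded turbulent velocity, kinetic energy and dissipation rate
#' for a given wind forcing: \eqn{w(z) = w_0 e^{-z/\lambda}} on a uniform
#' grid from the surface (z = 0) down to \code{z_max}, with
#' \eqn{k(z) = w(z)^2} and \eqn{\varepsilon(z) = w(z)^3/l_{mix}}. All
#' three decay monotonically and are effectively zero at the bottom under
#' the default decay scale.
#'
#' @param forcing A [wind_forcing()].
#' @param params A [turbulence_params()].
#' @return An object of class \code{"turbulence_profile"}: a data.frame
#'   with columns \code{z} (m, positive downward), \code{w} (m/s),
#'   \code{k} (m^2/s^2), \code{eps} (m^2/s^3), plus attributes
#'   \code{forcing} and \code{params}.
#' @examples
#' prof <- turbulence_profile(wind_forcing(0.8, "June"))
#' head(prof)
#' @export
turbulence_profile <- function(forcing, params = turbulence_params()) {
  stopifnot(inherits(forcing, "wind_forcing"),
            inherits(params, "turbulence_params"))
  if (params$dz >= params$z_max)
    stop("grid step 'dz' must be smaller than 'z_max'", call. = FALSE)
  z <- seq(0, params$z_max, by = params$dz)
  w0 <- surface_turbulent_velocity(forcing, params)
  w <- w0 * exp(-z / params$lambda_decay)
  out <- data.frame(z = z, w = w, k = tke_from_w(w),
                    eps = dissipation_rate(w, params))
  attr(out, "forcing") <- forcing
  attr(out, "params") <- params
  class(out) <- c("turbulence_profile", "data.frame")
  out
}

#' @export
print.turbulence_profile <- function(x, ...) {
  f <- attr(x, "forcing")
  cat(sprintf(
    "<turbulence_profile> %s U = %g m/s: w(0) = %.4g m/s, eps(0) = %.3g m^2/s^3, %d depths to %g m\n",
    if (nzchar(f$season_label)) paste0(f$season_label, ",") else "wind",
    f$U, x$w[1], x$eps[1], nrow(x), x$z[nrow(x)]))
  invisible(x)
}

#' @export
plot.turbulence_profile <- function(x, which = c("w", "eps"), ...) {
  which <- match.arg(which)
  lab <- if (which == "w") "turbulent velocity (m/s)" else
    "dissipation rate (m^2/s^3)"
  graphics::plot(x[[which]], -x$z, type = "l", xlab = lab, ylab = "depth (m)",
                 ...)
  invisible(x)
}
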