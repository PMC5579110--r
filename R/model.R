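#' Model parameters for the dimensionless CH / CHC system
#'
#' Collects the physical and numerical parameters of the dimensionless
#' Cahn-Hilliard(-Cook) system.  Defaults are the unit-sphere study
#' conditions: mean concentration 0.3 with a random perturbation of
#' amplitude 0.01, Peclet number 1, Cahn number 0.015, and a time step
#' proportional to the grid spacing, \eqn{\Delta t = 5.12 \times 10^{-3} h}.
#'
#' @param Pe Surface Peclet number (> 0).
#' @param Cn Cahn number (> 0); interfaces have thickness proportional
#'   to Cn, so the grid must resolve it.
#' @param sigma Noise intensity (>= 0); 0 recovers the deterministic CH
#'   model.
#' @param mobility_kind \code{"constant"} (\eqn{\nu = 1}) or
#'   \code{"degenerate"} (\eqn{\nu = 4 f (1 - f)}).
#' @param mean_concentration Average concentration, in (0, 1).
#' @param perturbation_amplitude Amplitude of the initial random
#'   perturbation.
#' @param dt Time step; if \code{NULL} it is set to \code{5.12e-3 * h} when
#'   a band is supplied to the solver.
#' @param perturbation_dist \code{"uniform"} (default) or
#'   \code{"gaussian"} initial perturbation.
#' @return An object of class \code{"model_params"}.
#' @export
model_params <- function(Pe = 1.0, Cn = 0.015, sigma = 0,
                         mobility_kind = c("constant", "degenerate"),
                         mean_concentration = 0.3,
                         perturbation_amplitude = 0.01,
                         dt = NULL,
                         perturbation_dist = c("uniform", "gaussian")) {
  mobility_kind <- match.arg(mobility_kind)
  perturbation_dist <- match.arg(perturbation_dist)
  stopifnot(Pe > 0, Cn > 0, sigma >= 0,
            mean_concentration > 0, mean_concentration < 1,
            perturbation_amplitude >= 0)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(list(Pe = Pe, Cn = Cn, sigma = sigma,
                 mobility_kind = mobility_kind,
                 mean_concentration = mean_concentration,
                 perturbation_amplitude = perturbation_amplitude,
                 dt = dt, perturbation_dist = perturbation_dist),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: Pe = %g, Cn = %g, sigma = %g, mobility = %s, f0 = %g +/- %g, dt = %s\n",
    x$Pe, x$Cn, x$sigma, x$mobility_kind, x$mean_concentration,
    x$perturbation_amplitude,
    if (is.null(x$dt)) "5.12e-3 h (grid-derived)" else format(x$dt)))
  invisible(x)
}

## internal: resolve dt for a given grid spacing
resolve_dt <- function(params, h) {
  if (is.null(params$dt)) 5.12e-3 * h else params$dt
}

#' Double-well mixing energy
#'
#' \eqn{g(f) = f^2 (1 - f)^2}, with wells at the pure phases \eqn{f = 0}
#' and \eqn{f = 1}.
#'
#' @param f Concentration values (any numeric).
#' @return \eqn{g(f)}, elementwise.
#' @export
mixing_energy <- function(f) f^2 * (1 - f)^2

#' Derivative of the mixing energy
#'
#' \eqn{g'(f) = 2 f (1 - f)(1 - 2 f)}, the nonlinear part of the chemical
#' potential.
#'
#' @param f Concentration values.
#' @return \eqn{g'(f)}, elementwise.
#' @export
g_prime <- function(f) 2 * f * (1 - f) * (1 - 2 * f)

#' Dimensionless mobility
#'
#' Constant mobility returns 1 everywhere; degenerate mobility returns
#' \eqn{4 f (1 - f)}, clamped at zero from below so that the
#' mobility-weighted Laplacian stays well posed when the scheme overshoots
#' the physical range \eqn{[0, 1]}.
#'
#' @param f Concentration values.
#' @param kind \code{"constant"} or \code{"degenerate"}.
#' @return Mobility values, elementwise.
#' @export
mobility <- function(f, kind = c("constant", "degenerate")) {
  kind <- match.arg(kind)
  if (kind == "constant") rep(1, length(f)) else pmax(4 * f * (1 - f), 0)
}
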