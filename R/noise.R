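## internal: run expr under a private RNG state derived from (seed, step),
## restoring the caller's RNG state afterwards
mix_seed <- function(seed, step = 0L) {
  # deterministic 31-bit mix of the run seed and the time-step index
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(step) + 1) * 1299721
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample the tangential random field driving the conserved noise
#'
#' At each band node's closest surface point, draws two independent standard
#' normals \eqn{\rho_1, \rho_2} and forms the tangential vector
#' \eqn{\rho = \rho_1 t + \rho_2 b} in the node's orthonormal tangent frame.
#' Draws are fresh at every time step (white in time) and reproducible from
#' \code{(seed, step)}.
#'
#' @param band A \code{"narrow_band"}.
#' @param seed Integer run seed.
#' @param step Time-step index (>= 0).
#' @return An object of class \code{"noise_realization"} with the
#'   node-wise tangential field \code{rho} (n x 3), the raw draws
#'   \code{rho1}, \code{rho2}, and the \code{(seed, step)} provenance.
#' @export
sample_tangential_field <- function(band, seed, step = 0L) {
  stopifnot(inherits(band, "narrow_band"))
  n <- band$n
  draws <- with_seed(mix_seed(seed, step), matrix(stats::rnorm(2 * n), n, 2L))
  rho <- draws[, 1L] * band$tvec + draws[, 2L] * band$bvec
  structure(list(rho = rho, rho1 = draws[, 1L], rho2 = draws[, 2L],
                 seed = seed, step = step),
            class = "noise_realization")
}

#' Conserved Gaussian noise field
#'
#' Builds the stochastic forcing of the Cahn-Hilliard-Cook model from a
#' tangential random field:
#' \deqn{\xi = \sqrt{\sigma\, \nu(f) / (h^2 \Delta t)}\;
#'   \nabla_s \cdot \tilde\rho,}
#' where the surface divergence is computed as the centred Cartesian
#' divergence of the extended tangential field, re-extended off the surface
#' with the cubic closest-point interpolation.  Written as a divergence, the
#' forcing conserves the surface-integrated concentration; the amplitude is
#' evaluated pointwise at the current field (Ito-style), making the noise
#' multiplicative under degenerate mobility.
#'
#' @param rho A \code{"noise_realization"}.
#' @param f Extended concentration field (sets the mobility amplitude).
#' @param params A \code{"model_params"} (supplies \code{sigma},
#'   \code{mobility_kind}, \code{dt}).
#' @param ops A \code{"cp_operators"} bundle.
#' @return Extended noise field \eqn{\xi} on band nodes.
#' @export
conserved_noise <- function(rho, f, params, ops) {
  stopifnot(inherits(rho, "noise_realization"), inherits(ops, "cp_operators"))
  if (params$sigma < 0) stop("conserved_noise: sigma must be non-negative")
  n <- ops$band$n
  if (params$sigma == 0) {
    out <- numeric(n)
    attr(out, "extended") <- TRUE
    return(out)
  }
  h <- ops$h
  dt <- resolve_dt(params, h)
  div <- ops$mv$Gx(rho$rho[, 1L]) + ops$mv$Gy(rho$rho[, 2L]) +
    ops$mv$Gz(rho$rho[, 3L])
  ext <- ops$mv$E3(div)
  nu <- mobility(f, params$mobility_kind)
  out <- sqrt(params$sigma * nu / (h^2 * dt)) * ext
  attr(out, "extended") <- TRUE
  out
}
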