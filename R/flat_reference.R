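#' One-dimensional equilibrium interface profile
#'
#' The stationary phase-field profile across a flat interface,
#' \deqn{f_{eq}(x) = \tfrac12\big[\tanh\big(x / (Cn\sqrt2)\big) + 1\big],}
#' connecting the pure phases 0 and 1 over a width proportional to the
#' Cahn number.
#'
#' @param x Signed distance from the interface (dimensionless).
#' @param Cn Cahn number (> 0).
#' @return Profile values in (0, 1).
#' @export
equilibrium_profile <- function(x, Cn) {
  stopifnot(Cn > 0)
  0.5 * (tanh(x / (Cn * sqrt(2))) + 1)
}

#' Noise-to-mobility scaling diagnostic
#'
#' For degenerate mobility \eqn{\nu = 4 f (1 - f)}, compares the scale of
#' the diffusive term (proportional to \eqn{\nu}) with the discrete noise
#' magnitude \eqn{\sqrt{\sigma \nu / h^2}}.  Their ratio,
#' \eqn{\sqrt{\sigma / (\nu h^2)}}, grows without bound as \eqn{f \to 0}
#' or \eqn{1}: in well-segregated regions the noise dominates the
#' diffusion, which is why noise accelerates coarsening under degenerate
#' mobility.
#'
#' @param f Concentration values.
#' @param sigma Noise intensity (>= 0).
#' @param h Grid spacing.
#' @return Data frame with columns \code{f}, \code{mobility},
#'   \code{noise_magnitude}, \code{ratio} and the logical
#'   \code{overflow} flag marking pure phases where the ratio is
#'   infinite.
#' @export
noise_mobility_diagnostic <- function(f, sigma, h) {
  stopifnot(sigma >= 0, h > 0)
  nu <- mobility(f, "degenerate")
  noise <- sqrt(sigma * nu / h^2)
  ratio <- ifelse(nu > 0, sqrt(sigma / (nu * h^2)),
                  ifelse(sigma > 0, Inf, 0))
  data.frame(f = f, mobility = nu, noise_magnitude = noise, ratio = ratio,
             overflow = !is.finite(ratio))
}

#' Residual of the 1-D dynamics on a given profile
#'
#' Evaluates \eqn{\partial f/\partial t = -(1/Pe)\,\partial_{xx}\big(
#' g'(f) - Cn^2 \partial_{xx} f\big)} spectrally on a periodic domain.
#' Used to verify that the equilibrium profile is stationary.
#'
#' @param f Periodic samples of the field.
#' @param L Domain period.
#' @param Cn Cahn number.
#' @param Pe Peclet number.
#' @return The time derivative at each sample.
#' @export
flat_ch_residual_1d <- function(f, L, Cn, Pe = 1) {
  n <- length(f)
  k <- 2 * pi / L * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fh <- stats::fft(f)
  lap <- function(uh) -k^2 * uh
  mu <- g_prime(f) - Cn^2 * Re(stats::fft(lap(fh), inverse = TRUE)) / n
  Re(stats::fft(lap(stats::fft(mu)), inverse = TRUE)) / (n * Pe)
}

#' Flat periodic Cahn-Hilliard(-Cook) reference solver
#'
#' Pseudo-spectral solver for the same dimensionless model on a periodic
#' square (the curvature-free limit), used as validation infrastructure:
#' flat two-dimensional coarsening obeys the classical
#' \eqn{\bar R \propto t^{1/3}} law for constant mobility.  Time stepping
#' is first-order semi-implicit with a standard Eyre-style stabilisation
#' shift, which is all the asymptotic coarsening statistics require.
#'
#' @param n Grid size per axis (power of two recommended).
#' @param params A \code{"model_params"}; \code{dt} must be set
#'   explicitly (there is no embedding grid to derive it from).
#' @param t_end Final time.
#' @param seed Integer seed.
#' @param L Domain period (default 1).
#' @param stride Record diagnostics every \code{stride} steps.
#' @param stab Stabilisation shift added to the implicit shell
#'   (default 2, an upper bound for \eqn{|g''|} on the relevant range).
#' @param dt_growth Geometric growth factor of the step size (default 1:
#'   constant step).  Coarsening is self-similar with a local timescale
#'   proportional to \eqn{t}, so a slow geometric ramp reaches the
#'   late-time scaling regime at equal accuracy per decade; used only for
#'   long coarsening-statistics runs.
#' @param dt_max Cap on the ramped step.
#' @return A \code{"chc_run"}-like list with \code{series} (columns
#'   \code{t}, \code{R_bar}, \code{energy}, \code{mass}) and the final
#'   field \code{f} (an n x n matrix).
#' @export
flat_ch_run <- function(n, params, t_end, seed, L = 1, stride = 10L,
                        stab = 2, dt_growth = 1, dt_max = Inf) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(params$dt)) {
    stop("flat_ch_run: params$dt must be set explicitly for the flat solver")
  }
  h <- L / n
  if (params$Cn * sqrt(2) * 2 < 4 * h) {
    warning("flat_ch_run: interface width below 4 grid cells; under-resolved")
  }
  dt <- params$dt
  Pe <- params$Pe
  Cn <- params$Cn
  kv <- 2 * pi / L * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k2 <- outer(kv^2, kv^2, "+")
  k4 <- k2^2
  denom <- 1 + dt * (Cn^2 * k4 + stab * k2) / Pe
  constant_mob <- params$mobility_kind == "constant"
  ramped <- dt_growth != 1 || is.finite(dt_max)

  f <- with_seed(mix_seed(seed, -1L), {
    matrix(params$mean_concentration +
             stats::runif(n * n, -params$perturbation_amplitude,
                          params$perturbation_amplitude), n, n)
  })
  fft2 <- function(x) stats::fft(x)
  ifft2 <- function(x) Re(stats::fft(x, inverse = TRUE)) / (n * n)

  record <- function(f, t) {
    fh <- fft2(f)
    gx <- ifft2(1i * kv * fh)            # d/dx acts on rows (first index)
    gy <- ifft2(t(1i * kv * t(fh)))      # d/dy on columns
    gn <- sqrt(gx^2 + gy^2)
    A <- sum(f) * h^2
    Ln <- sum(gn) * h^2
    data.frame(t = t,
               R_bar = if (Ln > 0) A / Ln else NA_real_,
               energy = sum(mixing_energy(f) + Cn^2 / 2 * gn^2) * h^2,
               mass = A)
  }
  rows <- list(record(f, 0))
  nrows <- 1L

  fh <- fft2(f)
  t <- 0
  s <- 0L
  while (t < t_end - 1e-12 * t_end) {
    s <- s + 1L
    if (ramped && s > 1L) {
      dt_new <- min(dt * dt_growth, dt_max, t_end - t)
      if (dt_new != dt) {
        dt <- dt_new
        denom <- 1 + dt * (Cn^2 * k4 + stab * k2) / Pe
      }
    }
    fr <- ifft2(fh)
    gp <- g_prime(fr)
    if (constant_mob) {
      nlh <- fft2(gp - stab * fr)
      expl <- -k2 * nlh / Pe
    } else {
      # pseudo-spectral div(nu grad mu) with explicit mobility
      muh <- fft2(gp) + Cn^2 * k2 * fh
      mx <- ifft2(1i * kv * muh)
      my <- ifft2(t(1i * kv * t(muh)))
      nu <- mobility(fr, "degenerate")
      fluxh <- 1i * kv * fft2(nu * mx) + t(1i * kv * t(fft2(nu * my)))
      expl <- fluxh / Pe + (Cn^2 * k4 + stab * k2) * fh / Pe
    }
    if (params$sigma > 0) {
      rr <- with_seed(mix_seed(seed, s - 1L),
                      matrix(stats::rnorm(2 * n * n), n, 2L * n))
      nu <- if (constant_mob) 1 else mobility(fr, "degenerate")
      amp <- sqrt(params$sigma * nu / (h^2 * dt))
      # amplitude inside the divergence keeps the forcing exactly conserved
      xih <- 1i * kv * fft2(amp * rr[, seq_len(n)]) +
        t(1i * kv * t(fft2(amp * rr[, n + seq_len(n)])))
    } else {
      xih <- 0
    }
    fh <- (fh + dt * (expl + xih)) / denom
    t <- t + dt
    if (s %% stride == 0L || t >= t_end - 1e-12 * t_end) {
      nrows <- nrows + 1L
      rows[[nrows]] <- record(ifft2(fh), t)
    }
  }
  series <- do.call(rbind, rows[seq_len(nrows)])
  structure(list(series = series, f = ifft2(fh), params = params,
                 seed = seed, dt = dt, t_end = t_end, n = n, L = L,
                 geom_name = "flat_torus"),
            class = "chc_run")
}
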