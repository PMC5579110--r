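#' Default growth-rate fit windows
#'
#' Time windows over which the coarsening regime \eqn{\bar R \propto
#' t^\alpha} is fitted, per geometry and model: constant-mobility and
#' deterministic sphere runs use \eqn{t \in [0.1, 10]}; the faster
#' degenerate-mobility stochastic sphere runs use \eqn{t \in [0.1, 0.8]};
#' the dumbbell has an early and a late deterministic regime and a single
#' stochastic window.  All are plain config values.
#'
#' @return Named list of \code{c(t_lo, t_hi)} windows.
#' @export
growth_windows <- function() {
  list(sphere_default = c(0.1, 10),
       sphere_chc_degenerate = c(0.1, 0.8),
       dumbbell_ch_early = c(0.02, 0.2),
       dumbbell_ch_late = c(1, 10),
       dumbbell_chc = c(0.1, 10))
}

#' Fit the coarsening growth exponent
#'
#' Ordinary least squares of \eqn{\ln \bar R} against \eqn{\ln t} over the
#' samples falling in the window; the slope is the growth exponent
#' \eqn{\alpha}.
#'
#' @param series A data frame with columns \code{t} and \code{R_bar} (a
#'   \code{chc_run$series}), or a \code{"chc_run"}.
#' @param window \code{c(t_lo, t_hi)} fit window; both endpoints and all
#'   included \code{R_bar} must be positive.
#' @return An object of class \code{"growth_fit"}: list with
#'   \code{alpha}, \code{intercept}, \code{window}, \code{n} (samples
#'   used) and \code{residual} (root-mean-square log residual).
#' @export
fit_growth_rate <- function(series, window) {
  if (inherits(series, "chc_run")) series <- series$series
  stopifnot(all(c("t", "R_bar") %in% names(series)),
            length(window) == 2L, window[1L] < window[2L])
  sel <- series$t >= window[1L] & series$t <= window[2L] &
    is.finite(series$R_bar)
  t <- series$t[sel]
  R <- series$R_bar[sel]
  if (length(t) < 10L) {
    stop(sprintf("fit_growth_rate: only %d samples in window [%g, %g] (need >= 10)",
                 length(t), window[1L], window[2L]))
  }
  if (any(t <= 0) || any(R <= 0)) {
    stop("fit_growth_rate: times and characteristic lengths must be positive")
  }
  fit <- stats::lm.fit(cbind(1, log(t)), log(R))
  structure(list(alpha = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 window = window, n = length(t),
                 residual = sqrt(mean(fit$residuals^2))),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: alpha = %.4f over t in [%g, %g] (%d samples, rms log-residual %.3g)\n",
              x$alpha, x$window[1L], x$window[2L], x$n, x$residual))
  invisible(x)
}

#' Summary statistics of an ensemble of growth exponents
#'
#' @param alphas Numeric vector of per-realisation growth exponents.
#' @return List with \code{mean}, \code{sd} (sample, n-1 denominator) and
#'   \code{cv} (coefficient of variation, sd/mean); \code{sd} and
#'   \code{cv} are \code{NA} for a single value.
#' @export
ensemble_stats <- function(alphas) {
  if (!length(alphas)) stop("ensemble_stats: empty sample")
  m <- mean(alphas)
  s <- if (length(alphas) >= 2L) stats::sd(alphas) else NA_real_
  list(mean = m, sd = s, cv = s / m, n = length(alphas))
}

#' Lognormal maximum-likelihood fit with a Kolmogorov-Smirnov check
#'
#' Fits the lognormal density
#' \deqn{f(x \mid \mu, \sigma_{pdf}) = \frac{1}{x \sigma_{pdf}\sqrt{2\pi}}
#'   \exp\!\Big(-\frac{(\ln x - \mu)^2}{2\sigma_{pdf}^2}\Big), \quad x > 0,}
#' by MLE on the logs (\eqn{\mu} = mean of \eqn{\ln x}, \eqn{\sigma_{pdf}}
#' = standard deviation of \eqn{\ln x} with the MLE \eqn{n} denominator)
#' and tests the sample against the fitted distribution with a
#' Kolmogorov-Smirnov test at the 5\% level.  The plain parametric test is
#' the default; \code{lilliefors = TRUE} calibrates the KS null by Monte
#' Carlo to account for the estimated parameters (a stricter test).
#'
#' @param alphas Strictly positive sample (growth exponents).
#' @param lilliefors Use a Monte-Carlo (Lilliefors-style) null.
#' @param B Number of Monte-Carlo replicates when \code{lilliefors}.
#' @return An object of class \code{"lognormal_fit"}: \code{mu},
#'   \code{sigma_pdf}, \code{ks_stat}, \code{p_value}, \code{accept_5pct}.
#' @export
fit_lognormal <- function(alphas, lilliefors = FALSE, B = 500L) {
  if (any(alphas <= 0)) {
    stop("fit_lognormal: lognormal support requires strictly positive values")
  }
  lx <- log(alphas)
  n <- length(lx)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))  # MLE: n denominator
  if (sigma == 0) {
    return(structure(list(mu = mu, sigma_pdf = 0, ks_stat = NA_real_,
                          p_value = NA_real_, accept_5pct = NA, n = n),
                     class = "lognormal_fit"))
  }
  ks <- suppressWarnings(
    stats::ks.test(alphas, "plnorm", meanlog = mu, sdlog = sigma))
  p <- ks$p.value
  if (lilliefors) {
    stat0 <- unname(ks$statistic)
    stats_mc <- replicate(B, {
      y <- stats::rlnorm(n, mu, sigma)
      ly <- log(y)
      m2 <- mean(ly); s2 <- sqrt(mean((ly - m2)^2))
      unname(suppressWarnings(
        stats::ks.test(y, "plnorm", meanlog = m2, sdlog = s2))$statistic)
    })
    p <- mean(stats_mc >= stat0)
  }
  structure(list(mu = mu, sigma_pdf = sigma,
                 ks_stat = unname(ks$statistic), p_value = p,
                 accept_5pct = p >= 0.05, n = n),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "lognormal_fit: mu = %.4f, sigma_pdf = %.4f (n = %d); KS D = %.3g, p = %.3g -> %s at 5%%\n",
    x$mu, x$sigma_pdf, x$n, x$ks_stat, x$p_value,
    if (isTRUE(x$accept_5pct)) "accepted" else "rejected"))
  invisible(x)
}

#' Pointwise envelope of an ensemble of time series
#'
#' @param series_list List of data frames sharing the same time grid,
#'   each with columns \code{t} and \code{R_bar} (or \code{"chc_run"}
#'   objects).
#' @return Data frame with columns \code{t}, \code{min}, \code{mean},
#'   \code{max}.
#' @export
ensemble_envelope <- function(series_list) {
  if (!length(series_list)) stop("ensemble_envelope: empty ensemble")
  series_list <- lapply(series_list, function(s) {
    if (inherits(s, "chc_run")) s$series else s
  })
  t0 <- series_list[[1L]]$t
  for (s in series_list) {
    if (length(s$t) != length(t0) || any(abs(s$t - t0) > 1e-12 * (1 + t0))) {
      stop("ensemble_envelope: time grids do not match")
    }
  }
  vals <- vapply(series_list, function(s) s$R_bar, numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  data.frame(t = t0,
             min = apply(vals, 1L, min),
             mean = rowMeans(vals),
             max = apply(vals, 1L, max))
}
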