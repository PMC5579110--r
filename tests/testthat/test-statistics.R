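make_series <- function(t, R) data.frame(t = t, R_bar = R,
                                         energy = NA_real_, mass = 1)

test_that("growth-rate fitting is exact on noiseless power laws", {
  t <- exp(seq(log(0.1), log(10), length.out = 50))
  s <- make_series(t, 3 * t^0.3)
  fit <- fit_growth_rate(s, c(0.1, 10))
  expect_equal(fit$alpha, 0.3, tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
  expect_gte(fit$n, 49L)  # endpoint inclusion is subject to fp rounding
  # narrow window with a single sample errors
  expect_error(fit_growth_rate(s, c(0.09, 0.11)), "need >= 10")
})

test_that("growth-rate fitting recovers the exponent under lognormal noise", {
  t <- exp(seq(log(0.1), log(10), length.out = 80))
  set.seed(12)
  alphas <- replicate(100, {
    R <- 2 * t^0.3 * rlnorm(length(t), 0, 0.01)
    fit_growth_rate(make_series(t, R), c(0.1, 10))$alpha
  })
  expect_lt(abs(mean(alphas) - 0.3), 0.01)
  expect_lt(max(abs(alphas - 0.3)), 0.05)
})

test_that("ensemble statistics reproduce the published coefficient of variation", {
  # mean 0.2814 and sd 0.0215 give CV = 0.0764 at the printed precision
  expect_equal(round(0.0215 / 0.2814, 4), 0.0764)
  set.seed(3)
  x <- rnorm(64, 0.2814, 0.0215)
  st <- ensemble_stats(x)
  expect_equal(st$cv, st$sd / st$mean)
  # permutation invariance
  st2 <- ensemble_stats(sample(x))
  expect_equal(st, st2)
  # degenerate cases
  stc <- ensemble_stats(rep(0.5, 8))
  expect_equal(stc$sd, 0)
  expect_equal(stc$cv, 0)
  expect_error(ensemble_stats(numeric(0)), "empty")
})

test_that("lognormal fit handles degenerate samples and matches the published moment identity", {
  fit <- fit_lognormal(rep(exp(-1), 20))
  expect_equal(fit$mu, -1)
  expect_equal(fit$sigma_pdf, 0)
  # the published sphere parameters reproduce the published mean growth
  # rate through exp(mu + sigma^2/2)
  expect_lt(abs(exp(-1.2707 + 0.0748^2 / 2) - 0.2814), 0.001)
  expect_error(fit_lognormal(c(0.1, -0.2, 0.3)), "positive")
})

test_that("lognormal MLE recovers parameters on simulated data", {
  set.seed(99)
  x <- rlnorm(1e4, -1.27, 0.075)
  fit <- fit_lognormal(x)
  se_mu <- 0.075 / sqrt(1e4)
  se_sd <- 0.075 / sqrt(2e4)
  expect_lt(abs(fit$mu - (-1.27)), 3 * se_mu)
  expect_lt(abs(fit$sigma_pdf - 0.075), 3 * se_sd)
  expect_true(fit$accept_5pct)
})

test_that("KS test accepts samples genuinely drawn from the fitted family most of the time", {
  set.seed(7)
  acc <- replicate(200, {
    x <- rlnorm(64, -1.27, 0.075)
    fit_lognormal(x)$accept_5pct
  })
  # conservative because the parameters are estimated from the sample
  expect_gte(mean(acc), 0.9)
})

test_that("the ensemble envelope orders and aggregates correctly", {
  t <- 1:20
  s1 <- make_series(t, 1 + 0.1 * t)
  single <- ensemble_envelope(list(s1))
  expect_equal(single$min, single$max)
  expect_equal(single$mean, s1$R_bar)

  s2 <- make_series(t, 2 + 0.1 * t)  # everywhere larger
  both <- ensemble_envelope(list(s1, s2))
  expect_equal(both$min, s1$R_bar)
  expect_equal(both$max, s2$R_bar)
  expect_gt(min(both$mean - single$mean), 0)

  # accumulating noise widens the envelope over time
  set.seed(5)
  noisy <- lapply(1:10, function(i) {
    make_series(t, 1 + 0.1 * t + cumsum(rnorm(length(t), 0, 0.05)))
  })
  env <- ensemble_envelope(noisy)
  w <- env$max - env$min
  expect_gt(mean(w[11:20]), mean(w[1:10]))

  expect_error(ensemble_envelope(list(s1, make_series(1:19, 1:19))),
               "time grids")
  expect_error(ensemble_envelope(list()), "empty")
})

test_that("default fit windows carry the published regimes", {
  w <- growth_windows()
  expect_equal(w$sphere_default, c(0.1, 10))
  expect_equal(w$sphere_chc_degenerate, c(0.1, 0.8))
  expect_equal(w$dumbbell_ch_early, c(0.02, 0.2))
  expect_equal(w$dumbbell_ch_late, c(1, 10))
})
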