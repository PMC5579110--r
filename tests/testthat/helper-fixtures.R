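# Shared fixtures, memoised so expensive bands/operators are built once
# per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

sphere_band <- function(N, half_width_in_h = 5) {
  memo(sprintf("sphere_band_%d_%g", N, half_width_in_h), {
    g <- grid_spec(N)
    build_band(sphere_geometry(), g, half_width = half_width_in_h * g$h)
  })
}

sphere_ops <- function(N) {
  memo(sprintf("sphere_ops_%d", N), cp_operators(sphere_band(N)))
}

dumbbell_band <- function(N) {
  memo(sprintf("dumbbell_band_%d", N), {
    g <- grid_spec(N, -2.2, 2.2)
    build_band(dumbbell_geometry(), g)
  })
}

# dense sampling of the dumbbell union surface, for brute-force
# closest-point oracles (n_theta controls density)
dumbbell_surface_samples <- function(n_theta = 700) {
  memo(sprintf("dumbbell_samples_%d", n_theta), {
    Rs <- 0.75; Rc <- 0.375; xc <- 1.125
    cap_cos <- sqrt(1 - (Rc / Rs)^2)  # cos of the half-angle of the trimmed cap
    th <- seq(0, pi, length.out = n_theta)
    ph <- seq(0, 2 * pi, length.out = 2 * n_theta + 1)[-1]
    sph <- as.matrix(expand.grid(th = th, ph = ph))
    pts1 <- cbind(Rs * cos(sph[, "th"]),
                  Rs * sin(sph[, "th"]) * cos(sph[, "ph"]),
                  Rs * sin(sph[, "th"]) * sin(sph[, "ph"]))
    # right sphere: keep points not inside the cylinder (trim the neck cap)
    keep_r <- pts1[, 1L] > -cap_cos * Rs
    right <- cbind(pts1[keep_r, 1L] + xc, pts1[keep_r, 2L], pts1[keep_r, 3L])
    keep_l <- pts1[, 1L] < cap_cos * Rs
    left <- cbind(pts1[keep_l, 1L] - xc, pts1[keep_l, 2L], pts1[keep_l, 3L])
    xj <- xc - Rs * cap_cos  # junction circle |x|
    xs <- seq(-xj, xj, length.out = n_theta)
    cyl <- as.matrix(expand.grid(x = xs, ph = ph))
    cylp <- cbind(cyl[, "x"], Rc * cos(cyl[, "ph"]), Rc * sin(cyl[, "ph"]))
    rbind(right, left, cylp)
  })
}

brute_force_cp <- function(query, samples) {
  t(apply(query, 1L, function(q) {
    d2 <- (samples[, 1L] - q[1L])^2 + (samples[, 2L] - q[2L])^2 +
      (samples[, 3L] - q[3L])^2
    samples[which.min(d2), ]
  }))
}

# closed-form area of the dumbbell union surface
dumbbell_area_exact <- function() {
  Rs <- 0.75; Rc <- 0.375; xc <- 1.125
  cap_h <- Rs - sqrt(Rs^2 - Rc^2)
  xj <- xc - sqrt(Rs^2 - Rc^2)
  2 * (4 * pi * Rs^2 - 2 * pi * Rs * cap_h) + 2 * pi * Rc * (2 * xj)
}

# spherical-cap tanh profile on the unit sphere: interface at geodesic
# distance r0 from the pole axis direction
tanh_cap_field <- function(band, r0, Cn, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  cosg <- (band$x %*% axis) / sqrt(rowSums(band$x^2))
  d <- r0 - acos(pmin(pmax(cosg, -1), 1))  # signed geodesic distance
  f <- 0.5 * (tanh(d / (Cn * sqrt(2))) + 1)
  as.numeric(f)
}
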