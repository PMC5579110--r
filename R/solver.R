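#' Linear solver options for the semi-implicit time stepper
#'
#' @param tol Relative residual tolerance of the outer flexible GMRES.
#' @param restart Restart length of the outer iteration.
#' @param maxit Maximum outer iterations (over all restarts).
#' @param schur How the approximate Schur-complement inverse is applied:
#'   \code{"gmres"} (matrix-free inner Krylov solve, any band size) or
#'   \code{"direct"} (explicit sparse Schur complement factorised once;
#'   limited to bands below \code{direct_max_n} nodes).
#' @param inner_tol,inner_maxit Tolerance and iteration cap of the inner
#'   Schur solve in \code{"gmres"} mode.
#' @param direct_max_n Largest band size admitted in \code{"direct"} mode.
#' @param face_mean Face-mobility averaging rule for the variable
#'   Laplacian.
#' @return A list of class \code{"solver_options"}.
#' @export
solver_options <- function(tol = 1e-8, restart = 30L, maxit = 200L,
                           schur = c("gmres", "direct"),
                           inner_tol = 1e-9, inner_maxit = 200L,
                           direct_max_n = 25000L,
                           face_mean = "arithmetic") {
  schur <- match.arg(schur)
  structure(list(tol = tol, restart = as.integer(restart),
                 maxit = as.integer(maxit), schur = schur,
                 inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
                 direct_max_n = as.integer(direct_max_n),
                 face_mean = face_mean),
            class = "solver_options")
}

#' Flexible GMRES
#'
#' Right-preconditioned flexible GMRES with restarts.  The preconditioner
#' may vary between iterations (it is itself an iterative solve), which is
#' what the flexible variant permits.
#'
#' @param amul Function applying the system operator to a vector.
#' @param b Right-hand side.
#' @param precond Function applying the preconditioner (identity if
#'   \code{NULL}).
#' @param x0 Initial guess (zero if \code{NULL}).
#' @param tol Relative residual tolerance (w.r.t. \code{||b||}).
#' @param restart Restart length.
#' @param maxit Total iteration cap.
#' @return List with \code{x}, \code{iters}, \code{relres},
#'   \code{converged}.
#' @export
fgmres <- function(amul, b, precond = NULL, x0 = NULL,
                   tol = 1e-8, restart = 30L, maxit = 200L) {
  n <- length(b)
  if (is.null(precond)) precond <- identity
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) {
    return(list(x = numeric(n), iters = 0L, relres = 0, converged = TRUE))
  }
  x <- if (is.null(x0)) numeric(n) else x0
  total <- 0L
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r * r))
    if (beta / bnorm < tol) {
      return(list(x = x, iters = total, relres = beta / bnorm,
                  converged = TRUE))
    }
    m <- min(restart, maxit - total)
    if (m <= 0L) {
      return(list(x = x, iters = total, relres = beta / bnorm,
                  converged = FALSE))
    }
    V <- matrix(0, n, m + 1L)
    Z <- matrix(0, n, m)
    H <- matrix(0, m + 1L, m)
    V[, 1L] <- r / beta
    j <- 0L
    relres <- beta / bnorm
    for (jj in seq_len(m)) {
      j <- jj
      Z[, j] <- precond(V[, j])
      w <- amul(Z[, j])
      for (i in seq_len(j)) {
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1L, j] <- sqrt(sum(w * w))
      if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
      e1 <- c(beta, numeric(j))
      y <- qr.solve(H[seq_len(j + 1L), seq_len(j), drop = FALSE], e1)
      relres <- sqrt(sum((H[seq_len(j + 1L), seq_len(j), drop = FALSE] %*% y -
                            e1)^2)) / bnorm
      total <- total + 1L
      if (relres < tol || H[j + 1L, j] == 0) break
    }
    x <- x + as.numeric(Z[, seq_len(j), drop = FALSE] %*% y)
    if (relres < tol) {
      return(list(x = x, iters = total, relres = relres, converged = TRUE))
    }
    if (total >= maxit) {
      return(list(x = x, iters = total, relres = relres, converged = FALSE))
    }
  }
}

#' Initial concentration field
#'
#' Mean concentration plus an i.i.d. random perturbation (uniform by
#' default) drawn at every band node's closest point, then extended off the
#' surface with the trilinear closest-point interpolation, whose convex
#' weights preserve the perturbation bound.  The initial surface mass
#' \eqn{M_0} is recorded as an attribute and conserved by the stepper.
#'
#' @param params A \code{"model_params"}.
#' @param band A \code{"narrow_band"}.
#' @param seed Integer run seed.
#' @param ops A \code{"cp_operators"} bundle for the band.
#' @param quad Quadrature used to record \eqn{M_0}.
#' @return Extended band field with attributes \code{"M0"} and
#'   \code{"extended"}.
#' @export
initial_condition <- function(params, band, seed, ops,
                              quad = quadrature_spec()) {
  n <- band$n
  amp <- params$perturbation_amplitude
  pert <- with_seed(mix_seed(seed, -1L), {
    if (params$perturbation_dist == "uniform") {
      stats::runif(n, -amp, amp)
    } else {
      stats::rnorm(n, 0, amp)
    }
  })
  f0 <- as.numeric(ops$E1 %*% (params$mean_concentration + pert))
  attr(f0, "extended") <- TRUE
  attr(f0, "M0") <- surface_integral(f0, band, quad)
  f0
}

## internal: fresh solver state from an initial field
new_solver_state <- function(f0, quad = quadrature_spec()) {
  structure(list(f = f0, fm1 = NULL, mu = NULL, t = 0, step = 0L,
                 M0 = attr(f0, "M0")),
            class = "solver_state")
}

#' Assemble the semi-implicit block system for one time step
#'
#' Builds the 2x2 block operator of the BDF2-discretised split system in
#' the unknown ordering \eqn{(\mu^{n+1}, f^{n+1})}:
#' \deqn{\begin{pmatrix} I & Cn^2 M \\ -\frac{2\Delta t}{3 Pe} M^\nu & I
#'   \end{pmatrix}
#'   \begin{pmatrix} \mu \\ f \end{pmatrix} =
#'   \begin{pmatrix} g'(\hat f) \\
#'   \tfrac43 f^n - \tfrac13 f^{n-1} + \tfrac23 \Delta t\, \tilde\xi^n
#'   \end{pmatrix}}
#' with the predictor \eqn{\hat f = 2 f^n - f^{n-1}}.  The very first step
#' (one history level) uses backward Euler with \eqn{\hat f = f^0}.  The
#' mobility inside \eqn{M^\nu} is evaluated at the predictor.
#'
#' @param state A \code{"solver_state"}.
#' @param params A \code{"model_params"}.
#' @param ops A \code{"cp_operators"} bundle.
#' @param xi Extended noise field for this step (zero field for the
#'   deterministic model).
#' @param opts A \code{"solver_options"} list.
#' @return An object of class \code{"block_system"}: matrix-free actions
#'   \code{amul}, \code{Bmv}, \code{Cmv}, the right-hand side, and
#'   \code{blocks()}, which materialises the sparse off-diagonal blocks
#'   on demand (used by the direct Schur mode and linear-algebra
#'   cross-checks).
#' @export
assemble_system <- function(state, params, ops, xi = NULL,
                            opts = solver_options()) {
  n <- ops$band$n
  if (is.null(xi)) {
    xi <- numeric(n)
    attr(xi, "extended") <- TRUE
  }
  if (!is_extended(state$f)) stop("assemble_system: f is not extended")
  if (!is.null(state$fm1) && !is_extended(state$fm1)) {
    stop("assemble_system: f^{n-1} is not extended")
  }
  if (!is_extended(xi)) stop("assemble_system: xi is not extended")
  dt <- resolve_dt(params, ops$h)
  bdf2 <- !is.null(state$fm1)
  if (bdf2) {
    fhat <- 2 * state$f - state$fm1
    coef <- 2 * dt / (3 * params$Pe)
    rhs2 <- (4 / 3) * state$f - (1 / 3) * state$fm1 + (2 * dt / 3) * xi
  } else {
    fhat <- as.numeric(state$f)
    coef <- dt / params$Pe
    rhs2 <- state$f + dt * xi
  }
  constant <- params$mobility_kind == "constant"
  Mmv <- ops$mv$M
  Bmv <- function(v) params$Cn^2 * Mmv(v)
  if (constant) {
    Lnu <- NULL
    Cmv <- function(v) coef * Mmv(v)
  } else {
    # the variable surface operator is never materialised per step: its
    # action is composed from the fresh (cheap, 7-point) mobility
    # Laplacian and the cached interpolation blocks
    Lnu <- variable_laplacian(ops$band, mobility(fhat, "degenerate"),
                              opts$face_mean)
    Lnumv <- matvec_fun(Lnu)
    E1mv <- ops$mv$E1
    sidemv <- ops$mv$aE3mI
    Cmv <- function(v) coef * (E1mv(Lnumv(v)) + sidemv(v))
  }
  blocks <- function() {
    Mnu <- if (constant) ops$M else {
      Mn <- ops$E1 %*% Lnu + ops$aE3mI
      attr(Mn, "label") <- "Mnu"
      Mn
    }
    list(B = params$Cn^2 * ops$M, C = coef * Mnu)
  }
  rhs <- c(g_prime(fhat), rhs2)
  amul <- function(x) {
    x1 <- x[seq_len(n)]
    x2 <- x[n + seq_len(n)]
    c(x1 + Bmv(x2), x2 - Cmv(x1))
  }
  structure(list(blocks = blocks, Bmv = Bmv, Cmv = Cmv, n = n, rhs = rhs,
                 amul = amul, coef = coef, dt = dt,
                 scheme = if (bdf2) "BDF2" else "BDF1", fhat = fhat),
            class = "block_system")
}

#' Schur-complement preconditioner for the block system
#'
#' Exact block factorisation of the system operator,
#' \deqn{P^{-1}\;\mathrm{via}\;
#'   \begin{pmatrix} I & -B \\ 0 & I \end{pmatrix}
#'   \begin{pmatrix} I & 0 \\ 0 & \hat S^{-1} \end{pmatrix}
#'   \begin{pmatrix} I & 0 \\ C & I \end{pmatrix},
#'   \qquad S = I + C B,}
#' where \eqn{B = Cn^2 M} and \eqn{C = \frac{2\Delta t}{3 Pe} M^\nu}.  With
#' an exact Schur solve this is the exact inverse, so the outer flexible
#' GMRES converges in a single iteration; \eqn{\hat S^{-1}} is realised
#' either matrix-free by an inner GMRES or by a sparse direct factorisation
#' of the explicitly assembled Schur complement (small bands).
#'
#' @param system A \code{"block_system"}.
#' @param opts A \code{"solver_options"} list.
#' @return A function applying the preconditioner to a length-\eqn{2n}
#'   vector, with attribute \code{"mode"}.
#' @export
schur_preconditioner <- function(system, opts = solver_options()) {
  n <- system$n
  Bmv <- system$Bmv
  Cmv <- system$Cmv
  if (opts$schur == "direct") {
    if (n > opts$direct_max_n) {
      stop(sprintf(
        "schur_preconditioner: band size %d exceeds direct_max_n = %d; use schur = 'gmres'",
        n, opts$direct_max_n))
    }
    bl <- system$blocks()
    S <- Diagonal(n) + bl$C %*% bl$B
    fac <- Matrix::lu(S)
    sinv <- function(w) as.numeric(Matrix::solve(fac, w))
  } else {
    smul <- function(y) y + Cmv(Bmv(y))
    sinv <- function(w) {
      sol <- fgmres(smul, w, tol = opts$inner_tol,
                    restart = min(opts$inner_maxit, 30L),
                    maxit = opts$inner_maxit)
      sol$x
    }
  }
  out <- function(r) {
    r1 <- r[seq_len(n)]
    r2 <- r[n + seq_len(n)]
    y2 <- sinv(r2 + Cmv(r1))
    c(r1 - Bmv(y2), y2)
  }
  attr(out, "mode") <- opts$schur
  out
}

#' Advance the solver state by one time step
#'
#' Solves the block system by Schur-preconditioned flexible GMRES, applies
#' the mass-conserving \eqn{\beta} correction, and advances the BDF
#' history.  The solved fields satisfy the \eqn{\alpha} side condition and
#' are therefore already constant along surface normals; no separate
#' interpolation pass is applied (doing so would accumulate spatial
#' interpolation error linearly in the step count and can inject energy).
#'
#' @param state A \code{"solver_state"}.
#' @param params A \code{"model_params"}.
#' @param ops A \code{"cp_operators"} bundle.
#' @param xi Extended noise field for this step (\code{NULL} for none).
#' @param opts A \code{"solver_options"} list.
#' @param quad Quadrature for the mass correction.
#' @param system Optionally a pre-assembled \code{"block_system"} (its
#'   right-hand side is still rebuilt from \code{state}; only the operator
#'   blocks are reused, valid for constant mobility).
#' @param precond Optionally a pre-built preconditioner matching
#'   \code{system}.
#' @return The advanced \code{"solver_state"}, with attributes
#'   \code{"iters"} (outer iterations), \code{"relres"} and \code{"beta"}.
#' @export
bdf2_step <- function(state, params, ops, xi = NULL,
                      opts = solver_options(), quad = quadrature_spec(),
                      system = NULL, precond = NULL) {
  scheme_now <- if (is.null(state$fm1)) "BDF1" else "BDF2"
  if (is.null(system) || !identical(system$scheme, scheme_now)) {
    system <- assemble_system(state, params, ops, xi, opts)
    precond <- schur_preconditioner(system, opts)
  } else {
    # reuse the operator blocks; rebuild only the right-hand side
    if (is.null(xi)) {
      xi <- numeric(system$n)
      attr(xi, "extended") <- TRUE
    }
    dt <- system$dt
    if (scheme_now == "BDF2") {
      system$fhat <- 2 * state$f - state$fm1
      rhs2 <- (4 / 3) * state$f - (1 / 3) * state$fm1 + (2 * dt / 3) * xi
    } else {
      system$fhat <- as.numeric(state$f)
      rhs2 <- state$f + dt * xi
    }
    system$rhs <- c(g_prime(system$fhat), rhs2)
    if (is.null(precond)) precond <- schur_preconditioner(system, opts)
  }
  n <- system$n
  x0 <- c(if (is.null(state$mu)) g_prime(system$fhat) else state$mu,
          as.numeric(system$fhat))
  sol <- fgmres(system$amul, system$rhs, precond = precond, x0 = x0,
                tol = opts$tol, restart = opts$restart, maxit = opts$maxit)
  if (!sol$converged) {
    stop(sprintf(
      "bdf2_step: flexible GMRES did not converge in %d iterations (relative residual %.3e)",
      sol$iters, sol$relres))
  }
  # the alpha side condition inside the solve already pins both fields to
  # be constant along normals (to solver tolerance); a separate
  # interpolation pass would re-inject O(h^4) error at every step
  mu <- sol$x[seq_len(n)]
  attr(mu, "extended") <- TRUE
  f <- sol$x[n + seq_len(n)]
  attr(f, "extended") <- TRUE
  f <- beta_correction(f, state$M0, ops$band, quad)
  out <- structure(list(f = f, fm1 = state$f, mu = mu,
                        t = state$t + system$dt, step = state$step + 1L,
                        M0 = state$M0),
                   class = "solver_state")
  attr(out, "iters") <- sol$iters
  attr(out, "relres") <- sol$relres
  attr(out, "beta") <- attr(f, "beta")
  out
}

#' Run a full surface phase-segregation simulation
#'
#' Integrates the (stochastic) Cahn-Hilliard system on a static implicit
#' surface from \eqn{t = 0} to \code{t_end}, recording the characteristic
#' length, total energy and surface mass at a configurable stride.
#'
#' @param geom A \code{"levelset_geometry"}.
#' @param grid A \code{"grid_spec"}.
#' @param params A \code{"model_params"}.
#' @param t_end Final dimensionless time.
#' @param seed Integer run seed (initial condition and noise).
#' @param stride Record diagnostics every \code{stride} steps.
#' @param snapshot_times Times at which to keep field snapshots (in
#'   memory; written to disk by the command-layer wrappers).  Must lie in
#'   \code{[0, t_end]}.
#' @param band,ops Optional pre-built narrow band and operator bundle
#'   (rebuilt from \code{geom}/\code{grid} when \code{NULL}).
#' @param opts A \code{"solver_options"} list.
#' @param quad A \code{"quadrature_spec"}.
#' @param progress Print a progress line every 100 steps.
#' @return An object of class \code{"chc_run"}: list with the diagnostics
#'   data frame \code{series} (columns \code{t}, \code{R_bar},
#'   \code{energy}, \code{mass}), the final \code{state}, snapshots,
#'   parameters and provenance.
#' @export
run_simulation <- function(geom, grid, params, t_end, seed,
                           stride = 1L, snapshot_times = numeric(0),
                           band = NULL, ops = NULL,
                           opts = solver_options(),
                           quad = quadrature_spec(),
                           progress = FALSE) {
  stopifnot(t_end >= 0)
  if (length(snapshot_times) &&
      (min(snapshot_times) < 0 || max(snapshot_times) > t_end)) {
    stop("run_simulation: snapshot times must lie in [0, t_end]")
  }
  if (is.null(band)) band <- build_band(geom, grid)
  if (is.null(ops)) ops <- cp_operators(band)
  dt <- resolve_dt(params, band$grid$h)
  nsteps <- floor(t_end / dt + 1e-9)

  f0 <- initial_condition(params, band, seed, ops, quad)
  state <- new_solver_state(f0, quad)

  record <- function(state) {
    rb <- tryCatch(characteristic_length(state$f, band, ops, quad),
                   error = function(e) NA_real_)
    data.frame(t = state$t, R_bar = rb,
               energy = total_energy(state$f, params, band, ops, quad),
               mass = surface_integral(state$f, band, quad))
  }
  rows <- vector("list", nsteps %/% stride + 2L)
  nrows <- 1L
  rows[[1L]] <- record(state)

  snap_steps <- if (length(snapshot_times)) {
    unique(pmin(pmax(round(snapshot_times / dt), 0L), nsteps))
  } else integer(0)
  snapshots <- list()
  if (0L %in% snap_steps) snapshots[["0"]] <- list(t = 0, f = state$f, mu = NULL)

  iters <- integer(nsteps)
  cached_system <- NULL
  cached_precond <- NULL
  constant_mob <- params$mobility_kind == "constant"

  for (k in seq_len(nsteps)) {
    xi <- if (params$sigma > 0) {
      conserved_noise(sample_tangential_field(band, seed, state$step),
                      state$f, params, ops)
    } else NULL
    if (constant_mob) {
      scheme_now <- if (is.null(state$fm1)) "BDF1" else "BDF2"
      if (is.null(cached_system) ||
          !identical(cached_system$scheme, scheme_now)) {
        # blocks change between the BDF1 startup step and BDF2 proper
        cached_system <- assemble_system(state, params, ops, xi, opts)
        cached_precond <- schur_preconditioner(cached_system, opts)
      }
      st <- bdf2_step(state, params, ops, xi, opts, quad,
                      system = cached_system, precond = cached_precond)
    } else {
      st <- bdf2_step(state, params, ops, xi, opts, quad)
    }
    state <- st
    iters[k] <- attr(st, "iters")
    if (k %% stride == 0L || k == nsteps) {
      nrows <- nrows + 1L
      rows[[nrows]] <- record(state)
    }
    if (k %in% snap_steps) {
      snapshots[[as.character(k)]] <- list(t = state$t, f = state$f,
                                           mu = state$mu)
    }
    if (progress && k %% 100L == 0L) {
      message(sprintf("step %d / %d (t = %.4g), gmres iters %d",
                      k, nsteps, state$t, iters[k]))
    }
  }
  series <- do.call(rbind, rows[seq_len(nrows)])
  if (nsteps == 0L) series <- rows[[1L]]
  structure(list(series = series, state = state, snapshots = snapshots,
                 params = params, geom_name = geom$name, grid = grid,
                 seed = seed, dt = dt, t_end = t_end, nsteps = nsteps,
                 band_n = band$n, iters = iters),
            class = "chc_run")
}

#' @export
print.chc_run <- function(x, ...) {
  cat(sprintf(
    "chc_run: %s, N = %d (band %d), %d steps to t = %g, seed %d\n",
    x$geom_name, x$grid$N, x$band_n, x$nsteps, x$t_end, x$seed))
  if (nrow(x$series)) {
    last <- x$series[nrow(x$series), ]
    cat(sprintf("  final: R_bar = %.4g, energy = %.4g, mass = %.6g\n",
                last$R_bar, last$energy, last$mass))
  }
  invisible(x)
}
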