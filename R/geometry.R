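#' Cartesian grid specification for the embedding domain
#'
#' Defines the uniform Cartesian grid on which the narrow band lives.  The
#' spacing is identical in all three axes; the default domain is the cube
#' \eqn{[-1.25, 1.25]^3} used for the unit-sphere runs.
#'
#' @param N Number of grid nodes per axis (so there are \code{N - 1} cells).
#' @param lower,upper Domain corners.  Scalars are recycled to length 3.
#' @return An object of class \code{"grid_spec"} with fields \code{N},
#'   \code{lower}, \code{upper} and the spacing \code{h}.
#' @examples
#' g <- grid_spec(33)
#' g$h  # 2.5 / 32
#' @export
grid_spec <- function(N, lower = -1.25, upper = 1.25) {
  stopifnot(length(N) == 1L, N >= 2)
  lower <- rep_len(as.numeric(lower), 3L)
  upper <- rep_len(as.numeric(upper), 3L)
  if (any(upper <= lower)) stop("grid_spec: upper must exceed lower")
  h <- (upper - lower) / (N - 1)
  if (diff(range(h)) > 1e-12 * max(h)) {
    stop("grid_spec: spacing must be identical in all axes")
  }
  structure(list(N = as.integer(N), lower = lower, upper = upper, h = h[1L]),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: N = %d per axis, h = %.6g, domain [%g, %g]^3\n",
              x$N, x$h, x$lower[1L], x$upper[1L]))
  invisible(x)
}

#' Grid node coordinates along one axis
#' @param grid A \code{grid_spec}.
#' @param axis Axis index (1, 2 or 3).
#' @return Numeric vector of \code{N} node coordinates.
#' @export
grid_axis <- function(grid, axis) {
  grid$lower[axis] + (seq_len(grid$N) - 1) * grid$h
}

## internal: ensure a coordinate argument is an n x 3 matrix
as_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), 1L, 3L)
  }
}

row_norms <- function(x) sqrt(rowSums(x * x))

new_levelset_geometry <- function(phi, grad, cp, name) {
  structure(list(phi = phi, grad = grad, cp = cp, name = name),
            class = "levelset_geometry")
}

#' @export
print.levelset_geometry <- function(x, ...) {
  cat(sprintf("levelset_geometry: %s\n", x$name))
  invisible(x)
}

#' Implicit sphere geometry
#'
#' Exact signed-distance representation of a sphere.  The closest-point map
#' is the radial projection and is exact to machine precision.
#'
#' @param radius Sphere radius (> 0).
#' @param center Centre, length-3 numeric.
#' @return A \code{"levelset_geometry"}: a list of vectorised evaluators
#'   \code{phi(x)} (signed distance), \code{grad(x)} (its gradient) and
#'   \code{cp(x)} (closest surface point).  \code{cp} attaches a logical
#'   attribute \code{"degenerate"} marking points without a unique closest
#'   point (the centre), for which an arbitrary surface point is returned.
#' @examples
#' s <- sphere_geometry()
#' s$phi(c(0, 0, 0))    # -1
#' s$cp(c(0, 0, 2))     # (0, 0, 1)
#' @export
sphere_geometry <- function(radius = 1, center = c(0, 0, 0)) {
  stopifnot(radius > 0, length(center) == 3L)
  center <- as.numeric(center)
  phi <- function(x) {
    x <- as_points(x)
    sqrt((x[, 1L] - center[1L])^2 + (x[, 2L] - center[2L])^2 +
         (x[, 3L] - center[3L])^2) - radius
  }
  grad <- function(x) {
    x <- as_points(x)
    d <- sweep(x, 2L, center)
    r <- row_norms(d)
    bad <- r < .Machine$double.eps
    r[bad] <- 1
    g <- d / r
    if (any(bad)) g[bad, ] <- matrix(c(0, 0, 1), sum(bad), 3L, byrow = TRUE)
    g
  }
  cp <- function(x) {
    x <- as_points(x)
    d <- sweep(x, 2L, center)
    r <- row_norms(d)
    bad <- r < .Machine$double.eps
    r[bad] <- 1
    if (any(bad)) d[bad, ] <- matrix(c(0, 0, 1), sum(bad), 3L, byrow = TRUE)
    out <- sweep(d * (radius / r), 2L, center, "+")
    attr(out, "degenerate") <- bad
    out
  }
  new_levelset_geometry(phi, grad, cp,
                        sprintf("sphere(r = %g, c = [%g, %g, %g])",
                                radius, center[1L], center[2L], center[3L]))
}

## internal: signed distance and gradient of a finite (capped) cylinder with
## axis along x, |x| <= hx, lateral radius R.  Returns list(phi, grad).
cylinder_sdf <- function(x, R, hx) {
  x <- as_points(x)
  r <- sqrt(x[, 2L]^2 + x[, 3L]^2)
  qr <- r - R          # radial distance to lateral surface
  qx <- abs(x[, 1L]) - hx  # axial distance past the caps
  inside <- pmin(pmax(qr, qx), 0)
  pr <- pmax(qr, 0)
  px <- pmax(qx, 0)
  phi <- inside + sqrt(pr^2 + px^2)

  # gradient: radial direction, axial direction, or their normalized mix
  n <- nrow(x)
  rsafe <- ifelse(r < .Machine$double.eps, 1, r)
  dirr <- cbind(0, x[, 2L] / rsafe, x[, 3L] / rsafe)
  dirx <- cbind(sign(x[, 1L]), 0, 0)
  grad <- matrix(0, n, 3L)
  out_corner <- pr > 0 & px > 0
  out_rad <- pr > 0 & !out_corner
  out_ax <- px > 0 & !out_corner
  ins <- !(out_corner | out_rad | out_ax)
  if (any(out_corner)) {
    w <- cbind(px[out_corner], pr[out_corner])
    nw <- sqrt(rowSums(w^2))
    grad[out_corner, ] <- dirx[out_corner, , drop = FALSE] * (w[, 1L] / nw) +
      dirr[out_corner, , drop = FALSE] * (w[, 2L] / nw)
  }
  grad[out_rad, ] <- dirr[out_rad, , drop = FALSE]
  grad[out_ax, ] <- dirx[out_ax, , drop = FALSE]
  if (any(ins)) {
    # inside: nearest face decides
    lat <- ins & (qr >= qx)
    axf <- ins & !(qr >= qx)
    grad[lat, ] <- dirr[lat, , drop = FALSE]
    grad[axf, ] <- dirx[axf, , drop = FALSE]
  }
  list(phi = phi, grad = grad)
}

#' Dumbbell geometry: two spheres joined by a cylinder
#'
#' Union of two spheres of radius 0.75 centred at \eqn{(\pm 1.125, 0, 0)}
#' and a connecting cylinder of radius 0.375 spanning the region between the
#' sphere centres.  The level-set function is the pointwise minimum of the
#' three primitive signed distances; it is an exact signed distance
#' everywhere except near the junction skeleton, where it remains a valid
#' implicit representation of the union surface.  Closest points are found
#' by projecting onto each primitive, discarding candidates that fall inside
#' the union, and keeping the nearest survivor.
#'
#' @return A \code{"levelset_geometry"} (see [sphere_geometry()]).
#' @examples
#' d <- dumbbell_geometry()
#' d$cp(c(2.5, 0, 0))  # (1.875, 0, 0): apex of the right sphere
#' @export
dumbbell_geometry <- function() {
  Rs <- 0.75; Rc <- 0.375; xc <- 1.125
  s1 <- sphere_geometry(Rs, c(-xc, 0, 0))
  s2 <- sphere_geometry(Rs, c(xc, 0, 0))

  phi <- function(x) {
    x <- as_points(x)
    pmin(s1$phi(x), s2$phi(x), cylinder_sdf(x, Rc, xc)$phi)
  }
  grad <- function(x) {
    x <- as_points(x)
    p1 <- s1$phi(x); p2 <- s2$phi(x)
    cyl <- cylinder_sdf(x, Rc, xc)
    pm <- pmin(p1, p2, cyl$phi)
    g <- cyl$grad
    use1 <- p1 <= pm + 0 & p1 == pm
    use2 <- p2 == pm & !use1
    g[use1, ] <- s1$grad(x[use1, , drop = FALSE])
    g[use2, ] <- s2$grad(x[use2, , drop = FALSE])
    g
  }
  cp <- function(x) {
    x <- as_points(x)
    n <- nrow(x)
    # junction circles: the reentrant crease where sphere meets cylinder.
    # Points in the concave wedge have their closest point on the crease,
    # which no single-primitive projection returns.
    xj <- xc - sqrt(Rs^2 - Rc^2)
    junction_cand <- function(side) {
      r <- sqrt(x[, 2L]^2 + x[, 3L]^2)
      bad <- r < .Machine$double.eps
      rs <- ifelse(bad, 1, r)
      yy <- x[, 2L] / rs; zz <- x[, 3L] / rs
      yy[bad] <- 1; zz[bad] <- 0
      cc <- cbind(side * xj, Rc * yy, Rc * zz)
      attr(cc, "degenerate") <- bad
      cc
    }
    cands <- list(s1$cp(x), s2$cp(x),
                  junction_cand(-1), junction_cand(1), {
      # lateral projection onto the cylinder with the axial coordinate
      # clamped to the finite extent
      r <- sqrt(x[, 2L]^2 + x[, 3L]^2)
      bad <- r < .Machine$double.eps
      rs <- ifelse(bad, 1, r)
      yy <- x[, 2L] / rs; zz <- x[, 3L] / rs
      yy[bad] <- 1; zz[bad] <- 0
      cc <- cbind(pmin(pmax(x[, 1L], -xc), xc), Rc * yy, Rc * zz)
      attr(cc, "degenerate") <- bad
      cc
    })
    best <- matrix(NA_real_, n, 3L)
    bestd <- rep(Inf, n)
    deg <- rep(FALSE, n)
    for (cc in cands) {
      d <- row_norms(x - cc)
      # a candidate is admissible only if it lies on the union boundary,
      # i.e. it is not strictly inside another primitive
      onb <- phi(cc) > -1e-9
      take <- onb & d < bestd
      best[take, ] <- cc[take, , drop = FALSE]
      bestd[take] <- d[take]
      dg <- attr(cc, "degenerate")
      if (!is.null(dg)) deg <- deg | (dg & take)
    }
    if (anyNA(best[, 1L])) {
      # points (e.g. deep inside, equidistant skeleton) where every
      # candidate was discarded: fall back to nearest candidate regardless
      miss <- is.na(best[, 1L])
      for (cc in cands) {
        d <- row_norms(x - cc)
        take <- miss & d < bestd
        best[take, ] <- cc[take, , drop = FALSE]
        bestd[take] <- d[take]
      }
      deg[miss] <- TRUE
    }
    attr(best, "degenerate") <- deg
    best
  }
  new_levelset_geometry(phi, grad, cp, "dumbbell")
}

## internal: linear index of node (i, j, k), 1-based, i fastest
lin_index <- function(ijk, N) {
  (ijk[, 3L] - 1L) * N * N + (ijk[, 2L] - 1L) * N + ijk[, 1L]
}

#' Build the computational narrow band around an implicit surface
#'
#' Collects every grid node within \code{half_width} of the surface and
#' precomputes, per node: the closest surface point, signed distance, unit
#' normal and an orthonormal tangent pair.  The default half-width of five
#' grid spacings guarantees that every tricubic interpolation stencil
#' (centred at a closest point) and every centred-difference stencil applied
#' at those stencil sources lies entirely inside the band.
#'
#' @param geom A \code{"levelset_geometry"}.
#' @param grid A \code{"grid_spec"}.
#' @param half_width Band half-width as a length; defaults to
#'   \code{5 * grid$h}.
#' @return An object of class \code{"narrow_band"}: a list with the node
#'   index matrix \code{ijk}, linear indices \code{idx}, coordinates
#'   \code{x}, signed distances \code{phi}, closest points \code{cp},
#'   frames \code{nvec}, \code{tvec}, \code{bvec}, a reverse lookup
#'   \code{map} (linear grid index to band row, 0 outside), the logical
#'   \code{interior} mask (all six neighbours in band), and the inputs.
#'   Band ordering is deterministic (ascending linear index).
#' @export
build_band <- function(geom, grid, half_width = 5 * grid$h) {
  stopifnot(inherits(geom, "levelset_geometry"), inherits(grid, "grid_spec"))
  if (half_width <= 0) stop("build_band: half_width must be positive")
  N <- grid$N
  ax <- grid_axis(grid, 1L); ay <- grid_axis(grid, 2L); az <- grid_axis(grid, 3L)

  # evaluate phi over the full grid in z-slabs to bound memory
  keep_i <- integer(0); keep_j <- integer(0); keep_k <- integer(0)
  keep_phi <- numeric(0)
  ij <- cbind(rep(ax, times = N), rep(ay, each = N))
  for (k in seq_len(N)) {
    ph <- geom$phi(cbind(ij, az[k]))
    sel <- which(abs(ph) <= half_width)
    if (length(sel)) {
      keep_i <- c(keep_i, ((sel - 1L) %% N) + 1L)
      keep_j <- c(keep_j, ((sel - 1L) %/% N) + 1L)
      keep_k <- c(keep_k, rep(k, length(sel)))
      keep_phi <- c(keep_phi, ph[sel])
    }
  }
  if (!length(keep_i)) stop("build_band: empty band (surface outside domain?)")

  ijk <- cbind(keep_i, keep_j, keep_k)
  idx <- lin_index(ijk, N)
  ord <- order(idx)
  ijk <- ijk[ord, , drop = FALSE]
  idx <- idx[ord]
  phi <- keep_phi[ord]
  x <- cbind(ax[ijk[, 1L]], ay[ijk[, 2L]], az[ijk[, 3L]])

  cp <- geom$cp(x)
  deg <- attr(cp, "degenerate")
  if (!is.null(deg) && any(deg)) {
    stop("build_band: node(s) without a unique closest point inside the band")
  }
  g <- geom$grad(x)
  gnorm <- row_norms(g)
  nvec <- g / gnorm

  # tangent frame: cross the normal with the coordinate axis least aligned
  # with it; deterministic and well conditioned
  least <- max.col(-abs(nvec), ties.method = "first")
  e <- diag(3)[least, , drop = FALSE]
  tvec <- cbind(nvec[, 2L] * e[, 3L] - nvec[, 3L] * e[, 2L],
                nvec[, 3L] * e[, 1L] - nvec[, 1L] * e[, 3L],
                nvec[, 1L] * e[, 2L] - nvec[, 2L] * e[, 1L])
  tvec <- tvec / row_norms(tvec)
  bvec <- cbind(nvec[, 2L] * tvec[, 3L] - nvec[, 3L] * tvec[, 2L],
                nvec[, 3L] * tvec[, 1L] - nvec[, 1L] * tvec[, 3L],
                nvec[, 1L] * tvec[, 2L] - nvec[, 2L] * tvec[, 1L])

  map <- integer(N^3)
  map[idx] <- seq_along(idx)

  # interior nodes: all six axis neighbours present
  nb <- function(di, dj, dk) {
    jj <- ijk + matrix(c(di, dj, dk), nrow(ijk), 3L, byrow = TRUE)
    ok <- jj[, 1L] >= 1L & jj[, 1L] <= N & jj[, 2L] >= 1L & jj[, 2L] <= N &
      jj[, 3L] >= 1L & jj[, 3L] <= N
    res <- integer(nrow(ijk))
    res[ok] <- map[lin_index(jj[ok, , drop = FALSE], N)]
    res
  }
  neigh <- cbind(nb(-1L, 0L, 0L), nb(1L, 0L, 0L), nb(0L, -1L, 0L),
                 nb(0L, 1L, 0L), nb(0L, 0L, -1L), nb(0L, 0L, 1L))
  interior <- rowSums(neigh > 0L) == 6L

  structure(list(geom = geom, grid = grid, half_width = half_width,
                 ijk = ijk, idx = idx, x = x, phi = phi, cp = cp,
                 gnorm = gnorm, nvec = nvec, tvec = tvec, bvec = bvec, map = map,
                 neigh = neigh, interior = interior, n = length(idx)),
            class = "narrow_band")
}

#' @export
print.narrow_band <- function(x, ...) {
  cat(sprintf(
    "narrow_band: %d nodes (%d interior) around %s; N = %d, half-width = %.3g (%.2f h)\n",
    x$n, sum(x$interior), x$geom$name, x$grid$N, x$half_width,
    x$half_width / x$grid$h))
  invisible(x)
}
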