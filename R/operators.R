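#' @importFrom Matrix sparseMatrix Diagonal
NULL

## internal: 1-D Lagrange basis weights.  xq: query coords (vector);
## xs: (d+1) stencil node coords per query, given as base coord + h * 0:d.
## Returns an n x (d+1) weight matrix.
lagrange_weights <- function(xq, xbase, h, degree) {
  p <- degree + 1L
  s <- (xq - xbase) / h  # in [0, degree] for complete stencils
  W <- matrix(1, length(xq), p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      if (a != b) W[, a] <- W[, a] * (s - (b - 1L)) / ((a - 1L) - (b - 1L))
    }
  }
  W
}

#' Closest-point interpolation operator
#'
#' Builds the sparse operator that maps a band field to its tensor-product
#' polynomial interpolant evaluated at each node's closest surface point.
#' Degree 1 (trilinear, 8-node stencils, convex weights) and degree 3
#' (tricubic, 64-node stencils) are supported.  Rows sum to one, so
#' constants are reproduced exactly.
#'
#' @param band A \code{"narrow_band"}.
#' @param degree Interpolation degree, 1 or 3.
#' @return A \code{dgCMatrix} of dimension \code{band$n} square, with
#'   attribute \code{"label"} (\code{"E1"} or \code{"E3"}).
#' @export
interpolation_operator <- function(band, degree = 3L) {
  stopifnot(inherits(band, "narrow_band"), degree %in% c(1L, 3L))
  grid <- band$grid
  N <- grid$N; h <- grid$h
  n <- band$n
  p <- degree + 1L

  base <- matrix(0L, n, 3L)
  W <- vector("list", 3L)
  for (ax in 1:3) {
    cell <- floor((band$cp[, ax] - grid$lower[ax]) / h)  # 0-based cell
    b0 <- if (degree == 1L) cell else cell - 1L
    b0 <- pmin(pmax(b0, 0L), N - p)  # clamp stencil inside the grid
    base[, ax] <- as.integer(b0) + 1L  # 1-based base node
    xb <- grid$lower[ax] + b0 * h
    W[[ax]] <- lagrange_weights(band$cp[, ax], xb, h, degree)
  }

  nst <- p^3
  rows <- rep.int(seq_len(n), nst)
  cols <- integer(n * nst)
  vals <- numeric(n * nst)
  pos <- 0L
  for (c3 in seq_len(p)) for (c2 in seq_len(p)) for (c1 in seq_len(p)) {
    ijk <- cbind(base[, 1L] + (c1 - 1L), base[, 2L] + (c2 - 1L),
                 base[, 3L] + (c3 - 1L))
    cc <- band$map[lin_index(ijk, N)]
    if (any(cc == 0L)) {
      bad <- which(cc == 0L)[1L]
      stop(sprintf(
        "interpolation_operator: incomplete degree-%d stencil for band node %d at (%.4g, %.4g, %.4g); widen the band",
        degree, bad, band$x[bad, 1L], band$x[bad, 2L], band$x[bad, 3L]))
    }
    cols[pos + seq_len(n)] <- cc
    vals[pos + seq_len(n)] <- W[[1L]][, c1] * W[[2L]][, c2] * W[[3L]][, c3]
    pos <- pos + n
  }
  E <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  attr(E, "label") <- paste0("E", degree)
  E
}

#' Cartesian 7-point Laplacian on the band
#'
#' Standard second-order centred finite-difference Laplacian scaled by
#' \code{1/h^2}.  Rows are assembled only for interior band nodes (all six
#' axis neighbours present); the attribute \code{"valid"} marks them.  The
#' closest-point composition checks that only valid rows are ever used.
#'
#' @param band A \code{"narrow_band"}.
#' @return A \code{dgCMatrix} with attributes \code{"label" = "L"} and
#'   \code{"valid"} (logical row mask).
#' @export
cartesian_laplacian <- function(band) {
  stopifnot(inherits(band, "narrow_band"))
  n <- band$n; h2 <- band$grid$h^2
  int <- which(band$interior)
  rows <- rep(int, 7L)
  cols <- c(int, band$neigh[int, 1L], band$neigh[int, 2L],
            band$neigh[int, 3L], band$neigh[int, 4L],
            band$neigh[int, 5L], band$neigh[int, 6L])
  vals <- c(rep(-6 / h2, length(int)), rep(1 / h2, 6L * length(int)))
  L <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  attr(L, "label") <- "L"
  attr(L, "valid") <- band$interior
  L
}

#' Variable-coefficient (mobility-weighted) Laplacian
#'
#' Conservative face-flux discretisation of \eqn{\nabla\cdot(\nu\nabla\,\cdot)}
#' with the face mobility taken as the mean of the two adjacent node values
#' (arithmetic by default).  Reduces exactly to [cartesian_laplacian()] when
#' \eqn{\nu \equiv 1}.
#'
#' @param band A \code{"narrow_band"}.
#' @param nu Mobility values on band nodes (extended off the surface);
#'   must be non-negative.
#' @param face_mean \code{"arithmetic"} (default) or \code{"harmonic"}.
#' @return A \code{dgCMatrix} with attributes \code{"label" = "Lnu"} and
#'   \code{"valid"}.
#' @export
variable_laplacian <- function(band, nu, face_mean = c("arithmetic", "harmonic")) {
  stopifnot(inherits(band, "narrow_band"), length(nu) == band$n)
  face_mean <- match.arg(face_mean)
  if (any(nu < 0)) stop("variable_laplacian: mobility must be non-negative")
  n <- band$n; h2 <- band$grid$h^2
  int <- which(band$interior)
  ni <- length(int)
  rows <- rep(int, 7L)
  cols <- integer(7L * ni)
  vals <- numeric(7L * ni)
  cols[seq_len(ni)] <- int
  diag_acc <- numeric(ni)
  for (f in 1:6) {
    j <- band$neigh[int, f]
    nf <- if (face_mean == "arithmetic") {
      (nu[int] + nu[j]) / 2
    } else {
      ifelse(nu[int] + nu[j] > 0, 2 * nu[int] * nu[j] / (nu[int] + nu[j]), 0)
    }
    cols[f * ni + seq_len(ni)] <- j
    vals[f * ni + seq_len(ni)] <- nf / h2
    diag_acc <- diag_acc - nf / h2
  }
  vals[seq_len(ni)] <- diag_acc
  Lv <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  attr(Lv, "label") <- "Lnu"
  attr(Lv, "valid") <- band$interior
  Lv
}

#' Closest-point surface Laplacian
#'
#' Combines a Cartesian Laplacian with the interpolation operators into the
#' closest-point approximation of the Laplace-Beltrami operator,
#' \deqn{M = E_1 L + \alpha (E_3 - I), \qquad \alpha = 6 / h^2,}
#' where the \eqn{\alpha} side condition pins fields to be constant along
#' surface normals.  Passing a mobility-weighted Laplacian gives the
#' variable-coefficient surface operator.
#'
#' @param E1,E3 Interpolation operators from [interpolation_operator()].
#' @param L A Cartesian Laplacian ([cartesian_laplacian()] or
#'   [variable_laplacian()]).
#' @param alpha Side-condition constant; defaults to \eqn{6/h^2} inferred
#'   from \code{band}.
#' @param band The \code{"narrow_band"} (used for \code{alpha} and the
#'   stencil-support check).
#' @return A \code{dgCMatrix} labelled \code{"M"} or \code{"Mnu"}.
#' @export
surface_laplacian_operator <- function(E1, E3, L, band, alpha = 6 / band$grid$h^2) {
  stopifnot(nrow(E1) == nrow(L), nrow(E3) == nrow(L))
  valid <- attr(L, "valid")
  if (!is.null(valid)) {
    used <- which(diff(E1@p) > 0L)  # columns of E1 with nonzeros
    if (!all(valid[used])) {
      bad <- used[!valid[used]][1L]
      stop(sprintf(
        "surface_laplacian_operator: E1 references band node %d whose Laplacian stencil is incomplete; widen the band",
        bad))
    }
  }
  M <- E1 %*% L + alpha * (E3 - Diagonal(nrow(E3)))
  attr(M, "label") <- if (identical(attr(L, "label"), "Lnu")) "Mnu" else "M"
  M
}

#' Centred-difference gradient operators on the band
#'
#' Returns the three sparse centred first-difference operators
#' \eqn{\partial_x, \partial_y, \partial_z} (rows at interior nodes only,
#' marked by the \code{"valid"} attribute).  Used by the conserved-noise
#' divergence and by the surface-gradient observables.
#'
#' @param band A \code{"narrow_band"}.
#' @return List of three \code{dgCMatrix} objects \code{Gx}, \code{Gy},
#'   \code{Gz}.
#' @export
gradient_operators <- function(band) {
  stopifnot(inherits(band, "narrow_band"))
  n <- band$n; h <- band$grid$h
  int <- which(band$interior)
  mk <- function(f_lo, f_hi) {
    G <- sparseMatrix(i = c(int, int),
                      j = c(band$neigh[int, f_lo], band$neigh[int, f_hi]),
                      x = c(rep(-1 / (2 * h), length(int)),
                            rep(1 / (2 * h), length(int))),
                      dims = c(n, n))
    attr(G, "valid") <- band$interior
    G
  }
  list(Gx = mk(1L, 2L), Gy = mk(3L, 4L), Gz = mk(5L, 6L))
}

## internal: closure applying a dgCMatrix to dense vectors through the
## compiled CSC kernel; bypasses S4 dispatch in the hot stepping loops
matvec_fun <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  p <- A@p; i <- A@i; x <- A@x; nr <- nrow(A)
  function(v) csc_matvec(p, i, x, v, nr)
}

#' Assemble the full closest-point operator set for a band
#'
#' Convenience bundle: \code{E1}, \code{E3}, \code{L}, the gradient
#' operators, the side-condition constant \code{alpha}, the precomputed
#' constant-coefficient surface Laplacian \code{M}, and compiled
#' matrix-vector closures (\code{mv}) for the hot solver loops.
#'
#' @param band A \code{"narrow_band"}.
#' @return A list of class \code{"cp_operators"}.
#' @export
cp_operators <- function(band) {
  E1 <- interpolation_operator(band, 1L)
  E3 <- interpolation_operator(band, 3L)
  L <- cartesian_laplacian(band)
  alpha <- 6 / band$grid$h^2
  M <- surface_laplacian_operator(E1, E3, L, band, alpha)
  G <- gradient_operators(band)
  # precomputed side-condition block, reused by every variable-mobility
  # assembly (it does not depend on the mobility)
  aE3mI <- alpha * (E3 - Diagonal(nrow(E3)))
  mv <- list(M = matvec_fun(M), E1 = matvec_fun(E1), E3 = matvec_fun(E3),
             aE3mI = matvec_fun(aE3mI),
             Gx = matvec_fun(G$Gx), Gy = matvec_fun(G$Gy),
             Gz = matvec_fun(G$Gz))
  structure(list(band = band, E1 = E1, E3 = E3, L = L, M = M,
                 Gx = G$Gx, Gy = G$Gy, Gz = G$Gz, mv = mv,
                 alpha = alpha, aE3mI = aE3mI, h = band$grid$h),
            class = "cp_operators")
}

#' Variable-coefficient surface Laplacian for a mobility field
#'
#' @param ops A \code{"cp_operators"} bundle.
#' @param nu Extended mobility values on band nodes.
#' @param face_mean Face-averaging rule, see [variable_laplacian()].
#' @return Sparse surface operator \eqn{M^\nu = E_1 L^\nu + \alpha(E_3 - I)}.
#' @export
surface_laplacian_nu <- function(ops, nu, face_mean = "arithmetic") {
  Lnu <- variable_laplacian(ops$band, nu, face_mean)
  # E1's stencil support was validated against the Laplacian row mask when
  # the bundle was built; reuse the precomputed side-condition block
  M <- ops$E1 %*% Lnu + ops$aE3mI
  attr(M, "label") <- "Mnu"
  M
}

#' Extend a band field constant along surface normals
#'
#' Applies the cubic closest-point interpolation once, replacing each node
#' value by the interpolated field value at its closest surface point.
#'
#' @param f Numeric band field.
#' @param ops A \code{"cp_operators"} bundle.
#' @return Extended field with attribute \code{"extended" = TRUE}.
#' @export
extend_field <- function(f, ops) {
  out <- as.numeric(ops$E3 %*% f)
  attr(out, "extended") <- TRUE
  out
}

is_extended <- function(f) isTRUE(attr(f, "extended"))
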