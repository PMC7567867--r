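#' Orthonormal Fourier basis for electron densities
#'
#' Real trigonometric tensor-product basis on a cubic box of edge
#' \code{box_length}.  The 1D family on \code{[0, L)} is
#' \deqn{\{1/\sqrt L,\ \sqrt{2/L}\cos(2\pi k x/L),\ \sqrt{2/L}\sin(2\pi k x/L)\}}
#' which is orthonormal under the continuum inner product; 3D functions
#' are products of one 1D function per axis.  Two truncations are
#' available: \code{"tensor"} keeps all \code{per_dim^3} products,
#' \code{"ball"} keeps products whose total frequency
#' \eqn{k_x + k_y + k_z} does not exceed the maximum 1D frequency,
#' trading span for a smaller coefficient budget.  Basis functions are
#' ordered by total frequency, then lexicographically by their 1D
#' indices; the ordering is deterministic and stable.
#'
#' @param per_dim number of 1D basis functions per axis (odd; default
#'   25 gives 1D frequencies up to 12)
#' @param box_length box edge in Angstrom
#' @param mode \code{"tensor"} or \code{"ball"}
#' @param origin position of the box corner (3-vector, Angstrom)
#' @return an object of class \code{fourier_basis}
#' @export
fourier_basis <- function(per_dim = 25, box_length, mode = c("tensor", "ball"),
                          origin = c(0, 0, 0)) {
  mode <- match.arg(mode)
  per_dim <- as.integer(per_dim)
  if (per_dim < 1L) stop("per_dim must be positive")
  if (per_dim %% 2L == 0L) {
    stop("per_dim must be odd (a constant plus full cos/sin pairs)")
  }
  if (box_length <= 0) stop("box_length must be positive")
  f1 <- .freq_1d(seq_len(per_dim))
  idx <- expand.grid(ix = seq_len(per_dim), iy = seq_len(per_dim),
                     iz = seq_len(per_dim))
  freq <- f1[idx$ix] + f1[idx$iy] + f1[idx$iz]
  if (mode == "ball") {
    keep <- freq <= max(f1)
    idx <- idx[keep, ]; freq <- freq[keep]
  }
  ord <- order(freq, idx$ix, idx$iy, idx$iz)
  idx <- idx[ord, ]; freq <- freq[ord]
  structure(list(per_dim = per_dim, box_length = as.numeric(box_length),
                 mode = mode, origin = as.numeric(origin),
                 index = cbind(ix = idx$ix, iy = idx$iy, iz = idx$iz),
                 freq = freq, L = nrow(idx)),
            class = "fourier_basis")
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat("fourier_basis:", x$L, "functions (", x$mode, ", per_dim",
      x$per_dim, ") on box", x$box_length, "A\n")
  invisible(x)
}

# 1D frequency of 1-based function index: 1 -> 0, 2k/2k+1 -> k
.freq_1d <- function(j) j %/% 2L

# n_points x per_dim matrix of 1D basis values at relative coords t
.basis_1d <- function(t, per_dim, L) {
  B <- matrix(0, length(t), per_dim)
  B[, 1] <- 1 / sqrt(L)
  kmax <- (per_dim - 1L) %/% 2L
  for (k in seq_len(kmax)) {
    w <- 2 * pi * k * t / L
    B[, 2L * k] <- sqrt(2 / L) * cos(w)
    if (2L * k + 1L <= per_dim) B[, 2L * k + 1L] <- sqrt(2 / L) * sin(w)
  }
  B
}

#' Evaluate all basis functions at arbitrary points
#'
#' @param basis a \code{fourier_basis}
#' @param points matrix of Cartesian points (rows) inside the box
#' @return a \code{nrow(points) x L} matrix of basis-function values,
#'   columns in the basis ordering
#' @export
evaluate_basis <- function(basis, points) {
  points <- matrix(points, ncol = 3L)
  t <- sweep(points, 2L, basis$origin)
  eps <- 1e-9 * basis$box_length
  if (any(t < -eps) || any(t > basis$box_length + eps)) {
    stop("point(s) outside the basis box")
  }
  Px <- .basis_1d(t[, 1], basis$per_dim, basis$box_length)
  Py <- .basis_1d(t[, 2], basis$per_dim, basis$box_length)
  Pz <- .basis_1d(t[, 3], basis$per_dim, basis$box_length)
  Px[, basis$index[, "ix"], drop = FALSE] *
    Py[, basis$index[, "iy"], drop = FALSE] *
    Pz[, basis$index[, "iz"], drop = FALSE]
}

#' Project a grid field onto the density basis
#'
#' Voxel-volume-weighted Riemann sum of \eqn{n(r)\phi_l(r)} over the
#' uniform grid, computed separably per axis.  On a uniform periodic
#' box sampling this quadrature is exact for band-limited integrands,
#' so the grid must resolve the basis: the maximum 1D frequency has to
#' stay below \code{points_per_dim / 2} (Nyquist).
#'
#' @param grid_values field values (length \code{points_per_dim^3}, x
#'   fastest)
#' @param gs the \code{grid_spec} of the field; must coincide with the
#'   basis box
#' @param basis a \code{fourier_basis}
#' @return an object of class \code{density_coeffs} with elements
#'   \code{u} (length L) and \code{basis}
#' @export
project_density <- function(grid_values, gs, basis) {
  n <- gs$points_per_dim
  if (length(grid_values) != n^3) stop("grid value count does not match grid")
  .check_basis_grid(basis, gs)
  kmax <- (basis$per_dim - 1L) %/% 2L
  if (2L * kmax >= n) {
    stop("Nyquist violation: 1D frequency ", kmax,
         " needs more than ", n, " grid points per dimension")
  }
  t1 <- gs$spacing * (seq_len(n) - 1)
  B <- .basis_1d(t1, basis$per_dim, basis$box_length)  # shared by all axes
  p <- basis$per_dim
  a <- array(grid_values, dim = c(n, n, n))
  # contract x: (p, ny, nz)
  tx <- array(crossprod(B, matrix(a, n, n * n)), dim = c(p, n, n))
  # contract y: bring y first -> (n_y, nz, p_x), multiply -> (p_y, nz, p_x)
  ty <- array(crossprod(B, matrix(aperm(tx, c(2L, 3L, 1L)), n, n * p)),
              dim = c(p, n, p))
  # contract z: bring z first -> (n_z, p_x, p_y) -> (p_z, p_x, p_y)
  tz <- array(crossprod(B, matrix(aperm(ty, c(2L, 3L, 1L)), n, p * p)),
              dim = c(p, p, p))
  u_full <- aperm(tz, c(2L, 3L, 1L)) * gs$spacing^3  # (p_x, p_y, p_z)
  u <- u_full[basis$index]
  structure(list(u = u, basis = basis), class = "density_coeffs")
}

#' Reconstruct the continuous density at arbitrary points
#'
#' \eqn{n(r) = \sum_l u_l \phi_l(r)}: grid-independent evaluation of the
#' expanded density.
#'
#' @param coeffs a \code{density_coeffs}
#' @param points matrix of Cartesian points inside the box
#' @return numeric vector of density values
#' @export
reconstruct_density <- function(coeffs, points) {
  drop(evaluate_basis(coeffs$basis, points) %*% coeffs$u)
}

#' Reconstruct a density on a full grid
#'
#' Separable fast path equivalent to calling
#' \code{\link{reconstruct_density}} at every grid point.
#'
#' @param coeffs a \code{density_coeffs}
#' @param gs a \code{grid_spec} coinciding with the basis box
#' @return numeric vector of length \code{points_per_dim^3} (x fastest)
#' @export
reconstruct_on_grid <- function(coeffs, gs) {
  basis <- coeffs$basis
  .check_basis_grid(basis, gs)
  n <- gs$points_per_dim
  p <- basis$per_dim
  u_full <- array(0, dim = c(p, p, p))
  u_full[basis$index] <- coeffs$u
  t1 <- gs$spacing * (seq_len(n) - 1)
  B <- .basis_1d(t1, p, basis$box_length)
  m1 <- array(B %*% matrix(u_full, p, p * p), dim = c(n, p, p))
  m2 <- array(B %*% matrix(aperm(m1, c(2L, 3L, 1L)), p, p * n),
              dim = c(n, p, n))
  m3 <- array(B %*% matrix(aperm(m2, c(2L, 3L, 1L)), p, n * n),
              dim = c(n, n, n))  # axes (z, x, y)
  as.vector(aperm(m3, c(2L, 3L, 1L)))
}

#' Integral of an expanded density over the box
#'
#' Only the constant basis function has a nonzero integral, so the
#' electron count is \eqn{u_0 L^{3/2}} where \eqn{u_0} is the constant
#' coefficient.
#'
#' @param coeffs a \code{density_coeffs}
#' @return the integral (electron count for physical densities)
#' @export
integrate_density <- function(coeffs) {
  i0 <- which(coeffs$basis$freq == 0L)
  coeffs$u[i0] * coeffs$basis$box_length^1.5
}

.check_basis_grid <- function(basis, gs) {
  if (abs(basis$box_length - gs$box_length) > 1e-9) {
    stop("basis box length does not match grid box length")
  }
  if (max(abs(basis$origin - gs$origin)) > 1e-9) {
    stop("basis origin does not match grid origin")
  }
  invisible(TRUE)
}

.check_same_basis <- function(a, b) {
  if (a$per_dim != b$per_dim || a$mode != b$mode || a$L != b$L ||
      abs(a$box_length - b$box_length) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9) {
    stop("density bases do not match")
  }
  invisible(TRUE)
}
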