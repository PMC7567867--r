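#' Gaussian approximation to the nuclear potential on a grid
#'
#' The molecular descriptor of the learned Hohenberg-Kohn map: each
#' atom contributes a Gaussian of height equal to its charge,
#' \deqn{v(r) = \sum_\alpha Z_\alpha \exp(-\|r - R_\alpha\|^2 / (2\gamma^2)),}
#' evaluated at every grid point.  The width \code{gamma} is a
#' hyperparameter normally chosen by cross-validation together with the
#' grid spacing and the kernel width.
#'
#' @param conf a \code{conformer}
#' @param gs a \code{grid_spec}; descriptors are only comparable across
#'   conformers when they share one grid
#' @param gamma Gaussian width in Angstrom (> 0)
#' @return an object of class \code{potential_field} with elements
#'   \code{values} (length \code{points_per_dim^3}, x fastest),
#'   \code{gamma} and \code{grid}
#' @export
gaussian_potential <- function(conf, gs, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar")
  }
  if (!.conformer_in_grid(conf, gs)) {
    warning("atom(s) outside the descriptor grid box; ",
            "descriptor values near the boundary will be truncated")
  }
  n <- gs$points_per_dim
  ax <- gs$origin[1] + gs$spacing * (seq_len(n) - 1)
  ay <- gs$origin[2] + gs$spacing * (seq_len(n) - 1)
  az <- gs$origin[3] + gs$spacing * (seq_len(n) - 1)
  inv2g2 <- 1 / (2 * gamma^2)
  vals <- numeric(n^3)
  # separable per atom: exp(-|r-R|^2) = ex(x) ey(y) ez(z)
  for (a in seq_len(n_atoms(conf))) {
    ex <- exp(-(ax - conf$coords[a, 1])^2 * inv2g2)
    ey <- exp(-(ay - conf$coords[a, 2])^2 * inv2g2)
    ez <- exp(-(az - conf$coords[a, 3])^2 * inv2g2)
    vals <- vals + conf$charges[a] *
      as.vector(outer(as.vector(outer(ex, ey)), ez))
  }
  structure(list(values = vals, gamma = gamma, grid = gs),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("potential_field: gamma", x$gamma, "A on", x$grid$points_per_dim,
      "^3 grid; max", signif(max(x$values), 5), "\n")
  invisible(x)
}

#' Euclidean distance between two potential descriptors
#'
#' The unweighted Euclidean norm over grid values.  Voxel-volume
#' weighting is deliberately omitted: it would be a constant factor on
#' a shared grid and is absorbed into the kernel width when that width
#' is cross-validated.
#'
#' @param field_a,field_b \code{potential_field} objects sharing one
#'   grid and one gamma
#' @return non-negative scalar; zero iff the fields are identical
#' @export
descriptor_distance <- function(field_a, field_b) {
  .check_same_descriptor_config(field_a, field_b)
  sqrt(sum((field_a$values - field_b$values)^2))
}

.check_same_descriptor_config <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$points_per_dim != gb$points_per_dim ||
      abs(ga$box_length - gb$box_length) > 1e-12 ||
      max(abs(ga$origin - gb$origin)) > 1e-12) {
    stop("descriptor grids do not match")
  }
  if (abs(a$gamma - b$gamma) > 1e-12) stop("descriptor gamma values differ")
  invisible(TRUE)
}
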