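#' Molecular conformer
#'
#' A conformer bundles element symbols, per-atom charges and Cartesian
#' coordinates (Angstrom).  Charges default to valence electron counts
#' (frozen-core convention, H = 1, C = 4, O = 6), which is the
#' convention used by the Gaussian nuclear-potential descriptor and the
#' analytic valence densities; full nuclear charges can be requested.
#'
#' @param species character vector of element symbols
#' @param coords numeric matrix, one row per atom, three columns
#' @param charges optional numeric vector of per-atom charges; derived
#'   from \code{species} when missing
#' @param label free-form identifier
#' @param energy optional named numeric vector or list with elements
#'   \code{E_low} and/or \code{E_high} (kcal/mol)
#' @param full_z use full nuclear charges instead of valence counts
#' @return an object of class \code{conformer}
#' @export
conformer <- function(species, coords, charges = NULL, label = "",
                      energy = NULL, full_z = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have three columns")
  storage.mode(coords) <- "double"
  if (length(species) != nrow(coords)) {
    stop("species length (", length(species),
         ") does not match coordinate rows (", nrow(coords), ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(charges)) charges <- as.numeric(valence_charges(species, full_z))
  if (length(charges) != length(species)) {
    stop("charges length does not match species length")
  }
  if (any(!is.finite(charges)) || any(charges <= 0)) {
    stop("all charges must be positive and finite")
  }
  en <- NULL
  if (!is.null(energy)) {
    en <- list(E_low = NULL, E_high = NULL)
    energy <- as.list(energy)
    if (!is.null(energy$E_low)) en$E_low <- as.numeric(energy$E_low)
    if (!is.null(energy$E_high)) en$E_high <- as.numeric(energy$E_high)
  }
  structure(list(species = as.character(species),
                 charges = as.numeric(charges),
                 coords  = coords,
                 label   = as.character(label),
                 energy  = en),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("conformer:", length(x$species), "atoms")
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n  formula:", paste0(names(table(x$species)),
                             as.integer(table(x$species)), collapse = " "),
      "\n")
  if (!is.null(x$energy)) {
    if (!is.null(x$energy$E_low))
      cat("  E_low: ", format(x$energy$E_low), " kcal/mol\n", sep = "")
    if (!is.null(x$energy$E_high))
      cat("  E_high:", format(x$energy$E_high), "kcal/mol\n")
  }
  invisible(x)
}

#' Number of atoms in a conformer
#' @param conf a \code{conformer}
#' @return integer atom count
#' @export
n_atoms <- function(conf) length(conf$species)

#' Replace the coordinates of a conformer
#'
#' Convenience used throughout the dynamics and symmetry code: returns a
#' copy of \code{conf} with new coordinates and everything else intact.
#'
#' @param conf a \code{conformer}
#' @param coords new coordinate matrix (same shape)
#' @return a \code{conformer}
#' @export
set_coords <- function(conf, coords) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == dim(conf$coords))) stop("coordinate shape mismatch")
  conf$coords <- coords
  conf
}

#' Cubic grid specification
#'
#' A cubic, axis-aligned grid of \code{points_per_dim}^3 points with
#' spacing \code{box_length / points_per_dim}; point \code{(i, j, k)}
#' (zero-based) sits at \code{origin + spacing * (i, j, k)}.  This is
#' the sampling convention of Gaussian cube files and makes uniform
#' trigonometric quadrature on the periodic box exact.
#'
#' @param box_length cubic box edge in Angstrom
#' @param points_per_dim number of grid points along each axis
#' @param origin 3-vector, position of the first grid point (Angstrom)
#' @return an object of class \code{grid_spec}
#' @export
grid_spec <- function(box_length, points_per_dim, origin = c(0, 0, 0)) {
  if (box_length <= 0) stop("box_length must be positive")
  points_per_dim <- as.integer(points_per_dim)
  if (points_per_dim < 2L) stop("points_per_dim must be at least 2")
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("origin must be a finite 3-vector")
  }
  structure(list(box_length = as.numeric(box_length),
                 points_per_dim = points_per_dim,
                 origin = as.numeric(origin),
                 spacing = box_length / points_per_dim),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", x$points_per_dim, "^3 points, box", x$box_length,
      "A, spacing", signif(x$spacing, 6), "A\n")
  invisible(x)
}

#' Grid point coordinates
#'
#' @param gs a \code{grid_spec}
#' @return an \code{n^3 x 3} matrix of Cartesian grid point positions,
#'   with the first axis varying fastest (Fortran/cube ordering over z
#'   slowest is NOT used; here x varies fastest, consistent with R array
#'   linearization of \code{array(dim = c(n, n, n))})
#' @export
grid_points <- function(gs) {
  ax <- gs$origin[1] + gs$spacing * (seq_len(gs$points_per_dim) - 1)
  ay <- gs$origin[2] + gs$spacing * (seq_len(gs$points_per_dim) - 1)
  az <- gs$origin[3] + gs$spacing * (seq_len(gs$points_per_dim) - 1)
  n <- gs$points_per_dim
  cbind(rep(ax, times = n * n),
        rep(rep(ay, each = n), times = n),
        rep(az, each = n * n))
}

#' Grid spec centered on a conformer
#'
#' Builds a cubic grid whose center coincides with the nuclear centroid
#' of \code{conf}.  Descriptors of different conformers are only
#' comparable on a shared grid, so this is normally called once per
#' dataset on the aligned reference geometry.
#'
#' @param conf a \code{conformer}
#' @param box_length box edge in Angstrom
#' @param points_per_dim grid points per axis
#' @return a \code{grid_spec}
#' @export
centered_grid <- function(conf, box_length, points_per_dim) {
  ctr <- colMeans(conf$coords)
  grid_spec(box_length, points_per_dim, origin = ctr - box_length / 2)
}

# TRUE when every atom lies inside [origin, origin + box] with margin
.conformer_in_grid <- function(conf, gs, margin = 0) {
  lo <- gs$origin + margin
  hi <- gs$origin + gs$box_length - margin
  all(sweep(conf$coords, 2, lo, ">=")) && all(sweep(conf$coords, 2, hi, "<="))
}
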