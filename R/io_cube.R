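#' Write a scalar grid field to a Gaussian cube file
#'
#' Cube headers are in bohr; the package-internal Angstrom grid is
#' converted on the way out.  Values are written in the cube loop order
#' (x slowest, z fastest); internally fields are stored with x fastest,
#' matching R array linearization, and the reordering is handled here.
#'
#' @param field_values numeric vector of length \code{points_per_dim^3}
#'   (x varies fastest)
#' @param gs the \code{grid_spec} the field lives on
#' @param conf the \code{conformer} the field belongs to (atoms go into
#'   the cube header)
#' @param path output path
#' @param comment first header line
#' @return invisibly, \code{path}
#' @export
write_cube <- function(field_values, gs, conf, path,
                       comment = "densfunc grid field") {
  n <- gs$points_per_dim
  if (length(field_values) != n^3) {
    stop("field has ", length(field_values), " values but grid needs ", n^3)
  }
  b <- densfunc_units$bohr_angstrom
  hdr <- c(comment, "densfunc cube (all header lengths in bohr)")
  hdr <- c(hdr, sprintf("%5d %12.6f %12.6f %12.6f", n_atoms(conf),
                        gs$origin[1] / b, gs$origin[2] / b, gs$origin[3] / b))
  sp <- gs$spacing / b
  hdr <- c(hdr,
           sprintf("%5d %12.6f %12.6f %12.6f", n, sp, 0, 0),
           sprintf("%5d %12.6f %12.6f %12.6f", n, 0, sp, 0),
           sprintf("%5d %12.6f %12.6f %12.6f", n, 0, 0, sp))
  zfull <- valence_charges(conf$species, full_z = TRUE)
  hdr <- c(hdr, sprintf("%5d %12.6f %12.6f %12.6f %12.6f",
                        zfull, conf$charges,
                        conf$coords[, 1] / b, conf$coords[, 2] / b,
                        conf$coords[, 3] / b))
  a <- array(field_values, dim = c(n, n, n))
  vals <- as.vector(aperm(a, c(3L, 2L, 1L)))  # cube order: z fastest
  pad <- (6L - length(vals) %% 6L) %% 6L
  m <- matrix(c(sprintf("%13.6e", vals), rep("", pad)), ncol = 6L,
              byrow = TRUE)
  body <- trimws(apply(m, 1L, paste, collapse = " "), which = "right")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Inverse of \code{\link{write_cube}}: bohr header quantities are
#' converted back to Angstrom and values are reordered to the internal
#' x-fastest layout.  Only axis-aligned cubic grids are supported.
#'
#' @param path cube file path
#' @return a list with elements \code{values} (x fastest), \code{grid}
#'   (a \code{grid_spec}) and \code{conformer} (species recovered from
#'   nuclear charge, charges from the header charge column)
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  b <- densfunc_units$bohr_angstrom
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  l3 <- num(lines[3])
  nat <- as.integer(l3[1])
  origin <- l3[2:4] * b
  ax <- num(lines[4]); ay <- num(lines[5]); az <- num(lines[6])
  n <- as.integer(ax[1])
  if (as.integer(ay[1]) != n || as.integer(az[1]) != n) {
    stop("only cubic grids are supported")
  }
  if (any(abs(c(ax[3:4], ay[c(2, 4)], az[2:3])) > 1e-12)) {
    stop("only axis-aligned grids are supported")
  }
  spacing <- ax[2] * b
  gs <- grid_spec(spacing * n, n, origin)
  atoms <- t(vapply(lines[7:(6 + nat)], num, numeric(5)))
  zmap <- setNames(.element_data$symbol, .element_data$Z)
  species <- zmap[as.character(as.integer(atoms[, 1]))]
  if (anyNA(species)) stop("unsupported element in cube header")
  conf <- conformer(species, atoms[, 3:5] * b, charges = atoms[, 2])
  vals <- unlist(lapply(lines[-(1:(6 + nat))],
                        function(s) num(s)), use.names = FALSE)
  if (length(vals) != n^3) {
    stop("cube body has ", length(vals), " values, expected ", n^3)
  }
  a <- array(vals, dim = c(n, n, n))       # as read: z fastest
  values <- as.vector(aperm(a, c(3L, 2L, 1L)))  # back to x fastest
  list(values = values, grid = gs, conformer = conf)
}
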