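#' Physical constants and unit conversions
#'
#' All quantities inside the package are kept in a single unit system:
#' lengths in Angstrom, energies in kcal/mol, times in fs, masses in amu.
#' Conversions to the conventions of external file formats (cube files
#' use bohr) or of the literature (atomic-unit friction coefficients)
#' happen only at the boundaries, through the constants collected here.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_angstrom}{1 bohr in Angstrom (0.529177).}
#'   \item{au_time_fs}{1 atomic unit of time in fs (0.02418884).}
#'   \item{kB}{Boltzmann constant in kcal/mol/K.}
#'   \item{acc_conv}{Conversion factor from (kcal/mol/Angstrom)/amu to
#'     Angstrom/fs^2; its reciprocal converts amu Angstrom^2/fs^2 to
#'     kcal/mol for kinetic energies.}
#' }
#' @export
densfunc_units <- list(
  bohr_angstrom = 0.529177,
  au_time_fs    = 0.02418884,
  kB            = 0.0019872041,
  acc_conv      = 4.184e-4
)

#' Convert a friction coefficient from atomic units to inverse fs
#'
#' Langevin friction constants are often quoted in atomic units of
#' inverse time; integrators here take them in fs^-1.
#'
#' @param gamma_au friction in atomic units (inverse atomic time units)
#' @return friction in fs^-1
#' @examples
#' friction_au_to_fs(0.01)  # ~0.413 fs^-1
#' @export
friction_au_to_fs <- function(gamma_au) {
  gamma_au / densfunc_units$au_time_fs
}

# standard atomic weights (amu) and valence electron counts for the
# elements the toy systems use; valence counts follow the frozen-core
# convention (H = 1, C = 4, N = 5, O = 6)
.element_data <- data.frame(
  symbol  = c("H", "C", "N", "O"),
  mass    = c(1.008, 12.011, 14.007, 15.999),
  valence = c(1L, 4L, 5L, 6L),
  Z       = c(1L, 6L, 7L, 8L),
  stringsAsFactors = FALSE
)

#' Atomic masses for a vector of element symbols
#' @param species character vector of element symbols
#' @return numeric vector of masses in amu
#' @export
atomic_masses <- function(species) {
  i <- match(species, .element_data$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  .element_data$mass[i]
}

#' Valence electron counts (frozen-core convention) for element symbols
#' @param species character vector of element symbols
#' @param full_z if TRUE return full nuclear charges instead of valence
#'   counts
#' @return integer vector of charges
#' @export
valence_charges <- function(species, full_z = FALSE) {
  i <- match(species, .element_data$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  if (full_z) .element_data$Z[i] else .element_data$valence[i]
}
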