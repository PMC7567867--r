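#' Analytic surrogate molecular systems
#'
#' Each toy system bundles an equilibrium template geometry (built
#' from a Z-matrix), a deterministic low-level energy surface (harmonic
#' bonds and bends plus periodic torsion terms, zero at the template by
#' construction), a smooth geometry-dependent correction whose sum with
#' the low-level surface defines the high-level surface, and analytic
#' valence electron densities.  The two surfaces play the roles of a
#' semilocal density-functional calculation and a coupled-cluster
#' calculation: cheap labels everywhere, expensive labels differing by
#' a smooth correction of a few kcal/mol.  No stochastic noise is
#' added to labels -- both surfaces are deterministic functions of
#' geometry, as electronic-structure labels are.
#'
#' @name toy_systems
#' @seealso \code{\link{toy_water}}, \code{\link{toy_ethanol}},
#'   \code{\link{toy_ring}}
NULL

.new_toy_system <- function(name, species, zmat, eq, bonds, angles,
                            torsions, bond_corr, torsion_corr,
                            density_widths, bond_density_weight,
                            sample_sd, torsion_wells = NULL,
                            sad_widths = NULL) {
  template_coords <- .zmat_to_cartesian(zmat, eq)
  sys <- structure(list(name = name, species = species, zmat = zmat,
                        eq = eq, bonds = bonds, angles = angles,
                        torsions = torsions, bond_corr = bond_corr,
                        torsion_corr = torsion_corr,
                        density_widths = density_widths,
                        sad_widths = if (is.null(sad_widths))
                          density_widths else sad_widths,
                        bond_density_weight = bond_density_weight,
                        sample_sd = sample_sd,
                        torsion_wells = torsion_wells, E0 = 0),
                   class = "toy_system")
  sys$template <- conformer(species, template_coords,
                            label = paste0(name, ":template"))
  sys$E0 <- .raw_internal_energy(sys, template_coords)
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat("toy_system '", x$name, "': ", length(x$species), " atoms, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      length(x$torsions), " torsion terms\n", sep = "")
  invisible(x)
}

.raw_internal_energy <- function(sys, coords) {
  e <- 0
  b <- sys$bonds
  for (r in seq_len(nrow(b))) {
    e <- e + 0.5 * b$k[r] * (.bond_length(coords, b$i[r], b$j[r]) -
                             b$r0[r])^2
  }
  a <- sys$angles
  for (r in seq_len(nrow(a))) {
    e <- e + 0.5 * a$k[r] *
      (.bend_angle(coords, a$i[r], a$j[r], a$l[r]) - a$th0[r])^2
  }
  for (tt in sys$torsions) {
    e <- e + tt$V(.dihedral(coords, tt$idx[1], tt$idx[2], tt$idx[3],
                            tt$idx[4]))
  }
  e
}

.correction_energy <- function(sys, coords) {
  e <- 0
  bc <- sys$bond_corr
  if (!is.null(bc)) {
    for (r in seq_len(nrow(bc))) {
      d <- (.bond_length(coords, bc$i[r], bc$j[r]) - bc$r0[r]) / bc$w[r]
      e <- e + bc$a[r] * tanh(d) * exp(-(d / 2)^2)
    }
  }
  for (tc in sys$torsion_corr) {
    e <- e + tc$V(.dihedral(coords, tc$idx[1], tc$idx[2], tc$idx[3],
                            tc$idx[4]))
  }
  e
}

.check_species <- function(sys, conf) {
  if (!identical(sys$species, conf$species)) {
    stop("conformer species do not match system '", sys$name, "'")
  }
  invisible(TRUE)
}

#' Low-level surrogate energy
#'
#' Harmonic bond and bend terms plus periodic torsion terms, shifted so
#' the template geometry is exactly zero.  Plays the role of the cheap
#' self-consistent energy label.
#'
#' @param sys a \code{toy_system}
#' @param conf a \code{conformer} (or coordinate matrix) with the
#'   system's species
#' @return energy in kcal/mol
#' @export
low_level_energy <- function(sys, conf) {
  coords <- if (inherits(conf, "conformer")) {
    .check_species(sys, conf)
    conf$coords
  } else as.matrix(conf)
  .raw_internal_energy(sys, coords) - sys$E0
}

#' High-level surrogate energy
#'
#' The low-level surface plus a smooth, bounded, sign-asymmetric
#' correction: tagged bonds contribute
#' \eqn{a \tanh(d/w) \exp(-(d/2w)^2)} in the bond displacement
#' \eqn{d = r - r_0} (compressed and stretched bonds are corrected in
#' opposite directions), and tagged torsions contribute smooth periodic
#' terms that can reorder conformer minima between the two surfaces.
#' Amplitudes are calibrated so dataset-wide mean
#' \eqn{|E_{high}-E_{low}|} sits in the 1-3 kcal/mol regime typical of
#' semilocal functionals against coupled cluster.
#'
#' @inheritParams low_level_energy
#' @return energy in kcal/mol
#' @export
high_level_energy <- function(sys, conf) {
  coords <- if (inherits(conf, "conformer")) {
    .check_species(sys, conf)
    conf$coords
  } else as.matrix(conf)
  .raw_internal_energy(sys, coords) - sys$E0 +
    .correction_energy(sys, coords)
}

#' Toy water: 3 atoms, 2 bonds, 1 bend, mirror symmetry
#'
#' O-H bonds at 0.9572 A, bend at 104.52 degrees.  The sampling widths
#' emulate an ensemble of random (not merely thermal) geometries whose
#' low-level energies span on the order of 100 kcal/mol, as used for
#' small-molecule benchmark sets.  The high-low correction lives on
#' the two O-H bonds as a sign-asymmetric, near-linear function of the
#' bond displacement over the sampled range (length scale 0.8 A):
#' compressed bonds are destabilized, stretched bonds overstabilized,
#' and the correction surface has far smaller total variation than the
#' total surface.  Over the default ensemble the mean unsigned
#' correction is about 2.5 kcal/mol with extremes around 8 -- the error
#' regime of a semilocal functional against coupled cluster.
#'
#' @return a \code{toy_system}
#' @export
toy_water <- function() {
  zmat <- data.frame(ref1 = c(0L, 1L, 1L), ref2 = c(0L, 0L, 2L),
                     ref3 = c(0L, 0L, 0L))
  eq <- data.frame(bond = c(0, 0.9572, 0.9572), angle = c(0, 0, 104.52),
                   dihedral = c(0, 0, 0))
  .new_toy_system(
    name = "toy-water",
    species = c("O", "H", "H"),
    zmat = zmat, eq = eq,
    bonds = data.frame(i = c(2L, 3L), j = c(1L, 1L), k = c(600, 600),
                       r0 = c(0.9572, 0.9572)),
    angles = data.frame(i = 2L, j = 1L, l = 3L, k = 75,
                        th0 = 104.52 * pi / 180),
    torsions = list(),
    bond_corr = data.frame(i = c(2L, 3L), j = c(1L, 1L), a = c(10, 10),
                           r0 = c(0.9572, 0.9572), w = c(0.8, 0.8)),
    torsion_corr = list(),
    density_widths = c(O = 0.45, H = 0.40),
    sad_widths = c(O = 0.25, H = 0.22),
    bond_density_weight = 0.6,
    sample_sd = list(bond = 0.18, angle = 13, dihedral = 0)
  )
}

#' Toy ethanol: 9 atoms, hydroxyl torsion with anti/gauche minima
#'
#' A C-C-O-H chain with methyl and methylene hydrogens.  The hydroxyl
#' torsion has a three-fold well structure tilted so that the
#' low-level surface has its global minimum at gauche while the
#' high-level correction reverses the tilt and makes anti the global
#' minimum -- the classic situation where the two levels of theory
#' disagree about which conformer is lowest.  The template sits at the
#' exact low-level gauche minimum (located numerically, so the
#' template is a stationary point to machine precision).
#'
#' @return a \code{toy_system}
#' @export
toy_ethanol <- function() {
  zmat <- data.frame(
    ref1 = c(0L, 1L, 2L, 3L, 2L, 2L, 1L, 1L, 1L),
    ref2 = c(0L, 0L, 1L, 2L, 1L, 1L, 2L, 2L, 2L),
    ref3 = c(0L, 0L, 0L, 1L, 3L, 3L, 3L, 3L, 3L))
  a_low <- 0.5
  v_oh <- function(phi) {
    1.4 * (1 - cos(3 * (phi - pi))) + a_low * (1 + cos(phi - pi)) / 2
  }
  # template hydroxyl dihedral: exact gauche minimum of the tilted well
  phi_min <- stats::optimize(v_oh, c(0.1, 2))$minimum * 180 / pi
  eq <- data.frame(
    bond = c(0, 1.512, 1.431, 0.971, 1.094, 1.094, 1.090, 1.090, 1.090),
    angle = c(0, 0, 107.8, 108.5, 110.1, 110.1, 110.5, 110.5, 110.5),
    dihedral = c(0, 0, 0, phi_min, 121, -121, 60, 180, -60))
  v_me <- function(phi) 0.4 * (1 + cos(3 * phi))
  .new_toy_system(
    name = "toy-ethanol",
    species = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    zmat = zmat, eq = eq,
    bonds = data.frame(
      i = 2:9, j = zmat$ref1[2:9],
      k = c(350, 400, 550, 380, 380, 380, 380, 380),
      r0 = eq$bond[2:9]),
    angles = data.frame(
      i = 3:9, j = zmat$ref1[3:9], l = zmat$ref2[3:9],
      k = c(70, 65, 60, 60, 60, 60, 60),
      th0 = eq$angle[3:9] * pi / 180),
    torsions = list(
      list(idx = c(4L, 3L, 2L, 1L), V = v_oh),
      list(idx = c(7L, 1L, 2L, 3L), V = v_me)),
    bond_corr = data.frame(i = c(3L, 4L), j = c(2L, 3L), a = c(7, 7),
                           r0 = c(1.431, 0.971), w = c(0.5, 0.5)),
    torsion_corr = list(
      list(idx = c(4L, 3L, 2L, 1L),
           V = function(phi) -3 * (1 + cos(phi - pi)) / 2)),
    density_widths = c(C = 0.50, O = 0.45, H = 0.40),
    sad_widths = c(C = 0.28, O = 0.25, H = 0.22),
    bond_density_weight = 0.6,
    sample_sd = list(bond = 0.05, angle = 7, dihedral = 25),
    torsion_wells = list(
      list(row = 4L, centers = c(phi_min, 180, 360 - phi_min)))
  )
}

#' Toy ring systems: planar aromatic surrogates
#'
#' Three variants of a planar six-membered carbon ring.
#' \code{"c2v"} is a benzenediol-like molecule: two in-plane hydroxyl
#' oxygens at ring positions 1 and 3, each with a hydrogen whose
#' in-plane orientation (dihedral 0 or 180 degrees) gives four planar
#' minima that the order-4 point group of the heavy-atom skeleton maps
#' onto one another.  \code{"cs"} is the phenol-like fragment: the
#' same ring with a single hydroxyl at position 1, sharing the ring
#' and hydroxyl-rotation coordinates (and their energy terms) with the
#' c2v variant, so its conformers sample the same critical degrees of
#' freedom at lower cost.  \code{"d6h"} is a bare hexagonal ring with
#' one hydrogen per carbon -- a benzene-like geometry with a point
#' group of order 24.
#'
#' @param variant \code{"c2v"} (default), \code{"cs"} or \code{"d6h"}
#' @return a \code{toy_system}
#' @export
toy_ring <- function(variant = c("c2v", "cs", "d6h")) {
  variant <- match.arg(variant)
  ring_ref1 <- c(0L, 1L, 2L, 3L, 4L, 5L)
  ring_ref2 <- c(0L, 0L, 1L, 2L, 3L, 4L)
  ring_ref3 <- c(0L, 0L, 0L, 1L, 2L, 3L)
  if (variant == "d6h") {
    zmat <- data.frame(
      ref1 = c(ring_ref1, 1L, 2L, 3L, 4L, 5L, 6L),
      ref2 = c(ring_ref2, 2L, 3L, 4L, 5L, 6L, 1L),
      ref3 = c(ring_ref3, 3L, 4L, 5L, 6L, 1L, 2L))
    eq <- data.frame(
      bond = c(0, rep(1.40, 5), rep(1.09, 6)),
      angle = c(0, 0, rep(120, 4), rep(120, 6)),
      dihedral = c(rep(0, 6), rep(180, 6)))
    species <- c(rep("C", 6), rep("H", 6))
    torsions <- lapply(7:12, function(i) {
      list(idx = c(i, zmat$ref1[i], zmat$ref2[i], zmat$ref3[i]),
           V = function(phi) 8 * (1 + cos(phi)))
    })
    sd <- list(bond = 0.03, angle = 3, dihedral = 4)
    dens_w <- c(C = 0.50, H = 0.40)
    bond_corr <- data.frame(i = 2L, j = 1L, a = 4, r0 = 1.40, w = 0.25)
    torsion_corr <- list()
  } else if (variant == "cs") {
    # phenol-like fragment: C1..C6 ring, O7 on C1, ring H8..H12 on
    # C2/C3/C4/C5/C6, hydroxyl H13 on O7
    zmat <- data.frame(
      ref1 = c(ring_ref1, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
      ref2 = c(ring_ref2, 2L, 3L, 4L, 5L, 6L, 1L, 1L),
      ref3 = c(ring_ref3, 3L, 4L, 5L, 6L, 1L, 2L, 2L))
    eq <- data.frame(
      bond = c(0, rep(1.40, 5), 1.36, rep(1.09, 5), 0.97),
      angle = c(0, 0, rep(120, 4), 120, rep(120, 5), 109),
      dihedral = c(rep(0, 6), 180, 180, 180, 180, 180, 180, 0))
    species <- c(rep("C", 6), "O", rep("H", 5), "H")
    stiff <- function(phi) 8 * (1 + cos(phi))
    hydroxyl <- function(phi) 3 * (1 - cos(2 * phi))
    torsions <- c(
      lapply(8:12, function(i) {
        list(idx = c(i, zmat$ref1[i], zmat$ref2[i], zmat$ref3[i]),
             V = stiff)
      }),
      list(list(idx = c(13L, 7L, 1L, 2L), V = hydroxyl)))
    sd <- list(bond = 0.03, angle = 3, dihedral = 6)
    dens_w <- c(C = 0.50, O = 0.45, H = 0.40)
    bond_corr <- data.frame(i = 7L, j = 1L, a = 4, r0 = 1.36, w = 0.25)
    torsion_corr <- list()
  } else {
    # C1..C6 ring, O7 on C1, O8 on C3, ring H9..H12 on C2/C4/C5/C6,
    # hydroxyl H13 on O7, H14 on O8
    zmat <- data.frame(
      ref1 = c(ring_ref1, 1L, 3L, 2L, 4L, 5L, 6L, 7L, 8L),
      ref2 = c(ring_ref2, 2L, 4L, 3L, 5L, 6L, 1L, 1L, 3L),
      ref3 = c(ring_ref3, 3L, 5L, 4L, 6L, 1L, 2L, 2L, 4L))
    eq <- data.frame(
      bond = c(0, rep(1.40, 5), 1.36, 1.36, rep(1.09, 4), 0.97, 0.97),
      angle = c(0, 0, rep(120, 4), 120, 120, rep(120, 4), 109, 109),
      dihedral = c(rep(0, 6), 180, 180, 180, 180, 180, 180, 0, 0))
    species <- c(rep("C", 6), "O", "O", rep("H", 4), "H", "H")
    stiff <- function(phi) 8 * (1 + cos(phi))          # in-plane, eq 180
    hydroxyl <- function(phi) 3 * (1 - cos(2 * phi))   # wells at 0 and 180
    torsions <- c(
      lapply(7:12, function(i) {
        list(idx = c(i, zmat$ref1[i], zmat$ref2[i], zmat$ref3[i]),
             V = stiff)
      }),
      lapply(13:14, function(i) {
        list(idx = c(i, zmat$ref1[i], zmat$ref2[i], zmat$ref3[i]),
             V = hydroxyl)
      }))
    sd <- list(bond = 0.03, angle = 3, dihedral = 6)
    dens_w <- c(C = 0.50, O = 0.45, H = 0.40)
    bond_corr <- data.frame(i = c(7L, 8L), j = c(1L, 3L), a = c(4, 4),
                            r0 = c(1.36, 1.36), w = c(0.25, 0.25))
    torsion_corr <- list()
  }
  nb <- nrow(zmat)
  bonds <- data.frame(i = 2:nb, j = zmat$ref1[2:nb],
                      k = ifelse(species[2:nb] == "H", 420,
                                 ifelse(species[2:nb] == "O", 450, 500)),
                      r0 = eq$bond[2:nb])
  # explicit ring-closure bond keeps the hexagon rigid
  bonds <- rbind(bonds, data.frame(i = 6L, j = 1L, k = 500, r0 = 1.40))
  angles <- data.frame(i = 3:nb, j = zmat$ref1[3:nb], l = zmat$ref2[3:nb],
                       k = 70, th0 = eq$angle[3:nb] * pi / 180)
  .new_toy_system(
    name = paste0("toy-ring-", variant),
    species = species, zmat = zmat, eq = eq,
    bonds = bonds, angles = angles, torsions = torsions,
    bond_corr = bond_corr, torsion_corr = torsion_corr,
    density_widths = dens_w,
    sad_widths = dens_w * 0.55,
    bond_density_weight = 0.6,
    sample_sd = sd,
    torsion_wells = if (variant == "c2v") {
      list(list(row = 13L, centers = c(0, 180)),
           list(row = 14L, centers = c(0, 180)))
    } else if (variant == "cs") {
      list(list(row = 13L, centers = c(0, 180)))
    } else NULL)
}

#' The four planar minima of the c2v toy ring
#'
#' The hydroxyl-rotamer minima: both in-plane hydrogen orientations of
#' each of the two hydroxyl groups.  All four are planar, so the
#' molecular-plane reflection fixes each one and the order-4 skeleton
#' group maps the set onto itself -- they contribute exactly four
#' unique geometries to a symmetry-augmented training set.
#'
#' @param sys a \code{toy_ring("c2v")} system
#' @return list of four \code{conformer} objects
#' @export
toy_ring_minima <- function(sys) {
  if (!identical(sys$name, "toy-ring-c2v")) {
    stop("minima are defined for the c2v toy ring")
  }
  combos <- expand.grid(phi1 = c(0, 180), phi2 = c(0, 180))
  lapply(seq_len(nrow(combos)), function(r) {
    eq <- sys$eq
    eq$dihedral[13] <- combos$phi1[r]
    eq$dihedral[14] <- combos$phi2[r]
    conformer(sys$species, .zmat_to_cartesian(sys$zmat, eq),
              label = sprintf("%s:min-%d-%d", sys$name,
                              combos$phi1[r], combos$phi2[r]))
  })
}

#' Point group of a toy ring's heavy-atom skeleton
#'
#' For the c2v variant the group is detected on the 12-atom skeleton
#' (ring plus oxygens plus ring hydrogens, hydroxyl hydrogens
#' excluded), yielding the order-4 group \{E, C2, sigma_h, sigma_v\}
#' used for training-set augmentation; for the d6h variant the full
#' molecule's order-24 group is returned.
#'
#' @param sys a \code{toy_ring} system
#' @param tol detection tolerance (Angstrom)
#' @return a \code{symmetry_group}
#' @export
toy_ring_symmetry_group <- function(sys, tol = 1e-3) {
  if (identical(sys$name, "toy-ring-d6h")) {
    return(detect_point_group(sys$template, tol))
  }
  skel <- conformer(sys$species[1:12], sys$template$coords[1:12, ],
                    label = "skeleton")
  g <- detect_point_group(skel, tol)
  # operations act about the skeleton centroid; atom maps refer to the
  # skeleton only, so drop them for use with full conformers
  g$operations <- lapply(g$operations, function(op) {
    op$atom_map <- NULL
    op
  })
  g
}

#' Superposition-of-atomic-densities (SAD) valence density on a grid
#'
#' Each atom contributes an isotropic normalized Gaussian scaled by its
#' valence electron count:
#' \deqn{n(r) = \sum_\alpha N_\alpha (2\pi w_\alpha^2)^{-3/2}
#'   \exp(-\|r-R_\alpha\|^2/(2 w_\alpha^2)),}
#' integrating to the total valence count.  A cheap density carrying
#' no information about chemical bonds beyond the nuclear positions.
#' By default it uses the system's \code{sad_widths}: the sharper
#' peaks of isolated-atom densities, which the default grid
#' under-resolves slightly -- the counterpart of projecting cusped
#' atomic densities on a grid tuned for smooth pseudo-densities.
#'
#' @param sys a \code{toy_system} (provides per-species widths)
#' @param conf a \code{conformer}
#' @param gs a \code{grid_spec}
#' @param widths named per-species Gaussian widths; defaults to the
#'   system's \code{sad_widths}
#' @return numeric vector of grid values (x fastest)
#' @export
sad_density <- function(sys, conf, gs, widths = NULL) {
  if (is.null(widths)) widths <- sys$sad_widths
  w <- widths[conf$species]
  if (any(is.na(w)) || any(w <= 0)) stop("invalid density width")
  nval <- valence_charges(conf$species)
  n <- gs$points_per_dim
  ax <- gs$origin[1] + gs$spacing * (seq_len(n) - 1)
  ay <- gs$origin[2] + gs$spacing * (seq_len(n) - 1)
  az <- gs$origin[3] + gs$spacing * (seq_len(n) - 1)
  vals <- numeric(n^3)
  for (a in seq_len(n_atoms(conf))) {
    pref <- nval[a] / (2 * pi * w[a]^2)^1.5
    inv <- 1 / (2 * w[a]^2)
    ex <- exp(-(ax - conf$coords[a, 1])^2 * inv)
    ey <- exp(-(ay - conf$coords[a, 2])^2 * inv)
    ez <- exp(-(az - conf$coords[a, 3])^2 * inv)
    vals <- vals + pref * as.vector(outer(as.vector(outer(ex, ey)), ez))
  }
  vals
}

#' Bond-aware valence density on a grid
#'
#' The SAD density plus a normalized Gaussian at each bond midpoint
#' whose amplitude decreases smoothly with bond stretch,
#' \eqn{A(r) = w_{bond} (1 + \tanh((r_0 - r)/0.3))}; the total is then
#' rescaled so the grid integral equals the valence electron count.
#' Unlike SAD, this density changes shape (not just position) with
#' geometry, carrying bonding information the way a self-consistent
#' density does.
#'
#' @inheritParams sad_density
#' @param weight bond-term amplitude; defaults to the system's
#'   \code{bond_density_weight}; 0 reduces to \code{sad_density}
#' @return numeric vector of grid values
#' @export
bonded_density <- function(sys, conf, gs, weight = NULL) {
  if (is.null(weight)) weight <- sys$bond_density_weight
  vals <- sad_density(sys, conf, gs, widths = sys$density_widths)
  if (weight == 0) return(vals)
  n <- gs$points_per_dim
  ax <- gs$origin[1] + gs$spacing * (seq_len(n) - 1)
  ay <- gs$origin[2] + gs$spacing * (seq_len(n) - 1)
  az <- gs$origin[3] + gs$spacing * (seq_len(n) - 1)
  wb <- 0.45  # bond-blob width, Angstrom
  b <- sys$bonds
  for (r in seq_len(nrow(b))) {
    len <- .bond_length(conf$coords, b$i[r], b$j[r])
    amp <- weight * (1 + tanh((b$r0[r] - len) / 0.3))
    mid <- (conf$coords[b$i[r], ] + conf$coords[b$j[r], ]) / 2
    pref <- amp / (2 * pi * wb^2)^1.5
    inv <- 1 / (2 * wb^2)
    ex <- exp(-(ax - mid[1])^2 * inv)
    ey <- exp(-(ay - mid[2])^2 * inv)
    ez <- exp(-(az - mid[3])^2 * inv)
    vals <- vals + pref * as.vector(outer(as.vector(outer(ex, ey)), ez))
  }
  target <- sum(valence_charges(conf$species))
  total <- sum(vals) * gs$spacing^3
  vals * (target / total)
}

#' Sample thermally spread conformers of a toy system
#'
#' Seeded Gaussian displacements of the Z-matrix internal coordinates
#' (bond lengths, bend angles, dihedrals), scaled by \code{spread} and
#' the system's per-coordinate widths, mapped back to Cartesians.
#' Torsions registered as multi-well (\code{torsion_wells}) draw their
#' center uniformly among the well positions before the Gaussian
#' displacement, so ensembles of multi-minimum systems cover all
#' conformer basins the way trajectories harvested from
#' finite-temperature MD do.  At \code{spread = 1} the bundled systems
#' produce ensembles whose low-level energies span well over
#' 10 kcal/mol.
#'
#' @param sys a \code{toy_system}
#' @param n number of conformers
#' @param spread dimensionless thermal-spread multiplier
#' @param seed integer seed; the ensemble is reproducible bit for bit
#' @return list of \code{conformer} objects
#' @export
sample_conformers <- function(sys, n, spread = 1, seed = 1) {
  if (n < 1L) stop("n must be at least 1")
  if (spread < 0) stop("spread must be non-negative")
  nb <- nrow(sys$zmat)
  sd <- sys$sample_sd
  wells <- sys$torsion_wells
  .with_seed(seed, {
    lapply(seq_len(n), function(s) {
      vals <- sys$eq
      vals$bond <- vals$bond + stats::rnorm(nb, 0, sd$bond * spread)
      vals$angle <- vals$angle + stats::rnorm(nb, 0, sd$angle * spread)
      vals$dihedral <- vals$dihedral +
        stats::rnorm(nb, 0, sd$dihedral * spread)
      for (wl in wells) {
        ctr <- wl$centers[sample.int(length(wl$centers), 1L)]
        vals$dihedral[wl$row] <- ctr +
          stats::rnorm(1L, 0, sd$dihedral * spread)
      }
      vals$bond[1] <- 0
      conformer(sys$species, .zmat_to_cartesian(sys$zmat, vals),
                label = sprintf("%s:%04d", sys$name, s))
    })
  })
}

#' Default descriptor/density grid for a toy system
#'
#' A cubic box centered on the template with enough margin that both
#' the Gaussian potential and the analytic densities decay to
#' negligible values at the faces, at a spacing fine enough for the
#' atomic density widths.
#'
#' @param sys a \code{toy_system}
#' @param margin clearance beyond the molecular extent (Angstrom)
#' @param spacing target grid spacing (Angstrom)
#' @return a \code{grid_spec}
#' @export
default_grid <- function(sys, margin = 4, spacing = 0.4) {
  ext <- max(apply(sys$template$coords, 2L,
                   function(x) diff(range(x))))
  box <- ext + 2 * margin
  n <- ceiling(box / spacing)
  centered_grid(sys$template, box, n)
}

#' Build a complete surrogate dataset
#'
#' The full input side of the learning pipeline for one molecule:
#' sampled conformers, their Gaussian-potential descriptor fields,
#' density coefficients projected from the chosen analytic density,
#' and both energy labels.  Energies are stored relative to the lowest
#' low-level energy in the set (the shift is retained in
#' \code{reference_shift}); the difference column is unaffected by the
#' shift.
#'
#' @param sys a \code{toy_system}
#' @param n number of conformers
#' @param gs grid; defaults to \code{default_grid(sys)}
#' @param basis density basis; defaults to a ball-truncated Fourier
#'   basis with 7 functions per dimension on the grid box
#' @param density_mode \code{"bonded"} (default) or \code{"sad"}
#' @param seed integer seed for conformer sampling
#' @param spread thermal-spread multiplier
#' @param gamma Gaussian-potential width (Angstrom)
#' @param store_potentials keep the descriptor fields in the dataset
#'   (needed to fit a potential-to-density map)
#' @return an object of class \code{density_dataset} with fields
#'   \code{conformers}, \code{u} (n x L coefficients), \code{E_low},
#'   \code{E_high}, \code{delta}, \code{reference_shift},
#'   \code{molecule}, \code{potentials}, \code{basis}, \code{grid},
#'   \code{gamma}, \code{density_mode}
#' @export
make_dataset <- function(sys, n, gs = NULL, basis = NULL,
                         density_mode = c("bonded", "sad"), seed = 1,
                         spread = 1, gamma = 0.6,
                         store_potentials = TRUE) {
  density_mode <- match.arg(density_mode)
  if (is.null(gs)) gs <- default_grid(sys)
  if (is.null(basis)) {
    basis <- fourier_basis(7, gs$box_length, mode = "ball",
                           origin = gs$origin)
  }
  confs <- sample_conformers(sys, n, spread = spread, seed = seed)
  dens_fn <- if (density_mode == "sad") sad_density else bonded_density
  U <- matrix(NA_real_, n, basis$L)
  V <- if (store_potentials) {
    matrix(NA_real_, n, gs$points_per_dim^3)
  } else NULL
  E_low <- numeric(n)
  E_high <- numeric(n)
  for (i in seq_len(n)) {
    U[i, ] <- project_density(dens_fn(sys, confs[[i]], gs), gs, basis)$u
    if (store_potentials) {
      V[i, ] <- gaussian_potential(confs[[i]], gs, gamma)$values
    }
    E_low[i] <- low_level_energy(sys, confs[[i]])
    E_high[i] <- high_level_energy(sys, confs[[i]])
  }
  shift <- min(E_low)
  E_low <- E_low - shift
  E_high <- E_high - shift
  for (i in seq_len(n)) {
    confs[[i]]$energy <- list(E_low = E_low[i], E_high = E_high[i])
  }
  structure(list(conformers = confs, u = U, potentials = V,
                 E_low = E_low, E_high = E_high,
                 delta = E_high - E_low,
                 reference_shift = shift,
                 molecule = rep(sys$name, n),
                 basis = basis, grid = gs, gamma = gamma,
                 density_mode = density_mode, seed = seed),
            class = "density_dataset")
}

#' @export
print.density_dataset <- function(x, ...) {
  cat("density_dataset:", length(x$conformers), "records of",
      paste(unique(x$molecule), collapse = "+"), "\n")
  cat("  basis L =", x$basis$L, "(", x$basis$mode, "), grid",
      x$grid$points_per_dim, "^3, gamma =", x$gamma,
      ", density =", x$density_mode, "\n")
  cat("  E_low range", paste(signif(range(x$E_low), 4), collapse = " .. "),
      "kcal/mol; mean |delta| =", signif(mean(abs(x$delta)), 4), "\n")
  invisible(x)
}

#' Potential fields of a dataset as a list
#'
#' Reassembles \code{potential_field} objects from a dataset's stored
#' descriptor matrix, e.g. to fit a potential-to-density map.
#'
#' @param dataset a \code{density_dataset} built with
#'   \code{store_potentials = TRUE}
#' @return list of \code{potential_field} objects
#' @export
dataset_potentials <- function(dataset) {
  if (is.null(dataset$potentials)) {
    stop("dataset was built without stored potentials")
  }
  lapply(seq_len(nrow(dataset$potentials)), function(i) {
    structure(list(values = dataset$potentials[i, ],
                   gamma = dataset$gamma, grid = dataset$grid),
              class = "potential_field")
  })
}
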