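#' Point-group symmetry operation
#'
#' A 3x3 orthogonal matrix (determinant +1 or -1) acting about a fixed
#' origin, together with the atom permutation it induces on a
#' reference geometry (when known).
#'
#' @param matrix 3x3 orthogonal matrix
#' @param atom_map optional integer permutation: applying the operation
#'   to reference atom \code{i} lands on reference atom
#'   \code{atom_map[i]}
#' @param origin point the operation acts about (3-vector)
#' @return an object of class \code{symmetry_op}
#' @export
symmetry_operation <- function(matrix, atom_map = NULL,
                               origin = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (max(abs(crossprod(matrix) - diag(3))) > 1e-8) {
    stop("matrix is not orthogonal")
  }
  structure(list(matrix = matrix, atom_map = atom_map,
                 origin = as.numeric(origin)),
            class = "symmetry_op")
}

#' Apply a symmetry operation to a conformer
#'
#' Coordinates transform as \eqn{x' = R (x - o) + o}; species, charges
#' and energy labels (exact invariants under a symmetry of the
#' molecule) are carried over unchanged.
#'
#' @param conf a \code{conformer}
#' @param op a \code{symmetry_op}
#' @return the transformed \code{conformer}
#' @export
apply_symmetry_operation <- function(conf, op) {
  shifted <- sweep(conf$coords, 2L, op$origin)
  set_coords(conf, sweep(shifted %*% t(op$matrix), 2L, op$origin, "+"))
}

# species-preserving nearest-neighbour matching of two point sets;
# returns the permutation (new -> ref index) or NULL if no bijection
# exists within tol
.match_atoms <- function(ref, new, species, tol) {
  n <- nrow(ref)
  perm <- integer(n)
  used <- logical(n)
  for (i in seq_len(n)) {
    cand <- which(species == species[i] & !used)
    if (length(cand) == 0L) return(NULL)
    d <- sqrt(colSums((t(ref[cand, , drop = FALSE]) - new[i, ])^2))
    j <- cand[which.min(d)]
    if (min(d) > tol) return(NULL)
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}

#' Detect the point group of a rigid conformer
#'
#' Enumerates candidate orthogonal transforms from pairs of reference
#' atoms: any symmetry operation must map a chosen non-collinear atom
#' pair onto a species- and distance-compatible pair, and each such
#' image pair determines exactly one proper and one improper orthogonal
#' transform.  Transforms that map the full species-labelled point set
#' onto itself within \code{tol} are kept, deduplicated, and checked
#' for group closure.  Intended for rigid point groups of small
#' molecules (up to 64 atoms); linear molecules (continuous axes) are
#' not supported.
#'
#' @param conf a \code{conformer}; operations act about its nuclear
#'   centroid
#' @param tol position tolerance in Angstrom (default 1e-3)
#' @return an object of class \code{symmetry_group} with elements
#'   \code{operations} (including the identity), \code{order} and
#'   \code{closure_verified}
#' @export
detect_point_group <- function(conf, tol = 1e-3) {
  if (!all(is.finite(conf$coords))) stop("non-finite coordinates")
  if (n_atoms(conf) > 64L) {
    stop("point-group detection supports at most 64 atoms; ",
         "supply an explicit operation list instead")
  }
  ctr <- colMeans(conf$coords)
  X <- sweep(conf$coords, 2L, ctr)
  sp <- conf$species
  d <- sqrt(rowSums(X^2))
  ia <- which.max(d)
  if (d[ia] < 10 * tol) stop("degenerate geometry: all atoms at centroid")
  cr <- t(apply(X, 1L, function(v) .cross3(X[ia, ], v)))
  ib <- which.max(sqrt(rowSums(cr^2)))
  if (sqrt(sum(cr[ib, ]^2)) < 10 * tol * d[ia]) {
    stop("linear molecule: continuous axes are not supported")
  }
  Fref <- .pair_frame(X[ia, ], X[ib, ])
  dots_ab <- sum(X[ia, ] * X[ib, ])
  ops <- list()
  mats <- list()
  cand_a <- which(sp == sp[ia] & abs(d - d[ia]) < 2 * tol)
  cand_b <- which(sp == sp[ib] & abs(d - d[ib]) < 2 * tol)
  for (ja in cand_a) {
    for (jb in cand_b) {
      if (abs(sum(X[ja, ] * X[jb, ]) - dots_ab) >
          4 * tol * (d[ia] + d[ib])) next
      Fimg <- tryCatch(.pair_frame(X[ja, ], X[jb, ]),
                       error = function(e) NULL)
      if (is.null(Fimg)) next
      for (improper in c(FALSE, TRUE)) {
        Fi <- Fimg
        if (improper) Fi[, 3] <- -Fi[, 3]
        R <- Fi %*% t(Fref)
        if (.known_matrix(R, mats, 1e-6)) next
        perm <- .match_atoms(X, X %*% t(R), sp, tol)
        if (!is.null(perm)) {
          mats[[length(mats) + 1L]] <- R
          ops[[length(ops) + 1L]] <-
            symmetry_operation(R, atom_map = perm, origin = ctr)
        }
      }
    }
  }
  if (!.known_matrix(diag(3), mats, 1e-6)) {
    ops <- c(list(symmetry_operation(diag(3),
                                     atom_map = seq_len(n_atoms(conf)),
                                     origin = ctr)), ops)
    mats <- c(list(diag(3)), mats)
  }
  closed <- TRUE
  for (i in seq_along(mats)) {
    for (j in seq_along(mats)) {
      if (!.known_matrix(mats[[i]] %*% mats[[j]], mats, 1e-6)) {
        closed <- FALSE
        break
      }
    }
    if (!closed) break
  }
  structure(list(operations = ops, order = length(ops),
                 closure_verified = closed),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  nref <- sum(vapply(x$operations,
                     function(o) det(o$matrix) < 0, logical(1)))
  cat("symmetry_group: order", x$order, "(", x$order - nref, "proper,",
      nref, "improper );",
      if (x$closure_verified) "closure verified" else "NOT closed", "\n")
  invisible(x)
}

#' Build an explicit symmetry group from matrices
#'
#' The route for supplying externally known operations (the role a
#' dedicated symmetry package would play): matrices are orthogonality-
#' checked, the identity is added if absent, and closure is verified.
#'
#' @param matrices list of 3x3 orthogonal matrices
#' @param origin common origin of the operations
#' @return a \code{symmetry_group}
#' @export
symmetry_group_from_matrices <- function(matrices, origin = c(0, 0, 0)) {
  mats <- lapply(matrices, function(m) base::matrix(as.numeric(m), 3, 3))
  if (!.known_matrix(diag(3), mats, 1e-8)) mats <- c(list(diag(3)), mats)
  ops <- lapply(mats, symmetry_operation, origin = origin)
  closed <- TRUE
  for (i in seq_along(mats)) {
    for (j in seq_along(mats)) {
      if (!.known_matrix(mats[[i]] %*% mats[[j]], mats, 1e-8)) {
        closed <- FALSE
      }
    }
  }
  structure(list(operations = ops, order = length(ops),
                 closure_verified = closed),
            class = "symmetry_group")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal frame from two non-collinear vectors
.pair_frame <- function(a, b) {
  e1 <- a / sqrt(sum(a^2))
  u2 <- b - sum(b * e1) * e1
  n2 <- sqrt(sum(u2^2))
  if (n2 < 1e-10) stop("collinear pair")
  e2 <- u2 / n2
  cbind(e1, e2, .cross3(e1, e2))
}

.known_matrix <- function(R, mats, tol) {
  for (m in mats) if (max(abs(m - R)) < tol) return(TRUE)
  FALSE
}

#' Reflection through the least-squares heavy-atom plane
#'
#' Builds the mirror operation through the plane fitted (by singular
#' value decomposition) to all non-hydrogen atoms.  For a molecule
#' whose heavy atoms are coplanar, reflecting the hydrogens through
#' this plane is an exact symmetry of the energy, so applying it to a
#' training set of non-planar conformers doubles the effective number
#' of samples without any new electronic-structure labels.
#'
#' @param conf a \code{conformer} with at least three non-collinear
#'   heavy atoms
#' @param tol matching tolerance used to derive the induced atom map
#'   (the map is \code{NULL} when the reflected copy is a genuinely
#'   new geometry)
#' @return a \code{symmetry_op}
#' @export
mirror_through_heavy_atom_plane <- function(conf, tol = 1e-3) {
  heavy <- which(conf$species != "H")
  if (length(heavy) < 3L) stop("need at least three heavy atoms")
  H <- conf$coords[heavy, , drop = FALSE]
  ctr <- colMeans(H)
  Hc <- sweep(H, 2L, ctr)
  sv <- svd(Hc)
  if (sv$d[2] < 1e-6) stop("heavy atoms are collinear: no unique plane")
  nrm <- sv$v[, 3]
  R <- diag(3) - 2 * tcrossprod(nrm)
  new <- sweep(sweep(conf$coords, 2L, ctr) %*% t(R), 2L, ctr, "+")
  perm <- .match_atoms(conf$coords, new, conf$species, tol)
  symmetry_operation(R, atom_map = perm, origin = ctr)
}

#' Augment a conformer set by its point-group orbit
#'
#' Replaces every conformer by its orbit under the group, copying
#' energy labels unchanged (energies are exact invariants; descriptor
#' fields and densities must be recomputed from the transformed
#' coordinates downstream).  Geometric duplicates -- species-matched
#' point sets coinciding within \code{dedup_tol} after centroid
#' removal -- are removed, which is what keeps, e.g., a set of planar
#' minima that map onto one another from being double counted.
#' Duplicate geometries whose energy labels disagree by more than
#' 1e-9 kcal/mol raise an error.
#'
#' @param conformers list of \code{conformer} objects, in the group's
#'   reference frame
#' @param group a \code{symmetry_group}
#' @param dedup_tol duplicate tolerance in Angstrom (default 1e-4)
#' @return list of unique augmented \code{conformer} objects
#' @export
augment_dataset <- function(conformers, group, dedup_tol = 1e-4) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  images <- vector("list", length(conformers) * group$order)
  k <- 0L
  for (conf in conformers) {
    for (op in group$operations) {
      k <- k + 1L
      images[[k]] <- apply_symmetry_operation(conf, op)
    }
  }
  keep <- .dedup_conformers(images, dedup_tol)
  images[keep]
}

# indices of unique geometries; first occurrence wins.  Candidates are
# prefiltered by per-species sorted-coordinate signatures (pointwise
# match implies sorted match), then confirmed by full atom matching.
.dedup_conformers <- function(images, tol) {
  n_img <- length(images)
  if (n_img == 0L) return(integer(0))
  sp <- images[[1]]$species
  sp_order <- order(sp)
  sig <- t(vapply(images, function(cf) {
    Xc <- sweep(cf$coords, 2L, colMeans(cf$coords))
    Xo <- Xc[sp_order, , drop = FALSE]
    unlist(lapply(split(seq_along(sp_order), sp[sp_order]),
                  function(ii) c(sort(Xo[ii, 1]), sort(Xo[ii, 2]),
                                 sort(Xo[ii, 3]))))
  }, numeric(3L * length(sp))))
  ord <- order(sig[, 1])
  keep <- logical(n_img)
  kept_idx <- integer(0)
  for (pos in seq_len(n_img)) {
    i <- ord[pos]
    dup_of <- NA_integer_
    # scan kept items backwards while the leading signature is close
    for (j in rev(kept_idx)) {
      if (sig[i, 1] - sig[j, 1] > 3 * tol) break
      if (max(abs(sig[i, ] - sig[j, ])) > 3 * tol) next
      Xi <- sweep(images[[i]]$coords, 2L, colMeans(images[[i]]$coords))
      Xj <- sweep(images[[j]]$coords, 2L, colMeans(images[[j]]$coords))
      if (!is.null(.match_atoms(Xj, Xi, sp, tol))) {
        dup_of <- j
        break
      }
    }
    if (is.na(dup_of)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    } else {
      .check_label_agreement(images[[i]], images[[dup_of]])
    }
  }
  sort(which(keep))
}

.check_label_agreement <- function(a, b) {
  for (key in c("E_low", "E_high")) {
    ea <- a$energy[[key]]; eb <- b$energy[[key]]
    if (!is.null(ea) && !is.null(eb) && abs(ea - eb) > 1e-9) {
      stop("duplicate geometries carry conflicting ", key,
           " labels (", ea, " vs ", eb, ")")
    }
  }
  invisible(TRUE)
}

#' Align conformers to a reference by subset RMSD
#'
#' Kabsch superposition: for each conformer the optimal rigid rotation
#' and translation minimizing the RMSD of the chosen atom subset
#' (typically the carbon skeleton) to the reference is computed on the
#' subset and applied to all atoms.
#'
#' @param conformers list of \code{conformer} objects
#' @param reference the reference \code{conformer}
#' @param atom_subset integer indices of the atoms to superpose (at
#'   least 3); defaults to all atoms
#' @return a list with \code{conformers} (aligned) and \code{rmsd}
#'   (per-conformer subset RMSD in Angstrom)
#' @export
align_to_reference <- function(conformers, reference,
                               atom_subset = seq_len(n_atoms(reference))) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (length(atom_subset) < 3L) stop("alignment subset needs >= 3 atoms")
  if (any(atom_subset < 1L) || any(atom_subset > n_atoms(reference))) {
    stop("atom_subset out of range")
  }
  Q <- reference$coords[atom_subset, , drop = FALSE]
  qc <- colMeans(Q)
  Qc <- sweep(Q, 2L, qc)
  rmsd <- numeric(length(conformers))
  out <- vector("list", length(conformers))
  for (i in seq_along(conformers)) {
    conf <- conformers[[i]]
    P <- conf$coords[atom_subset, , drop = FALSE]
    pc <- colMeans(P)
    R <- .kabsch_rotation(sweep(P, 2L, pc), Qc)
    newc <- sweep(sweep(conf$coords, 2L, pc) %*% t(R), 2L, qc, "+")
    out[[i]] <- set_coords(conf, newc)
    D <- out[[i]]$coords[atom_subset, , drop = FALSE] - Q
    rmsd[i] <- sqrt(mean(rowSums(D^2)))
  }
  list(conformers = out, rmsd = rmsd)
}

# optimal proper rotation R with Pc %*% t(R) ~ Qc (both pre-centered)
.kabsch_rotation <- function(Pc, Qc) {
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}
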