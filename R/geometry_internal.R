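# internal-coordinate geometry helpers: bond lengths, angles, dihedrals
# and Z-matrix (NeRF) construction of Cartesian coordinates

.bond_length <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

# angle i-j-k in radians (j is the vertex)
.bend_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang)))
}

# signed dihedral i-j-k-l in radians, IUPAC convention
.dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# place atom D given positions of ref1 (A, bonded), ref2 (B, angle) and
# ref3 (C, dihedral): r = |D-A|, theta = angle D-A-B, phi = dihedral
# D-A-B-C (NeRF construction)
.place_atom <- function(A, B, C, r, theta, phi) {
  bc <- A - B
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - C, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
         -r * sin(theta) * sin(phi))
  A + d[1] * bc + d[2] * m + d[3] * n
}

# build Cartesian coordinates from a Z-matrix.
# zmat: data.frame with integer columns ref1, ref2, ref3 (0 = absent);
# values: data.frame with columns bond (A), angle (deg), dihedral (deg)
.zmat_to_cartesian <- function(zmat, values) {
  n <- nrow(zmat)
  X <- matrix(0, n, 3L)
  if (n >= 2L) X[2, ] <- c(values$bond[2], 0, 0)
  if (n >= 3L) {
    # virtual reference below the ref2 atom fixes the initial plane
    C0 <- X[zmat$ref2[3], ] + c(0, 0, 1)
    X[3, ] <- .place_atom(X[zmat$ref1[3], ], X[zmat$ref2[3], ], C0,
                          values$bond[3], values$angle[3] * pi / 180, 0)
  }
  for (i in seq_len(n)[-(1:min(3L, n))]) {
    X[i, ] <- .place_atom(X[zmat$ref1[i], ], X[zmat$ref2[i], ],
                          X[zmat$ref3[i], ],
                          values$bond[i], values$angle[i] * pi / 180,
                          values$dihedral[i] * pi / 180)
  }
  X
}
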