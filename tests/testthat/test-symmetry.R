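test_that("symmetry operations validate orthogonality and apply correctly", {
  expect_error(symmetry_operation(matrix(1, 3, 3)), "orthogonal")
  op <- symmetry_operation(diag(c(-1, 1, 1)), origin = c(1, 0, 0))
  w <- water_xy()
  img <- apply_symmetry_operation(w, op)
  expect_equal(img$coords[, 1], 2 - w$coords[, 1])
  expect_equal(img$coords[, 2:3], w$coords[, 2:3])
})

test_that("hexagonal ring geometry has a point group of order 24", {
  g <- detect_point_group(benzene_conformer())
  expect_identical(g$order, 24L)
  expect_true(g$closure_verified)
  # 12 proper + 12 improper operations
  dets <- vapply(g$operations, function(o) det(o$matrix), numeric(1))
  expect_identical(sum(dets > 0), 12L)
  # every operation induces a species-preserving permutation
  for (op in g$operations) {
    expect_true(!is.null(op$atom_map))
    expect_identical(sort(op$atom_map), 1:12)
  }
})

test_that("asymmetric and mildly symmetric point sets are classified", {
  set.seed(3)
  asym <- conformer(c("C", "C", "O", "H"), matrix(rnorm(12), 4))
  expect_identical(detect_point_group(asym)$order, 1L)
  expect_identical(detect_point_group(water_xy())$order, 4L)  # C2v
})

test_that("planar molecules contain the molecular-plane reflection", {
  w <- water_xy()
  g <- detect_point_group(w)
  # brute-force oracle: reflections through centroid planes spanned by
  # atom-pair directions and their normals
  ctr <- colMeans(w$coords)
  X <- sweep(w$coords, 2, ctr)
  found <- list()
  dirs <- list()
  for (i in 1:2) for (j in (i + 1):3) {
    dirs <- c(dirs, list(X[i, ] - X[j, ], densfunc:::.cross3(X[i, ], X[j, ])))
  }
  for (d in dirs) {
    nd <- sqrt(sum(d^2))
    if (nd < 1e-8) next
    nrm <- d / nd
    R <- diag(3) - 2 * tcrossprod(nrm)
    if (!is.null(densfunc:::.match_atoms(X, X %*% t(R), w$species, 1e-3))) {
      found <- c(found, list(R))
    }
  }
  # every brute-force reflection must appear in the detected group
  mats <- lapply(g$operations, `[[`, "matrix")
  for (R in found) {
    expect_true(densfunc:::.known_matrix(R, mats, 1e-6))
  }
  # and the molecular plane (z = 0) reflection is among them
  expect_true(densfunc:::.known_matrix(diag(c(1, 1, -1)), mats, 1e-6))
})

test_that("group closure holds for detected groups", {
  g <- detect_point_group(benzene_conformer())
  mats <- lapply(g$operations, `[[`, "matrix")
  for (i in c(1, 5, 12)) {
    for (j in c(2, 8, 24)) {
      expect_true(densfunc:::.known_matrix(mats[[i]] %*% mats[[j]],
                                           mats, 1e-6))
    }
  }
})

test_that("heavy-atom-plane mirror is an involution that doubles datasets", {
  e <- ethanol_system()
  mir <- mirror_through_heavy_atom_plane(e$template)
  expect_equal(abs(det(mir$matrix)), 1, tolerance = 1e-10)
  twice <- apply_symmetry_operation(
    apply_symmetry_operation(e$template, mir), mir)
  expect_lt(max(abs(twice$coords - e$template$coords)), 1e-10)
  # energies are invariant under the mirror
  img <- apply_symmetry_operation(e$template, mir)
  expect_equal(low_level_energy(e, img), low_level_energy(e, e$template),
               tolerance = 1e-9)
  # a planar conformer maps onto itself
  w <- water_xy()
  mw <- mirror_through_heavy_atom_plane(
    conformer(c("C", "C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0),
                                      c(0.7, 1.2, 0))))
  expect_identical(mw$atom_map, 1:3)
  # n distinct non-planar conformers -> 2n samples
  confs <- sample_conformers(e, 10, seed = 5)
  grp <- structure(list(operations = list(
    symmetry_operation(diag(3), origin = mir$origin), mir),
    order = 2L, closure_verified = TRUE), class = "symmetry_group")
  expect_length(augment_dataset(confs, grp), 20L)
  # collinear heavy atoms have no unique plane
  lin <- conformer(c("C", "C", "C", "H"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)))
  expect_error(mirror_through_heavy_atom_plane(lin), "collinear")
})

test_that("augmentation bookkeeping handles orbits and duplicates", {
  rc <- toy_ring("c2v")
  g4 <- toy_ring_symmetry_group(rc)
  expect_identical(g4$order, 4L)
  mins <- toy_ring_minima(rc)
  # the four planar minima map onto one another: still 4 after augmenting
  expect_length(augment_dataset(mins, g4), 4L)
  # generic conformers have full orbits
  gen <- sample_conformers(rc, 25, seed = 2)
  expect_length(augment_dataset(gen, g4), 100L)
  # identity-only group leaves the dataset unchanged
  id_grp <- symmetry_group_from_matrices(list(diag(3)))
  expect_length(augment_dataset(gen, id_grp), 25L)
  # mixed set reproduces the generic*order + minima count
  expect_length(augment_dataset(c(gen, mins), g4), 104L)
  # orbit-size bound
  expect_lte(length(augment_dataset(c(gen, mins), g4)),
             4L * (length(gen) + length(mins)))
})

test_that("duplicate geometries with conflicting labels are rejected", {
  w1 <- water_xy(); w2 <- water_xy()
  w1$energy <- list(E_low = 1.0)
  w2$energy <- list(E_low = 1.5)
  id_grp <- symmetry_group_from_matrices(list(diag(3)))
  expect_error(augment_dataset(list(w1, w2), id_grp), "conflicting")
  w2$energy <- list(E_low = 1.0)
  expect_length(augment_dataset(list(w1, w2), id_grp), 1L)
})

test_that("a model trained on augmented data treats images identically", {
  sys <- water_system()
  n_grid <- 20
  gs <- grid_spec(10, n_grid,
                  origin = -c(1, 1, 1) * (10 / n_grid) * (n_grid - 1) / 2)
  b <- fourier_basis(5, 10, mode = "ball", origin = gs$origin)
  mirror <- symmetry_group_from_matrices(list(diag(c(-1, 1, 1))))
  set.seed(77)
  confs <- lapply(1:8, function(i) {
    th <- (104.52 + rnorm(1, 0, 8)) * pi / 180
    r1 <- 0.9572 + rnorm(1, 0, 0.1); r2 <- 0.9572 + rnorm(1, 0, 0.1)
    cf <- conformer(c("O", "H", "H"),
                    rbind(c(0, 0, 0),
                          c(r1 * sin(th / 2), r1 * cos(th / 2), 0),
                          c(-r2 * sin(th / 2), r2 * cos(th / 2), 0)))
    cf$energy <- list(E_low = low_level_energy(sys, cf),
                      E_high = high_level_energy(sys, cf))
    cf
  })
  aug <- augment_dataset(confs, mirror)
  U <- do.call(rbind, lapply(aug, function(cf) {
    project_density(bonded_density(sys, cf, gs), gs, b)$u
  }))
  y <- vapply(aug, function(cf) cf$energy$E_high, numeric(1))
  em <- fit_energy_map(U, y, "high", b, sigma = median_sigma(U))
  # an unseen conformer and its mirror image get equal predictions
  test_cf <- conformer(c("O", "H", "H"),
                       rbind(c(0, 0, 0), c(0.80, 0.49, 0),
                             c(-0.72, 0.55, 0)))
  test_img <- apply_symmetry_operation(test_cf, mirror$operations[[2]])
  u1 <- project_density(bonded_density(sys, test_cf, gs), gs, b)$u
  u2 <- project_density(bonded_density(sys, test_img, gs), gs, b)$u
  p1 <- predict_energy(em, matrix(u1, 1))
  p2 <- predict_energy(em, matrix(u2, 1))
  expect_lt(abs(p1 - p2) / max(abs(p1), 1e-8), 1e-6)
})

test_that("Kabsch alignment recovers rigid transforms", {
  e <- ethanol_system()
  ref <- e$template
  # rotated + translated copy aligns back exactly
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- set_coords(ref, sweep(ref$coords %*% t(R), 2, c(3, -1, 2), "+"))
  res <- align_to_reference(list(moved), ref)
  expect_lt(res$rmsd[1], 1e-8)
  expect_lt(max(abs(res$conformers[[1]]$coords - ref$coords)), 1e-7)
  # reference aligned to itself is untouched
  self <- align_to_reference(list(ref), ref)
  expect_lt(max(abs(self$conformers[[1]]$coords - ref$coords)), 1e-10)
  # carbon-subset alignment runs and reports subset RMSD
  confs <- sample_conformers(e, 3, seed = 8)
  sub <- which(ref$species != "H")
  res2 <- align_to_reference(confs, ref, atom_subset = sub)
  expect_length(res2$rmsd, 3L)
  expect_true(all(res2$rmsd > 0))
  expect_error(align_to_reference(confs, ref, atom_subset = 1:2), ">= 3")
})

test_that("Kabsch matches a brute-force Euler-angle grid search", {
  set.seed(12)
  P <- matrix(rnorm(15), 5, 3)
  th <- c(0.4, -0.7, 1.1)
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  Rtrue <- Rz(th[1]) %*% Ry(th[2]) %*% Rz(th[3])
  ref <- conformer(rep("C", 5), P %*% t(Rtrue))
  probe <- conformer(rep("C", 5), P + matrix(rnorm(15, 0, 0.02), 5, 3))
  res <- align_to_reference(list(probe), ref)
  # brute-force grid search over 30^3 Euler angles, then a second 30^3
  # pass refining around the coarse optimum
  Pc <- sweep(probe$coords, 2, colMeans(probe$coords))
  Qc <- sweep(ref$coords, 2, colMeans(ref$coords))
  scan <- function(as, bs, cs) {
    best <- Inf; arg <- c(0, 0, 0)
    for (a in as) {
      Rza <- Rz(a)
      for (bb in bs) {
        Rab <- Rza %*% Ry(bb)
        for (cc in cs) {
          v <- sqrt(mean(rowSums((Pc %*% t(Rab %*% Rz(cc)) - Qc)^2)))
          if (v < best) { best <- v; arg <- c(a, bb, cc) }
        }
      }
    }
    list(best = best, arg = arg)
  }
  coarse <- scan(seq(0, 2 * pi, length.out = 30),
                 seq(0, pi, length.out = 30),
                 seq(0, 2 * pi, length.out = 30))
  st <- c(2 * pi, pi, 2 * pi) / 29
  fine <- scan(seq(coarse$arg[1] - st[1], coarse$arg[1] + st[1],
                   length.out = 30),
               seq(coarse$arg[2] - st[2], coarse$arg[2] + st[2],
                   length.out = 30),
               seq(coarse$arg[3] - st[3], coarse$arg[3] + st[3],
                   length.out = 30))
  expect_lte(res$rmsd[1], fine$best + 1e-3)
  expect_lt(abs(res$rmsd[1] - fine$best), 1e-3)
})
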