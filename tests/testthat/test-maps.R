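test_that("single-output potential-to-density map reduces to fit_krr", {
  ds <- water_dataset()
  fields <- dataset_potentials(ds)[1:8]
  u1 <- ds$u[1:8, 1, drop = FALSE]
  b1 <- ds$basis; b1$L <- 1L
  b1$index <- b1$index[1, , drop = FALSE]; b1$freq <- b1$freq[1]
  hk <- fit_hk_map(fields, u1, b1, sigma = 500, lambda = 1e-8,
                   prior_mean_mode = "zero")
  V <- do.call(rbind, lapply(fields, `[[`, "values"))
  ref <- fit_krr(V, u1[, 1], sigma = 500, lambda = 1e-8,
                 prior_mean_mode = "zero")
  expect_equal(drop(hk$dual_coefficients), ref$dual_coefficients,
               tolerance = 1e-12)
})

test_that("shared factorization equals independent per-coefficient fits", {
  ds <- water_dataset()
  fields <- dataset_potentials(ds)[1:10]
  U <- ds$u[1:10, 1:10]
  b <- ds$basis; b$L <- 10L
  b$index <- b$index[1:10, ]; b$freq <- b$freq[1:10]
  hk <- fit_hk_map(fields, U, b, sigma = 400, lambda = 1e-6,
                   prior_mean_mode = "zero")
  V <- do.call(rbind, lapply(fields, `[[`, "values"))
  for (l in c(1, 5, 10)) {
    ref <- fit_krr(V, U[, l], sigma = 400, lambda = 1e-6,
                   prior_mean_mode = "zero")
    expect_lt(max(abs(hk$dual_coefficients[, l] - ref$dual_coefficients)),
              1e-10)
  }
  expect_error(fit_hk_map(fields, U[1:5, ], b, sigma = 400), "rows")
})

test_that("the density map interpolates its training conformers", {
  ds <- water_dataset()
  idx <- 1:12
  hk <- fit_hk_map(dataset_potentials(ds)[idx], ds$u[idx, ], ds$basis,
                   sigma = median_sigma(ds$potentials[idx, ]),
                   lambda = 0)
  co <- predict_density(hk, ds$conformers[[3]])
  expect_lt(max(abs(co$u - ds$u[3, ])), 1e-6)
  # the predicted density of a near-equilibrium conformer integrates to
  # the valence electron count of water
  sys <- water_system()
  near_eq <- sample_conformers(sys, 1, spread = 0.1, seed = 99)[[1]]
  co2 <- predict_density(hk, near_eq)
  expect_equal(integrate_density(co2), 8, tolerance = 0.1)
})

test_that("maps trained on mirror-symmetric data predict symmetric densities", {
  sys <- water_system()
  n_grid <- 24
  gs <- grid_spec(10, n_grid,
                  origin = -c(1, 1, 1) * (10 / n_grid) * (n_grid - 1) / 2)
  b <- fourier_basis(5, 10, mode = "ball", origin = gs$origin)
  # conformers symmetric-pair training set: x -> -x mirror images
  set.seed(31)
  confs <- list()
  for (i in 1:6) {
    th <- (104.52 + rnorm(1, 0, 8)) * pi / 180
    r1 <- 0.9572 + rnorm(1, 0, 0.1)
    r2 <- 0.9572 + rnorm(1, 0, 0.1)
    cf <- conformer(c("O", "H", "H"),
                    rbind(c(0, 0, 0),
                          c(r1 * sin(th / 2), r1 * cos(th / 2), 0),
                          c(-r2 * sin(th / 2), r2 * cos(th / 2), 0)))
    mir <- set_coords(cf, cf$coords %*% diag(c(-1, 1, 1)))
    confs <- c(confs, list(cf, mir))
  }
  fields <- lapply(confs, gaussian_potential, gs = gs, gamma = 0.6)
  U <- do.call(rbind, lapply(confs, function(cf) {
    project_density(sad_density(sys, cf, gs), gs, b)$u
  }))
  V <- do.call(rbind, lapply(fields, `[[`, "values"))
  hk <- fit_hk_map(fields, U, b, sigma = median_sigma(V), lambda = 1e-8)
  co <- predict_density(hk, water_xy())  # symmetric query
  pts <- cbind(runif(20, 0.2, 2), runif(20, -2, 2), runif(20, -1, 1))
  mirrored <- pts %*% diag(c(-1, 1, 1))
  expect_lt(max(abs(reconstruct_density(co, pts) -
                    reconstruct_density(co, mirrored))), 1e-8)
})

test_that("energy maps interpolate, delegate and respect priors", {
  ds <- water_dataset()
  idx <- 1:20
  em <- fit_energy_map(ds$u[idx, ], ds$E_high[idx], "high", ds$basis,
                       sigma = median_sigma(ds$u[idx, ]), lambda = 0)
  expect_lt(max(abs(predict_energy(em, ds$u[idx, ]) - ds$E_high[idx])),
            1e-6 * max(ds$E_high[idx]))
  # delegation: identical to predict_krr on the embedded model
  expect_identical(predict_energy(em, ds$u[idx, ]),
                   predict_krr(em$model, ds$u[idx, ]))
  # constant labels with a train-mean prior predict the constant
  emc <- fit_energy_map(ds$u[idx, ], rep(7.5, 20), "low", ds$basis,
                        sigma = 1, lambda = 1e-8)
  expect_equal(predict_energy(emc, ds$u[40, , drop = FALSE]), 7.5,
               tolerance = 1e-6)
  # delta maps are forced to a zero prior
  dm <- fit_energy_map(ds$u[idx, ], ds$delta[idx], "delta", ds$basis,
                       sigma = median_sigma(ds$u[idx, ]))
  expect_identical(dm$model$prior_mean, 0)
})

test_that("delta-corrected totals reduce to their limits", {
  ds <- water_dataset()
  idx <- 1:15
  sig <- median_sigma(ds$u[idx, ])
  mk_co <- function(i) structure(list(u = ds$u[i, ], basis = ds$basis),
                                 class = "density_coeffs")
  # zero-difference training: total is exactly E_low
  dm0 <- fit_energy_map(ds$u[idx, ], rep(0, 15), "delta", ds$basis,
                        sigma = sig, lambda = 0)
  expect_identical(delta_dft_total_energy(3.21, dm0, mk_co(40)), 3.21)
  # interpolation through the corrected total: training conformer
  # recovers its high-level label
  dm <- fit_energy_map(ds$u[idx, ], ds$delta[idx], "delta", ds$basis,
                       sigma = sig, lambda = 0)
  i <- idx[4]
  expect_equal(delta_dft_total_energy(ds$E_low[i], dm, mk_co(i)),
               ds$E_high[i], tolerance = 1e-6)
  # far from the training manifold the correction vanishes
  far <- structure(list(u = ds$u[1, ] + 1e3, basis = ds$basis),
                   class = "density_coeffs")
  expect_equal(delta_dft_total_energy(5, dm, far), 5, tolerance = 1e-9)
  em <- fit_energy_map(ds$u[idx, ], ds$E_high[idx], "high", ds$basis,
                       sigma = sig)
  expect_error(delta_dft_total_energy(5, em, mk_co(1)), "delta")
})

test_that("composed potential->density->energy pipeline reproduces labels", {
  ds <- water_dataset()
  idx <- 1:15
  hk <- fit_hk_map(dataset_potentials(ds)[idx], ds$u[idx, ], ds$basis,
                   sigma = median_sigma(ds$potentials[idx, ]),
                   lambda = 0)
  # energy map trained on the map's own predicted densities
  U_pred <- do.call(rbind, lapply(idx, function(i) {
    predict_density(hk, ds$conformers[[i]])$u
  }))
  em <- fit_energy_map(U_pred, ds$E_high[idx], "high", ds$basis,
                       sigma = median_sigma(U_pred), lambda = 0)
  for (i in c(2, 9)) {
    pred <- predict_energy(em, predict_density(hk, ds$conformers[[i]]))
    expect_equal(pred, ds$E_high[i],
                 tolerance = 1e-6 * max(abs(ds$E_high[idx])))
  }
})

test_that("energy-map learning curve improves over the protocol sizes", {
  ds <- water_dataset()
  res <- shuffle_evaluate(ds$u, ds$E_high,
                          subset_sizes = c(10, 15, 20, 30, 40, 50),
                          n_shuffles = 20, train_size = 50, seed = 5,
                          prior_mean_mode = "train_mean")
  expect_true(all(diff(res$mae) <= 1e-8))
  expect_lt(res$mae["50"], res$mae["10"] / 2)
})

test_that("SAD-projected inputs learn no better than bond-aware inputs", {
  sys <- water_system()
  dsb <- memo("water_b", make_dataset(sys, 102, seed = 11,
                                      density_mode = "bonded",
                                      store_potentials = FALSE))
  dss <- memo("water_s", make_dataset(sys, 102, seed = 11,
                                      density_mode = "sad",
                                      store_potentials = FALSE))
  maes <- sapply(1:3, function(s) {
    perm <- densfunc:::.with_seed(200 + s, sample.int(102))
    tr <- perm[1:50]; te <- perm[-(1:50)]
    db <- cv_fit(dsb$u[tr, ], dsb$delta[tr], "delta", dsb$basis, s)
    ss <- cv_fit(dss$u[tr, ], dss$delta[tr], "delta", dss$basis, s)
    c(bonded = test_mae(db, dsb$u[te, ], dsb$delta[te]),
      sad = test_mae(ss, dss$u[te, ], dss$delta[te]))
  })
  expect_gte(mean(maes["sad", ]), mean(maes["bonded", ]))
})

test_that("combining datasets concatenates records with provenance", {
  ds <- water_dataset()
  expect_identical(combine_datasets(ds)$u, ds$u)  # combine(A) = A
  half1 <- ds; half2 <- ds
  for (f in c("u", "E_low", "E_high", "delta", "molecule", "potentials")) {
    half1[[f]] <- if (is.matrix(ds[[f]])) ds[[f]][1:50, ] else ds[[f]][1:50]
    half2[[f]] <- if (is.matrix(ds[[f]])) ds[[f]][51:102, ] else ds[[f]][51:102]
  }
  half1$conformers <- ds$conformers[1:50]
  half2$conformers <- ds$conformers[51:102]
  both <- combine_datasets(half1, half2)
  expect_identical(nrow(both$u), 102L)
  expect_length(both$molecule, 102L)
  other <- ds
  other$basis <- fourier_basis(5, ds$basis$box_length,
                               origin = ds$basis$origin)
  expect_error(combine_datasets(ds, other), "bases")
})

test_that("fragment data improves the large-molecule energy map", {
  rc <- toy_ring("c2v"); cs <- toy_ring("cs")
  gs <- default_grid(rc)
  b <- fourier_basis(7, gs$box_length, mode = "ball", origin = gs$origin)
  ds_rc <- memo("ring_ds", make_dataset(rc, 70, gs = gs, basis = b,
                                        seed = 3,
                                        store_potentials = FALSE))
  ds_cs <- memo("frag_ds", make_dataset(cs, 60, gs = gs, basis = b,
                                        seed = 4,
                                        store_potentials = FALSE))
  comb <- combine_datasets(ds_rc, ds_cs)
  expect_identical(nrow(comb$u), 130L)
  expect_setequal(unique(comb$molecule), c("toy-ring-c2v", "toy-ring-cs"))
  maes <- sapply(1:4, function(s) {
    perm <- densfunc:::.with_seed(50 + s, sample.int(70))
    tr <- perm[1:30]; te <- perm[-(1:30)]
    keep <- comb$molecule == "toy-ring-cs"
    m_only <- cv_fit(ds_rc$u[tr, ], ds_rc$E_high[tr], "high", b, s)
    m_comb <- cv_fit(rbind(ds_rc$u[tr, ], comb$u[keep, ]),
                     c(ds_rc$E_high[tr], comb$E_high[keep]), "high", b, s)
    c(only = test_mae(m_only, ds_rc$u[te, ], ds_rc$E_high[te]),
      comb = test_mae(m_comb, ds_rc$u[te, ], ds_rc$E_high[te]))
  })
  # evaluated on the large molecule only, at equal large-molecule budget
  expect_lt(mean(maes["comb", ]), mean(maes["only", ]))
})
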