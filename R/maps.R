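#' Fit the learned potential-to-density (Hohenberg-Kohn) map
#'
#' One kernel ridge regression per density-basis coefficient, all
#' sharing a single Gram matrix over the Gaussian-potential
#' descriptors: the regularized kernel system is factorized once and
#' solved against all L coefficient columns, which is exactly
#' equivalent to L independent fits and preserves the per-coefficient
#' independence granted by basis orthonormality.
#'
#' @param potential_fields list of \code{potential_field} objects (one
#'   per training conformer, shared grid and gamma)
#' @param coefficient_matrix numeric matrix, one row of density
#'   coefficients per field
#' @param basis the \code{fourier_basis} the coefficients live in
#' @param sigma Gaussian kernel width over descriptor distance
#' @param lambda ridge regularization (default scale-free jitter as in
#'   \code{\link{fit_krr}})
#' @param prior_mean_mode \code{"train_mean"} (default: far from the
#'   training set the predicted density reverts to the mean training
#'   density) or \code{"zero"}
#' @return an object of class \code{hk_map}
#' @export
fit_hk_map <- function(potential_fields, coefficient_matrix, basis,
                       sigma, lambda = NULL,
                       prior_mean_mode = c("train_mean", "zero")) {
  prior_mean_mode <- match.arg(prior_mean_mode)
  coefficient_matrix <- as.matrix(coefficient_matrix)
  M <- length(potential_fields)
  if (M < 1L) stop("no training potentials")
  if (nrow(coefficient_matrix) != M) {
    stop("coefficient rows (", nrow(coefficient_matrix),
         ") do not match the number of potentials (", M, ")")
  }
  if (ncol(coefficient_matrix) != basis$L) {
    stop("coefficient columns do not match the basis size")
  }
  for (f in potential_fields[-1]) {
    .check_same_descriptor_config(potential_fields[[1]], f)
  }
  V <- do.call(rbind, lapply(potential_fields, `[[`, "values"))
  if (is.null(lambda)) lambda <- 1e-10
  K <- .kernel_matrix(V, V, sigma)
  prior <- if (prior_mean_mode == "train_mean") {
    colMeans(coefficient_matrix)
  } else rep(0, basis$L)
  R <- chol(K + diag(lambda, M))
  rhs <- sweep(coefficient_matrix, 2L, prior)
  dual <- backsolve(R, forwardsolve(t(R), rhs))  # M x L
  structure(list(sigma = sigma, lambda = lambda,
                 train_inputs = V, dual_coefficients = dual,
                 prior_mean = prior, prior_mean_mode = prior_mean_mode,
                 basis = basis,
                 gamma = potential_fields[[1]]$gamma,
                 grid = potential_fields[[1]]$grid),
            class = "hk_map")
}

#' @export
print.hk_map <- function(x, ...) {
  cat("hk_map:", nrow(x$train_inputs), "training potentials ->",
      x$basis$L, "density coefficients; sigma =", signif(x$sigma, 5),
      ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Predict the density coefficients of a conformer
#'
#' Builds the Gaussian-potential descriptor of \code{conf} on the
#' map's training grid and evaluates all per-coefficient models.
#'
#' @param hkmap an \code{hk_map}
#' @param conf a \code{conformer}
#' @return a \code{density_coeffs} usable by \code{reconstruct_density}
#'   and by any energy map sharing the basis
#' @export
predict_density <- function(hkmap, conf) {
  v <- gaussian_potential(conf, hkmap$grid, hkmap$gamma)
  Kq <- .kernel_matrix(matrix(v$values, 1L), hkmap$train_inputs,
                       hkmap$sigma)
  u <- drop(Kq %*% hkmap$dual_coefficients) + hkmap$prior_mean
  structure(list(u = u, basis = hkmap$basis), class = "density_coeffs")
}

#' Fit an energy map over density coefficients
#'
#' Kernel ridge regression from density-coefficient vectors to an
#' energy label: the low-level energy, the high-level energy, or their
#' difference (\code{"delta"}).  Delta maps always use a zero prior
#' mean, so the learned correction vanishes far from the training
#' manifold and the corrected total falls back on the uncorrected
#' low-level energy.  Direct maps default to a train-mean prior.
#'
#' @param coefficient_matrix numeric matrix, one coefficient vector
#'   per training conformer
#' @param energies numeric vector of labels (kcal/mol); for
#'   \code{"delta"} these are \code{E_high - E_low} per conformer
#' @param label_kind \code{"low"}, \code{"high"} or \code{"delta"}
#' @param basis the \code{fourier_basis} of the coefficients
#' @param sigma Gaussian kernel width over coefficient distance
#' @param lambda ridge regularization
#' @param training_reference the reference shift (kcal/mol) the labels
#'   are relative to; stored for provenance
#' @return an object of class \code{energy_map}
#' @export
fit_energy_map <- function(coefficient_matrix, energies,
                           label_kind = c("low", "high", "delta"),
                           basis, sigma, lambda = NULL,
                           training_reference = 0) {
  label_kind <- match.arg(label_kind)
  prior <- if (label_kind == "delta") "zero" else "train_mean"
  model <- fit_krr(coefficient_matrix, energies, sigma = sigma,
                   lambda = lambda, prior_mean_mode = prior)
  structure(list(model = model, label_kind = label_kind, basis = basis,
                 training_reference = training_reference),
            class = "energy_map")
}

#' @export
print.energy_map <- function(x, ...) {
  cat("energy_map [", x$label_kind, "]: ", sep = "")
  print(x$model)
  invisible(x)
}

#' Predict an energy from density coefficients
#'
#' @param energy_map an \code{energy_map}
#' @param coeffs a \code{density_coeffs} (basis must match training),
#'   or a matrix of coefficient rows
#' @return predicted energy (kcal/mol), one value per coefficient row
#' @export
predict_energy <- function(energy_map, coeffs) {
  if (inherits(coeffs, "density_coeffs")) {
    .check_same_basis(coeffs$basis, energy_map$basis)
    coeffs <- matrix(coeffs$u, nrow = 1L)
  }
  predict_krr(energy_map$model, coeffs)
}

#' Delta-corrected total energy
#'
#' The working equation of density-based delta learning: the total
#' energy is the externally computed low-level energy plus the learned
#' correction evaluated on the (learned) density,
#' \eqn{E = E_{low} + \Delta E_{ML}[n]}.  When the correction model
#' was trained on identically zero differences the total reduces to
#' \code{E_low} exactly; far from the training set the zero-prior
#' correction decays and the total falls back on \code{E_low}.
#'
#' @param E_low low-level energy of the conformer (kcal/mol)
#' @param delta_map an \code{energy_map} with \code{label_kind
#'   = "delta"}
#' @param coeffs \code{density_coeffs} of the conformer
#' @return corrected total energy (kcal/mol)
#' @export
delta_dft_total_energy <- function(E_low, delta_map, coeffs) {
  if (delta_map$label_kind != "delta") {
    stop("delta_map must have label_kind = 'delta'")
  }
  E_low + predict_energy(delta_map, coeffs)
}

#' Combine datasets of different molecules
#'
#' Concatenates the coefficient/energy records of several datasets
#' sharing one basis and one descriptor configuration, so a single
#' density-to-energy map can be trained on the union.  Atom counts may
#' differ; the density representation has fixed length regardless.
#' Per-record molecule provenance is retained, so test error can still
#' be computed per molecule after combination.
#'
#' @param ... \code{density_dataset} objects (see
#'   \code{\link{make_dataset}})
#' @return a combined \code{density_dataset}
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1]], "density_dataset")) {
    ds <- ds[[1]]
  }
  if (length(ds) == 0L) stop("no datasets to combine")
  for (d in ds) {
    if (!inherits(d, "density_dataset")) stop("not a density_dataset")
  }
  ref <- ds[[1]]
  for (d in ds[-1]) {
    .check_same_basis(ref$basis, d$basis)
    if (ref$grid$points_per_dim != d$grid$points_per_dim ||
        abs(ref$grid$box_length - d$grid$box_length) > 1e-9 ||
        max(abs(ref$grid$origin - d$grid$origin)) > 1e-9 ||
        abs(ref$gamma - d$gamma) > 1e-12) {
      stop("datasets use different descriptor configurations")
    }
  }
  out <- ref
  out$u <- do.call(rbind, lapply(ds, `[[`, "u"))
  out$E_low <- unlist(lapply(ds, `[[`, "E_low"))
  out$E_high <- unlist(lapply(ds, `[[`, "E_high"))
  out$delta <- unlist(lapply(ds, `[[`, "delta"))
  out$molecule <- unlist(lapply(ds, `[[`, "molecule"))
  out$conformers <- do.call(c, lapply(ds, `[[`, "conformers"))
  pots <- lapply(ds, `[[`, "potentials")
  out$potentials <- if (any(vapply(pots, is.null, logical(1)))) NULL
                    else do.call(rbind, pots)
  out$reference_shift <- ref$reference_shift
  out
}

#' Fit an energy map with cross-validated hyperparameters
#'
#' The standard fitting protocol: the kernel width is tuned by
#' fivefold cross-validation over a geometric grid centered on the
#' median-distance heuristic (factors 1/8 to 8), jointly with the
#' ridge parameter over \{1e-10, 1e-7, 1e-4\}.
#'
#' @inheritParams fit_energy_map
#' @param seed seed for the CV fold shuffle
#' @param folds number of CV folds
#' @return an \code{energy_map}; the chosen hyperparameters are in
#'   \code{$model$sigma} and \code{$model$lambda}
#' @export
fit_energy_map_cv <- function(coefficient_matrix, energies,
                              label_kind = c("low", "high", "delta"),
                              basis, seed = 1, folds = 5,
                              training_reference = 0) {
  label_kind <- match.arg(label_kind)
  prior <- if (label_kind == "delta") "zero" else "train_mean"
  s0 <- median_sigma(coefficient_matrix)
  cv <- kfold_cv_score(coefficient_matrix, energies,
                       sigma_grid = s0 * 2^seq(-3, 3),
                       lambda_grid = c(1e-10, 1e-7, 1e-4),
                       folds = folds, seed = seed,
                       prior_mean_mode = prior)
  fit_energy_map(coefficient_matrix, energies, label_kind, basis,
                 sigma = cv$best_sigma, lambda = cv$best_lambda,
                 training_reference = training_reference)
}
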