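#' Gaussian kernel between two descriptor vectors
#'
#' \deqn{k(x, y) = \exp(-\|x - y\|^2 / (2\sigma^2))}
#'
#' @param x,y numeric vectors of equal length
#' @param sigma kernel width (> 0), in the units of the input-space
#'   Euclidean distance
#' @return scalar in (0, 1]
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("kernel inputs differ in length")
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# full Gaussian kernel matrix between rows of A and rows of B
.kernel_matrix <- function(A, B, sigma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fit a kernel ridge regression model
#'
#' Solves \eqn{(K + \lambda I) c = y - \mu} for the dual coefficients
#' via a Cholesky factorization of the (symmetric positive definite)
#' regularized kernel matrix, where \eqn{\mu} is an additive prior mean.
#' With \code{prior_mean_mode = "zero"} predictions decay to zero far
#' from all training points -- the behaviour that lets a delta-learning
#' correction fall back on the uncorrected energy outside the training
#' manifold.  With \code{"train_mean"} they revert to the training-label
#' mean instead, which suits direct energy models.
#'
#' @param inputs numeric matrix, one training descriptor per row
#' @param labels numeric vector of training targets
#' @param sigma Gaussian kernel width
#' @param lambda ridge regularization (>= 0).  The default
#'   \code{NULL} uses the scale-free jitter
#'   \code{1e-10 * mean(diag(K))}, which preserves near-interpolation
#'   while keeping the factorization stable.
#' @param prior_mean_mode \code{"zero"} or \code{"train_mean"}
#' @return an object of class \code{krr_model}
#' @export
fit_krr <- function(inputs, labels, sigma, lambda = NULL,
                    prior_mean_mode = c("zero", "train_mean")) {
  prior_mean_mode <- match.arg(prior_mean_mode)
  inputs <- as.matrix(inputs)
  M <- nrow(inputs)
  if (M < 1L) stop("at least one training point is required")
  if (length(labels) != M) stop("labels length does not match inputs")
  if (!all(is.finite(labels))) stop("labels must be finite")
  if (is.null(lambda)) lambda <- 1e-10
  if (lambda < 0) stop("lambda must be non-negative")
  K <- .kernel_matrix(inputs, inputs, sigma)
  prior <- if (prior_mean_mode == "train_mean") mean(labels) else 0
  R <- tryCatch(chol(K + diag(lambda, M)),
                error = function(e) {
                  stop("kernel system is singular (duplicate inputs with ",
                       "lambda = 0?); use lambda > 0", call. = FALSE)
                })
  coef <- backsolve(R, forwardsolve(t(R), labels - prior))
  structure(list(sigma = sigma, train_inputs = inputs,
                 dual_coefficients = as.numeric(coef),
                 lambda = lambda, prior_mean = prior,
                 prior_mean_mode = prior_mean_mode),
            class = "krr_model")
}

#' @export
print.krr_model <- function(x, ...) {
  cat("krr_model: M =", nrow(x$train_inputs), "training points, sigma =",
      signif(x$sigma, 5), ", lambda =", signif(x$lambda, 3),
      ", prior =", signif(x$prior_mean, 5), "\n")
  invisible(x)
}

#' Predict with a KRR model
#'
#' \eqn{\hat y(x) = \sum_i c_i k(x, x_i) + \mu}.  Far from all training
#' inputs the kernel sums underflow and the prediction tends to the
#' prior mean.
#'
#' @param model a \code{krr_model}
#' @param x a query vector, or a matrix of query rows
#' @return numeric vector of predictions
#' @export
predict_krr <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$train_inputs)) {
    stop("query dimensionality (", ncol(x), ") does not match training (",
         ncol(model$train_inputs), ")")
  }
  Kq <- .kernel_matrix(x, model$train_inputs, model$sigma)
  drop(Kq %*% model$dual_coefficients) + model$prior_mean
}

#' Grid search with k-fold cross-validation
#'
#' Exhaustive search over a (sigma, lambda) grid scored by
#' cross-validated mean absolute error.  Folds are formed by a seeded
#' shuffle followed by contiguous blocks whose sizes differ by at most
#' one, so results are reproducible bit for bit.
#'
#' @param inputs training descriptor matrix
#' @param labels training targets
#' @param sigma_grid candidate kernel widths
#' @param lambda_grid candidate regularizations
#' @param folds number of folds (default 5)
#' @param seed integer seed for the fold shuffle
#' @param prior_mean_mode passed to \code{\link{fit_krr}}
#' @return a list with \code{best_sigma}, \code{best_lambda}, and
#'   \code{table} (a data frame of sigma, lambda, cv_mae)
#' @export
kfold_cv_score <- function(inputs, labels, sigma_grid, lambda_grid = 1e-10,
                           folds = 5, seed = 1,
                           prior_mean_mode = c("zero", "train_mean")) {
  prior_mean_mode <- match.arg(prior_mean_mode)
  inputs <- as.matrix(inputs)
  M <- nrow(inputs)
  if (M < folds) stop("need at least as many samples as folds")
  if (length(sigma_grid) == 0L || length(lambda_grid) == 0L) {
    stop("hyperparameter grid is empty")
  }
  perm <- .with_seed(seed, sample.int(M))
  sizes <- rep(M %/% folds, folds) + c(rep(1L, M %% folds),
                                       rep(0L, folds - M %% folds))
  fold_id <- rep(seq_len(folds), times = sizes)
  tab <- expand.grid(sigma = sigma_grid, lambda = lambda_grid,
                     KEEP.OUT.ATTRS = FALSE)
  tab$cv_mae <- NA_real_
  for (g in seq_len(nrow(tab))) {
    errs <- numeric(0)
    for (f in seq_len(folds)) {
      hold <- perm[fold_id == f]
      keep <- setdiff(perm, hold)
      m <- fit_krr(inputs[keep, , drop = FALSE], labels[keep],
                   sigma = tab$sigma[g], lambda = tab$lambda[g],
                   prior_mean_mode = prior_mean_mode)
      pred <- predict_krr(m, inputs[hold, , drop = FALSE])
      errs <- c(errs, abs(pred - labels[hold]))
    }
    tab$cv_mae[g] <- mean(errs)
  }
  best <- which.min(tab$cv_mae)
  list(best_sigma = tab$sigma[best], best_lambda = tab$lambda[best],
       table = tab)
}

#' Median-distance heuristic for the kernel width
#'
#' The median pairwise Euclidean distance between input rows: a
#' standard deterministic starting point (and grid center) for the
#' cross-validated kernel width.
#'
#' @param inputs descriptor matrix
#' @return scalar width
#' @export
median_sigma <- function(inputs) {
  inputs <- as.matrix(inputs)
  d <- stats::dist(inputs)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Select k representative dataset members via k-means
#'
#' Runs seeded k-means++ initialization followed by Lloyd iterations
#' (capped at 300) on the feature rows, then returns, for each final
#' center, the index of the nearest dataset member.  Duplicate picks
#' are resolved by moving to the next-nearest unused member; distance
#' ties break toward the lowest index.
#'
#' @param features numeric matrix, one feature vector per row
#' @param k number of members to select (1..nrow)
#' @param seed integer seed
#' @return integer vector of k unique row indices
#' @export
kmeans_select <- function(features, k, seed = 1) {
  features <- as.matrix(features)
  M <- nrow(features)
  if (k <= 0) stop("k must be positive")
  if (k > M) stop("k exceeds the number of dataset members")
  if (k == M) return(seq_len(M))
  centers <- .with_seed(seed, {
    init <- .kmeanspp_init(features, k)
    if (k == 1L) {
      matrix(colMeans(features), 1L)
    } else {
      km <- stats::kmeans(features, centers = features[init, , drop = FALSE],
                          iter.max = 300L, algorithm = "Lloyd")
      km$centers
    }
  })
  chosen <- integer(0)
  for (c_i in seq_len(nrow(centers))) {
    d2 <- colSums((t(features) - centers[c_i, ])^2)
    ord <- order(d2, seq_len(M))  # ties -> lowest index
    pick <- ord[!(ord %in% chosen)][1]
    chosen <- c(chosen, pick)
  }
  chosen
}

.kmeanspp_init <- function(features, k) {
  M <- nrow(features)
  idx <- integer(k)
  idx[1] <- sample.int(M, 1L)
  if (k == 1L) return(idx)
  d2 <- colSums((t(features) - features[idx[1], ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / M, M)
    idx[j] <- sample.int(M, 1L, prob = p)
    d2 <- pmin(d2, colSums((t(features) - features[idx[j], ])^2))
  }
  idx
}

#' Repeated-shuffle learning-curve evaluation
#'
#' The small-dataset protocol for stable accuracy estimates: the data
#' are shuffled \code{n_shuffles} times; each shuffle takes
#' \code{train_size} samples as the training pool and the remainder as
#' the out-of-sample test set.  For subset sizes below
#' \code{train_size} the training subset is chosen from the pool by
#' k-means selection on the input features.  Mean absolute test error
#' is reported per subset size, averaged over shuffles.
#'
#' @param inputs descriptor matrix (one row per sample)
#' @param labels numeric targets
#' @param subset_sizes training-set sizes to evaluate (each <=
#'   \code{train_size})
#' @param n_shuffles number of shuffles (default 40)
#' @param train_size size of the training pool (default 50)
#' @param seed integer seed; shuffle s uses \code{seed + s}
#' @param sigma kernel width; \code{NULL} for the median heuristic on
#'   each training subset
#' @param lambda ridge parameter passed to \code{\link{fit_krr}}
#' @param prior_mean_mode passed to \code{\link{fit_krr}}
#' @return a list with \code{mae} (named mean MAE per subset size),
#'   \code{sd} (dispersion across shuffles), and \code{per_shuffle}
#'   (matrix n_shuffles x sizes)
#' @export
shuffle_evaluate <- function(inputs, labels, subset_sizes,
                             n_shuffles = 40, train_size = 50, seed = 1,
                             sigma = NULL, lambda = NULL,
                             prior_mean_mode = c("zero", "train_mean")) {
  prior_mean_mode <- match.arg(prior_mean_mode)
  inputs <- as.matrix(inputs)
  M <- nrow(inputs)
  if (train_size >= M) stop("train_size must be below the dataset size")
  if (any(subset_sizes > train_size)) {
    stop("subset sizes cannot exceed train_size")
  }
  res <- matrix(NA_real_, n_shuffles, length(subset_sizes),
                dimnames = list(NULL, as.character(subset_sizes)))
  for (s in seq_len(n_shuffles)) {
    perm <- .with_seed(seed + s, sample.int(M))
    pool <- perm[seq_len(train_size)]
    test <- perm[-seq_len(train_size)]
    for (j in seq_along(subset_sizes)) {
      sz <- subset_sizes[j]
      tr <- if (sz < train_size) {
        pool[kmeans_select(inputs[pool, , drop = FALSE], sz,
                           seed = seed + s)]
      } else pool
      sg <- if (is.null(sigma)) median_sigma(inputs[tr, , drop = FALSE])
            else sigma
      m <- fit_krr(inputs[tr, , drop = FALSE], labels[tr], sigma = sg,
                   lambda = lambda, prior_mean_mode = prior_mean_mode)
      pred <- predict_krr(m, inputs[test, , drop = FALSE])
      res[s, j] <- mean(abs(pred - labels[test]))
    }
  }
  list(mae = colMeans(res), sd = apply(res, 2L, stats::sd),
       per_shuffle = res, train_size = as.integer(train_size),
       test_size = as.integer(M - train_size))
}

# evaluate expr under a local RNG state seeded with seed, restoring the
# caller's state afterwards: no randomized operation touches global RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
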