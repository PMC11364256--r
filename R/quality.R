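# View-quality regression: an L1-penalised linear model from
# time-averaged penultimate embeddings to normalised quality scores in
# [0, 1]. The solver is cyclic coordinate descent on the objective
#
#   Loss(w, b) = 1/(2N) * sum_k (w . l_k + b - y_k)^2 + alpha * ||w||_1
#
# with the intercept unpenalised, features used unstandardised, and the
# penalty weight alpha selected by seeded k-fold cross-validation.


# Centred Gram reformulation: with column-centred X and centred y the
# unpenalised intercept separates out (b = mean(y) - w . colmeans(X))
# and a coordinate update costs O(D) instead of O(N).
lasso_gram <- function(X, y) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  list(G = crossprod(Xc) / nrow(X),
       q = as.numeric(crossprod(Xc, y - ym)) / nrow(X),
       xm = xm, ym = ym)
}

# Cyclic coordinate descent with warm starts down a decreasing alpha
# path and active-set iteration; converges when the largest coefficient
# update falls below tol. The sweeps are compiled (lasso_path_cpp).
lasso_path <- function(X, y, alphas, w = NULL, tol = 1e-8,
                       max_iter = 100000L) {
  gr <- lasso_gram(X, y)
  if (is.null(w)) w <- numeric(ncol(X))
  fit <- lasso_path_cpp(gr$G, gr$q, alphas, w, tol, as.integer(max_iter))
  b <- gr$ym - as.numeric(crossprod(fit$W, gr$xm))
  list(W = fit$W, b = b, iterations = fit$iterations)
}

# Single-alpha convenience used by the unit checks.
lasso_cd <- function(X, y, alpha, w = NULL, b = NULL, tol = 1e-10,
                     max_iter = 100000L) {
  fit <- lasso_path(X, y, alpha, w = w, tol = tol, max_iter = max_iter)
  list(w = as.numeric(fit$W[, 1]), b = fit$b[1],
       iterations = fit$iterations[1])
}

lasso_objective <- function(X, y, w, b, alpha) {
  res <- as.vector(X %*% w) + b - y
  sum(res^2) / (2 * nrow(X)) + alpha * sum(abs(w))
}

# Smallest alpha that zeroes every coefficient (at w = 0, b = mean(y)),
# from which the default grid descends four decades. Computed through
# the same centred Gram arithmetic as the solver so that the boundary
# alpha really yields the all-zero solution bitwise.
lasso_alpha_max <- function(X, y) {
  max(abs(lasso_gram(X, y)$q))
}

#' Fit the quality-regression Lasso with cross-validated penalty
#'
#' Minimises the mean-squared-error plus L1-penalty objective for every
#' alpha on the grid, selects the alpha with the smallest mean
#' out-of-fold squared error under a seeded k-fold partition, and refits
#' on all data at the selected alpha. Features enter unstandardised
#' (optionally standardised behind a flag); the intercept is
#' unpenalised.
#'
#' @param features `N x D` matrix of time-averaged embeddings from a
#'   frozen classifier.
#' @param labels Length-`N` quality labels in `[0, 1]`.
#' @param folds Number of cross-validation folds (default 5).
#' @param alpha_grid Optional decreasing vector of penalty weights; by
#'   default 50 log-spaced values from the data-derived `alpha_max`
#'   (the smallest penalty zeroing all weights) down four decades.
#' @param seed Integer seed for the fold partition.
#' @param standardize Standardise the feature columns before fitting
#'   (coefficients are mapped back to the original scale). Off by
#'   default, matching the objective exactly as written.
#' @param tol Coordinate-descent convergence tolerance.
#' @return An object of class `quality_model`: list with `w`, `b`,
#'   `alpha`, `nonzero_count`, `cv` (per-alpha mean out-of-fold MSE),
#'   `folds`, `seed`, `alpha_grid`.
#' @export
fit_quality_lasso <- function(features, labels, folds = 5L,
                              alpha_grid = NULL, seed = 1L,
                              standardize = FALSE, tol = 1e-8) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  N <- nrow(X)
  if (length(y) != N) stop("features and labels disagree in length")
  if (any(y < 0 | y > 1)) stop("labels must lie in [0, 1]")
  if (folds < 2) stop("folds must be >= 2")
  if (N < folds) stop("need at least as many samples as folds")
  ctr <- NULL; scl <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  if (stats::sd(y) == 0) {
    warning("constant labels; returning the intercept-only model")
    return(structure(list(w = numeric(ncol(X)), b = mean(y), alpha = NA_real_,
                          nonzero_count = 0L, cv = NULL, folds = folds,
                          seed = as.integer(seed), alpha_grid = numeric(0),
                          center = ctr, scale = scl),
                     class = "quality_model"))
  }
  if (is.null(alpha_grid)) {
    amax <- lasso_alpha_max(X, y)
    alpha_grid <- exp(seq(log(amax), log(amax * 1e-4), length.out = 50))
    alpha_grid[1] <- amax # exp(log(.)) can lose a ulp at the boundary
  }
  alpha_grid <- sort(alpha_grid, decreasing = TRUE)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), N)))
  cv_mse <- matrix(NA_real_, length(alpha_grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    path <- lasso_path(X[tr, , drop = FALSE], y[tr], alpha_grid, tol = tol)
    pred <- X[!tr, , drop = FALSE] %*% path$W +
      matrix(path$b, sum(!tr), length(alpha_grid), byrow = TRUE)
    cv_mse[, f] <- colMeans((pred - y[!tr])^2)
  }
  mean_mse <- rowMeans(cv_mse)
  best <- which.min(mean_mse)
  # refit on all data, warm-started down the path to the selected alpha
  full <- lasso_path(X, y, alpha_grid[seq_len(best)], tol = tol)
  w <- as.numeric(full$W[, best])
  b <- full$b[best]
  if (standardize) {
    w <- w / scl
    b <- b - sum(w * ctr)
  }
  structure(list(w = w, b = b, alpha = alpha_grid[best],
                 nonzero_count = sum(w != 0),
                 cv = data.frame(alpha = alpha_grid, mean_oof_mse = mean_mse),
                 folds = as.integer(folds), seed = as.integer(seed),
                 alpha_grid = alpha_grid, center = NULL, scale = NULL),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model> D = %d, alpha = %.4g, %d nonzero weights, b = %.4f\n",
              length(x$w), x$alpha, x$nonzero_count, x$b))
  invisible(x)
}

#' Predict a view-quality score
#'
#' Linear prediction `w . embedding + b`, clamped to `[0, 1]`.
#'
#' @param model A `quality_model`.
#' @param embeddings Length-`D` embedding or `N x D` matrix.
#' @return Quality score(s) in `[0, 1]`.
#' @export
predict_quality <- function(model, embeddings) {
  stopifnot(inherits(model, "quality_model"))
  X <- if (is.null(dim(embeddings))) matrix(embeddings, nrow = 1)
  else as.matrix(embeddings)
  if (ncol(X) != length(model$w))
    stop("embedding dimension mismatch: expected ", length(model$w))
  raw <- as.vector(X %*% model$w) + model$b
  clamp01(raw)
}

#' Bin a quality score into ordinal categories
#'
#' Intervals: poor `[0, 0.25]`, fair `(0.25, 0.5]`, good `(0.5, 0.75]`,
#' excellent `(0.75, 1]` — each boundary belongs to the lower bin.
#'
#' @param score Numeric quality score(s) in `[0, 1]`.
#' @return Factor with levels `poor < fair < good < excellent`.
#' @export
bin_quality <- function(score) {
  if (any(score < 0 | score > 1)) stop("quality scores must lie in [0, 1]")
  cut(score, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = TRUE, ordered_result = TRUE)
}

#' Save / load a quality model as JSON
#'
#' @param model A `quality_model`.
#' @param path JSON file path.
#' @return `write_quality_model()`: invisibly, the path;
#'   `read_quality_model()`: the model.
#' @export
write_quality_model <- function(model, path) {
  stopifnot(inherits(model, "quality_model"))
  jsonlite::write_json(list(w = model$w, b = model$b, alpha = model$alpha,
                            nonzero_count = model$nonzero_count,
                            folds = model$folds, seed = model$seed,
                            D = length(model$w)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quality_model
#' @export
read_quality_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(j$w), b = j$b, alpha = j$alpha,
                 nonzero_count = j$nonzero_count, cv = NULL,
                 folds = j$folds, seed = j$seed,
                 alpha_grid = numeric(0), center = NULL, scale = NULL),
            class = "quality_model")
}
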