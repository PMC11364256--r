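# L1-penalised quality regression: coordinate-descent solver, penalty
# selection, clamped prediction and ordinal binning.

make_lasso_problem <- function(seed, N = 25, D = 4) {
  set.seed(seed)
  X <- matrix(rnorm(N * D), N, D)
  w_true <- c(1.5, -0.8, rep(0, D - 2))
  y <- as.vector(X %*% w_true) + 0.3 + rnorm(N, sd = 0.3)
  y <- (y - min(y)) / (max(y) - min(y)) # into [0, 1]
  list(X = X, y = y)
}

test_that("constant labels yield the intercept-only model", {
  X <- matrix(rnorm(40), 10, 4)
  expect_warning(m <- fit_quality_lasso(X, rep(0.7, 10)), "constant")
  expect_equal(m$w, rep(0, 4))
  expect_equal(m$b, 0.7)
  expect_equal(unname(predict_quality(m, X)), rep(0.7, 10))
})

test_that("single-feature solutions equal the soft-thresholded OLS slope", {
  set.seed(2)
  for (rep in 1:10) {
    N <- 30
    x <- rnorm(N)
    x <- x - mean(x)
    x <- x / sqrt(mean(x^2)) # centred, unit second moment
    y <- 0.5 + 0.8 * x + rnorm(N, sd = 0.2)
    beta_ols <- mean(x * y) - mean(x) * mean(y)
    for (alpha in c(0.01, 0.3, abs(beta_ols) + 0.5)) {
      fit <- openecho:::lasso_cd(matrix(x, ncol = 1), y, alpha, tol = 1e-14)
      expect_equal(fit$w[1],
                   sign(beta_ols) * max(abs(beta_ols) - alpha, 0),
                   tolerance = 1e-8)
      expect_equal(fit$b, mean(y) - fit$w[1] * mean(x), tolerance = 1e-8)
    }
  }
})

test_that("the solver matches an independent coordinate-descent oracle", {
  skip_if_not_installed("glmnet")
  for (seed in 1:12) {
    prob <- make_lasso_problem(seed, N = sample(10:30, 1), D = sample(2:5, 1))
    amax <- openecho:::lasso_alpha_max(prob$X, prob$y)
    for (alpha in amax * c(0.5, 0.1, 0.01)) {
      fit <- openecho:::lasso_cd(prob$X, prob$y, alpha, tol = 1e-13)
      g <- glmnet::glmnet(prob$X, prob$y, lambda = alpha,
                          standardize = FALSE, thresh = 1e-14)
      obj_mine <- openecho:::lasso_objective(prob$X, prob$y, fit$w, fit$b,
                                             alpha)
      obj_ref <- openecho:::lasso_objective(prob$X, prob$y,
                                            as.numeric(g$beta),
                                            as.numeric(g$a0), alpha)
      expect_lt(abs(obj_mine - obj_ref), 1e-6)
    }
  }
})

test_that("cross-validated fitting improves on the intercept-only objective", {
  prob <- make_lasso_problem(3)
  m <- fit_quality_lasso(prob$X, prob$y, folds = 5, seed = 9)
  obj_fit <- openecho:::lasso_objective(prob$X, prob$y, m$w, m$b, m$alpha)
  obj_null <- openecho:::lasso_objective(prob$X, prob$y, rep(0, 4),
                                         mean(prob$y), m$alpha)
  expect_lte(obj_fit, obj_null)
  expect_identical(m$nonzero_count, sum(m$w != 0))
  # seeded fold partition: same seed, same model
  m2 <- fit_quality_lasso(prob$X, prob$y, folds = 5, seed = 9)
  expect_equal(m$w, m2$w)
  expect_equal(m$alpha, m2$alpha)
})

test_that("sparsity is non-increasing along the penalty path", {
  prob <- make_lasso_problem(7, N = 30, D = 5)
  amax <- openecho:::lasso_alpha_max(prob$X, prob$y)
  grid <- exp(seq(log(amax), log(amax * 1e-3), length.out = 20))
  grid[1] <- amax
  nz <- integer(0)
  w <- NULL; b <- NULL
  for (a in grid) {
    fit <- openecho:::lasso_cd(prob$X, prob$y, a, w = w, b = b, tol = 1e-12)
    w <- fit$w; b <- fit$b
    nz <- c(nz, sum(w != 0))
  }
  expect_true(all(diff(nz) >= 0)) # grid descends, support grows
  expect_identical(nz[1], 0L)     # alpha_max zeroes everything
})

test_that("predictions are clamped to [0, 1]", {
  m <- structure(list(w = c(1), b = 0, alpha = 0.1, nonzero_count = 1L,
                      cv = NULL, folds = 5L, seed = 1L,
                      alpha_grid = numeric(0), center = NULL, scale = NULL),
                 class = "quality_model")
  expect_equal(predict_quality(m, -0.3), 0)
  expect_equal(predict_quality(m, 1.7), 1)
  expect_equal(predict_quality(m, 0.42), 0.42)
  expect_error(predict_quality(m, c(1, 2)), "dimension mismatch")
})

test_that("quality bins place boundaries in the lower category", {
  expect_equal(as.character(bin_quality(c(0, 0.25))), c("poor", "poor"))
  expect_equal(as.character(bin_quality(0.5)), "fair")
  expect_equal(as.character(bin_quality(0.75)), "good")
  expect_equal(as.character(bin_quality(c(0.76, 1))),
               c("excellent", "excellent"))
  expect_error(bin_quality(1.2), "\\[0, 1\\]")
  expect_true(is.ordered(bin_quality(0.3)))
})

test_that("quality models round-trip through JSON", {
  prob <- make_lasso_problem(5)
  m <- fit_quality_lasso(prob$X, prob$y, folds = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_quality_model(m, path)
  m2 <- read_quality_model(path)
  expect_equal(m2$w, m$w)
  expect_equal(m2$b, m$b)
  expect_equal(predict_quality(m2, prob$X), predict_quality(m, prob$X))
})
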