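# PLS regression, PCA(95%) reduction, SVR and the hyperparameter search.

test_that("PLS1 solves the exact linear case with one component", {
  # orthogonal predictors: the first covariance direction is exactly the
  # informative column, so one latent variable reproduces y
  X <- unclass(poly(1:40, 6))
  y <- 3 * X[, 2]
  fit <- pls1(X, y, 1)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-8)

  # single-latent-factor data: validation RMSE is minimised by one component
  set.seed(1)
  t_ <- rnorm(100)
  X1 <- outer(t_, runif(6, 0.5, 2)) + matrix(rnorm(600, 0, 0.01), 100)
  y1 <- t_ + rnorm(100, 0, 0.01)
  sel <- select_latent_variables(X1[1:80, ], y1[1:80], X1[81:100, ],
                                 y1[81:100], max_lv = 5)
  expect_equal(sel$ncomp, 1L)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(60, 0, 0.3)
  fit <- pls1(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(fit, X)), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("PLS is invariant to sample order and errors beyond the rank", {
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rnorm(30)
  b1 <- coef(pls1(X, y, 4))
  p <- sample(30)
  b2 <- coef(pls1(X[p, ], y[p], 4))
  expect_equal(b1, b2, tolerance = 1e-9)
  Xr <- cbind(X[, 1:2], X[, 1] + X[, 2])   # rank 2
  expect_error(pls1(Xr, y, 3), class = "vibrofirm_domain_error")
})

test_that("latent-variable selection minimises validation RMSE", {
  set.seed(4)
  n <- 300
  scores <- matrix(rnorm(n * 3), n)
  load <- matrix(rnorm(3 * 50), 3)
  X <- scores %*% load + matrix(rnorm(n * 50, 0, 0.3), n)
  y <- drop(scores %*% c(2, -1, 0.5)) + rnorm(n, 0, 0.2)
  tr <- 1:200; va <- 201:300
  sel <- select_latent_variables(X[tr, ], y[tr], X[va, ], y[va], max_lv = 10)
  expect_true(sel$ncomp %in% 2:4)
  expect_true(all(sel$rmse[sel$ncomp] <= sel$rmse))
})

test_that("PCA retains the smallest count exceeding 95% variance", {
  set.seed(5)
  S <- matrix(rnorm(200 * 2), 200)
  X2 <- cbind(S %*% matrix(c(1, 0, 0.5, 1), 2), 0 * S[, 1], 0 * S[, 1])
  expect_equal(fit_pca_95(X2)$retained, 2L)

  Xi <- matrix(rnorm(2000 * 10), 2000)
  expect_equal(fit_pca_95(Xi)$retained, 10L)

  basis <- fit_pca_95(Xi)
  expect_true(all(diff(basis$explained_ratio) <= 1e-12))
  rot <- fit_pca_95(X2)$rotation
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(fit_pca_95(matrix(1, 10, 3)),
               class = "vibrofirm_degenerate_signal")
})

test_that("PCA reconstruction error respects the variance threshold", {
  set.seed(6)
  X <- matrix(rnorm(100 * 20), 100) %*% diag(seq(3, 0.1, length.out = 20))
  b <- fit_pca_95(X)
  Z <- predict(b, X)
  recon <- sweep(Z %*% t(b$rotation), 2, b$center, "+")
  err <- sum((X - recon)^2)
  expect_lt(err / sum(sweep(X, 2, colMeans(X))^2), 0.05)
})

test_that("SVR fits realizable linear data and honours its configuration", {
  set.seed(7)
  X <- matrix(rnorm(50 * 3), 50)
  y <- drop(X %*% c(1, 2, -1))
  fit <- fit_svr(X, y, "linear", C = 1e3, epsilon = 0.01)
  expect_true(all(abs(predict(fit, X) - y) <= 0.02))

  # externally supplied optimum accepted verbatim
  opt <- fit_svr(X, y, "linear", C = 0.0109, epsilon = 0.0086)
  expect_equal(opt$C, 0.0109)
  expect_equal(opt$epsilon, 0.0086)
  expect_length(predict(opt, X), 50)

  expect_error(fit_svr(X, y, "banana", 1, 0.1),
               class = "vibrofirm_domain_error")
  expect_error(fit_svr(X, y, "linear", -1, 0.1),
               class = "vibrofirm_domain_error")
})

test_that("SVR predictions are invariant to duplication and ordering", {
  set.seed(8)
  X <- matrix(rnorm(40 * 3), 40)
  y <- drop(X %*% c(1, -1, 2))           # realizable: duplication is neutral
  g <- matrix(rnorm(10 * 3), 10)
  # tight optimizer tolerance so the solutions are converged enough for a
  # 1e-6 comparison
  f1 <- fit_svr(X, y, "linear", C = 100, epsilon = 0.01, tolerance = 1e-9)
  f2 <- fit_svr(rbind(X, X), c(y, y), "linear", C = 100, epsilon = 0.01,
                tolerance = 1e-9)
  expect_equal(predict(f1, g), predict(f2, g), tolerance = 1e-6)
  p <- sample(40)
  f3 <- fit_svr(X[p, ], y[p], "linear", C = 100, epsilon = 0.01,
                tolerance = 1e-9)
  expect_equal(predict(f1, g), predict(f3, g), tolerance = 1e-6)
})

test_that("hyperparameter search: degenerate space, incumbent optimality, grid oracle", {
  set.seed(9)
  n <- 80
  X <- matrix(rnorm(n * 4), n)
  y <- drop(X %*% c(0.5, 1, -1, 0.2)) + rnorm(n, 0, 0.4)
  tr <- 1:50; va <- 51:80
  one <- bayes_opt_svr(X[tr, ], y[tr], X[va, ], y[va], kernels = "linear",
                       C_range = c(1, 1), eps_range = c(0.1, 0.1), budget = 1,
                       seed = 1)
  expect_equal(nrow(one$history), 1L)
  expect_equal(one$best$C, 1)

  res <- bayes_opt_svr(X[tr, ], y[tr], X[va, ], y[va], budget = 25, seed = 2)
  expect_equal(min(res$history$rmse), res$best$rmse)
  # deterministic under the seed
  res2 <- bayes_opt_svr(X[tr, ], y[tr], X[va, ], y[va], budget = 25, seed = 2)
  expect_identical(res$history, res2$history)

  # dense grid oracle over C (linear kernel, fixed epsilon)
  grid <- 10^seq(-3, 3, length.out = 25)
  g_rmse <- vapply(grid, function(C) {
    f <- fit_svr(X[tr, ], y[tr], "linear", C, 0.05)
    sqrt(mean((y[va] - predict(f, X[va, ]))^2))
  }, numeric(1))
  best_C <- grid[which.min(g_rmse)]
  lin <- bayes_opt_svr(X[tr, ], y[tr], X[va, ], y[va], kernels = "linear",
                       eps_range = c(0.05, 0.05), budget = 40, seed = 3)
  expect_lt(abs(log10(lin$best$C) - log10(best_C)), 1)
})
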