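#' PCA basis retaining a variance fraction
#'
#' Principal components are fitted on the training matrix only; the number
#' retained is the smallest count whose cumulative explained-variance ratio
#' exceeds `var_cutoff`. New data are projected after centring with the
#' training mean (no information from validation/test partitions enters the
#' basis).
#'
#' @param x Training matrix, samples x features (>= 2 samples).
#' @param var_cutoff Cumulative explained-variance threshold (default 0.95).
#' @return Object of class `pca_basis` with `rotation`, `center`,
#'   `explained_ratio` and `retained`.
#' @export
fit_pca_95 <- function(x, var_cutoff = 0.95) {
  x <- as.matrix(x)
  vf_check(nrow(x) >= 2, "vibrofirm_domain_error", "need >= 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  vf_check(sum(v) > 0, "vibrofirm_degenerate_signal",
           "degenerate input: zero total variance")
  ratio <- v / sum(v)
  retained <- which(cumsum(ratio) > var_cutoff)[1]
  structure(list(rotation = pc$rotation[, seq_len(retained), drop = FALSE],
                 center = pc$center, explained_ratio = ratio,
                 retained = retained, var_cutoff = var_cutoff),
            class = "pca_basis")
}

#' @param object A `pca_basis`.
#' @param newdata Matrix or vector on the training feature grid.
#' @param ... Unused.
#' @rdname fit_pca_95
#' @export
predict.pca_basis <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(newdata, 2, object$center) %*% object$rotation
}

# map the package's kernel vocabulary onto the underlying SVM implementation
svr_kernel_name <- function(kernel) {
  map <- c(linear = "linear", polynomial = "polynomial",
           gaussian = "radial", sigmoid = "sigmoid")
  vf_check(kernel %in% names(map), "vibrofirm_domain_error",
           sprintf("unknown kernel '%s'", kernel))
  unname(map[kernel])
}

#' Epsilon-insensitive support vector regression
#'
#' Thin wrapper around the `e1071` eps-regression SVM with the kernel
#' vocabulary used here (`linear`, `polynomial`, `gaussian`, `sigmoid`).
#' Inputs are assumed already scaled (no internal rescaling).
#'
#' @param x Training matrix (e.g. retained principal-component scores).
#' @param y Response vector.
#' @param kernel Kernel name.
#' @param C Box constraint, > 0.
#' @param epsilon Tube half-width, >= 0.
#' @param ... Further kernel parameters passed through (e.g. `gamma`,
#'   `degree`).
#' @return Object of class `svr_fit`.
#' @export
fit_svr <- function(x, y, kernel = "linear", C = 1, epsilon = 0.1, ...) {
  vf_check(C > 0, "vibrofirm_domain_error", "C must be > 0")
  vf_check(epsilon >= 0, "vibrofirm_domain_error", "epsilon must be >= 0")
  kn <- svr_kernel_name(kernel)
  m <- e1071::svm(as.matrix(x), y, type = "eps-regression", kernel = kn,
                  cost = C, epsilon = epsilon, scale = FALSE, ...)
  structure(list(model = m, kernel = kernel, C = C, epsilon = epsilon),
            class = "svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  as.numeric(stats::predict(object$model, as.matrix(newdata)))
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf("<svr_fit> kernel %s, C = %g, epsilon = %g, %d support vectors\n",
              x$kernel, x$C, x$epsilon, x$model$tot.nSV))
  invisible(x)
}

#' PCA + SVR pipeline fit
#'
#' Dimensionality reduction to the components explaining more than
#' `var_cutoff` of training variance, followed by eps-insensitive support
#' vector regression on the scores.
#'
#' @inheritParams fit_svr
#' @param var_cutoff Variance fraction retained by the PCA step.
#' @return Object of class `pca_svr` with `basis` and `svr` parts.
#' @export
pca_svr <- function(x, y, kernel = "linear", C = 1, epsilon = 0.1,
                    var_cutoff = 0.95, ...) {
  basis <- fit_pca_95(x, var_cutoff = var_cutoff)
  z <- predict(basis, x)
  structure(list(basis = basis, svr = fit_svr(z, y, kernel, C, epsilon, ...)),
            class = "pca_svr")
}

#' @export
predict.pca_svr <- function(object, newdata, ...) {
  predict(object$svr, predict(object$basis, newdata))
}

#' @export
print.pca_svr <- function(x, ...) {
  cat(sprintf("<pca_svr> %d components (> %g%% variance), ",
              x$basis$retained, 100 * x$basis$var_cutoff))
  print(x$svr)
  invisible(x)
}

# --- Gaussian-process expected-improvement search over SVR hyperparameters ---

# encode a configuration as numeric coordinates: kernel one-hot + scaled logs
svr_encode <- function(df, kernels, logC_range, logeps_range) {
  oh <- outer(df$kernel, kernels, "==") * 1
  scale01 <- function(x, rng) {
    w <- diff(rng)
    if (w == 0) rep(0.5, length(x)) else (x - rng[1]) / w
  }
  cbind(oh, scale01(log(df$C), logC_range),
        scale01(log(df$epsilon), logeps_range))
}

gp_ei <- function(Xobs, yobs, Xcand, lengthscale = 0.7, noise = 1e-4) {
  mu0 <- mean(yobs); s0 <- stats::sd(yobs)
  if (!is.finite(s0) || s0 == 0) s0 <- 1
  yz <- (yobs - mu0) / s0
  sq <- function(A, B) outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  K <- exp(-pmax(sq(Xobs, Xobs), 0) / (2 * lengthscale^2)) + diag(noise, nrow(Xobs))
  Ks <- exp(-pmax(sq(Xcand, Xobs), 0) / (2 * lengthscale^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  mu <- drop(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(V^2), 1e-12)
  sdv <- sqrt(s2)
  best <- min(yz)
  imp <- best - mu
  z <- imp / sdv
  imp * stats::pnorm(z) + sdv * stats::dnorm(z)
}

#' Hyperparameter search for SVR by Bayesian optimisation
#'
#' Minimises validation RMSE over kernel choice and log-uniform ranges of the
#' box constraint and epsilon. The default method fits a Gaussian-process
#' surrogate (RBF kernel on encoded coordinates) to the observed RMSEs and
#' picks each next configuration by expected improvement over a random
#' candidate pool; `method = "random"` is a seeded pure random search. The
#' default configuration (linear kernel, C = 1, epsilon = 0.1) is always
#' evaluated first, so the incumbent can never be worse than it.
#'
#' @param x_train,y_train Training inputs (already reduced/scaled) and
#'   response.
#' @param x_val,y_val Validation partition used as the search objective.
#' @param kernels Candidate kernel names.
#' @param C_range,eps_range Log-uniform search ranges.
#' @param budget Total number of evaluated configurations (>= 1).
#' @param seed Integer seed; the search is deterministic given it.
#' @param method `"gp"` (expected improvement) or `"random"`.
#' @return Object of class `svr_search`: `history` (one row per evaluation
#'   with validation RMSE), `best` (incumbent row) and `model` (refit of the
#'   incumbent configuration).
#' @export
bayes_opt_svr <- function(x_train, y_train, x_val, y_val,
                          kernels = c("linear", "polynomial", "gaussian", "sigmoid"),
                          C_range = c(1e-3, 1e3), eps_range = c(1e-3, 1),
                          budget = 40, seed = 1L, method = c("gp", "random")) {
  method <- match.arg(method)
  vf_check(budget >= 1, "vibrofirm_domain_error", "budget must be >= 1")
  vf_check(length(kernels) >= 1, "vibrofirm_domain_error", "empty search space")
  set.seed(as.integer(seed %% 2147483647))
  lC <- log(C_range); le <- log(eps_range)
  draw <- function(n) data.frame(
    kernel = sample(kernels, n, replace = TRUE),
    C = exp(stats::runif(n, lC[1], lC[2])),
    epsilon = exp(stats::runif(n, le[1], le[2])),
    stringsAsFactors = FALSE)
  evaluate <- function(cfg) {
    fit <- fit_svr(x_train, y_train, cfg$kernel, cfg$C, cfg$epsilon)
    sqrt(mean((y_val - predict(fit, x_val))^2))
  }
  default_cfg <- data.frame(kernel = "linear", C = 1, epsilon = 0.1,
                            stringsAsFactors = FALSE)
  if (!("linear" %in% kernels)) default_cfg$kernel <- kernels[1]
  n0 <- min(max(4, ceiling(budget / 4)), budget)
  hist <- utils::head(rbind(default_cfg, draw(max(n0 - 1, 0))), budget)
  hist$rmse <- vapply(seq_len(nrow(hist)), function(i) evaluate(hist[i, ]),
                      numeric(1))
  while (nrow(hist) < budget) {
    cand <- draw(256)
    if (method == "gp") {
      Xo <- svr_encode(hist, kernels, lC, le)
      Xc <- svr_encode(cand, kernels, lC, le)
      ei <- gp_ei(Xo, hist$rmse, Xc)
      pick <- if (all(!is.finite(ei))) 1L else which.max(ei)
      nxt <- cand[pick, ]
    } else {
      nxt <- cand[1, ]
    }
    nxt$rmse <- evaluate(nxt)
    hist <- rbind(hist, nxt)
  }
  rownames(hist) <- NULL
  best <- hist[which.min(hist$rmse), ]
  model <- fit_svr(x_train, y_train, best$kernel, best$C, best$epsilon)
  structure(list(history = hist, best = best, model = model),
            class = "svr_search")
}

#' @export
print.svr_search <- function(x, ...) {
  cat(sprintf("<svr_search> %d evaluations; best: %s kernel, C = %.4g, epsilon = %.4g (val RMSE %.4f)\n",
              nrow(x$history), x$best$kernel, x$best$C, x$best$epsilon,
              x$best$rmse))
  invisible(x)
}
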