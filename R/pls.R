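#' Partial least squares regression (single response)
#'
#' Fits a univariate-response PLS regression by the NIPALS/PLS1 recursion:
#' each component's weight vector is the covariance direction between the
#' deflated predictors and the response, so successive latent variables
#' maximise covariance with firmness. Predictors and response are centred
#' internally; the returned model is affine in the input. With `ncomp` equal
#' to the predictor rank the fit coincides with ordinary least squares.
#'
#' @param x Numeric matrix, samples x predictors (typically standardized
#'   spectra).
#' @param y Numeric response vector.
#' @param ncomp Number of latent variables, `1 <= ncomp <= min(n - 1, p)`.
#' @return Object of class `pls1` with per-component weights `W`, loadings
#'   `P`, response loadings `q`, coefficient paths and training means.
#' @export
pls1 <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  vf_check(length(y) == n, "vibrofirm_domain_error", "x and y size mismatch")
  vf_check(ncomp >= 1 && ncomp <= min(n - 1, p), "vibrofirm_domain_error",
           "ncomp must be in [1, min(n - 1, p)]")
  xm <- colMeans(x); ym <- mean(y)
  X <- sweep(x, 2, xm); yy <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(X, yy))
    nw <- sqrt(sum(w^2))
    vf_check(nw > 1e-12, "vibrofirm_domain_error",
             "ncomp exceeds the rank of the training data")
    w <- w / nw
    t_ <- drop(X %*% w)
    tt <- sum(t_^2)
    pl <- drop(crossprod(X, t_)) / tt
    qa <- sum(yy * t_) / tt
    X <- X - tcrossprod(t_, pl)
    yy <- yy - qa * t_
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  structure(list(W = W, P = P, q = q, x_center = xm, y_center = ym,
                 ncomp = ncomp), class = "pls1")
}

# regression vector + intercept for the first `a` components
pls1_coef_a <- function(object, a) {
  Wa <- object$W[, seq_len(a), drop = FALSE]
  Pa <- object$P[, seq_len(a), drop = FALSE]
  beta <- drop(Wa %*% solve(crossprod(Pa, Wa), object$q[seq_len(a)]))
  c(intercept = object$y_center - sum(object$x_center * beta), beta)
}

#' @export
coef.pls1 <- function(object, ncomp = object$ncomp, ...) {
  pls1_coef_a(object, ncomp)
}

#' @param object A fitted `pls1` model.
#' @param newdata Matrix or vector of predictors.
#' @param ncomp Number of components to use (defaults to all fitted).
#' @param ... Unused.
#' @rdname pls1
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  b <- pls1_coef_a(object, ncomp)
  drop(newdata %*% b[-1]) + b[1]
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d latent variables, %d predictors\n",
              x$ncomp, nrow(x$W)))
  invisible(x)
}

#' Select the number of latent variables on a validation set
#'
#' Fits PLS1 with up to `max_lv` components on the training partition and
#' returns the component count minimising validation RMSE (ties go to the
#' smaller count).
#'
#' @param x_train,y_train Training predictors/response.
#' @param x_val,y_val Validation predictors/response.
#' @param max_lv Upper bound on the number of latent variables searched.
#' @return List with `ncomp` (selected count), `rmse` (per-count validation
#'   RMSE) and `model` (the full `max_lv`-component fit).
#' @export
select_latent_variables <- function(x_train, y_train, x_val, y_val,
                                    max_lv = 60) {
  vf_check(max_lv >= 1, "vibrofirm_domain_error", "max_lv must be >= 1")
  max_lv <- min(max_lv, nrow(x_train) - 1, ncol(x_train))
  fit <- pls1(x_train, y_train, max_lv)
  rmse <- vapply(seq_len(max_lv), function(a) {
    pr <- predict(fit, x_val, ncomp = a)
    sqrt(mean((y_val - pr)^2))
  }, numeric(1))
  list(ncomp = which.min(rmse), rmse = rmse, model = fit)
}
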