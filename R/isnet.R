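#' ISNet-1D architecture configuration
#'
#' Defines the one-dimensional Inception/squeeze-and-excitation regression
#' network: a stem convolution (16 filters, kernel 3) with batch
#' normalization, ReLU and max-pooling; a four-branch Inception block (1x1;
#' 1x1 then 3; 1x1 then 5; max-pool then 1x1) whose outputs are
#' depth-concatenated; an SE channel-attention block (global average pool,
#' two 1x1 convolutions with ReLU then sigmoid gating); a post convolution
#' (32 filters, kernel 5) with max-pooling; and a 64-unit fully connected
#' layer with dropout 0.3 feeding a single linear output.
#'
#' @param input_length Spectrum length fed to the network (default 2623).
#' @param stem_filters,stem_kernel Stem convolution width and kernel size.
#' @param inception_filters Length-4 filter counts for the four branches.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param post_filters,post_kernel Post-Inception convolution width/kernel.
#' @param fc_units Fully connected layer width.
#' @param dropout Dropout rate in `[0, 1)` after the FC layer.
#' @return Object of class `isnet_config`.
#' @export
isnet_config <- function(input_length = 2623, stem_filters = 16,
                         stem_kernel = 3, inception_filters = c(16, 16, 16, 16),
                         se_reduction = 4, post_filters = 32, post_kernel = 5,
                         fc_units = 64, dropout = 0.3) {
  vf_check(dropout >= 0 && dropout < 1, "vibrofirm_domain_error",
           "dropout must be in [0, 1)")
  vf_check(length(inception_filters) == 4 && all(inception_filters >= 1),
           "vibrofirm_domain_error", "need four positive branch widths")
  vf_check(stem_kernel %% 2 == 1 && post_kernel %% 2 == 1,
           "vibrofirm_domain_error", "kernel sizes must be odd")
  cc <- sum(inception_filters)
  vf_check(cc %% se_reduction == 0, "vibrofirm_domain_error",
           "concatenated channels must be divisible by se_reduction")
  structure(list(
    input_length = as.integer(input_length), stem_filters = stem_filters,
    stem_kernel = stem_kernel, inception_filters = inception_filters,
    se_reduction = se_reduction, post_filters = post_filters,
    post_kernel = post_kernel, fc_units = fc_units, dropout = dropout,
    concat_channels = cc,
    L1 = as.integer(input_length) %/% 2L,
    L2 = (as.integer(input_length) %/% 2L) %/% 2L
  ), class = "isnet_config")
}

#' ISNet-1D training configuration
#'
#' Adam optimisation with a step-decay learning-rate schedule and early
#' stopping on validation loss. Defaults follow the reference schedule: batch
#' size 16, initial learning rate 1e-4 dropped by a factor 0.1 every 50
#' epochs, L2 penalty coefficient 1e-4 on convolutional and fully connected
#' weights, at most 300 epochs.
#'
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param lr_drop_factor,lr_drop_period Step-decay factor and period (epochs).
#' @param lambda L2 regularization coefficient in the training loss.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param seed Integer seed controlling initialisation, shuffling and dropout.
#' @param precision Working precision of the compiled training step:
#'   `"single"` (default, faster) or `"double"`. Parameters, optimiser state
#'   and predictions are always double precision; either choice is
#'   deterministic under the seed.
#' @param verbose Print per-epoch losses.
#' @return Object of class `isnet_control`.
#' @export
isnet_control <- function(batch_size = 16, lr = 1e-4, lr_drop_factor = 0.1,
                          lr_drop_period = 50, lambda = 1e-4,
                          max_epochs = 300, patience = 30, seed = 1L,
                          precision = c("single", "double"),
                          verbose = FALSE) {
  precision <- match.arg(precision)
  vf_check(all(c(batch_size, lr, lr_drop_factor, lr_drop_period,
                 max_epochs, patience) > 0) && lambda >= 0,
           "vibrofirm_domain_error", "control values must be positive")
  vf_check(patience < max_epochs, "vibrofirm_domain_error",
           "patience must be below max_epochs")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period), lambda = lambda,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 precision = precision, verbose = isTRUE(verbose)),
            class = "isnet_control")
}

# He-style initialisation; consumes the active RNG stream
isnet_init <- function(cfg) {
  he <- function(co, ci_k) matrix(stats::rnorm(co * ci_k, 0, sqrt(2 / ci_k)),
                                  co, ci_k)
  fi <- cfg$inception_filters
  sf <- cfg$stem_filters
  cc <- cfg$concat_channels
  cr <- cc %/% cfg$se_reduction
  flat <- cfg$L2 * cfg$post_filters
  list(
    conv1_W = he(sf, cfg$stem_kernel), conv1_b = numeric(sf),
    bn_gamma = rep(1, sf), bn_beta = numeric(sf),
    i1_W = he(fi[1], sf), i1_b = numeric(fi[1]),
    i2a_W = he(fi[2], sf), i2a_b = numeric(fi[2]),
    i2b_W = he(fi[2], fi[2] * 3), i2b_b = numeric(fi[2]),
    i3a_W = he(fi[3], sf), i3a_b = numeric(fi[3]),
    i3b_W = he(fi[3], fi[3] * 5), i3b_b = numeric(fi[3]),
    i4_W = he(fi[4], sf), i4_b = numeric(fi[4]),
    se1_W = he(cr, cc), se1_b = numeric(cr),
    se2_W = he(cc, cr), se2_b = numeric(cc),
    conv2_W = he(cfg$post_filters, cc * cfg$post_kernel),
    conv2_b = numeric(cfg$post_filters),
    fc1_W = he(cfg$fc_units, flat), fc1_b = numeric(cfg$fc_units),
    out_W = matrix(stats::rnorm(cfg$fc_units, 0, 0.01), 1, cfg$fc_units),
    out_b = 0
  )
}

isnet_buffers <- function(cfg) {
  list(bn_mean = numeric(cfg$stem_filters), bn_var = rep(1, cfg$stem_filters))
}

# names of parameters subject to the L2 penalty (weights only)
isnet_weight_names <- function(par) grep("_W$", names(par), value = TRUE)

#' ISNet-1D training loss
#'
#' Mean squared error plus an L2 weight penalty:
#' `mean((y - yhat)^2) + lambda/2 * sum(w^2)`, where the penalty runs over
#' convolutional and fully connected weights only (not biases or batch-norm
#' parameters). With `lambda = 0` this is exactly the MSE.
#'
#' @param y,yhat Reference and predicted values, equal nonzero length.
#' @param weights List of weight arrays (e.g. the `_W` entries of a fitted
#'   network), or NULL for no penalty term.
#' @param lambda Penalty coefficient, >= 0.
#' @return Scalar loss.
#' @export
isnet_loss <- function(y, yhat, weights = NULL, lambda = 0) {
  vf_check(length(y) == length(yhat) && length(y) >= 1,
           "vibrofirm_domain_error", "y and yhat must match and be nonempty")
  vf_check(lambda >= 0, "vibrofirm_domain_error", "lambda must be >= 0")
  pen <- if (is.null(weights) || lambda == 0) 0
         else 0.5 * lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  mean((y - yhat)^2) + pen
}

# forward pass; x is an nb x input_length matrix. Returns yhat and, when
# keep_cache, everything backward needs.
isnet_fwd <- function(par, buffers, x, cfg, ws, train = FALSE,
                      bn_train = train, keep_cache = train,
                      dropout_mask = NULL) {
  nb <- nrow(x)
  L0 <- cfg$input_length
  vf_check(ncol(x) == L0, "vibrofirm_domain_error",
           sprintf("input length %d does not match network input %d",
                   ncol(x), L0))
  L1 <- cfg$L1; L2 <- cfg$L2
  px1 <- ws_get(ws, paste0("p1_", nb), function() nn_pool2_idx(L0, nb))
  idxp <- ws_get(ws, paste0("ip_", nb), function() nn_conv_idx(L1, nb, 3L))
  px2 <- ws_get(ws, paste0("p2_", nb), function() nn_pool2_idx(L1, nb))
  Msum <- ws_get(ws, paste0("ms_", nb), function() nn_group_mat(L1, nb))
  gidx <- rep(seq_len(nb), each = L1)

  A0 <- matrix(as.vector(t(x)), nrow = 1)
  c1 <- nn_conv_fwd(A0, par$conv1_W, par$conv1_b, L0, nb, cfg$stem_kernel)
  bn <- nn_bn_fwd(c1$Y, par$bn_gamma, par$bn_beta, buffers$bn_mean,
                  buffers$bn_var, train = bn_train)
  r1 <- nn_relu(bn$Y)
  p1 <- nn_pool2_fwd(r1$Y, px1)

  b1c <- nn_conv_fwd(p1$Y, par$i1_W, par$i1_b, L1, nb, 1L); b1 <- nn_relu(b1c$Y)
  b2a <- nn_conv_fwd(p1$Y, par$i2a_W, par$i2a_b, L1, nb, 1L); b2ar <- nn_relu(b2a$Y)
  b2b <- nn_conv_fwd(b2ar$Y, par$i2b_W, par$i2b_b, L1, nb, 3L); b2 <- nn_relu(b2b$Y)
  b3a <- nn_conv_fwd(p1$Y, par$i3a_W, par$i3a_b, L1, nb, 1L); b3ar <- nn_relu(b3a$Y)
  b3b <- nn_conv_fwd(b3ar$Y, par$i3b_W, par$i3b_b, L1, nb, 5L); b3 <- nn_relu(b3b$Y)
  b4p <- nn_pool3_fwd(p1$Y, idxp)
  b4c <- nn_conv_fwd(b4p$Y, par$i4_W, par$i4_b, L1, nb, 1L); b4 <- nn_relu(b4c$Y)
  cc <- rbind(b1$Y, b2$Y, b3$Y, b4$Y)

  se <- nn_se_fwd(cc, par$se1_W, par$se1_b, par$se2_W, par$se2_b, Msum, L1, gidx)
  c2 <- nn_conv_fwd(se$Y, par$conv2_W, par$conv2_b, L1, nb, cfg$post_kernel)
  r2 <- nn_relu(c2$Y)
  p2 <- nn_pool2_fwd(r2$Y, px2)

  Z <- p2$Y
  dim(Z) <- c(cfg$post_filters * L2, nb)
  h <- par$fc1_W %*% Z + par$fc1_b
  hm <- h > 0
  hr <- h * hm
  if (train && cfg$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        stats::rbinom(length(hr), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
        nrow(hr), ncol(hr))
    }
    hd <- hr * dropout_mask
  } else {
    dropout_mask <- NULL
    hd <- hr
  }
  yhat <- drop(par$out_W %*% hd + par$out_b)

  out <- list(yhat = yhat,
              bn_run = list(bn_mean = bn$run_mean, bn_var = bn$run_var))
  if (keep_cache) {
    out$cache <- list(nb = nb, A0 = A0, c1 = c1, bn = bn, r1 = r1, p1 = p1,
                      b1c = b1c, b1 = b1, b2a = b2a, b2ar = b2ar, b2b = b2b,
                      b2 = b2, b3a = b3a, b3ar = b3ar, b3b = b3b, b3 = b3,
                      b4p = b4p, b4c = b4c, b4 = b4, cc = cc, se = se,
                      c2 = c2, r2 = r2, p2 = p2, Z = Z, hm = hm, hr = hr,
                      hd = hd, dropout_mask = dropout_mask,
                      idx = list(px1 = px1, idxp = idxp, px2 = px2,
                                 Msum = Msum, gidx = gidx))
  }
  out
}

# backward from d(yhat) to the conv2 post-activation feature maps; shared by
# full backprop and the saliency-map gradient
isnet_bwd_head <- function(par, cfg, cache, dyhat) {
  nb <- cache$nb
  dout <- matrix(dyhat, nrow = 1)
  g <- list()
  g$out_W <- tcrossprod(dout, cache$hd)
  g$out_b <- sum(dout)
  dhd <- crossprod(par$out_W, dout)
  dhr <- if (!is.null(cache$dropout_mask)) dhd * cache$dropout_mask else dhd
  dh <- dhr * cache$hm
  g$fc1_W <- tcrossprod(dh, cache$Z)
  g$fc1_b <- rowSums(dh)
  dZ <- crossprod(par$fc1_W, dh)
  dim(dZ) <- c(cfg$post_filters, cfg$L2 * nb)
  dr2 <- nn_pool2_bwd(dZ, cache$p2$mask, cache$idx$px2, cfg$L1 * nb)
  dc2 <- dr2 * cache$r2$mask
  list(grads = g, dc2 = dc2, dr2 = dr2)
}

isnet_bwd <- function(par, cfg, cache, dyhat) {
  nb <- cache$nb
  L1 <- cfg$L1
  ix <- cache$idx
  head <- isnet_bwd_head(par, cfg, cache, dyhat)
  g <- head$grads
  cb <- nn_conv_bwd(head$dc2, cache$se$Y, par$conv2_W, L1, nb, cfg$post_kernel)
  g$conv2_W <- cb$dW; g$conv2_b <- cb$db
  seb <- nn_se_bwd(cb$dA, cache$cc, cache$se, par$se1_W, par$se2_W,
                   ix$Msum, cfg$L1, ix$gidx)
  g$se1_W <- seb$dW1; g$se1_b <- seb$db1
  g$se2_W <- seb$dW2; g$se2_b <- seb$db2

  fi <- cfg$inception_filters
  splits <- cumsum(c(0, fi))
  dcc <- seb$dA
  dp1 <- matrix(0, cfg$stem_filters, cfg$L1 * nb)

  db1 <- dcc[(splits[1] + 1):splits[2], , drop = FALSE] * cache$b1$mask
  bb <- nn_conv_bwd(db1, cache$p1$Y, par$i1_W, L1, nb, 1L)
  g$i1_W <- bb$dW; g$i1_b <- bb$db; dp1 <- dp1 + bb$dA

  db2 <- dcc[(splits[2] + 1):splits[3], , drop = FALSE] * cache$b2$mask
  bb <- nn_conv_bwd(db2, cache$b2ar$Y, par$i2b_W, L1, nb, 3L)
  g$i2b_W <- bb$dW; g$i2b_b <- bb$db
  da <- bb$dA * cache$b2ar$mask
  bb <- nn_conv_bwd(da, cache$p1$Y, par$i2a_W, L1, nb, 1L)
  g$i2a_W <- bb$dW; g$i2a_b <- bb$db; dp1 <- dp1 + bb$dA

  db3 <- dcc[(splits[3] + 1):splits[4], , drop = FALSE] * cache$b3$mask
  bb <- nn_conv_bwd(db3, cache$b3ar$Y, par$i3b_W, L1, nb, 5L)
  g$i3b_W <- bb$dW; g$i3b_b <- bb$db
  da <- bb$dA * cache$b3ar$mask
  bb <- nn_conv_bwd(da, cache$p1$Y, par$i3a_W, L1, nb, 1L)
  g$i3a_W <- bb$dW; g$i3a_b <- bb$db; dp1 <- dp1 + bb$dA

  db4 <- dcc[(splits[4] + 1):splits[5], , drop = FALSE] * cache$b4$mask
  bb <- nn_conv_bwd(db4, cache$b4p$Y, par$i4_W, L1, nb, 1L)
  g$i4_W <- bb$dW; g$i4_b <- bb$db
  dp1 <- dp1 + nn_pool3_bwd(bb$dA, cache$b4p$masks, ix$idxp)

  dr1 <- nn_pool2_bwd(dp1, cache$p1$mask, ix$px1, cfg$input_length * nb)
  dbn_in <- dr1 * cache$r1$mask
  bnb <- nn_bn_bwd(dbn_in, cache$c1$Y, cache$bn, par$bn_gamma)
  g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  cb <- nn_conv_bwd(bnb$dA, cache$A0, par$conv1_W, cfg$input_length, nb, cfg$stem_kernel)
  g$conv1_W <- cb$dW; g$conv1_b <- cb$db
  g
}

isnet_predict_engine <- function(par, buffers, x, cfg, ws = NULL, chunk = 64L) {
  vf_check(ncol(x) == cfg$input_length, "vibrofirm_domain_error",
           sprintf("input length %d does not match network input %d",
                   ncol(x), cfg$input_length))
  n <- nrow(x)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    st <- isnet_step_cpp(par, buffers, x[i:j, , drop = FALSE], cfg,
                         numeric(j - i + 1L), FALSE, matrix(0, 0, 0), FALSE)
    out[i:j] <- st$yhat
    i <- j + 1L
  }
  out
}

# core training loop shared by isnet() and fine_tune()
isnet_engine <- function(par, buffers, x, y, x_val, y_val, cfg, ctl,
                         lr_factors = NULL, bn_train = TRUE) {
  n <- nrow(x)
  vf_check(n >= 2 && length(y) == n, "vibrofirm_domain_error",
           "nonempty matched training data required")
  vf_check(nrow(x_val) == length(y_val) && length(y_val) >= 1,
           "vibrofirm_domain_error", "nonempty validation partition required")
  ws <- new.env(parent = emptyenv())
  wn <- isnet_weight_names(par)
  factors <- if (is.null(lr_factors)) numeric(0) else unlist(lr_factors)
  single_prec <- identical(ctl$precision, "single")
  # the compiled step updates parameters and moments in place, so the engine
  # must own them exclusively: deep-copy on entry and at every snapshot
  deep_copy <- function(l) unserialize(serialize(l, NULL))
  par <- deep_copy(par)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  best <- list(val = Inf, par = deep_copy(par), buffers = buffers,
               epoch = 0L)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  t_adam <- 0L
  stale <- 0L
  for (epoch in seq_len(ctl$max_epochs)) {
    lr <- ctl$lr * ctl$lr_drop_factor^((epoch - 1L) %/% ctl$lr_drop_period)
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + ctl$batch_size - 1L, n)
      sel <- ord[i:j]
      nb <- length(sel)
      mask <- if (cfg$dropout > 0) {
        matrix(stats::rbinom(cfg$fc_units * nb, 1, 1 - cfg$dropout) /
                 (1 - cfg$dropout), cfg$fc_units, nb)
      } else {
        matrix(0, 0, 0)
      }
      t_adam <- t_adam + 1L
      st <- isnet_train_step_cpp(par, buffers, x[sel, , drop = FALSE], cfg,
                                 y[sel], bn_train, mask, state$m, state$v,
                                 lr, ctl$lambda, t_adam, factors,
                                 single_prec)
      if (bn_train) {
        buffers$bn_mean <- st$bn_mean
        buffers$bn_var <- st$bn_var
      }
      res <- st$yhat - y[sel]
      if (!all(is.finite(res))) {
        vf_stop("vibrofirm_training_diverged", "training diverged to non-finite loss")
      }
      ep_loss <- ep_loss + sum(res^2)
      i <- j + 1L
    }
    train_loss <- ep_loss / n +
      0.5 * ctl$lambda * sum(vapply(par[wn], function(w) sum(w^2), numeric(1)))
    vp <- isnet_predict_engine(par, buffers, x_val, cfg, ws)
    val_loss <- mean((y_val - vp)^2)
    hist_tr <- c(hist_tr, train_loss); hist_val <- c(hist_val, val_loss)
    if (ctl$verbose) {
      message(sprintf("epoch %3d  lr %.2g  train %.5f  val %.5f",
                      epoch, lr, train_loss, val_loss))
    }
    if (is.finite(val_loss) && val_loss < best$val) {
      best <- list(val = val_loss, par = deep_copy(par), buffers = buffers,
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= ctl$patience) break
    }
  }
  list(par = best$par, buffers = best$buffers, best_epoch = best$epoch,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_val))
}

#' Fit the ISNet-1D firmness regression network
#'
#' Trains the Inception/squeeze-and-excitation 1D convolutional network on
#' standardized spectra with the Adam optimiser, a step-decay learning-rate
#' schedule, the MSE + L2 composite loss ([isnet_loss()]) and early stopping;
#' the returned weights are those of the epoch with the lowest validation
#' loss. Training is deterministic for a fixed `control$seed`.
#'
#' @param x,y Training spectra (samples x bins, standardized) and firmness.
#' @param x_val,y_val Validation partition monitored for early stopping.
#' @param config An [isnet_config()]; its `input_length` must equal `ncol(x)`.
#' @param control An [isnet_control()].
#' @return Object of class `isnet` with elements `params`, `buffers`,
#'   `config`, `control`, `history`, `best_epoch`, `data`.
#' @seealso [predict.isnet()], [grad_cam_1d()], [fine_tune()]
#' @export
isnet <- function(x, y, x_val, y_val,
                  config = isnet_config(input_length = ncol(x)),
                  control = isnet_control()) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  set.seed(control$seed)
  par <- isnet_init(config)
  # centring the output bias on the training mean speeds early epochs
  par$out_b <- mean(y)
  fit <- isnet_engine(par, isnet_buffers(config), x, y, x_val, y_val,
                      config, control)
  structure(list(params = fit$par, buffers = fit$buffers, config = config,
                 control = control, history = fit$history,
                 best_epoch = fit$best_epoch,
                 data = list(x = x, y = y, x_val = x_val, y_val = y_val)),
            class = "isnet")
}

#' Predict firmness with a fitted ISNet-1D
#'
#' @param object A fitted `isnet`.
#' @param newdata Matrix (samples x bins) or single spectrum vector,
#'   standardized like the training data.
#' @param chunk Internal prediction batch size (results are batch-size
#'   independent).
#' @param ... Unused.
#' @return Numeric vector of predicted firmness values (N/mm).
#' @export
predict.isnet <- function(object, newdata, chunk = 64L, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  ws <- new.env(parent = emptyenv())
  isnet_predict_engine(object$params, object$buffers, as.matrix(newdata),
                       object$config, ws, chunk = chunk)
}

#' @export
print.isnet <- function(x, ...) {
  cat(sprintf("<isnet> input %d, %s params, best epoch %d/%d (val loss %.5f)\n",
              x$config$input_length,
              format(isnet_n_params(x), big.mark = ","), x$best_epoch,
              nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param object A fitted `isnet` or a raw parameter list.
#' @return Integer parameter count.
#' @export
isnet_n_params <- function(object) {
  par <- if (inherits(object, "isnet")) object$params else object
  sum(vapply(par, length, integer(1)))
}

#' @export
summary.isnet <- function(object, ...) {
  cfg <- object$config
  cat("ISNet-1D regression network\n")
  cat(sprintf("  input length      : %d\n", cfg$input_length))
  cat(sprintf("  stem              : %d filters, kernel %d (+ batch norm)\n",
              cfg$stem_filters, cfg$stem_kernel))
  cat(sprintf("  inception branches: %s (concat %d channels)\n",
              paste(cfg$inception_filters, collapse = "/"),
              cfg$concat_channels))
  cat(sprintf("  SE reduction      : %d\n", cfg$se_reduction))
  cat(sprintf("  post conv         : %d filters, kernel %d\n",
              cfg$post_filters, cfg$post_kernel))
  cat(sprintf("  head              : FC %d (dropout %.2f) -> 1\n",
              cfg$fc_units, cfg$dropout))
  cat(sprintf("  parameters        : %s\n",
              format(isnet_n_params(object), big.mark = ",")))
  cat(sprintf("  best epoch        : %d (val loss %.5f)\n",
              object$best_epoch, min(object$history$val_loss)))
  invisible(object)
}

#' @export
coef.isnet <- function(object, ...) object$params

#' @export
residuals.isnet <- function(object, ...) {
  object$data$y - predict(object, object$data$x)
}

#' Plot ISNet-1D training curves
#'
#' @param x A fitted `isnet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.isnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
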