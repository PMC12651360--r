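# Architecture, loss, gradients and training behaviour of the network.

test_that("training loss identities", {
  expect_equal(isnet_loss(c(1, 2), c(1, 2), lambda = 0), 0)
  expect_equal(isnet_loss(0, 2, lambda = 0), 4)
  expect_equal(isnet_loss(c(1, 2), c(1, 2), weights = list(c(1, 1)), lambda = 2), 2)
  set.seed(1)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(isnet_loss(y, yh, weights = list(matrix(1, 2, 2)), lambda = 0),
               mean((y - yh)^2))
  expect_error(isnet_loss(numeric(0), numeric(0)),
               class = "vibrofirm_domain_error")
})

test_that("default architecture matches its printed hyperparameters", {
  cfg <- isnet_config()
  expect_equal(cfg$input_length, 2623L)
  expect_equal(cfg$stem_filters, 16)
  expect_equal(cfg$stem_kernel, 3)
  expect_equal(cfg$inception_filters, c(16, 16, 16, 16))
  expect_equal(cfg$post_filters, 32)
  expect_equal(cfg$post_kernel, 5)
  expect_equal(cfg$fc_units, 64)
  expect_equal(cfg$dropout, 0.3)
  ctl <- isnet_control()
  expect_equal(ctl$batch_size, 16L)
  expect_equal(ctl$lr, 1e-4)
  expect_equal(ctl$lr_drop_factor, 0.1)
  expect_equal(ctl$lr_drop_period, 50L)
  expect_equal(ctl$lambda, 1e-4)
  expect_equal(ctl$max_epochs, 300L)
})

test_that("parameter count equals an independent per-layer hand count", {
  cfg <- isnet_config()
  set.seed(1)
  par <- vibrofirm:::isnet_init(cfg)
  L1 <- 2623 %/% 2; L2 <- L1 %/% 2
  hand <- (3 * 1 * 16 + 16) +            # stem conv
    (16 + 16) +                          # batch norm gamma/beta
    (1 * 16 * 16 + 16) +                 # inception branch 1: 1x1
    (1 * 16 * 16 + 16) + (3 * 16 * 16 + 16) +  # branch 2: 1x1 then 3
    (1 * 16 * 16 + 16) + (5 * 16 * 16 + 16) +  # branch 3: 1x1 then 5
    (1 * 16 * 16 + 16) +                 # branch 4: pool then 1x1
    (64 * 16 + 16) + (16 * 64 + 64) +    # SE excitation convs
    (5 * 64 * 32 + 32) +                 # post conv
    (L2 * 32 * 64 + 64) +                # fully connected
    (64 * 1 + 1)                         # linear output
  expect_equal(isnet_n_params(par), hand)
})

test_that("forward pass is well-posed and the SE gate lies strictly in (0,1)", {
  net <- tiny_net()
  x0 <- matrix(0, 1, 40)
  expect_true(is.finite(predict(net, x0)))
  ws <- new.env()
  fw <- vibrofirm:::isnet_fwd(net$params, net$buffers, matrix(rnorm(80), 2, 40),
                              net$config, ws, train = FALSE, keep_cache = TRUE)
  expect_true(all(fw$cache$se$g > 0 & fw$cache$se$g < 1))
  expect_error(predict(net, matrix(0, 1, 39)), class = "vibrofirm_domain_error")
})

test_that("predictions are batch-size independent and respect a zeroed head", {
  net <- tiny_net()
  X <- matrix(rnorm(7 * 40), 7, 40)
  one_by_one <- vapply(seq_len(7), function(i) predict(net, X[i, ]), numeric(1))
  expect_equal(predict(net, X), one_by_one, tolerance = 1e-6)
  expect_equal(predict(net, X, chunk = 3), one_by_one, tolerance = 1e-6)

  net0 <- net
  net0$params$out_W[] <- 0
  net0$params$out_b <- 4.2
  expect_equal(predict(net0, X), rep(4.2, 7))
})

test_that("analytic gradients match finite differences on a tiny network", {
  # fixed draw chosen away from ReLU/pooling kinks so central differences
  # are valid everywhere
  set.seed(42)
  cfg <- tiny_config()
  par <- vibrofirm:::isnet_init(cfg)
  buf <- vibrofirm:::isnet_buffers(cfg)
  x <- matrix(rnorm(3 * 40), 3, 40)
  y <- rnorm(3)
  ws <- new.env()
  lossfn <- function(p) {
    fw <- vibrofirm:::isnet_fwd(p, buf, x, cfg, ws, train = TRUE,
                                bn_train = TRUE, keep_cache = FALSE)
    mean((fw$yhat - y)^2)
  }
  fw <- vibrofirm:::isnet_fwd(par, buf, x, cfg, ws, train = TRUE,
                              bn_train = TRUE, keep_cache = TRUE)
  g <- vibrofirm:::isnet_bwd(par, cfg, fw$cache, 2 * (fw$yhat - y) / 3)
  eps <- 1e-6
  worst <- 0
  for (nm in names(par)) {
    idx <- seq_len(min(3, length(par[[nm]])))
    for (i in idx) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      worst <- max(worst, abs(num - g[[nm]][i]) /
                     max(1e-6, abs(num) + abs(g[[nm]][i])))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("compiled training step agrees with the R reference path", {
  set.seed(21)
  cfg <- tiny_config()
  par <- vibrofirm:::isnet_init(cfg)
  buf <- vibrofirm:::isnet_buffers(cfg)
  x <- matrix(rnorm(4 * 40), 4, 40)
  y <- rnorm(4)
  ws <- new.env()
  fw <- vibrofirm:::isnet_fwd(par, buf, x, cfg, ws, train = TRUE,
                              keep_cache = TRUE)
  gR <- vibrofirm:::isnet_bwd(par, cfg, fw$cache, 2 * (fw$yhat - y) / 4)
  st <- vibrofirm:::isnet_step_cpp(par, buf, x, cfg, y, TRUE,
                                   matrix(0, 0, 0), TRUE)
  expect_equal(st$yhat, fw$yhat, tolerance = 1e-12)
  expect_equal(st$bn_mean, fw$bn_run$bn_mean, tolerance = 1e-12)
  for (nm in names(gR)) {
    expect_equal(as.numeric(st$grads[[nm]]), as.numeric(gR[[nm]]),
                 tolerance = 1e-10, label = paste("grad", nm))
  }
  # eval mode too
  fwE <- vibrofirm:::isnet_fwd(par, buf, x, cfg, ws, train = FALSE,
                               keep_cache = FALSE)
  stE <- vibrofirm:::isnet_step_cpp(par, buf, x, cfg, y, FALSE,
                                    matrix(0, 0, 0), FALSE)
  expect_equal(stE$yhat, fwE$yhat, tolerance = 1e-12)
})

test_that("a small network memorizes a tiny training set", {
  set.seed(12)
  cfg <- tiny_config(input_length = 64)
  X <- matrix(rnorm(10 * 64), 10)
  y <- rnorm(10, 3, 1)
  ctl <- isnet_control(batch_size = 10, lr = 3e-3, lr_drop_period = 100,
                       lambda = 0, max_epochs = 80, patience = 79, seed = 5)
  fit <- isnet(X, y, X, y, config = cfg, control = ctl)
  expect_lt(min(fit$history$val_loss), 0.05 * fit$history$train_loss[1])
  # early-stopping contract: the kept epoch attains the minimum
  expect_equal(fit$history$val_loss[fit$best_epoch],
               min(fit$history$val_loss))
})

test_that("training is bit-reproducible for a fixed seed", {
  set.seed(13)
  X <- matrix(rnorm(12 * 40), 12)
  y <- rnorm(12)
  ctl <- isnet_control(batch_size = 4, lr = 1e-3, max_epochs = 5,
                       patience = 4, seed = 7)
  f1 <- isnet(X[1:8, ], y[1:8], X[9:12, ], y[9:12], config = tiny_config(),
              control = ctl)
  f2 <- isnet(X[1:8, ], y[1:8], X[9:12, ], y[9:12], config = tiny_config(),
              control = ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})
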