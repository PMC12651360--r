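# Internal 1D neural-network primitives.
#
# Activations are stored channels-first as a C x (L*N) matrix whose columns
# are ordered position-fastest, sample-next, so per-channel operations recycle
# over columns and convolutions become single BLAS matrix products on an
# im2col gather. Gather/scatter index matrices depend only on (L, N, k) and
# are cached per fit in a workspace environment.

nn_conv_idx <- function(L, N, k) {
  pad <- (k - 1L) %/% 2L
  l <- rep(seq_len(L), N)
  base <- rep((seq_len(N) - 1L) * L, each = L)
  LN <- L * N
  idx <- matrix(LN + 1L, nrow = k, ncol = LN)
  for (j in seq_len(k)) {
    pos <- l + (j - 1L) - pad
    ok <- pos >= 1L & pos <= L
    idx[j, ok] <- base[ok] + pos[ok]
  }
  idx
}

nn_pool2_idx <- function(L, N) {
  Lout <- L %/% 2L
  i1 <- rep((seq_len(N) - 1L) * L, each = Lout) +
    rep(seq.int(1L, 2L * Lout, by = 2L), N)
  list(i1 = i1, i2 = i1 + 1L, Lout = Lout)
}

# per-sample column-sum indicator (L*N x N); divide by L for the mean
nn_group_mat <- function(L, N) {
  M <- matrix(0, L * N, N)
  M[cbind(seq_len(L * N), rep(seq_len(N), each = L))] <- 1
  M
}

ws_get <- function(ws, key, maker) {
  if (is.null(ws[[key]])) ws[[key]] <- maker()
  ws[[key]]
}

# same-padded 1D convolutions delegate to the compiled per-offset GEMM
# kernels (src/conv1d.cpp); a 1x1 kernel is a single matrix product
nn_conv_fwd <- function(A, W, b, L, N, k) {
  if (k == 1L) return(list(Y = W %*% A + b))
  list(Y = conv1d_fwd_cpp(A, W, b, L, N, k))
}

nn_conv_bwd <- function(dY, A, W, L, N, k) {
  if (k == 1L) {
    return(list(dA = crossprod(W, dY), dW = tcrossprod(dY, A),
                db = rowSums(dY)))
  }
  conv1d_bwd_cpp(A, W, dY, L, N, k)
}

nn_pool2_fwd <- function(A, px) {
  A1 <- A[, px$i1, drop = FALSE]
  A2 <- A[, px$i2, drop = FALSE]
  m <- A1 >= A2
  Y <- A1
  Y[!m] <- A2[!m]
  list(Y = Y, mask = m)
}

nn_pool2_bwd <- function(dY, mask, px, LN_in) {
  dA <- matrix(0, nrow(dY), LN_in)
  dA[, px$i1] <- dY * mask
  dA[, px$i2] <- dY * !mask
  dA
}

nn_pool3_fwd <- function(A, idx) {
  LN <- ncol(A)
  Ap <- cbind(A, -Inf)
  g1 <- Ap[, idx[1, ], drop = FALSE]
  g2 <- Ap[, idx[2, ], drop = FALSE]
  g3 <- Ap[, idx[3, ], drop = FALSE]
  Y <- pmax(g1, g2, g3)
  m1 <- g1 == Y
  m2 <- (g2 == Y) & !m1
  m3 <- !(m1 | m2)
  list(Y = Y, masks = list(m1, m2, m3))
}

nn_pool3_bwd <- function(dY, masks, idx) {
  LN <- ncol(dY)
  dA <- matrix(0, nrow(dY), LN)
  for (j in 1:3) {
    cols <- idx[j, ]
    ok <- cols <= LN
    contrib <- dY * masks[[j]]
    dA[, cols[ok]] <- dA[, cols[ok]] + contrib[, ok, drop = FALSE]
  }
  dA
}

nn_bn_fwd <- function(A, gamma, beta, run_mean, run_var, train,
                      momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- rowMeans(A)
    v <- rowMeans(A * A) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (A - mu) * ivar
  list(Y = gamma * xhat + beta, xhat = xhat, ivar = ivar, mu = mu,
       train = train, run_mean = run_mean, run_var = run_var)
}

nn_bn_bwd <- function(dY, A, cache, gamma) {
  dxhat <- dY * gamma
  if (!cache$train) {
    # inference-mode statistics are constants
    return(list(dA = dxhat * cache$ivar, dgamma = rowSums(dY * cache$xhat),
                dbeta = rowSums(dY)))
  }
  M <- ncol(A)
  xc <- A - cache$mu
  dvar <- rowSums(dxhat * xc) * (-0.5) * cache$ivar^3
  dmu <- -rowSums(dxhat) * cache$ivar + dvar * rowMeans(-2 * xc)
  dA <- dxhat * cache$ivar + dvar * (2 * xc / M) + dmu / M
  list(dA = dA, dgamma = rowSums(dY * cache$xhat), dbeta = rowSums(dY))
}

nn_relu <- function(A) {
  m <- A > 0
  A[!m] <- 0
  list(Y = A, mask = m)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

nn_se_fwd <- function(A, W1, b1, W2, b2, Msum, L, gidx) {
  s <- (A %*% Msum) / L
  h <- W1 %*% s + b1
  hm <- h > 0
  hr <- h * hm
  g <- sigmoid(W2 %*% hr + b2)
  Gex <- g[, gidx, drop = FALSE]
  list(Y = A * Gex, s = s, hm = hm, hr = hr, g = g, Gex = Gex)
}

nn_se_bwd <- function(dY, A, cache, W1, W2, Msum, L, gidx) {
  dg <- (dY * A) %*% Msum
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(dz2, cache$hr)
  db2 <- rowSums(dz2)
  dh <- crossprod(W2, dz2) * cache$hm
  dW1 <- tcrossprod(dh, cache$s)
  db1 <- rowSums(dh)
  ds <- crossprod(W1, dh) / L
  dA <- dY * cache$Gex + ds[, gidx, drop = FALSE]
  list(dA = dA, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}
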