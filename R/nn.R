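# Minimal neural-network engine: dense / 1D-conv / batch-norm layers with
# analytic backpropagation, plus Adam and RMSprop optimizers. Written in
# base R matrix operations; gradients are verified against finite
# differences in the test suite. Only what the detector architecture needs
# is implemented.

relu  <- function(x) pmax(x, 0)
drelu <- function(x) (x > 0) * 1

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

nn_dense_init <- function(n_in, n_out) {
  list(W = glorot_uniform(n_in, n_out), b = numeric(n_out))
}

nn_bn_init <- function(n_feat) {
  list(gamma = rep(1, n_feat), beta = numeric(n_feat),
       mmean = numeric(n_feat), mvar = rep(1, n_feat))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# Batch norm over a matrix with features in columns. Training mode uses
# batch statistics (population variance) and returns an updated moving
# average; inference mode uses the stored moving statistics.
bn_forward <- function(X, bn, training) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    v <- pmax(v, 0)
  } else {
    mu <- bn$mmean
    v <- bn$mvar
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(X, 2, mu, "-"), 2, inv, "*")
  Y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(Y = Y, xhat = xhat, inv = inv, mu = mu, v = v)
}

bn_backward <- function(dY, cache, gamma) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(
    dxhat - sweep(cache$xhat, 2, s2 / m, "*") -
      matrix(s1 / m, nrow = m, ncol = ncol(dY), byrow = TRUE),
    2, cache$inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_update_moving <- function(bn, cache) {
  bn$mmean <- BN_MOMENTUM * bn$mmean + (1 - BN_MOMENTUM) * cache$mu
  bn$mvar  <- BN_MOMENTUM * bn$mvar  + (1 - BN_MOMENTUM) * cache$v
  bn
}

# ---- optimizers ------------------------------------------------------------

# Both optimizers operate on a flat named list of numeric arrays.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

rmsprop_init <- function(params) {
  list(cache = lapply(params, function(p) p * 0))
}

rmsprop_step <- function(params, grads, st, lr = 1e-3,
                         rho = 0.9, eps = 1e-7) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$cache[[nm]] <- rho * st$cache[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(st$cache[[nm]]) + eps)
  }
  list(params = params, state = st)
}

# ---- autoencoder forward/backward -----------------------------------------

# params: W1,b1 (L_s->u1), W2,b2 (u1->u2), W3,b3 (u2->u3), W4,b4 (u3->L_s)
ae_forward <- function(p, X) {
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+"); A1 <- relu(Z1)
  Z2 <- sweep(A1 %*% p$W2, 2, p$b2, "+"); A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% p$W3, 2, p$b3, "+"); A3 <- relu(Z3)
  Y  <- sweep(A3 %*% p$W4, 2, p$b4, "+")
  list(Y = Y, X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3)
}

ae_backward <- function(p, cache) {
  m <- nrow(cache$X); d <- ncol(cache$X)
  dY <- 2 * (cache$Y - cache$X) / (m * d)      # d(MSE)/dY
  g <- list()
  g$W4 <- t(cache$A3) %*% dY; g$b4 <- colSums(dY)
  dA3 <- dY %*% t(p$W4) * drelu(cache$Z3)
  g$W3 <- t(cache$A2) %*% dA3; g$b3 <- colSums(dA3)
  dA2 <- dA3 %*% t(p$W3) * drelu(cache$Z2)
  g$W2 <- t(cache$A1) %*% dA2; g$b2 <- colSums(dA2)
  dA1 <- dA2 %*% t(p$W2) * drelu(cache$Z1)
  g$W1 <- t(cache$X) %*% dA1; g$b1 <- colSums(dA1)
  g
}

# ---- classifier head forward/backward -------------------------------------

# Geometry helpers for the non-overlapping 1D convolution (stride == kernel):
# step s consumes time samples (s-1)*k+1 .. s*k across all C channels,
# flattened time-fastest into a (k*C)-vector.
conv_steps <- function(L_s, kernel, stride) {
  as.integer(floor((L_s - kernel) / stride) + 1L)
}

# X3: batch x L_s x C array. Returns per-step design matrices stacked.
conv_blocks <- function(X3, kernel, steps) {
  b <- dim(X3)[1]; C <- dim(X3)[3]
  lapply(seq_len(steps), function(s) {
    blk <- X3[, ((s - 1L) * kernel + 1L):(s * kernel), , drop = FALSE]
    dim(blk) <- c(b, kernel * C)
    blk
  })
}

# Classifier parameters as a flat list: bn1.gamma, bn1.beta, conv.W, conv.b,
# bn2.gamma, bn2.beta, d1.W, d1.b, d2.W, d2.b, d3.W, d3.b.
clf_init <- function(cfg) {
  kC <- cfg$conv_kernel * cfg$channels
  Fl <- cfg$conv_steps * cfg$conv_filters
  u <- cfg$dense_units
  list(
    params = list(
      bn1.gamma = rep(1, cfg$channels), bn1.beta = numeric(cfg$channels),
      conv.W = glorot_uniform(kC, cfg$conv_filters),
      conv.b = numeric(cfg$conv_filters),
      bn2.gamma = rep(1, Fl), bn2.beta = numeric(Fl),
      d1.W = glorot_uniform(Fl, u[1]), d1.b = numeric(u[1]),
      d2.W = glorot_uniform(u[1], u[2]), d2.b = numeric(u[2]),
      d3.W = glorot_uniform(u[2], u[3]), d3.b = numeric(u[3])
    ),
    moving = list(
      bn1.mean = numeric(cfg$channels), bn1.var = rep(1, cfg$channels),
      bn2.mean = numeric(Fl), bn2.var = rep(1, Fl)
    )
  )
}

# Forward pass. X3: batch x L_s x C. Returns probability vector and, when
# `training`, the caches needed for backprop (dropout masks are sampled
# from the current RNG stream).
clf_forward <- function(clf, X3, cfg, training = FALSE) {
  b <- dim(X3)[1]; L <- dim(X3)[2]; C <- dim(X3)[3]
  k <- cfg$conv_kernel; S <- cfg$conv_steps; Fn <- cfg$conv_filters
  p <- clf$params

  # BN over channels: columns = channels, rows = batch x time.
  Xm <- X3; dim(Xm) <- c(b * L, C)
  bn1 <- list(gamma = p$bn1.gamma, beta = p$bn1.beta,
              mmean = clf$moving$bn1.mean, mvar = clf$moving$bn1.var)
  c1 <- bn_forward(Xm, bn1, training)
  Y3 <- c1$Y; dim(Y3) <- c(b, L, C)

  # Non-overlapping conv + ReLU, flattened step-major.
  blocks <- conv_blocks(Y3, k, S)
  Zc <- matrix(0, nrow = b, ncol = S * Fn)
  for (s in seq_len(S))
    Zc[, ((s - 1L) * Fn + 1L):(s * Fn)] <-
      sweep(blocks[[s]] %*% p$conv.W, 2, p$conv.b, "+")
  Ac <- relu(Zc)

  bn2 <- list(gamma = p$bn2.gamma, beta = p$bn2.beta,
              mmean = clf$moving$bn2.mean, mvar = clf$moving$bn2.var)
  c2 <- bn_forward(Ac, bn2, training)

  Z1 <- sweep(c2$Y %*% p$d1.W, 2, p$d1.b, "+"); A1 <- relu(Z1)
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    m1 <- matrix(stats::runif(length(A1)) < keep, nrow = b) / keep
    A1d <- A1 * m1
  } else { m1 <- NULL; A1d <- A1 }

  Z2 <- sweep(A1d %*% p$d2.W, 2, p$d2.b, "+"); A2 <- relu(Z2)
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    m2 <- matrix(stats::runif(length(A2)) < keep, nrow = b) / keep
    A2d <- A2 * m2
  } else { m2 <- NULL; A2d <- A2 }

  Z3 <- sweep(A2d %*% p$d3.W, 2, p$d3.b, "+")
  prob <- as.numeric(sigmoid(Z3))

  list(prob = prob,
       cache = if (training) list(
         blocks = blocks, c1 = c1, c2 = c2, Zc = Zc, Ac = Ac,
         Z1 = Z1, A1 = A1, A1d = A1d, m1 = m1,
         Z2 = Z2, A2 = A2, A2d = A2d, m2 = m2,
         Z3 = Z3, b = b, L = L, C = C) else NULL)
}

# Backprop of mean binary cross-entropy. Returns gradients named like params.
clf_backward <- function(clf, cfg, cache, y) {
  p <- clf$params
  b <- cache$b; L <- cache$L; C <- cache$C
  k <- cfg$conv_kernel; S <- cfg$conv_steps; Fn <- cfg$conv_filters
  g <- list()

  prob <- sigmoid(cache$Z3)
  dZ3 <- (prob - matrix(y, ncol = 1)) / b       # BCE + sigmoid shortcut
  g$d3.W <- t(cache$A2d) %*% dZ3; g$d3.b <- colSums(dZ3)

  dA2d <- dZ3 %*% t(p$d3.W)
  if (!is.null(cache$m2)) dA2d <- dA2d * cache$m2
  dZ2 <- dA2d * drelu(cache$Z2)
  g$d2.W <- t(cache$A1d) %*% dZ2; g$d2.b <- colSums(dZ2)

  dA1d <- dZ2 %*% t(p$d2.W)
  if (!is.null(cache$m1)) dA1d <- dA1d * cache$m1
  dZ1 <- dA1d * drelu(cache$Z1)
  g$d1.W <- t(cache$c2$Y) %*% dZ1; g$d1.b <- colSums(dZ1)

  dBn2Y <- dZ1 %*% t(p$d1.W)
  bb2 <- bn_backward(dBn2Y, cache$c2, p$bn2.gamma)
  g$bn2.gamma <- bb2$dgamma; g$bn2.beta <- bb2$dbeta

  dZc <- bb2$dX * drelu(cache$Zc)
  g$conv.W <- matrix(0, nrow = k * C, ncol = Fn)
  g$conv.b <- numeric(Fn)
  dY3 <- array(0, dim = c(b, L, C))
  for (s in seq_len(S)) {
    dZs <- dZc[, ((s - 1L) * Fn + 1L):(s * Fn), drop = FALSE]
    g$conv.W <- g$conv.W + t(cache$blocks[[s]]) %*% dZs
    g$conv.b <- g$conv.b + colSums(dZs)
    dblk <- dZs %*% t(p$conv.W)
    dim(dblk) <- c(b, k, C)
    dY3[, ((s - 1L) * k + 1L):(s * k), ] <- dblk
  }

  dYm <- dY3; dim(dYm) <- c(b * L, C)
  bb1 <- bn_backward(dYm, cache$c1, p$bn1.gamma)
  g$bn1.gamma <- bb1$dgamma; g$bn1.beta <- bb1$dbeta

  g[names(p)]
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
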