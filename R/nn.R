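# Minimal neural-network engine: 1-D convolution (per-lead, "same"
# zero-padding, strided), batch normalization, ReLU, inverted dropout,
# max-pooling, dense layers, softmax cross-entropy and the Adam optimizer,
# with hand-derived backward passes. Activations are (batch, channels,
# length) arrays; morphology leads are folded into the batch dimension so
# convolution weights are shared across leads and no cross-lead mixing
# occurs before flattening.

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- conv1d ---------------------------------------------------------------

# X: (B, C, L); W: (F, C, k); b: length F; output (B, F, ceiling(L/stride)).
.conv1d_fwd <- function(X, W, b, stride) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; L <- d[3L]
  Fn <- dim(W)[1L]; k <- dim(W)[3L]
  L_out <- as.integer(ceiling(L / stride))
  pad_total <- max((L_out - 1L) * stride + k - L, 0L)
  pl <- pad_total %/% 2L
  Lp <- L + pad_total
  Xp <- array(0, c(B, C, Lp))
  Xp[, , pl + seq_len(L)] <- X
  idx <- outer(seq_len(k), (seq_len(L_out) - 1L) * stride, "+")  # (k, L_out)
  XpM <- Xp
  dim(XpM) <- c(B * C, Lp)
  A <- XpM[, as.vector(idx), drop = FALSE]
  dim(A) <- c(B, C, k, L_out)
  A <- aperm(A, c(1L, 4L, 2L, 3L))
  dim(A) <- c(B * L_out, C * k)
  Wm <- W
  dim(Wm) <- c(Fn, C * k)
  Y <- A %*% t(Wm)
  Y <- sweep(Y, 2L, b, "+")
  dim(Y) <- c(B, L_out, Fn)
  Y <- aperm(Y, c(1L, 3L, 2L))
  list(Y = Y, cache = list(A = A, idx = idx, B = B, C = C, L = L,
                           Lp = Lp, pl = pl, L_out = L_out, k = k,
                           Fn = Fn, stride = stride))
}

.conv1d_bwd <- function(dY, W, cache) {
  B <- cache$B; C <- cache$C; L <- cache$L
  L_out <- cache$L_out; k <- cache$k; Fn <- cache$Fn
  dYm <- aperm(dY, c(1L, 3L, 2L))
  dim(dYm) <- c(B * L_out, Fn)
  dW <- t(dYm) %*% cache$A
  dim(dW) <- c(Fn, C, k)
  db <- colSums(dYm)
  Wm <- W
  dim(Wm) <- c(Fn, C * k)
  dA <- dYm %*% Wm
  dim(dA) <- c(B, L_out, C, k)
  dA <- aperm(dA, c(1L, 3L, 4L, 2L))
  dim(dA) <- c(B * C, k * L_out)
  iv <- as.vector(cache$idx)
  acc <- rowsum(t(dA), group = iv)           # (n_unique_pos, B*C), sorted
  full <- matrix(0, B * C, cache$Lp)
  full[, as.integer(rownames(acc))] <- t(acc)
  dim(full) <- c(B, C, cache$Lp)
  dX <- full[, , cache$pl + seq_len(L), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalization --------------------------------------------------

.bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9,
                    eps = 1e-5) {
  d <- dim(X)
  if (training) {
    mu <- apply(X, 2L, mean)
    v <- apply(X, 2L, function(z) mean((z - mean(z))^2))
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    training = training))
}

.bn_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- apply(dY * xhat, 2L, sum)
  dbeta <- apply(dY, 2L, sum)
  if (cache$training) {
    mdy <- apply(dY, 2L, mean)
    mdyx <- apply(dY * xhat, 2L, mean)
    t1 <- sweep(dY, 2L, mdy, "-")
    t2 <- sweep(xhat, 2L, mdyx, "*")
    dX <- sweep(t1 - t2, 2L, cache$gamma * cache$inv_sd, "*")
  } else {
    dX <- sweep(dY, 2L, cache$gamma * cache$inv_sd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- relu / dropout / maxpool ---------------------------------------------

.relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

.dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- array(stats::runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(Y = X * mask, cache = mask)
}

.maxpool_fwd <- function(X, factor) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; L <- d[3L]
  L_out <- as.integer(ceiling(L / factor))
  Lp <- L_out * factor
  Xp <- array(-Inf, c(B, C, Lp))
  Xp[, , seq_len(L)] <- X
  dim(Xp) <- c(B, C, factor, L_out)
  Y <- Xp[, , 1L, , drop = FALSE]
  arg <- array(1L, c(B, C, 1L, L_out))
  for (j in seq_len(factor)[-1L]) {
    cand <- Xp[, , j, , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    arg[upd] <- j
  }
  dim(Y) <- c(B, C, L_out)
  dim(arg) <- c(B, C, L_out)
  list(Y = Y, cache = list(arg = arg, factor = factor, L = L,
                           L_out = L_out, B = B, C = C))
}

.maxpool_bwd <- function(dY, cache) {
  B <- cache$B; C <- cache$C
  Lp <- cache$L_out * cache$factor
  dXp <- array(0, c(B, C, cache$factor, cache$L_out))
  # linear indices of the argmax positions
  bi <- rep(seq_len(B), times = C * cache$L_out)
  ci <- rep(rep(seq_len(C), each = B), times = cache$L_out)
  ti <- rep(seq_len(cache$L_out), each = B * C)
  ji <- as.vector(cache$arg)
  lin <- bi + (ci - 1L) * B + (ji - 1L) * B * C +
    (ti - 1L) * B * C * cache$factor
  dXp[lin] <- as.vector(dY)
  dim(dXp) <- c(B, C, Lp)
  dXp[, , seq_len(cache$L), drop = FALSE]
}

# ---- dense / softmax ------------------------------------------------------

.dense_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, cache = X)
}

.dense_bwd <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = t(cache) %*% dY, db = colSums(dY))
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam -----------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, opt, lr, trainable,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    if (!trainable[[nm]]) next
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
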