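# Minimal neural-network primitives (forward + manual backward) on BLAS
# matrix ops. Sequences are (positions x channels) matrices throughout.

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

softplus_grad <- function(x) 1 / (1 + exp(-x))

# --- im2col-style 1D convolution -------------------------------------------
# X: (T x C_in); W: (C_in * k x C_out), columns of a patch ordered by offset
# (offset-major: rows 1..C_in are offset 1, etc.); stride s, zero pad p.

nn_im2col <- function(X, k, stride, pad, dilation = 1L) {
  T_in <- nrow(X); C <- ncol(X)
  span <- (k - 1L) * dilation + 1L
  T_out <- (T_in + 2L * pad - span) %/% stride + 1L
  P <- matrix(0, T_out, C * k)
  t0 <- (seq_len(T_out) - 1L) * stride - pad  # 0-based start of each patch
  for (j in seq_len(k)) {
    rows <- t0 + (j - 1L) * dilation + 1L  # 1-based source row for offset j
    ok <- rows >= 1L & rows <= T_in
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (any(ok)) P[which(ok), cols] <- X[rows[ok], , drop = FALSE]
  }
  P
}

nn_conv_forward <- function(X, layer, W_eff = NULL) {
  W <- if (is.null(W_eff)) conv_weight(layer) else W_eff
  P <- nn_im2col(X, layer$k, layer$stride, layer$pad,
                 if (is.null(layer$dilation)) 1L else layer$dilation)
  Y <- P %*% W
  Y <- sweep(Y, 2L, layer$b, `+`)
  list(Y = Y, cache = list(P = P, dims = dim(X), W = W))
}

nn_conv_backward <- function(dY, layer, cache) {
  P <- cache$P
  dW <- crossprod(P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(cache$W)
  T_in <- cache$dims[1L]; C <- cache$dims[2L]
  dX <- matrix(0, T_in, C)
  dil <- if (is.null(layer$dilation)) 1L else layer$dilation
  t0 <- (seq_len(nrow(dY)) - 1L) * layer$stride - layer$pad
  for (j in seq_len(layer$k)) {
    rows <- t0 + (j - 1L) * dil + 1L
    ok <- rows >= 1L & rows <= T_in
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (any(ok))
      dX[rows[ok], ] <- dX[rows[ok], , drop = FALSE] + dP[which(ok), cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# Effective convolution weight including a LoRA term, if injected.
conv_weight <- function(layer) {
  if (is.null(layer$lora)) return(layer$W)
  layer$W + (layer$lora$alpha / layer$lora$rank) * (layer$lora$A %*% layer$lora$B)
}

# Map the gradient of the effective weight onto the low-rank factors.
lora_factor_grads <- function(layer, dW_eff) {
  s <- layer$lora$alpha / layer$lora$rank
  list(dA = s * (dW_eff %*% t(layer$lora$B)),
       dB = s * (t(layer$lora$A) %*% dW_eff))
}

# --- dense layer ------------------------------------------------------------

nn_dense_forward <- function(X, layer, W_eff = NULL) {
  W <- if (is.null(W_eff)) conv_weight(layer) else W_eff
  Y <- sweep(X %*% W, 2L, layer$b, `+`)
  list(Y = Y, cache = list(X = X, W = W))
}

nn_dense_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# --- batch normalization over positions (per channel) -----------------------

nn_bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C), eps = 1e-5, momentum = 0.1)
}

nn_bn_forward <- function(X, bn, training, update_stats = training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    xc <- sweep(X, 2L, mu)
  }
  istd <- 1 / sqrt(v + bn$eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  Y <- sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  new_stats <- NULL
  if (update_stats) {
    new_stats <- list(
      run_mean = (1 - bn$momentum) * bn$run_mean + bn$momentum * mu,
      run_var = (1 - bn$momentum) * bn$run_var + bn$momentum * v)
  }
  list(Y = Y, cache = list(xhat = xhat, istd = istd, gamma = bn$gamma,
                           training = training, n = nrow(X)),
       new_stats = new_stats)
}

nn_bn_backward <- function(dY, cache) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, `*`)
  if (cache$training) {
    n <- cache$n
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
    dX <- sweep(t1 - t2, 2L, cache$istd, `*`)
  } else {
    dX <- sweep(dxhat, 2L, cache$istd, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- single-head self-attention --------------------------------------------

nn_attn_forward <- function(X, att) {
  Wq <- if (is.null(att$lora_q)) att$Wq else
    att$Wq + (att$lora_q$alpha / att$lora_q$rank) * (att$lora_q$A %*% att$lora_q$B)
  Wv <- if (is.null(att$lora_v)) att$Wv else
    att$Wv + (att$lora_v$alpha / att$lora_v$rank) * (att$lora_v$A %*% att$lora_v$B)
  Q <- X %*% Wq; K <- X %*% att$Wk; V <- X %*% Wv
  sc <- 1 / sqrt(ncol(Q))
  S <- tcrossprod(Q, K) * sc
  S <- S - apply(S, 1L, max)  # rowwise max for stable softmax
  A <- exp(S)
  A <- A / rowSums(A)
  O <- A %*% V
  Y <- O %*% att$Wo
  list(Y = Y, cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                           sc = sc, Wq = Wq, Wv = Wv))
}

nn_attn_backward <- function(dY, att, cache) {
  dWo <- crossprod(cache$O, dY)
  dO <- dY %*% t(att$Wo)
  dA <- dO %*% t(cache$V)
  dV <- crossprod(cache$A, dO)
  # softmax backward, rowwise
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- (dS %*% cache$K) * cache$sc
  dK <- (crossprod(dS, cache$Q)) * cache$sc
  dWq <- crossprod(cache$X, dQ)
  dWk <- crossprod(cache$X, dK)
  dWv <- crossprod(cache$X, dV)
  dX <- dQ %*% t(cache$Wq) + dK %*% t(att$Wk) + dV %*% t(cache$Wv)
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# --- AdamW optimizer --------------------------------------------------------
# Decoupled weight decay; params and grads are flat named lists of arrays.

adamw_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-6) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

adamw_step <- function(state, params, grads, lr_by_param) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr <- lr_by_param[[nm]]
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + state$eps) +
                                           state$weight_decay * params[[nm]])
  }
  list(state = state, params = params)
}

# Global gradient-norm clipping; returns scaled grads.
clip_grad_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  attr(grads, "norm") <- total
  grads
}

# Accumulate one flat grad list into another.
acc_grads <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
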