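# Minimal neural-network machinery for the CVAE: strided 1-D convolutions
# (non-overlapping patches), dense layers, ReLU, diagonal-Gaussian and
# Gaussian-mixture density heads, all with hand-derived reverse-mode
# gradients (finite-difference checked in the test suite), plus Adam.
#
# Batched throughout: activations are B x features matrices; multi-channel
# sequences are stored channel-fastest (column = (position-1)*C + channel).

# ---- reshape helpers for patch (stride = kernel) convolutions --------------

# X: B x (L*C) -> (Lout*B) x (k*C), row = (b-1)*Lout + p
nn_patchify <- function(X, kC) {
  t(matrix(t(X), nrow = kC))
}

nn_unpatchify_grad <- function(P, LC) { # inverse of nn_patchify
  t(matrix(t(P), nrow = LC))
}

# Y: (Lout*B) x cout -> B x (Lout*cout) channel-fastest
nn_stack <- function(Y, Lout) {
  B <- nrow(Y) / Lout
  t(matrix(t(Y), ncol = B))
}

nn_unstack_grad <- function(dA, Lout, cout) { # inverse of nn_stack
  t(matrix(t(dA), nrow = cout))
}

# ---- layers ----------------------------------------------------------------

nn_conv_fwd <- function(X, W, b, k, Cin) {
  kC <- k * Cin
  P <- nn_patchify(X, kC)            # (Lout*B) x kC
  Z <- P %*% W                        # (Lout*B) x cout
  Z <- sweep(Z, 2, b, "+")
  A <- pmax(Z, 0)
  Lout <- ncol(X) / kC
  list(out = nn_stack(A, Lout), P = P, Z = Z, Lout = Lout)
}

nn_conv_bwd <- function(cache, dOut, W, k, Cin) {
  cout <- ncol(W)
  dA <- nn_unstack_grad(dOut, cache$Lout, cout)   # (Lout*B) x cout
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- dZ %*% t(W)
  dX <- nn_unpatchify_grad(dP, ncol(cache$P) * cache$Lout)
  list(dX = dX, dW = dW, db = db)
}

nn_dense_fwd <- function(X, W, b, relu = TRUE) {
  Z <- sweep(X %*% W, 2, b, "+")
  list(out = if (relu) pmax(Z, 0) else Z, X = X, Z = Z, relu = relu)
}

nn_dense_bwd <- function(cache, dOut, W) {
  dZ <- if (cache$relu) dOut * (cache$Z > 0) else dOut
  list(dX = dZ %*% t(W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

# ---- density heads ---------------------------------------------------------

# diagonal Gaussian log density, batched: x, mu, lv are B x d
nn_gauss_logp <- function(x, mu, lv) {
  -0.5 * rowSums(log(2 * pi) + lv + (x - mu)^2 * exp(-lv))
}

# parse a GMM head output (B x (2*m*d + m)) into per-component mats
nn_gmm_parse <- function(H, m, d) {
  list(mu = lapply(seq_len(m), function(k) H[, ((k - 1) * d + 1):(k * d), drop = FALSE]),
       lv = lapply(seq_len(m), function(k) H[, m * d + ((k - 1) * d + 1):(k * d), drop = FALSE]),
       w = H[, (2 * m * d + 1):(2 * m * d + m), drop = FALSE])
}

nn_logsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# GMM log density at x (B x d); returns logp plus responsibilities and
# component log densities needed for gradients
nn_gmm_logp <- function(x, gmm) {
  m <- length(gmm$mu)
  logw <- gmm$w - nn_logsumexp(gmm$w)                 # log softmax
  comp <- vapply(seq_len(m), function(k)
    nn_gauss_logp(x, gmm$mu[[k]], gmm$lv[[k]]), numeric(nrow(x)))
  comp <- matrix(comp, nrow = nrow(x))
  a <- comp + logw
  logp <- nn_logsumexp(a)
  gamma <- exp(a - logp)
  list(logp = logp, gamma = gamma, logw = logw)
}

# gradient of sum(coef * logp) wrt head output H and wrt x
nn_gmm_grad <- function(x, gmm, info, coef = 1) {
  m <- length(gmm$mu); d <- ncol(x); B <- nrow(x)
  dH <- matrix(0, B, 2 * m * d + m)
  dx <- matrix(0, B, d)
  g <- info$gamma * coef
  for (k in seq_len(m)) {
    v <- exp(-gmm$lv[[k]])
    diff <- x - gmm$mu[[k]]
    dH[, ((k - 1) * d + 1):(k * d)] <- g[, k] * diff * v
    dH[, m * d + ((k - 1) * d + 1):(k * d)] <- g[, k] * 0.5 * (diff^2 * v - 1)
    dx <- dx - g[, k] * diff * v
  }
  sw <- exp(info$logw)  # softmax weights
  dH[, (2 * m * d + 1):(2 * m * d + m)] <- g - rowSums(g) * sw
  list(dH = dH, dx = dx)
}

# ---- parameter init and Adam ----------------------------------------------

nn_init_mat <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(rnorm(nin * nout, sd = scale), nin, nout)
}

nn_adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

nn_adam_init <- function(par) {
  list(t = 0,
       m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}
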