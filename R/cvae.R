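#' CVAE hyperparameters
#'
#' Architecture and optimisation settings for the conditional variational
#' autoencoder. The three sub-networks (recognition encoder Q1, conditional
#' prior encoder R1, decoder R2) share a strided 1-D convolutional feature
#' extractor; each head is a two-layer perceptron emitting the parameters of
#' a diagonal Gaussian (Q1) or Gaussian mixture (R1 over the latent space,
#' R2 over the factor space).
#'
#' @param nz latent dimension.
#' @param m mixture components (R1 and R2).
#' @param conv list of `c(kernel, channels)` per strided conv layer; kernels
#'   must tile the trace length exactly.
#' @param feat_width,head_width widths of the shared feature layer and head
#'   hidden layers.
#' @param batch_size,lr minibatch size and Adam learning rate.
#' @param epochs_flat,epochs_ramp KL annealing schedule: the KL weight alpha
#'   is 0 for the first `epochs_flat` epochs, rises linearly to 1 over the
#'   next `epochs_ramp`, then stays at 1.
#' @param max_epochs,patience epoch cap and early-stopping patience on the
#'   validation loss (counted only once annealing is complete).
#' @param seed RNG seed for initialization, shuffling and sampling.
#' @export
cvae_config <- function(nz = 8L, m = 16L,
                        conv = list(c(8L, 16L), c(5L, 32L), c(5L, 32L)),
                        feat_width = 64L, head_width = 64L,
                        batch_size = 128L, lr = 3e-4,
                        epochs_flat = 30L, epochs_ramp = 60L,
                        max_epochs = 150L, patience = 20L, seed = 1L) {
  stopifnot(nz >= 1, m >= 1, feat_width >= 1, head_width >= 1,
            batch_size >= 1, lr > 0, epochs_flat >= 0, epochs_ramp >= 1,
            max_epochs >= 1)
  structure(list(nz = as.integer(nz), m = as.integer(m), conv = conv,
                 feat_width = as.integer(feat_width),
                 head_width = as.integer(head_width),
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs_flat = as.integer(epochs_flat),
                 epochs_ramp = as.integer(epochs_ramp),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cvae_config")
}

#' KL annealing weight
#'
#' `alpha(epoch)` is 0 during the flat phase, rises linearly to 1 across the
#' ramp phase, and is 1 afterwards (epochs are 0-based). Annealing prevents
#' the optimiser from pinning the KL term at its minimum of zero before the
#' reconstruction term is learned.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param flat,ramp schedule lengths in epochs (default 30 and 60).
#' @export
anneal_alpha <- function(epoch, flat = 30, ramp = 60) {
  pmin(1, pmax(0, (epoch - flat) / ramp))
}

# ---- architecture / parameter construction ---------------------------------

cvae_arch <- function(T_len, d, cfg) {
  L <- T_len; Cin <- 1L
  convs <- list()
  for (i in seq_along(cfg$conv)) {
    k <- cfg$conv[[i]][1]; cout <- cfg$conv[[i]][2]
    if (L %% k != 0)
      stop("cvae: conv kernel ", k, " does not tile sequence length ", L)
    convs[[i]] <- list(k = k, Cin = Cin, Cout = cout, Lin = L, Lout = L %/% k)
    L <- L %/% k; Cin <- cout
  }
  list(T_len = T_len, d = d, nz = cfg$nz, m = cfg$m, convs = convs,
       flat = L * Cin, fc = cfg$feat_width, hw = cfg$head_width)
}

cvae_init_params <- function(arch) {
  p <- list()
  for (i in seq_along(arch$convs)) {
    cv <- arch$convs[[i]]
    p[[paste0("conv", i, "_W")]] <- nn_init_mat(cv$k * cv$Cin, cv$Cout)
    p[[paste0("conv", i, "_b")]] <- numeric(cv$Cout)
  }
  p$feat_W <- nn_init_mat(arch$flat, arch$fc)
  p$feat_b <- numeric(arch$fc)
  p$q1_W1 <- nn_init_mat(arch$fc + arch$d, arch$hw)
  p$q1_b1 <- numeric(arch$hw)
  p$q1_W2 <- nn_init_mat(arch$hw, 2 * arch$nz, scale = 1e-2)
  p$q1_b2 <- c(numeric(arch$nz), rep(-2, arch$nz))
  p$r1_W1 <- nn_init_mat(arch$fc, arch$hw)
  p$r1_b1 <- numeric(arch$hw)
  p$r1_W2 <- nn_init_mat(arch$hw, 2 * arch$m * arch$nz + arch$m, scale = 1e-2)
  p$r1_b2 <- c(rnorm(arch$m * arch$nz, sd = 0.5), rep(-2, arch$m * arch$nz),
               numeric(arch$m))
  p$r2_W1 <- nn_init_mat(arch$fc + arch$nz, arch$hw)
  p$r2_b1 <- numeric(arch$hw)
  p$r2_W2 <- nn_init_mat(arch$hw, 2 * arch$m * arch$d + arch$m, scale = 1e-2)
  p$r2_b2 <- c(runif(arch$m * arch$d), rep(-2, arch$m * arch$d),
               numeric(arch$m))
  p
}

# shared convolutional feature extractor
cvae_shared_fwd <- function(par, arch, X) {
  caches <- list()
  A <- X
  for (i in seq_along(arch$convs)) {
    cv <- arch$convs[[i]]
    cc <- nn_conv_fwd(A, par[[paste0("conv", i, "_W")]],
                      par[[paste0("conv", i, "_b")]], cv$k, cv$Cin)
    caches[[i]] <- cc
    A <- cc$out
  }
  fc <- nn_dense_fwd(A, par$feat_W, par$feat_b, relu = TRUE)
  list(feat = fc$out, conv_caches = caches, feat_cache = fc)
}

cvae_shared_bwd <- function(par, arch, fwd, dFeat, grads) {
  g <- nn_dense_bwd(fwd$feat_cache, dFeat, par$feat_W)
  grads$feat_W <- grads$feat_W + g$dW
  grads$feat_b <- grads$feat_b + g$db
  dA <- g$dX
  for (i in rev(seq_along(arch$convs))) {
    cv <- arch$convs[[i]]
    gc <- nn_conv_bwd(fwd$conv_caches[[i]], dA,
                      par[[paste0("conv", i, "_W")]], cv$k, cv$Cin)
    grads[[paste0("conv", i, "_W")]] <- grads[[paste0("conv", i, "_W")]] + gc$dW
    grads[[paste0("conv", i, "_b")]] <- grads[[paste0("conv", i, "_b")]] + gc$db
    dA <- gc$dX
  }
  grads
}

cvae_head_fwd <- function(par, prefix, X) {
  h1 <- nn_dense_fwd(X, par[[paste0(prefix, "_W1")]],
                     par[[paste0(prefix, "_b1")]], relu = TRUE)
  h2 <- nn_dense_fwd(h1$out, par[[paste0(prefix, "_W2")]],
                     par[[paste0(prefix, "_b2")]], relu = FALSE)
  list(out = h2$out, h1 = h1, h2 = h2)
}

cvae_head_bwd <- function(par, prefix, fwd, dOut, grads) {
  g2 <- nn_dense_bwd(fwd$h2, dOut, par[[paste0(prefix, "_W2")]])
  grads[[paste0(prefix, "_W2")]] <- grads[[paste0(prefix, "_W2")]] + g2$dW
  grads[[paste0(prefix, "_b2")]] <- grads[[paste0(prefix, "_b2")]] + g2$db
  g1 <- nn_dense_bwd(fwd$h1, g2$dX, par[[paste0(prefix, "_W1")]])
  grads[[paste0(prefix, "_W1")]] <- grads[[paste0(prefix, "_W1")]] + g1$dW
  grads[[paste0(prefix, "_b1")]] <- grads[[paste0(prefix, "_b1")]] + g1$db
  list(grads = grads, dX = g1$dX)
}

# ---- loss and gradients ----------------------------------------------------

# One forward/backward pass of the annealed variational loss
#   mean over the batch of  -log R2(r | f, z) + alpha * [log Q1(z) - log R1(z)]
# with z drawn from Q1 by reparameterisation (z = mu + sigma * eps).
cvae_loss_grads <- function(par, arch, X, R, eps, alpha,
                            compute_grads = TRUE) {
  B <- nrow(X)
  sh <- cvae_shared_fwd(par, arch, X)
  feat <- sh$feat

  q1 <- cvae_head_fwd(par, "q1", cbind(feat, R))
  nz <- arch$nz
  muq <- q1$out[, 1:nz, drop = FALSE]
  lvq <- q1$out[, nz + 1:nz, drop = FALSE]
  lv_lo <- -12; lv_hi <- 12
  lv_mask <- (lvq > lv_lo) & (lvq < lv_hi)
  lvq <- pmin(pmax(lvq, lv_lo), lv_hi)
  sig <- exp(lvq / 2)
  z <- muq + sig * eps

  r1 <- cvae_head_fwd(par, "r1", feat)
  gmm1 <- nn_gmm_parse(r1$out, arch$m, nz)
  r2 <- cvae_head_fwd(par, "r2", cbind(feat, z))
  gmm2 <- nn_gmm_parse(r2$out, arch$m, arch$d)

  info2 <- nn_gmm_logp(R, gmm2)
  logq <- nn_gauss_logp(z, muq, lvq)
  info1 <- nn_gmm_logp(z, gmm1)
  L <- info2$logp
  kl <- logq - info1$logp
  loss <- mean(-L + alpha * kl)
  out <- list(loss = loss, L = mean(L), kl = mean(kl))
  if (!compute_grads) return(out)

  grads <- lapply(par, function(pp) pp * 0)

  # decoder R2: d/dparams of mean(-logp2)
  g2 <- nn_gmm_grad(R, gmm2, info2, coef = -1 / B)
  hb <- cvae_head_bwd(par, "r2", r2, g2$dH, grads)
  grads <- hb$grads
  dfeat <- hb$dX[, 1:arch$fc, drop = FALSE]
  dz <- hb$dX[, arch$fc + 1:nz, drop = FALSE]

  # prior head R1: d/dparams of mean(-alpha * logp1(z)), plus dz
  g1 <- nn_gmm_grad(z, gmm1, info1, coef = -alpha / B)
  hb <- cvae_head_bwd(par, "r1", r1, g1$dH, grads)
  grads <- hb$grads
  dfeat <- dfeat + hb$dX
  dz <- dz + g1$dx

  # recognition term: + (alpha/B) * logq(z; muq, lvq), direct and through z
  inv_sig <- exp(-lvq / 2)
  dz <- dz - (alpha / B) * eps * inv_sig               # d logq / dz
  dmu <- dz + (alpha / B) * eps * inv_sig               # via z + direct
  dlv <- dz * (0.5 * sig * eps) + (alpha / B) * 0.5 * (eps^2 - 1)
  dlv <- dlv * lv_mask
  hb <- cvae_head_bwd(par, "q1", q1, cbind(dmu, dlv), grads)
  grads <- hb$grads
  dfeat <- dfeat + hb$dX[, 1:arch$fc, drop = FALSE]

  grads <- cvae_shared_bwd(par, arch, sh, dfeat, grads)
  out$grads <- grads
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit the conditional variational autoencoder
#'
#' Trains the amortized posterior estimator on a standardized, split twitch
#' corpus by minimising the annealed variational objective `-L + alpha * KL`
#' with Adam: `L` is the log-density of the decoder mixture at the true rate
#' factors and `KL` is a single-sample Monte-Carlo estimate of the divergence
#' between the recognition Gaussian Q1 and the conditional prior mixture R1,
#' evaluated at the reparameterised draw. The KL weight follows the annealing
#' schedule of [anneal_alpha()]. Training is seed-reproducible; after the
#' annealing horizon it stops early when the validation loss has not improved
#' for `patience` epochs.
#'
#' @param dataset a `twitch_dataset`, split and standardized (a raw corpus is
#'   split 1% / standardized automatically).
#' @param config a [cvae_config()].
#' @param verbose print per-epoch losses.
#' @return an object of class `cvae` with elements `params`, `arch`,
#'   `history` (per-epoch train/validation losses and alpha), the dataset's
#'   standardization `stats`, prior `log_bounds`, varied factor names, and
#'   the optimiser/RNG state needed by [cvae_resume()].
#' @seealso [predict.cvae()] for posterior sampling, [pp_curve()] for
#'   calibration.
#' @export
cvae <- function(dataset, config = cvae_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "twitch_dataset"))
  if (is.null(dataset$split)) dataset <- split_dataset(dataset, 0.01,
                                                       seed = config$seed)
  if (!dataset$standardized) dataset <- standardize_dataset(dataset)

  vary <- dataset$vary
  d <- length(vary)
  arch <- cvae_arch(ncol(dataset$traces), d, config)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  par <- cvae_init_params(arch)
  adam <- nn_adam_init(par)

  model <- structure(list(params = par, arch = arch, config = config,
                          stats = dataset$stats,
                          log_bounds = dataset$log_bounds[, vary, drop = FALSE],
                          vary = vary, time = dataset$time,
                          history = data.frame(),
                          adam = adam, epochs_done = 0L,
                          rng_state = get(".Random.seed", globalenv())),
                     class = "cvae")
  cvae_train_epochs(model, dataset, config$max_epochs, verbose)
}

#' Resume CVAE training from a checkpoint
#'
#' Continues training a fitted [cvae()] for additional epochs with the stored
#' optimiser and RNG state; an interrupted-and-resumed run reproduces the
#' uninterrupted loss trajectory exactly.
#'
#' @param model a fitted `cvae`.
#' @param dataset the same corpus it was trained on.
#' @param extra_epochs additional epoch budget.
#' @param verbose print per-epoch losses.
#' @export
cvae_resume <- function(model, dataset, extra_epochs, verbose = FALSE) {
  stopifnot(inherits(model, "cvae"))
  if (is.null(dataset$split)) dataset <- split_dataset(dataset, 0.01,
                                                       seed = model$config$seed)
  if (!dataset$standardized) dataset <- standardize_dataset(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  cvae_train_epochs(model, dataset, model$epochs_done + extra_epochs, verbose)
}

cvae_train_epochs <- function(model, dataset, until_epoch, verbose) {
  cfg <- model$config
  assign(".Random.seed", model$rng_state, envir = globalenv())
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "validation")
  Xtr <- dataset$traces[tr_idx, , drop = FALSE]
  Rtr <- dataset$factors_unit[tr_idx, model$vary, drop = FALSE]
  Xva <- dataset$traces[va_idx, , drop = FALSE]
  Rva <- dataset$factors_unit[va_idx, model$vary, drop = FALSE]
  par <- model$params
  adam <- model$adam
  hist <- model$history
  prev <- if (nrow(hist)) hist$val_loss[hist$alpha >= 1] else numeric()
  best <- if (length(prev)) min(prev, na.rm = TRUE) else Inf
  wait <- 0L
  best_par <- model$best_params
  best_adam <- model$best_adam

  e <- model$epochs_done
  while (e < until_epoch) {
    alpha <- anneal_alpha(e, cfg$epochs_flat, cfg$epochs_ramp)
    ord <- sample(nrow(Xtr))
    tr_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      eps <- matrix(rnorm(length(idx) * model$arch$nz), length(idx))
      res <- cvae_loss_grads(par, model$arch, Xtr[idx, , drop = FALSE],
                             Rtr[idx, , drop = FALSE], eps, alpha)
      if (!is.finite(res$loss))
        stop("cvae: non-finite training loss at epoch ", e,
             " (L = ", res$L, ", KL = ", res$kl, ")")
      st <- nn_adam_step(par, res$grads, adam, cfg$lr)
      par <- st$par; adam <- st$state
      tr_loss <- tr_loss + res$loss; nb <- nb + 1
    }
    epsv <- matrix(rnorm(nrow(Xva) * model$arch$nz), nrow(Xva))
    va <- cvae_loss_grads(par, model$arch, Xva, Rva, epsv, alpha,
                          compute_grads = FALSE)
    hist <- rbind(hist, data.frame(epoch = e, alpha = alpha,
                                   train_loss = tr_loss / nb,
                                   val_loss = va$loss, val_L = va$L,
                                   val_kl = va$kl))
    if (verbose)
      message(sprintf("epoch %3d  alpha %.2f  train %8.4f  val %8.4f (L %.4f, KL %.4f)",
                      e, alpha, tr_loss / nb, va$loss, va$L, va$kl))
    e <- e + 1L
    if (alpha >= 1) {
      if (va$loss < best - 1e-6) {
        best <- va$loss; wait <- 0L
        best_par <- par; best_adam <- adam
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  model$params <- par
  model$adam <- adam
  model$best_params <- best_par
  model$best_adam <- best_adam
  model$history <- hist
  model$epochs_done <- e
  model$rng_state <- get(".Random.seed", globalenv())
  model
}

# use the best-validation checkpoint for inference when available
cvae_inference_params <- function(model) {
  if (!is.null(model$best_params)) model$best_params else model$params
}

#' @export
print.cvae <- function(x, ...) {
  cat(sprintf("CVAE posterior estimator: %d varied factors, nz = %d, m = %d\n",
              x$arch$d, x$arch$nz, x$arch$m))
  cat(sprintf("  trained %d epochs; final validation loss %.4f (-L %.4f, KL %.4f)\n",
              x$epochs_done, tail(x$history$val_loss, 1),
              -tail(x$history$val_L, 1), tail(x$history$val_kl, 1)))
  invisible(x)
}

#' @export
summary.cvae <- function(object, ...) {
  print(object)
  cat("  varied factors:", paste(object$vary, collapse = ", "), "\n")
  cat(sprintf("  parameters: %d\n",
              sum(vapply(object$params, length, 0L))))
  invisible(object)
}

#' @export
plot.cvae <- function(x, ...) {
  h <- x$history
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
          col = c("grey40", "firebrick"), xlab = "epoch", ylab = "loss", ...)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# ---- encoder / decoder surfaces -------------------------------------------

# standardize an arbitrary target trace with the training statistics
cvae_prepare_trace <- function(model, trace) {
  x <- if (inherits(trace, "twitch_trace")) trace$active_stress
       else if (is.data.frame(trace)) trace[[2]]
       else as.numeric(trace)
  if (length(x) != model$arch$T_len)
    stop("cvae: target trace length ", length(x), " does not match the model (",
         model$arch$T_len, ")")
  xs <- standardize_trace(x, model$stats)
  if (max(abs(xs)) > 50)
    warning("cvae: target trace looks unstandardizable (scale mismatch?)")
  xs
}

#' Recognition encoder Q1
#'
#' Returns the mean and log-variance of the unimodal latent Gaussian given a
#' (standardized) trace and its true rate factors — the training-time
#' encoder.
#'
#' @param model a fitted [cvae()].
#' @param trace target twitch (raw scale; standardized internally).
#' @param factors the true [rate_factors()] for the trace.
#' @export
cvae_encode <- function(model, trace, factors) {
  model$params <- cvae_inference_params(model)
  X <- cvae_prepare_trace(model, trace)
  f <- rate_factors(factors, check_bounds = FALSE)
  R <- factors_to_unit(matrix(as.numeric(f), 1,
                              dimnames = list(NULL, names(f))),
                       cbind(model$log_bounds,
                             matrix(c(-1, 2), 2,
                                    length(setdiff(FACTOR_NAMES, model$vary)),
                                    dimnames = list(c("lo", "hi"),
                                                    setdiff(FACTOR_NAMES, model$vary)))))
  R <- R[, model$vary, drop = FALSE]
  sh <- cvae_shared_fwd(model$params, model$arch, X)
  q1 <- cvae_head_fwd(model$params, "q1", cbind(sh$feat, R))
  nz <- model$arch$nz
  list(mean = q1$out[1, 1:nz], logvar = q1$out[1, nz + 1:nz])
}

#' Conditional prior encoder R1
#'
#' Gaussian-mixture parameters over the latent space given only the trace —
#' the inference-time encoder.
#'
#' @inheritParams cvae_encode
#' @return list with `means` (m x nz), `logvars` (m x nz), `logweights` (m,
#'   normalised).
#' @export
cvae_latent_prior <- function(model, trace) {
  model$params <- cvae_inference_params(model)
  X <- cvae_prepare_trace(model, trace)
  sh <- cvae_shared_fwd(model$params, model$arch, X)
  r1 <- cvae_head_fwd(model$params, "r1", sh$feat)
  gmm <- nn_gmm_parse(r1$out, model$arch$m, model$arch$nz)
  lw <- gmm$w[1, ] - nn_logsumexp(gmm$w)[1]
  list(means = do.call(rbind, lapply(gmm$mu, function(x) x[1, ])),
       logvars = do.call(rbind, lapply(gmm$lv, function(x) x[1, ])),
       logweights = lw)
}

#' Decoder R2
#'
#' Gaussian-mixture parameters over the (unit-box) factor space given the
#' trace and a latent point.
#'
#' @inheritParams cvae_encode
#' @param z latent point(s), vector of length nz or matrix n x nz.
#' @export
cvae_decode <- function(model, trace, z) {
  model$params <- cvae_inference_params(model)
  X <- cvae_prepare_trace(model, trace)
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != model$arch$nz) stop("cvae_decode: z has wrong dimension")
  sh <- cvae_shared_fwd(model$params, model$arch, X)
  feat <- sh$feat[rep(1, nrow(z)), , drop = FALSE]
  r2 <- cvae_head_fwd(model$params, "r2", cbind(feat, z))
  gmm <- nn_gmm_parse(r2$out, model$arch$m, model$arch$d)
  lw <- gmm$w - nn_logsumexp(gmm$w)
  list(means = gmm$mu, logvars = gmm$lv, logweights = lw)
}

# log density of the decoder mixture at unit-box points (teaching/testing aid)
cvae_decode_logp <- function(model, trace, z, r_unit) {
  model$params <- cvae_inference_params(model)
  X <- cvae_prepare_trace(model, trace)
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (is.null(dim(r_unit))) r_unit <- matrix(r_unit, nrow(z), length(r_unit),
                                             byrow = TRUE)
  sh <- cvae_shared_fwd(model$params, model$arch, X)
  feat <- sh$feat[rep(1, nrow(z)), , drop = FALSE]
  r2 <- cvae_head_fwd(model$params, "r2", cbind(feat, z))
  gmm <- nn_gmm_parse(r2$out, model$arch$m, model$arch$d)
  nn_gmm_logp(r_unit, gmm)$logp
}

# ---- posterior sampling ----------------------------------------------------

#' Sample the amortized posterior over rate factors
#'
#' Ancestral sampling at inference time: the conditional prior R1 yields a
#' latent mixture given the target twitch, a latent point is drawn from it,
#' and the decoder R2 conditioned on (trace, z) yields a factor-space mixture
#' from which one draw is taken; repeating `n` times builds the posterior
#' sample. Draws falling outside the prior box are kept but counted in the
#' `outside_prior` attribute.
#'
#' @param object a fitted [cvae()].
#' @param trace target twitch: a `twitch_trace`, a numeric stress vector on
#'   the model's time grid, or a two-column time/stress data frame. It is
#'   standardized with the training statistics.
#' @param n posterior sample size (default 5000).
#' @param seed RNG seed for the draws.
#' @param ... unused.
#' @return `posterior_samples`: an n x d matrix of log10 rate factors with
#'   the varied factor names, plus attributes (`factors` on the natural
#'   scale via `10^x`, `outside_prior` fraction, `vary`).
#' @export
predict.cvae <- function(object, trace, n = 5000L, seed = 1L, ...) {
  model <- object
  model$params <- cvae_inference_params(model)
  X <- cvae_prepare_trace(model, trace)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as_seed_int(seed))
  sh <- cvae_shared_fwd(model$params, model$arch, X)
  r1 <- cvae_head_fwd(model$params, "r1", sh$feat)
  gmm1 <- nn_gmm_parse(r1$out, model$arch$m, model$arch$nz)
  lw <- gmm1$w[1, ] - nn_logsumexp(gmm1$w)[1]
  comp <- sample.int(model$arch$m, n, replace = TRUE, prob = exp(lw))
  nz <- model$arch$nz
  mu1 <- do.call(rbind, lapply(gmm1$mu, function(x) x[1, , drop = FALSE]))
  sd1 <- exp(do.call(rbind, lapply(gmm1$lv, function(x) x[1, , drop = FALSE])) / 2)
  z <- mu1[comp, , drop = FALSE] +
    sd1[comp, , drop = FALSE] * matrix(rnorm(n * nz), n)

  feat <- sh$feat[rep(1, n), , drop = FALSE]
  r2 <- cvae_head_fwd(model$params, "r2", cbind(feat, z))
  gmm2 <- nn_gmm_parse(r2$out, model$arch$m, model$arch$d)
  lw2 <- gmm2$w - nn_logsumexp(gmm2$w)
  u <- runif(n)
  cum <- t(apply(exp(lw2), 1, cumsum))
  comp2 <- max.col(u < cum, ties.method = "first")
  d <- model$arch$d
  r_unit <- matrix(NA_real_, n, d)
  noise <- matrix(rnorm(n * d), n)
  for (k in seq_len(model$arch$m)) {
    rows <- which(comp2 == k)
    if (!length(rows)) next
    r_unit[rows, ] <- gmm2$mu[[k]][rows, , drop = FALSE] +
      exp(gmm2$lv[[k]][rows, , drop = FALSE] / 2) * noise[rows, , drop = FALSE]
  }
  lb <- model$log_bounds
  logf <- r_unit
  for (j in seq_len(d)) {
    lo <- lb["lo", j]; hi <- lb["hi", j]
    logf[, j] <- lo + r_unit[, j] * (hi - lo)
  }
  colnames(logf) <- model$vary
  outside <- mean(r_unit < 0 | r_unit > 1)
  structure(logf, class = c("posterior_samples", "matrix"),
            vary = model$vary, outside_prior = outside,
            log_bounds = lb)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior sample: %d draws over %d factors (log10 scale)\n",
              nrow(x), ncol(x)))
  q <- apply(unclass(x), 2, quantile, c(0.05, 0.5, 0.95))
  print(round(q, 3))
  cat(sprintf("  mass outside prior box: %.2f%%\n",
              100 * attr(x, "outside_prior")))
  invisible(x)
}

#' Save / load a fitted CVAE
#'
#' Self-describing checkpoint: parameters, architecture, optimiser state,
#' standardization statistics and training history in one native file.
#'
#' @param model a `cvae`.
#' @param path file path.
#' @export
write_cvae <- function(model, path) {
  stopifnot(inherits(model, "cvae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_cvae
#' @export
read_cvae <- function(path) {
  out <- readRDS(path)
  stopifnot(inherits(out, "cvae"))
  out
}
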