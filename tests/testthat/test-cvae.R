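test_that("KL annealing schedule: flat, linear ramp, then one", {
  expect_equal(anneal_alpha(0), 0)
  expect_equal(anneal_alpha(29), 0)
  expect_equal(anneal_alpha(30), 0)
  expect_equal(anneal_alpha(60), 0.5)
  expect_equal(anneal_alpha(90), 1)
  expect_equal(anneal_alpha(500), 1)
  expect_equal(anneal_alpha(15, flat = 10, ramp = 20), 0.25)
})

test_that("hand-derived gradients match finite differences on every parameter", {
  ns <- asNamespace("sarcotwitch")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(42)
  cfg <- cvae_config(nz = 2, m = 3, conv = list(c(5L, 4L), c(4L, 6L)),
                     feat_width = 10, head_width = 12)
  arch <- ns$cvae_arch(40L, 3L, cfg)
  par <- ns$cvae_init_params(arch)
  B <- 5
  X <- matrix(rnorm(B * 40), B)
  R <- matrix(runif(B * 3), B)
  eps <- matrix(rnorm(B * arch$nz), B)
  for (alpha in c(0, 0.6)) {
    res <- ns$cvae_loss_grads(par, arch, X, R, eps, alpha)
    expect_true(is.finite(res$loss))
    for (nm in names(par)) {
      idx <- sample(length(par[[nm]]), min(3, length(par[[nm]])))
      for (i in idx) {
        h <- 1e-5
        p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + h
        lp <- ns$cvae_loss_grads(p2, arch, X, R, eps, alpha,
                                 compute_grads = FALSE)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * h
        lm <- ns$cvae_loss_grads(p2, arch, X, R, eps, alpha,
                                 compute_grads = FALSE)$loss
        num <- (lp - lm) / (2 * h)
        ana <- res$grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
      }
    }
  }
})

test_that("mixture density heads are proper densities", {
  ns <- asNamespace("sarcotwitch")
  set.seed(8)
  m <- 3; d <- 2
  H <- matrix(c(rnorm(m * d, sd = 0.5), rnorm(m * d, sd = 0.3) - 0.5,
                rnorm(m)), 1)
  gmm <- ns$nn_gmm_parse(H, m, d)
  # weights normalise after exponentiation
  lw <- gmm$w - ns$nn_logsumexp(gmm$w)
  expect_equal(sum(exp(lw)), 1, tolerance = 1e-12)
  # the density integrates to one over a dense grid
  gr <- seq(-6, 6, length.out = 301)
  cell <- diff(gr[1:2])^2
  pts <- as.matrix(expand.grid(gr, gr))
  gmm_big <- lapply(gmm, function(x) x)
  gmm_big$mu <- lapply(gmm$mu, function(x) x[rep(1, nrow(pts)), , drop = FALSE])
  gmm_big$lv <- lapply(gmm$lv, function(x) x[rep(1, nrow(pts)), , drop = FALSE])
  gmm_big$w <- gmm$w[rep(1, nrow(pts)), , drop = FALSE]
  dens <- exp(ns$nn_gmm_logp(pts, gmm_big)$logp)
  expect_equal(sum(dens) * cell, 1, tolerance = 1e-3)
  # density at a component mean dominates a point 5 sigma away
  mu1 <- gmm$mu[[1]][1, ]
  far <- mu1 + 5 * exp(gmm$lv[[1]][1, ] / 2) * c(1, 1) +
    c(10, 10)  # well outside every component
  at_mu <- ns$nn_gmm_logp(matrix(mu1, 1), gmm)$logp
  at_far <- ns$nn_gmm_logp(matrix(far, 1), gmm)$logp
  expect_gt(at_mu, at_far)
})

test_that("encoder and decoder surfaces return the documented shapes", {
  ds <- toy_corpus(n = 200)
  ds <- split_dataset(ds, 0.1, seed = 1)
  ds <- standardize_dataset(ds)
  mod <- cvae(ds, toy_cvae_config(max_epochs = 2L, seed = 5))
  tr <- unstandardize_trace(ds$traces[1, ], ds$stats)
  enc <- cvae_encode(mod, as.numeric(tr), rate_factors(ds$factors[1, ]))
  expect_length(enc$mean, mod$arch$nz)
  expect_length(enc$logvar, mod$arch$nz)
  expect_true(all(is.finite(c(enc$mean, enc$logvar))))

  pri <- cvae_latent_prior(mod, as.numeric(tr))
  expect_equal(dim(pri$means), c(mod$arch$m, mod$arch$nz))
  expect_equal(dim(pri$logvars), c(mod$arch$m, mod$arch$nz))
  expect_length(pri$logweights, mod$arch$m)
  expect_equal(sum(exp(pri$logweights)), 1, tolerance = 1e-10)

  dec <- cvae_decode(mod, as.numeric(tr), numeric(mod$arch$nz))
  expect_equal(sum(exp(dec$logweights[1, ])), 1, tolerance = 1e-10)
  expect_length(dec$means, mod$arch$m)
  expect_equal(ncol(dec$means[[1]]), length(ds$vary))

  expect_error(cvae_decode(mod, as.numeric(tr), numeric(7)), "dimension")
  expect_error(predict(mod, numeric(10)), "length")

  # a single-sample KL estimate between Q1 and R1 is non-negative on average
  set.seed(31)
  kls <- replicate(2000, {
    z <- enc$mean + exp(enc$logvar / 2) * rnorm(mod$arch$nz)
    lq <- sum(dnorm(z, enc$mean, exp(enc$logvar / 2), log = TRUE))
    comp <- vapply(seq_len(mod$arch$m), function(k)
      pri$logweights[k] + sum(dnorm(z, pri$means[k, ],
                                    exp(pri$logvars[k, ] / 2), log = TRUE)),
      0)
    mx <- max(comp)
    lq - (mx + log(sum(exp(comp - mx))))
  })
  expect_gt(mean(kls), -0.05)
})

test_that("training reduces the validation loss and losses stay finite", {
  ds <- toy_corpus(n = 400)
  ds <- split_dataset(ds, 0.15, seed = 2)
  ds <- standardize_dataset(ds)
  mod <- cvae(ds, toy_cvae_config(max_epochs = 12L, seed = 3))
  h <- mod$history
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(is.finite(h$val_loss)))
  # the reconstruction term improves over training
  expect_gt(h$val_L[nrow(h)], h$val_L[1])
  # annealing weight follows the schedule in the log
  expect_equal(h$alpha, anneal_alpha(h$epoch, 2, 4))
})

test_that("posterior sampling is deterministic given a seed and finds the truth", {
  ds <- toy_corpus(n = 600, noise = 0.2)
  ds <- split_dataset(ds, 0.1, seed = 4)
  ds <- standardize_dataset(ds)
  mod <- cvae(ds, toy_cvae_config(max_epochs = 25L, lr = 2e-3, seed = 6))
  va <- which(ds$split == "validation")[1:5]
  for (i in va) {
    tr <- unstandardize_trace(ds$traces[i, ], ds$stats)
    ps <- predict(mod, as.numeric(tr), n = 1500, seed = 100 + i)
    expect_true(all(is.finite(ps)))
    truth <- log10(ds$factors[i, ds$vary])
    # the truth lies inside the per-dimension 99% box of the sample cloud
    for (j in seq_along(ds$vary)) {
      q <- quantile(ps[, j], c(0.005, 0.995))
      expect_gte(truth[j], q[1])
      expect_lte(truth[j], q[2])
    }
  }
  ps1 <- predict(mod, unstandardize_trace(ds$traces[va[1], ], ds$stats),
                 n = 500, seed = 9)
  ps2 <- predict(mod, unstandardize_trace(ds$traces[va[1], ], ds$stats),
                 n = 500, seed = 9)
  expect_identical(unclass(ps1), unclass(ps2))
  expect_equal(formals(predict.cvae)$n, 5000L)
})

test_that("interrupted-and-resumed training matches an uninterrupted run", {
  ds <- toy_corpus(n = 300)
  ds <- split_dataset(ds, 0.1, seed = 5)
  ds <- standardize_dataset(ds)
  full <- cvae(ds, toy_cvae_config(max_epochs = 6L, seed = 11))
  half <- cvae(ds, toy_cvae_config(max_epochs = 3L, seed = 11))
  resumed <- cvae_resume(half, ds, extra_epochs = 3L)
  expect_equal(resumed$history$train_loss, full$history$train_loss,
               tolerance = 1e-12)
  expect_equal(resumed$history$val_loss, full$history$val_loss,
               tolerance = 1e-12)
  expect_equal(resumed$params, full$params, tolerance = 1e-12)
})

test_that("model checkpoints round-trip through the container format", {
  ds <- toy_corpus(n = 200)
  mod <- cvae(split_dataset(ds, 0.1, 1), toy_cvae_config(max_epochs = 2L))
  path <- tempfile(fileext = ".rds")
  write_cvae(mod, path)
  back <- read_cvae(path)
  expect_equal(back$params, mod$params)
  expect_equal(back$history, mod$history)
  unlink(path)
})
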