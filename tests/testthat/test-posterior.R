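# pp-curve coverage arithmetic applied to externally supplied CDF values
pp_cov <- function(u, levels = seq(0, 1, by = 0.02)) {
  vapply(levels, function(l) mean(u <= l), 0)
}

test_that("a perfectly calibrated posterior traces the diagonal", {
  set.seed(19)
  n <- 600
  # truth and posterior samples share one distribution: the CDF value of the
  # truth under the posterior is uniform
  u <- vapply(seq_len(n), function(i) {
    truth <- rnorm(1)
    s <- rnorm(400)
    (sum(s < truth) + runif(1) * sum(s == truth)) / 400
  }, 0)
  levels <- seq(0, 1, by = 0.02)
  cov <- pp_cov(u, levels)
  # 99% Kolmogorov band for the empirical CDF of a uniform sample
  band <- 1.628 / sqrt(n)
  expect_lt(max(abs(cov - levels)), band + 1 / 400)
  expect_equal(cov[1], 0, tolerance = 0.02)
  expect_equal(cov[length(levels)], 1)
  expect_true(all(diff(cov) >= 0))
})

test_that("posterior mis-calibration bends the curve in the documented directions", {
  set.seed(23)
  cdf_vals <- function(sd_post) vapply(seq_len(500), function(i) {
    truth <- rnorm(1)
    s <- rnorm(400, sd = sd_post)
    (sum(s < truth) + runif(1) * sum(s == truth)) / 400
  }, 0)
  levels <- seq(0.6, 0.9, by = 0.05)
  # over-confident (too narrow): mass of the CDF values piles at the
  # extremes, pulling the upper arm of the curve below the diagonal
  over <- pp_cov(cdf_vals(sqrt(0.1)), levels)
  expect_true(all(over < levels))
  # under-confident (too wide): the upper arm sits above the diagonal
  under <- pp_cov(cdf_vals(3), levels)
  expect_true(all(under > levels))
})

test_that("signed KS equals a brute-force ECDF scan with the stated sign convention", {
  brute <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    Fa <- vapply(xs, function(x) mean(a <= x), 0)
    Fb <- vapply(xs, function(x) mean(b <= x), 0)
    i <- which.max(abs(Fa - Fb))
    Fa[i] - Fb[i]
  }
  expect_equal(signed_ks(c(1, 2, 3), c(1, 2, 3)), 0)
  # disjoint supports: |KS| = 1; the control CDF is larger at the crossing
  expect_equal(signed_ks(c(1, 2), c(3, 4)), 1)
  expect_equal(signed_ks(c(3, 4), c(1, 2)), -1)
  set.seed(3)
  for (i in 1:200) {
    a <- rnorm(sample(5:60, 1))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    expect_identical(signed_ks(a, b), brute(a, b))
    expect_lte(abs(signed_ks(a, b)), 1)
  }
  # an upward shift leaves the control CDF larger wherever they differ
  a <- rnorm(200)
  expect_gt(signed_ks(a, a + 2), 0)
  expect_lt(signed_ks(a, a - 2), 0)
})

test_that("signed KS operates per factor across posterior sample matrices", {
  set.seed(6)
  A <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("rt12", "rt41")))
  B <- A
  B[, "rt12"] <- B[, "rt12"] + 1.5
  ks <- signed_ks(A, B)
  expect_named(ks, c("rt12", "rt41"))
  # comparison samples shifted up: the control CDF is larger at the crossing
  expect_gt(ks[["rt12"]], 0.4)
  expect_lt(abs(ks[["rt41"]]), 0.1)
})

test_that("corner summary locates the mode of a known density", {
  set.seed(9)
  n <- 4000
  X <- cbind(rnorm(n, 0.3, 0.25), rnorm(n, -0.4, 0.25), rnorm(n, 1, 0.25))
  colnames(X) <- c("rt12", "rt41", "rx16")
  cs <- corner_summary(X)
  # the KDE peak sits near the true mean (tolerance from the estimator's
  # own spread at this n, a few bandwidths)
  expect_lt(max(abs(cs$peak - c(0.3, -0.4, 1))), 0.12)
  expect_lt(max(abs(cs$marginal_modes - c(0.3, -0.4, 1))), 0.12)
  expect_equal(cs$peak_factors, 10^cs$peak)
  expect_length(cs$pairs, 3)

  # permutation invariance
  cs2 <- corner_summary(X[sample(n), ])
  expect_equal(cs2$peak, cs$peak)

  expect_error(corner_summary(X[1:50, ]), "at least")
  Xd <- X; Xd[, 2] <- 0.7
  expect_warning(csd <- corner_summary(Xd), "degenerate")
  expect_equal(unname(csd$marginal_modes["rt41"]), 0.7)
})

test_that("corner plot renders with prior-box axes and returns the summary", {
  set.seed(2)
  X <- matrix(rnorm(3000, sd = 0.3), 1000, 3,
              dimnames = list(NULL, c("rt12", "rt41", "rx16")))
  ps <- structure(X, class = c("posterior_samples", "matrix"),
                  vary = colnames(X), outside_prior = 0,
                  log_bounds = matrix(c(-1, 2), 2, 3,
                                      dimnames = list(c("lo", "hi"),
                                                      colnames(X))))
  pdf(NULL)
  cs <- plot(ps, truth = c(rt12 = 0, rt41 = 0, rx16 = 0))
  dev.off()
  expect_s3_class(cs, "corner_summary")
})

test_that("hybrid factors graft the named coordinates from the variant", {
  control <- rate_factors(c(rx16 = 2, rt12 = 5, rt41 = 0.5))
  variant <- rate_factors(c(rt12 = 0.2, rt41 = 4, rx34 = 9))
  expect_equal(hybrid_factors(control, variant, swap = character(0)), control)
  expect_equal(hybrid_factors(control, variant, swap = FACTOR_NAMES), variant)
  hyb <- hybrid_factors(control, variant)   # default: calcium-affinity pair
  expect_equal(unname(hyb["rt12"]), 0.2)
  expect_equal(unname(hyb["rt41"]), 4)
  expect_equal(unname(hyb["rx16"]), 2)
  expect_equal(unname(hyb["rx34"]), 1)
  expect_equal(eval(formals(hybrid_factors)$swap), c("rt12", "rt41"))
  expect_error(hybrid_factors(control, variant, swap = "nope"), "unknown")
})

test_that("recruiting myosin heads from SRX raises peak twitch stress", {
  lat <- hs_lattice(anchor_config())
  base <- simulate_twitch(config = lat, seed = 31, replicates = 24)
  recr <- simulate_twitch(rate_factors(c(rx16 = 0.1)), config = lat,
                          seed = 31, replicates = 24)
  expect_gt(max(recr$active_stress), max(base$active_stress))
})

test_that("freezing every factor degenerates the intervention to the input", {
  hyb <- rate_factors(c(rx16 = 0.5, rt12 = 2))
  cfg <- tiny_config()
  out <- infer_intervention(hyb, target_trace = NULL, thick_names = character(0),
                            config = cfg, seed = 3, replicates = 2)
  expect_equal(out$peak, hyb)
  expect_s3_class(out$intervention, "twitch_trace")
  expect_null(out$posterior)
})

test_that("a planted thick-filament perturbation is recovered inside the 90% credible region", {
  cfg <- tiny_config()
  hyb <- rate_factors(c(rt12 = 2, rt41 = 0.5))   # thin rates to freeze
  planted <- hybrid_factors(rate_factors(c(rx16 = 0.2, rx12 = 5)), hyb,
                            swap = c("rt12", "rt41"))
  target <- simulate_twitch(planted, config = cfg, seed = 99, replicates = 16)
  out <- infer_intervention(hyb, target,
                            thick_names = c("rx12", "rx16"),
                            config = cfg, n_combos = 400L, replicates = 6L,
                            cvae_cfg = toy_cvae_config(m = 4L, max_epochs = 30L,
                                                       lr = 2e-3, seed = 8),
                            n = 1500L, seed = 12)
  expect_s3_class(out$posterior, "posterior_samples")
  expect_equal(colnames(out$posterior), c("rx12", "rx16"))
  # frozen thin rates pass through to the reported peak
  expect_equal(unname(out$peak["rt12"]), 2)
  expect_equal(unname(out$peak["rt41"]), 0.5)
  for (nm in c("rx12", "rx16")) {
    q <- quantile(out$posterior[, nm], c(0.05, 0.95))
    truth <- log10(planted[[nm]])
    expect_gte(truth, q[1])
    expect_lte(truth, q[2])
  }
  expect_s3_class(out$intervention, "twitch_trace")
})
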