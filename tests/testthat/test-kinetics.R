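test_that("forward crossbridge rate laws reproduce hand-evaluated values", {
  p <- kinetic_params()
  r0 <- xb_forward_rates(0, 10, 1, p)
  expect_equal(unname(r0["rx12"]), 7.2)          # tau e^0
  expect_equal(unname(r0["rx51"]), 0.1)          # constant H
  rln2 <- xb_forward_rates(log(2), 10, 1, p)
  expect_equal(unname(rln2["rx12"]), 3.6)        # tau / 2
  # rx23 saturates between 0 and 2A as the energy gap swings
  lo <- xb_forward_rates(0, 1000, 1, p)["rx23"]
  hi <- xb_forward_rates(1000, 0, 1, p)["rx23"]
  expect_lt(unname(lo), 1e-8)
  expect_equal(unname(hi), 2 * 0.8, tolerance = 1e-10)
})

test_that("reverse rates satisfy detailed balance with Boltzmann stationarity", {
  expect_equal(reverse_rate(2.5, 1.3, 1.3), 2.5)
  # the lower-free-energy destination is favoured: r_fwd / r_rev = e^{Gi - Gj}
  expect_equal(reverse_rate(1, 1, 0), exp(-1))
  expect_equal(1 / reverse_rate(1, 0, 1), exp(-1))
  expect_error(reverse_rate(-1, 0, 0), "non-negative")

  # long-run Monte-Carlo occupancy of an isolated reversible pair matches the
  # Boltzmann ratio within binomial error
  G1 <- 0; G2 <- -1.2
  k12 <- 0.8
  k21 <- reverse_rate(k12, G1, G2)
  Q <- rate_matrix(matrix(c(0, k12, k21, 0), 2, byrow = TRUE))
  P <- transition_matrix(Q, 0.5)
  set.seed(11)
  state <- 1L
  n_steps <- 40000L
  occ2 <- 0L
  u <- runif(n_steps)
  for (i in seq_len(n_steps)) {
    state <- sample_transition(P, state, u[i])
    occ2 <- occ2 + (state == 2L)
  }
  p2_hat <- occ2 / n_steps
  p2_true <- exp(G1 - G2) / (1 + exp(G1 - G2))
  se <- sqrt(p2_true * (1 - p2_true) / n_steps) * 3  # ignores autocorrelation
  expect_lt(abs(p2_hat - p2_true), max(3 * se, 0.02))
})

test_that("thin filament reverse rates reproduce the printed equilibrium constants", {
  p <- kinetic_params()
  for (ca in c(1e-7, 1e-6, 1e-4)) {
    rt <- thin_rates(ca, FALSE, p)
    expect_equal(unname(rt["rt21"]), 37650 / 260000, tolerance = 1e-12)
    expect_equal(unname(rt["rt32"]), 33.4 / 130, tolerance = 1e-12)
    expect_equal(unname(rt["rt43"]), 0.13 / 0.91, tolerance = 1e-12)
    # equilibrium constants recovered to machine precision
    expect_equal(unname(rt["rt12"] / rt["rt21"]), 260000 * ca)
    expect_equal(unname(rt["rt23"] / rt["rt32"]), 130)
    expect_equal(unname(rt["rt34"] / rt["rt43"]), 0.91)
    expect_equal(unname(rt["rt41"]), 0.77)
  }
})

test_that("an activated neighbour multiplies activation forwards by 100 only", {
  p <- kinetic_params()
  base <- thin_rates(1e-6, FALSE, p)
  coop <- thin_rates(1e-6, TRUE, p)
  for (nm in c("rt12", "rt23", "rt34"))
    expect_equal(unname(coop[nm] / base[nm]), 100)
  for (nm in c("rt21", "rt32", "rt43", "rt41"))
    expect_equal(unname(coop[nm]), unname(base[nm]))
})

test_that("SRX exchange: equal resting rates, Hill midpoint, monotone rise", {
  p <- kinetic_params()
  lo <- srx_rates(1e-12, p)
  expect_equal(unname(lo[, "rx61"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(lo[, "rx16"]), 0.05)
  # the isolated DRX/SRX pair therefore rests at 50/50
  Q <- rate_matrix(matrix(c(0, 0.05, 0.05, 0), 2, byrow = TRUE))
  expect_equal(stationary_distribution(Q), c(0.5, 0.5))
  mid <- srx_rates(p$ca50, p)
  expect_equal(unname(mid[, "rx61"]), (p$rx61_base + p$rx61_max) / 2)
  ca <- 10^seq(-8, -3, length.out = 40)
  expect_true(all(diff(srx_rates(ca, p)[, "rx61"]) >= 0))
})

test_that("all cycle rates are finite and non-negative across the strain range", {
  p <- kinetic_params()
  dx <- seq(-20, 45, by = 0.25)
  for (ca in c(1e-7, 1e-4)) {
    rr <- xb_cycle_rates(dx, ca, p)
    expect_true(all(is.finite(rr)))
    expect_true(all(rr >= 0))
    expect_true(all(rr <= p$rate_ceiling))
  }
})

test_that("calcium transient is anchored, peaks on time, and stays bounded", {
  cp <- ca_params()
  tt <- seq(0, 1, by = 1e-3)
  tr <- ca_transient(tt, cp)
  expect_equal(tr$ca[1], 1e-7)
  expect_equal(max(tr$ca), 1e-6, tolerance = 1e-9)
  expect_equal(tt[which.max(tr$ca)], cp$t_peak, tolerance = 2e-3)
  expect_true(all(tr$ca >= 1e-7 - 1e-15 & tr$ca <= 1e-6 + 1e-15))
  expect_equal(tr$pca, -log10(tr$ca))
  # a = 1 gives a profile symmetric about the peak
  cps <- ca_params(a = 1, t_peak = 0.4, w = 0.1)
  d <- seq(0.01, 0.3, by = 0.01)
  expect_equal(ca_transient(0.4 + d, cps)$ca, ca_transient(0.4 - d, cps)$ca,
               tolerance = 1e-12)
})

test_that("transient shape parameters are recoverable from a noise-free trace", {
  truth <- ca_params(a = 0.3, t_peak = 0.04, w = 0.12)
  tt <- seq(0, 1, by = 1e-3)
  ca <- ca_transient(tt, truth)$ca
  start <- ca_params(a = 0.4, t_peak = 0.06, w = 0.2)
  fit <- fit_ca_transient(tt, ca, start)
  expect_equal(fit$a, truth$a, tolerance = 1e-4)
  expect_equal(fit$t_peak, truth$t_peak, tolerance = 1e-4)
  expect_equal(fit$w, truth$w, tolerance = 1e-4)
})

test_that("rate factors enforce the prior box and apply multiplicatively", {
  expect_silent(rate_factors(c(rx12 = 0.1, rt41 = 100)))
  expect_error(rate_factors(c(rx12 = 0.099)), "prior range")
  expect_error(rate_factors(c(rx12 = 101)), "prior range")
  expect_error(rate_factors(c(bogus = 1)), "unknown")
  expect_error(rate_factors(c(rx12 = -2), check_bounds = FALSE), "positive")

  base <- c(rx12 = 7.2, rx16 = 0.05, rt41 = 0.77, rx51 = 0.1)
  out <- apply_rate_factors(base, rate_factors(c(rx16 = 0.1)))
  expect_equal(unname(out["rx16"]), 0.005)  # 50/s down to 5/s
  expect_equal(out[c("rx12", "rt41", "rx51")],
               base[c("rx12", "rt41", "rx51")])
  expect_equal(apply_rate_factors(base, rate_factors()), base)

  # factors scale the evaluated cycle rates, reverse partners included
  p <- kinetic_params()
  r1 <- xb_cycle_rates(14, 1e-6, p)
  r2 <- xb_cycle_rates(14, 1e-6, p, rate_factors(c(rx12 = 10)))
  expect_equal(r2[, "rx12"], 10 * r1[, "rx12"])
  expect_equal(r2[, "rx21"], 10 * r1[, "rx21"])   # detailed balance inherits
  expect_equal(r2[, "rx23"], r1[, "rx23"])
})
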