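test_that("rate matrix construction sets a conserving diagonal", {
  expect_equal(rate_matrix(matrix(0, 3, 3)), matrix(0, 3, 3))
  Q <- rate_matrix(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(Q, matrix(c(-1, 1, 1, -1), 2, byrow = TRUE))
  set.seed(2)
  R <- matrix(runif(36, 0, 10), 6)
  expect_equal(rowSums(rate_matrix(R)), rep(0, 6))
  R[2, 3] <- -0.1
  expect_error(rate_matrix(R), "negative")
})

test_that("matrix exponential yields the identity at dt = 0 and the 2-state closed form", {
  expect_equal(transition_matrix(matrix(0, 4, 4), 5), diag(4))
  Q <- rate_matrix(matrix(c(0, 0.7, 0.3, 0), 2, byrow = TRUE))
  expect_equal(transition_matrix(Q, 0), diag(2))
  for (dt in c(0.1, 1, 10)) {
    P <- transition_matrix(Q, dt)
    k12 <- 0.7; k21 <- 0.3; s <- k12 + k21
    p11 <- (k21 + k12 * exp(-s * dt)) / s
    p22 <- (k12 + k21 * exp(-s * dt)) / s
    expect_equal(P, matrix(c(p11, 1 - p11, 1 - p22, p22), 2, byrow = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(transition_matrix(matrix(c(0, 1, 1, 0), 2), 1), "sum to zero")
  expect_error(transition_matrix(matrix(NaN, 2, 2), 1), "non-finite")
})

test_that("matrix exponential agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(c(4L, 6L), 1)
    Q <- rate_matrix(matrix(rexp(n * n, 1 / 5), n))
    dt <- sample(c(0.1, 1, 10), 1)
    P <- transition_matrix(Q, dt)
    oracle <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
    expect_equal(P, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the crossbridge transition matrix is stochastic with multi-step paths", {
  p <- kinetic_params()
  rr <- xb_cycle_rates(13.5, 1e-4, p)  # near the binding window at pCa 4
  Q <- xb_rate_matrix(rr[1, ])
  P <- transition_matrix(Q, 1)
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-10)
  # no direct 1 -> 5 rate, yet the one-step probability is positive
  expect_equal(Q[1, 5], 0)
  expect_gt(P[1, 5], 0)
})

test_that("Chapman-Kolmogorov holds: P(2 dt) = P(dt)^2", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(c(4L, 6L), 1)
    Q <- rate_matrix(matrix(rexp(n * n, 1 / 3) *
                            rbinom(n * n, 1, 0.7), n))
    for (dt in c(0.1, 1)) {
      P1 <- transition_matrix(Q, dt)
      P2 <- transition_matrix(Q, 2 * dt)
      expect_equal(P2, P1 %*% P1, tolerance = 1e-9)
    }
  }
})

test_that("cumulative-inversion sampling is exact and unbiased", {
  P <- diag(4)
  for (s in 1:4) for (u in c(0, 0.3, 0.999))
    expect_equal(sample_transition(P, s, u), s)
  P2 <- matrix(c(0.25, 0.75, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(sample_transition(P2, 1, 0.2), 1)
  expect_equal(sample_transition(P2, 1, 0.3), 2)
  expect_equal(sample_transition(P2, 1, 0.25), 2)  # boundary: u < cumsum
  expect_error(sample_transition(P2, 1, 1), "\\[0, 1\\)")
  expect_error(sample_transition(P2, 1, -0.1), "\\[0, 1\\)")

  set.seed(5)
  draws <- vapply(runif(1e5), function(u) sample_transition(P2, 1, u), 0L)
  p_hat <- mean(draws == 2)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
})

test_that("stationary distributions match analytic and eigenvector oracles", {
  Q <- rate_matrix(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(stationary_distribution(Q), c(0.5, 0.5))

  # resting DRX/SRX pair at 50/s each
  Qs <- rate_matrix(matrix(c(0, 0.05, 0.05, 0), 2, byrow = TRUE))
  expect_equal(stationary_distribution(Qs), c(0.5, 0.5))

  set.seed(13)
  Q6 <- rate_matrix(matrix(rexp(36, 1), 6))
  pi_hat <- stationary_distribution(Q6)
  # power-iteration oracle on the transition matrix
  P <- transition_matrix(Q6, 1)
  v <- rep(1 / 6, 6)
  for (i in 1:10000) v <- as.numeric(v %*% P)
  expect_equal(pi_hat, v, tolerance = 1e-8)
  expect_equal(as.numeric(pi_hat %*% Q6), rep(0, 6), tolerance = 1e-10)
  # large-dt rows of the transition matrix reach the same distribution
  Pinf <- transition_matrix(Q6, 1e5)
  for (r in 1:6) expect_equal(Pinf[r, ], pi_hat, tolerance = 1e-8)
})

test_that("reducible rate matrices warn and return a component-wise mixture", {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 1; Q[2, 1] <- 2   # closed class {1,2}
  Q[3, 4] <- 3; Q[4, 3] <- 1   # closed class {3,4}
  Q <- rate_matrix(Q)
  expect_warning(pi_hat <- stationary_distribution(Q), "reducible")
  expect_equal(sum(pi_hat), 1)
  expect_equal(as.numeric(pi_hat %*% Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(pi_hat[1] / pi_hat[2], 2, tolerance = 1e-10)
})

test_that("occupancy trajectories at 1 ms match a 0.1 ms reference (coarse steps stay accurate)", {
  # a single crossbridge at fixed strain and saturating calcium, long run:
  # the time-averaged occupancies should agree across step sizes
  p <- kinetic_params()
  rr <- xb_cycle_rates(13.9, 1e-4, p)
  Q <- xb_rate_matrix(rr[1, ])
  run <- function(dt, n_steps, seed) {
    P <- transition_matrix(Q, dt)
    set.seed(seed)
    s <- 1L
    counts <- numeric(6)
    u <- runif(n_steps)
    for (i in seq_len(n_steps)) {
      s <- sample_transition(P, s, u[i])
      counts[s] <- counts[s] + 1
    }
    counts / n_steps
  }
  occ_coarse <- run(1, 20000, 21)
  occ_fine <- run(0.1, 200000, 22)
  expect_lt(max(abs(occ_coarse - occ_fine)), 0.02)
})
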