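test_that("lattice build yields the configured filament, head and site counts", {
  cfg <- tiny_config()
  lat <- hs_lattice(cfg)
  lc <- cfg$lattice
  expect_equal(lat$geom$n_thick, 4L)
  expect_equal(lat$geom$n_thin, 8L)
  expect_equal(lat$n_heads,
               lc$n_thick * lc$nodes_per_thick * lc$heads_per_node)
  expect_equal(lat$n_sites, lc$n_thin * lc$nodes_per_thin)
  # every head maps to exactly one thin filament index in range
  expect_true(all(lat$geom$head_thin >= 0 & lat$geom$head_thin < 8))
  # each thick filament sees six thin neighbours
  expect_equal(dim(lat$neighbours), c(4L, 6L))
})

test_that("geometry is deterministic and unaffected by simulation seeds", {
  a <- hs_lattice(tiny_config())
  b <- hs_lattice(tiny_config())
  expect_identical(a$geom, b$geom)
  # two different simulation seeds share the same geometry object
  t1 <- simulate_twitch(config = a, seed = 1, ca = rep(1e-7, 10))
  t2 <- simulate_twitch(config = a, seed = 2, ca = rep(1e-7, 10))
  expect_identical(attr(t1, "n_heads"), attr(t2, "n_heads"))
})

test_that("invalid geometry is rejected", {
  expect_error(lattice_config(k_thick = -1), "positive")
  expect_error(lattice_config(thick_node_spacing = 0), "positive")
  expect_error(lattice_config(nodes_per_thick = 200L,
                              half_sarcomere_length = 500), "longer")
})

test_that("passive state has unstrained thin filaments and titin-only reaction", {
  lat <- hs_lattice(tiny_config())
  res <- solve_balance(lat)
  g <- lat$geom
  # thin filaments carry no load: nodes exactly at rest
  for (f in seq_len(g$n_thin)) {
    rest <- g$half_sarcomere_length - g$thin_offset[f] -
      (g$nodes_per_thin - seq_len(g$nodes_per_thin) + 1) * g$thin_node_spacing
    expect_equal(res$xa[f, ], rest, tolerance = 1e-10)
  }
  # boundary reaction equals the titin force at the settled extension
  titin_total <- sum(titin_force(
    (g$half_sarcomere_length - res$xk[, g$nodes_per_thick]) - g$titin_rest,
    g$titin_a, g$titin_b))
  expect_equal(res$force_z, titin_total, tolerance = 1e-8)
  # Newton's third law across the lattice
  expect_equal(res$force_z, res$force_m, tolerance = 1e-8 * abs(res$force_z))
})

test_that("titin force is exponential: anchor value, doubling length, monotone", {
  expect_equal(titin_force(0), 220)
  dl <- seq(-100, 500, by = 10)
  f <- titin_force(dl)
  expect_true(all(f > 0))
  expect_true(all(diff(f) > 0))
  # exponential law: adding ln(2)/b doubles the force
  expect_equal(titin_force(dl + log(2) / 0.0045) / f, rep(2, length(dl)),
               tolerance = 1e-12)
})

test_that("crossbridge energy is a quadratic with its minimum at the rest pair", {
  p <- kinetic_params()
  expect_equal(xb_energy(p$r_W, p$theta_W, "weak", p), 0)
  expect_equal(xb_energy(p$r_S, p$theta_S, "strong", p), 0)
  # half k r^2 with k_r = 5 and 1 nm of stretch
  expect_equal(xb_energy(p$r_W + 1, p$theta_W, "weak", p), 2.5)
  # non-negative everywhere, minimized at each state's own rest pair
  r <- runif(50, 5, 30); th <- runif(50, 0, pi)
  expect_true(all(xb_energy(r, th, "weak", p) >= 0))
  expect_true(all(xb_energy(r, th, "strong", p) >= 0))
  expect_error(xb_energy(-1, 0.5, "weak", p), "positive")
  expect_error(xb_energy(10, 0.5, "wobbly", p))
})

test_that("spring force components are the exact gradient of the energy", {
  p <- kinetic_params()
  set.seed(4)
  r <- runif(100, 8, 30); th <- runif(100, 0.2, 2.5)
  for (state in c("weak", "strong")) {
    f <- xb_force(r, th, state, p)
    h <- 1e-6
    num_r <- (xb_energy(r + h, th, state, p) -
              xb_energy(r - h, th, state, p)) / (2 * h)
    num_t <- (xb_energy(r, th + h, state, p) -
              xb_energy(r, th - h, state, p)) / (2 * h)
    expect_equal(f$radial, num_r, tolerance = 1e-6)
    expect_equal(f$torsional, num_t, tolerance = 1e-6)
  }
  # zero strain gives zero force; sign reverses across the rest length
  expect_equal(xb_force(p$r_W, p$theta_W, "weak", p)$radial, 0)
  expect_lt(xb_force(p$r_W - 0.5, p$theta_W, "weak", p)$radial, 0)
  expect_gt(xb_force(p$r_W + 0.5, p$theta_W, "weak", p)$radial, 0)
})

test_that("axial force components match numerical derivatives of the energies", {
  p <- kinetic_params()
  dx <- seq(-5, 30, length.out = 71)
  g <- xb_geometry(dx, p)
  h <- 1e-5
  gp <- xb_geometry(dx + h, p); gm <- xb_geometry(dx - h, p)
  expect_equal(g$F_W_axial, (gp$U_W - gm$U_W) / (2 * h), tolerance = 1e-5)
  expect_equal(g$F_S_axial, (gp$U_S - gm$U_S) / (2 * h), tolerance = 1e-5)
})

test_that("cross-sectional area follows the rhombic unit cell geometry", {
  cfg <- sim_config()
  s <- cfg$lattice$lattice_spacing
  expect_equal(hs_area(cfg), 4 * s^2 * sin(pi / 3) * 1e-12)
  big <- sim_config(lattice = lattice_config(lattice_spacing = 2 * s))
  expect_equal(hs_area(big) / hs_area(cfg), 4)
})

test_that("force balance equals direct energy minimisation (oracle)", {
  lat <- hs_lattice(tiny_config())
  kin <- lat$config$kinetics
  g <- lat$geom
  # pick up to three heads with a plausibly reachable site and bind them
  na <- g$nodes_per_thin
  xh <- (g$head_node + 1) * g$thick_node_spacing
  cand <- data.frame(head = integer(), site = integer(), strong = logical())
  for (h in seq_len(lat$n_heads)) {
    tf <- g$head_thin[h] + 1
    xs <- g$half_sarcomere_length - g$thin_offset[tf] -
      (na - seq_len(na) + 1) * g$thin_node_spacing
    j <- which.min(abs(xs - (xh[h] + kin$dx_star)))
    dx <- xs[j] - xh[h]
    if (xb_geometry(dx, kin)$U_W < 6)
      cand <- rbind(cand, data.frame(head = h, site = (tf - 1) * na + j,
                                     strong = NA))
  }
  cand <- cand[!duplicated(cand$site), ][1:3, ]
  cand$strong <- c(FALSE, TRUE, FALSE)
  res <- solve_balance(lat, cand, tol = 1e-8)
  oracle <- minimize_energy(lat, cand)
  expect_lt(max(abs(res$xk - oracle$xk)), 1e-4)
  expect_lt(max(abs(res$xa - oracle$xa)), 1e-4)
  # equilibrium: boundary forces balance
  expect_equal(res$force_z, res$force_m, tolerance = 1e-8 * abs(res$force_z))
})

test_that("doubling thick filament stiffness halves its titin-driven stretch", {
  base <- tiny_config()
  stiff <- sim_config(lattice = reduced_lattice_config(
    k_thick = 2 * base$lattice$k_thick))
  r1 <- solve_balance(hs_lattice(base))
  r2 <- solve_balance(hs_lattice(stiff))
  g <- hs_lattice(base)$geom
  rest <- seq_len(g$nodes_per_thick) * g$thick_node_spacing
  d1 <- r1$xk[1, ] - rest
  d2 <- r2$xk[1, ] - rest
  expect_equal(d2 / d1, rep(0.5, length(d1)), tolerance = 1e-3)
})
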