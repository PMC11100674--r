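# Shared fixtures: all inputs are generated in code at test time.

# smallest usable lattice (24 heads, 24 sites): fast kinetic smoke tests
tiny_config <- function(...) {
  sim_config(lattice = reduced_lattice_config(), ...)
}

# mid-size lattice (80 heads) with full head-site offset coverage: occupancy
# anchors and mechanics tests
anchor_config <- function(...) {
  sim_config(lattice = reduced_lattice_config(nodes_per_thick = 20L,
                                              nodes_per_thin = 10L,
                                              half_sarcomere_length = 400),
             ...)
}

# total elastic energy of a lattice configuration, in pN nm — independent
# oracle for the force-balance solver (direct minimisation via optim)
lattice_energy <- function(lat, xk, xa, bound) {
  g <- lat$geom
  kin <- lat$config$kinetics
  en <- 0
  for (f in seq_len(g$n_thick)) {
    x <- xk[f, ]
    ext <- diff(c(0, x)) - g$thick_node_spacing
    en <- en + 0.5 * g$k_thick_seg * sum(ext^2)
    dl <- (g$half_sarcomere_length - x[g$nodes_per_thick]) - g$titin_rest
    en <- en + (g$titin_a / g$titin_b) * exp(g$titin_b * dl)
  }
  for (f in seq_len(g$n_thin)) {
    x <- xa[f, ]
    anchor <- g$half_sarcomere_length - g$thin_offset[f]
    ext <- diff(c(x, anchor)) - g$thin_node_spacing
    en <- en + 0.5 * g$k_thin_seg * sum(ext^2)
  }
  if (nrow(bound)) {
    na <- g$nodes_per_thin
    for (b in seq_len(nrow(bound))) {
      h <- bound$head[b]
      kf <- g$head_fil[h] + 1L; kn <- g$head_node[h] + 1L
      af <- (bound$site[b] - 1L) %/% na + 1L
      an <- (bound$site[b] - 1L) %% na + 1L
      dx <- xa[af, an] - xk[kf, kn]
      ge <- xb_geometry(dx, kin)
      u <- if (bound$strong[b]) ge$U_S else ge$U_W
      en <- en + u * kin$kT_pN_nm
    }
  }
  en
}

# minimise the total energy directly over all node positions (oracle)
minimize_energy <- function(lat, bound) {
  g <- lat$geom
  nk <- g$nodes_per_thick; na <- g$nodes_per_thin
  rest_k <- t(sapply(seq_len(g$n_thick), function(f)
    (seq_len(nk)) * g$thick_node_spacing))
  rest_a <- t(sapply(seq_len(g$n_thin), function(f)
    g$half_sarcomere_length - g$thin_offset[f] -
      (na - seq_len(na) + 1) * g$thin_node_spacing))
  pack <- function(xk, xa) c(as.numeric(xk), as.numeric(xa))
  unpack <- function(p) {
    list(xk = matrix(p[seq_len(g$n_thick * nk)], g$n_thick),
         xa = matrix(p[-seq_len(g$n_thick * nk)], g$n_thin))
  }
  obj <- function(p) {
    m <- unpack(p)
    lattice_energy(lat, m$xk, m$xa, bound)
  }
  fit <- optim(pack(rest_k, rest_a), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  unpack(fit$par)
}

# analytic toy corpus for CVAE unit tests: traces are a deterministic bump
# whose height / timing / width depend on three log-factors, plus noise.
# Cheap stand-in for the simulator when only the inference machinery is
# under test.
toy_corpus <- function(n = 400, T_len = 1000, noise = 0.3, seed = 5,
                       vary = c("rt12", "rt41", "rx16")) {
  fac <- sample_rate_factors(n, seed = seed, vary = vary)
  lf <- log10(fac[, vary, drop = FALSE])
  tt <- seq(0, 1, length.out = T_len)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1)
  traces <- matrix(0, n, T_len)
  for (i in seq_len(n)) {
    amp <- 2 + lf[i, 1] - 0.8 * lf[i, min(2, ncol(lf))]
    tp <- 0.15 + 0.05 * lf[i, min(3, ncol(lf))] + 0.02 * lf[i, min(2, ncol(lf))]
    w <- 0.08 * 10^(0.15 * lf[i, min(2, ncol(lf))])
    traces[i, ] <- amp * exp(-(tt - tp)^2 / (2 * w^2)) + rnorm(T_len, sd = noise)
  }
  structure(list(traces = traces, factors = fac,
                 log_bounds = attr(fac, "log_bounds"), vary = vary,
                 time = tt, seed = seed, replicates = 1L, active = TRUE,
                 freeze = NULL, standardized = FALSE, split = NULL),
            class = "twitch_dataset")
}

# small, quickly trainable CVAE configuration for unit tests
toy_cvae_config <- function(...) {
  args <- list(nz = 2L, m = 2L, conv = list(c(8L, 8L), c(5L, 8L), c(5L, 8L)),
               feat_width = 32L, head_width = 32L, batch_size = 128L,
               lr = 2e-3, epochs_flat = 2L, epochs_ramp = 4L,
               max_epochs = 10L, patience = 5L)
  args[names(list(...))] <- list(...)
  do.call(cvae_config, args)
}

# build a crossbridge rate matrix (1/ms) from the ten named cycle rates
xb_rate_matrix <- function(rr) {
  Q <- matrix(0, 6, 6)
  Q[1, 2] <- rr["rx12"]; Q[1, 6] <- rr["rx16"]
  Q[2, 1] <- rr["rx21"]; Q[2, 3] <- rr["rx23"]
  Q[3, 2] <- rr["rx32"]; Q[3, 4] <- rr["rx34"]
  Q[4, 3] <- rr["rx43"]; Q[4, 5] <- rr["rx45"]
  Q[5, 1] <- rr["rx51"]; Q[6, 1] <- rr["rx61"]
  diag(Q) <- -rowSums(Q)
  Q
}
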