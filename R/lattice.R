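#' Build the half-sarcomere filament lattice
#'
#' Instantiates the 3D spring-network geometry: four thick filaments on a
#' triangular transverse lattice (2 x 2 periodic cells) interleaved with eight
#' thin filaments at the trigonal positions, so that each thick filament sees
#' six thin neighbours and each thin filament three thick neighbours under the
#' periodic wrap. Thick filaments are anchored at the M-line (x = 0), thin
#' filaments at the Z-disc (x = half-sarcomere length); titin spans from each
#' thick filament free end to the Z-disc.
#'
#' Each thick-filament node (crown) carries `heads_per_node` myosin heads;
#' successive crowns rotate their head through the filament's thin-filament
#' neighbour list, mimicking the helical arrangement of crowns. Every thin
#' node is an actin binding site. Geometry is deterministic: a seed affects
#' only the kinetic sampling streams, never the lattice.
#'
#' @param config a [sim_config()] (or a [lattice_config()], in which case
#'   default kinetics are attached for mechanics evaluation).
#' @return an object of class `hs_lattice`: head/site tables, transverse
#'   coordinates, neighbour map and the flattened geometry passed to the
#'   mechanics core.
#' @export
hs_lattice <- function(config = sim_config()) {
  if (inherits(config, "lattice_config"))
    config <- sim_config(lattice = config)
  stopifnot(inherits(config, "sim_config"))
  lat <- config$lattice

  # transverse positions: thick on a triangular lattice (2x2 cells), thin at
  # the two trigonal points of each cell
  s <- lat$lattice_spacing
  a1 <- c(s, 0); a2 <- c(s / 2, s * sqrt(3) / 2)
  cells <- expand.grid(i = 0:1, j = 0:1)
  thick_xy <- t(apply(cells, 1, function(ij) ij[1] * a1 + ij[2] * a2))
  thin_xy <- rbind(
    t(apply(cells, 1, function(ij) (ij[1] + 2 / 3) * a1 + (ij[2] + 1 / 3) * a2)),
    t(apply(cells, 1, function(ij) (ij[1] + 1 / 3) * a1 + (ij[2] + 2 / 3) * a2)))
  # periodic wrap over the 2x2 supercell
  wrap_d <- function(p, q) {
    best <- Inf
    for (di in -1:1) for (dj in -1:1) {
      shift <- di * 2 * a1 + dj * 2 * a2
      d <- sqrt(sum((p - q - shift)^2))
      best <- min(best, d)
    }
    best
  }
  n_thick <- lat$n_thick; n_thin <- lat$n_thin
  if (nrow(thick_xy) != n_thick || nrow(thin_xy) != n_thin)
    stop("hs_lattice: transverse packing supports the default 4 thick / 8 thin geometry")
  ndist <- matrix(0, n_thick, n_thin)
  for (f in seq_len(n_thick)) for (g in seq_len(n_thin))
    ndist[f, g] <- wrap_d(thick_xy[f, ], thin_xy[g, ])
  # six nearest thin filaments per thick filament
  neighbours <- t(apply(ndist, 1, function(d) order(d)[1:6]))

  nk <- lat$nodes_per_thick; hp <- lat$heads_per_node
  head_fil <- rep(seq_len(n_thick), each = nk * hp)
  head_node <- rep(rep(seq_len(nk), each = hp), times = n_thick)
  head_slot <- rep(rep(seq_len(hp), times = nk), times = n_thick)
  head_thin <- integer(length(head_fil))
  for (h in seq_along(head_fil)) {
    ring <- neighbours[head_fil[h], ]
    head_thin[h] <- ring[((head_node[h] - 1) * hp + (head_slot[h] - 1)) %% 6 + 1]
  }

  thin_offset <- if (isTRUE(lat$thin_stagger)) {
    (seq_len(n_thin) - 1) / n_thin * lat$thin_node_spacing
  } else rep(0, n_thin)

  geom <- list(
    n_thick = n_thick, n_thin = n_thin,
    nodes_per_thick = nk, nodes_per_thin = lat$nodes_per_thin,
    heads_per_node = hp,
    thick_node_spacing = lat$thick_node_spacing,
    thin_node_spacing = lat$thin_node_spacing,
    k_thick_seg = lat$k_thick * lat$thick_repeat / lat$thick_node_spacing,
    k_thin_seg = lat$k_thin * lat$thin_repeat / lat$thin_node_spacing,
    half_sarcomere_length = lat$half_sarcomere_length,
    titin_rest = lat$titin_rest, titin_a = lat$titin_a,
    titin_b = lat$titin_b,
    thin_offset = thin_offset,
    head_fil = as.integer(head_fil - 1L),
    head_node = as.integer(head_node - 1L),
    head_thin = as.integer(head_thin - 1L))

  structure(list(config = config, geom = geom,
                 thick_xy = thick_xy, thin_xy = thin_xy,
                 neighbours = neighbours,
                 n_heads = length(head_fil),
                 n_sites = n_thin * lat$nodes_per_thin),
            class = "hs_lattice")
}

#' @export
print.hs_lattice <- function(x, ...) {
  cat(sprintf("Half-sarcomere lattice: %d thick + %d thin filaments, %d heads, %d sites\n",
              x$geom$n_thick, x$geom$n_thin, x$n_heads, x$n_sites))
  invisible(x)
}

#' Model cross-sectional area
#'
#' The transverse unit cell is the rhombus with vertices on the four thick
#' filaments (side = lattice spacing, angle 60 degrees); it contains one thick
#' and two thin filaments, and the model spans four such cells.
#'
#' @param config a [sim_config()] or [lattice_config()].
#' @return area in mm^2.
#' @export
hs_area <- function(config = sim_config()) {
  lat <- if (inherits(config, "sim_config")) config$lattice else config
  stopifnot(inherits(lat, "lattice_config"))
  s <- lat$lattice_spacing
  4 * s^2 * sin(pi / 3) * 1e-12  # nm^2 -> mm^2
}

#' Crossbridge spring energy
#'
#' Two-spring (linear + torsional) strain energy of a myosin head at polar
#' coordinates `(r, theta)` relative to its binding site, in kT:
#' `U = k_r (r - r_0)^2 / 2 + k_theta (theta - theta_0)^2 / 2`, with the rest
#' pair `(r_0, theta_0)` set by the weak or strong state.
#'
#' @param r lever length, nm (> 0).
#' @param theta lever angle, rad.
#' @param state `"weak"` or `"strong"`.
#' @param params a [kinetic_params()].
#' @return energy in kT (vectorised over `r`, `theta`).
#' @export
xb_energy <- function(r, theta, state = c("weak", "strong"),
                      params = kinetic_params()) {
  state <- match.arg(state)
  if (any(r <= 0)) stop("xb_energy: r must be positive")
  r0 <- if (state == "weak") params$r_W else params$r_S
  th0 <- if (state == "weak") params$theta_W else params$theta_S
  0.5 * params$k_r * (r - r0)^2 + 0.5 * params$k_theta * (theta - th0)^2
}

#' Crossbridge spring force components
#'
#' Gradient of [xb_energy()] in the two spring coordinates: the radial
#' component `k_r (r - r_0)` (kT/nm) and the torsional component
#' `k_theta (theta - theta_0)` (kT/rad).
#'
#' @inheritParams xb_energy
#' @return list with `radial` and `torsional` components.
#' @export
xb_force <- function(r, theta, state = c("weak", "strong"),
                     params = kinetic_params()) {
  state <- match.arg(state)
  if (any(r <= 0)) stop("xb_force: r must be positive")
  r0 <- if (state == "weak") params$r_W else params$r_S
  th0 <- if (state == "weak") params$theta_W else params$theta_S
  list(radial = params$k_r * (r - r0),
       torsional = params$k_theta * (theta - th0))
}

#' Titin passive force
#'
#' Exponential passive spring: `F = a exp(b dL)` with `dL` the titin extension
#' beyond its rest span.
#'
#' @param delta_L extension, nm (may be negative).
#' @param a force scale, pN.
#' @param b exponential constant, 1/nm.
#' @return force in pN, strictly positive and increasing in `delta_L`.
#' @export
titin_force <- function(delta_L, a = 220, b = 0.0045) {
  a * exp(b * delta_L)
}

#' Crossbridge geometry and energies at an axial offset
#'
#' Converts the axial head-to-site offset `dx` (site minus head, nm) at the
#' fixed radial span into lever coordinates `(r, theta)`, the weak and strong
#' strain energies (kT) and their axial derivatives (kT/nm; the axial force
#' components used by the strain-dependent rate laws).
#'
#' @param dx axial offsets, nm (vectorised).
#' @param params a [kinetic_params()].
#' @export
xb_geometry <- function(dx, params = kinetic_params()) {
  out <- cpp_xb_geometry(as.numeric(dx), unclass(params))
  as.data.frame(out)
}

#' Solve the isometric force balance
#'
#' Given a fixed set of bound crossbridges (head, site, weak/strong), solves
#' the axial equilibrium of every filament chain at fixed half-sarcomere
#' length and fixed radial spacing, by fixed-point iteration of per-filament
#' tridiagonal solves with the nonlinear crossbridge and titin loads
#' re-evaluated each pass.
#'
#' @param lattice an [hs_lattice()].
#' @param bound data frame with columns `head` (1-based head index within the
#'   lattice), `site` (1-based global site index), `strong` (logical); zero
#'   rows for the passive state.
#' @param tol convergence tolerance on node displacement, nm.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual.
#' @return list: node position matrices `xk`, `xa`; boundary forces (pN) at
#'   the Z-disc and M-line; per-head lever geometry for the bound set;
#'   iteration count.
#' @export
solve_balance <- function(lattice, bound = NULL, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(lattice, "hs_lattice"))
  g <- lattice$geom
  kin <- unclass(lattice$config$kinetics)
  if (is.null(bound) || nrow(bound) == 0) {
    bound <- data.frame(head = integer(), site = integer(), strong = logical())
  }
  na <- g$nodes_per_thin
  res <- cpp_solve_balance(
    g, kin,
    as.integer(bound$head - 1L),
    g$head_fil[bound$head], g$head_node[bound$head],
    as.integer((bound$site - 1L) %/% na),
    as.integer((bound$site - 1L) %% na),
    as.logical(bound$strong), tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("solve_balance: no convergence after %d iterations (residual %.3g nm)",
                 max_iter, res$residual))
  if (nrow(bound)) {
    kf <- g$head_fil[bound$head] + 1L
    kn <- g$head_node[bound$head] + 1L
    af <- (bound$site - 1L) %/% na + 1L
    an <- (bound$site - 1L) %% na + 1L
    dx <- res$xa[cbind(af, an)] - res$xk[cbind(kf, kn)]
    res$bound_geometry <- cbind(dx = dx,
                                as.data.frame(cpp_xb_geometry(dx, kin)))
  }
  res
}
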