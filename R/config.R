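#' Lattice geometry configuration
#'
#' Describes the elastic filament lattice of the half-sarcomere: four thick
#' filaments and eight thin filaments in a hexagonally packed, transversely
#' periodic box. Thick filaments are anchored at the M-line, thin filaments at
#' the Z-disc, and titin links each thick filament free end to the Z-disc.
#'
#' Filament stiffnesses are quoted per crystallographic repeat (43 nm thick,
#' 38.7 nm thin) and rescaled to the configured node spacing, so refining the
#' node grid leaves whole-filament compliance unchanged.
#'
#' @param n_thick,n_thin filament counts (the default geometry is 4 + 8).
#' @param nodes_per_thick,nodes_per_thin nodes (crowns / binding sites) per
#'   filament.
#' @param thick_repeat,thin_repeat stiffness-normalisation repeats, nm.
#' @param thick_node_spacing,thin_node_spacing axial node spacing, nm. Thick
#'   nodes are crowns (one per 14.3 nm); thin nodes are regulatory units
#'   (one troponin/tropomyosin target zone per 38.7 nm repeat).
#' @param thin_stagger stagger thin filament axial registers uniformly over
#'   one repeat (register disorder of the real lattice); deterministic.
#' @param k_thick,k_thin filament stiffness per repeat, pN/nm.
#' @param heads_per_node myosin heads per thick-filament node.
#' @param lattice_spacing centre-to-centre thick filament spacing, nm; sets
#'   the unit-cell cross-sectional area used for stress scaling.
#' @param half_sarcomere_length fixed (isometric) half-sarcomere length, nm.
#' @param titin_a,titin_b titin exponential-spring parameters (pN, 1/nm).
#' @param titin_rest titin rest span, nm; `NULL` means the gap between the
#'   thick filament free end and the Z-disc at rest.
#' @return object of class `lattice_config`.
#' @export
lattice_config <- function(n_thick = 4L, n_thin = 8L,
                           nodes_per_thick = 60L, nodes_per_thin = 30L,
                           thick_repeat = 43, thin_repeat = 38.7,
                           thick_node_spacing = 43 / 3,
                           thin_node_spacing = 38.7,
                           thin_stagger = TRUE,
                           k_thick = 2020, k_thin = 1743,
                           heads_per_node = 1L,
                           lattice_spacing = 42,
                           half_sarcomere_length = 1200,
                           titin_a = 220, titin_b = 0.0045,
                           titin_rest = NULL) {
  cfg <- list(n_thick = as.integer(n_thick), n_thin = as.integer(n_thin),
              nodes_per_thick = as.integer(nodes_per_thick),
              nodes_per_thin = as.integer(nodes_per_thin),
              thick_repeat = thick_repeat, thin_repeat = thin_repeat,
              thick_node_spacing = thick_node_spacing,
              thin_node_spacing = thin_node_spacing,
              k_thick = k_thick, k_thin = k_thin,
              heads_per_node = as.integer(heads_per_node),
              thin_stagger = isTRUE(thin_stagger),
              lattice_spacing = lattice_spacing,
              half_sarcomere_length = half_sarcomere_length,
              titin_a = titin_a, titin_b = titin_b)
  num <- c("thick_repeat", "thin_repeat", "thick_node_spacing",
           "thin_node_spacing", "k_thick", "k_thin", "lattice_spacing",
           "half_sarcomere_length", "titin_a", "titin_b")
  for (nm in num) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("lattice_config: `", nm, "` must be strictly positive")
  }
  for (nm in c("n_thick", "n_thin", "nodes_per_thick", "nodes_per_thin",
               "heads_per_node")) {
    if (cfg[[nm]] < 1L) stop("lattice_config: `", nm, "` must be >= 1")
  }
  thick_len <- cfg$nodes_per_thick * cfg$thick_node_spacing
  if (thick_len >= cfg$half_sarcomere_length)
    stop("lattice_config: thick filament longer than the half-sarcomere")
  cfg$titin_rest <- if (is.null(titin_rest))
    cfg$half_sarcomere_length - thick_len else titin_rest
  structure(cfg, class = "lattice_config")
}

#' Reduced lattice for fast simulation
#'
#' A short-filament version of the default geometry (same node spacings,
#' stiffness normalisation and transverse packing, fewer crowns and sites)
#' used for calibration checks and training-corpus generation where absolute
#' force magnitude is not the object of study.
#'
#' @param nodes_per_thick,nodes_per_thin nodes per filament.
#' @param ... passed to [lattice_config()].
#' @export
reduced_lattice_config <- function(nodes_per_thick = 6L, nodes_per_thin = 3L,
                                   ...) {
  args <- list(...)
  if (is.null(args$half_sarcomere_length))
    args$half_sarcomere_length <- nodes_per_thick * 43 / 3 + 34
  do.call(lattice_config, c(list(nodes_per_thick = nodes_per_thick,
                                 nodes_per_thin = nodes_per_thin), args))
}

#' Crossbridge and thin-filament kinetic parameters
#'
#' Baseline constants of the six-state crossbridge cycle (including SRX
#' exchange), the two-spring crossbridge mechanics, and the four-state thin
#' filament activation chain. Energies are in units of kT; rates in 1/ms
#' unless noted.
#'
#' The crossbridge states are 1 free (DRX, ATP), 2 loosely bound, 3
#' post-powerstroke, 4 rigor-like, 5 free (ADP), 6 super-relaxed (SRX).
#' Free energies are `G1`, `G2 = U_W + c2`, `G3 = U_S + c3`, `G4 = U_S + c4`,
#' with `U_W`, `U_S` the weak/strong two-spring strain energies. Reverse rates
#' follow detailed balance, `r_ji = r_ij exp(G_j - G_i)`, so the stationary
#' occupancies of a reversible pair obey the Boltzmann ratio
#' `pi_j / pi_i = exp(G_i - G_j)`.
#'
#' Two rate laws in the cycle admit more than one reading of their published
#' form; both are config-switchable. `rx34_variant = "strain"` gives
#' `D (1 + tanh(exp(-F_S)))` (bounded, decreasing in the axial strong-state
#' force `F_S`); `"kappa"` gives `D (1 + tanh(kappa F_S))`.
#' `rx45_variant = "detach"` gives `E max(0, U_S - dG_ATP + exp(-F_S))`
#' (ATP-induced detachment from rigor, fast and strain-accelerated);
#' `"printed"` keeps `E (U_S + dG_ATP + exp(-F_S))` clamped at zero.
#'
#' @param k_r,k_theta crossbridge linear (kT/nm^2) and torsional (kT/rad^2)
#'   spring stiffnesses.
#' @param r_W,r_S,theta_W,theta_S rest lengths (nm) and rest angles of the
#'   weak and strong states; the powerstroke shortens the lever (`r_S < r_W`).
#' @param theta_unit `"deg"` (default) or `"rad"` for the rest angles.
#' @param xb_span fixed radial distance bridged by a crossbridge, nm. The
#'   default is calibrated so that at maximal activation roughly 10% of heads
#'   are bound (see the methods vignette).
#' @param kT_pN_nm thermal energy used to convert kT-unit forces to pN.
#' @param G1,c2,c3,c4,dG_ATP free-energy offsets, kT.
#' @param tau,A,B,C,D,E,H crossbridge rate-law constants.
#' @param rx16,rx61_base,rx61_max DRX<->SRX exchange rates, 1/ms (the printed
#'   values are 50/s). `rx61` rises from `rx61_base` to `rx61_max` with
#'   calcium via a Hill function (`ca50`, `hill_b`).
#' @param rate_ceiling upper clip for crossbridge rates, 1/ms, keeping the
#'   rate matrix well conditioned near the steep strain walls.
#' @param rx34_variant,rx34_kappa,rx45_variant see Details.
#' @param rt12_coeff calcium association rate coefficient, 1/(M ms).
#' @param rt23,rt34,rt41 thin filament forward rates, 1/ms.
#' @param Kt1_coeff,Kt2,Kt3 equilibrium constants defining the reverse rates
#'   (`Kt1_coeff` per M; calcium cancels in `rt21`).
#' @param coop_factor nearest-neighbour boost of the activation-direction
#'   forward rates (x100).
#' @param coop_on_rt41 whether the boost also applies to the deactivating
#'   4->1 step (default `FALSE`).
#' @param coop_states site states (1-based) whose neighbours count as
#'   "calcium bound"; default `2:4`.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_r = 5, k_theta = 40,
                           r_W = 19.93, r_S = 16.4,
                           theta_W = 47.16, theta_S = 73.2,
                           theta_unit = c("deg", "rad"),
                           xb_span = 13.5, kT_pN_nm = 4.14,
                           G1 = -2.3, c2 = -4.3, c3 = -18.6, c4 = -20.72,
                           dG_ATP = -23,
                           tau = 7.2, A = 0.8, B = 5, C = 0.4,
                           D = 0.9, E = 1.2, H = 0.1,
                           rx16 = 0.05, rx61_base = 0.05, rx61_max = 0.5,
                           ca50 = 1e-6, hill_b = 4,
                           rate_ceiling = 1000,
                           rx34_variant = c("strain", "kappa"),
                           rx34_kappa = -0.2,
                           rx45_variant = c("detach", "printed"),
                           rt12_coeff = 37650, rt23 = 33.4, rt34 = 0.13,
                           rt41 = 0.77,
                           Kt1_coeff = 260000, Kt2 = 130, Kt3 = 0.91,
                           coop_factor = 100, coop_on_rt41 = FALSE,
                           coop_states = 2:4) {
  theta_unit <- match.arg(theta_unit)
  rx34_variant <- match.arg(rx34_variant)
  rx45_variant <- match.arg(rx45_variant)
  if (theta_unit == "deg") {
    theta_W <- theta_W * pi / 180
    theta_S <- theta_S * pi / 180
  }
  if (r_S >= r_W) stop("kinetic_params: the powerstroke must shorten the lever (r_S < r_W)")
  pos <- c(k_r = k_r, k_theta = k_theta, r_W = r_W, r_S = r_S,
           xb_span = xb_span, kT_pN_nm = kT_pN_nm, tau = tau, A = A,
           D = D, E = E, H = H, rate_ceiling = rate_ceiling,
           rt12_coeff = rt12_coeff, rt23 = rt23, rt34 = rt34, rt41 = rt41,
           Kt1_coeff = Kt1_coeff, Kt2 = Kt2, Kt3 = Kt3,
           coop_factor = coop_factor, ca50 = ca50, hill_b = hill_b)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) stop("kinetic_params: non-positive value for ", bad[1])
  if (rx16 < 0 || rx61_base < 0 || rx61_max < rx61_base)
    stop("kinetic_params: SRX rates must satisfy 0 <= rx61_base <= rx61_max")
  p <- list(k_r = k_r, k_theta = k_theta, r_W = r_W, r_S = r_S,
            theta_W = theta_W, theta_S = theta_S, xb_span = xb_span,
            kT_pN_nm = kT_pN_nm,
            G1 = G1, c2 = c2, c3 = c3, c4 = c4, dG_ATP = dG_ATP,
            tau = tau, A = A, B = B, C = C, D = D, E = E, H = H,
            rx16 = rx16, rx61_base = rx61_base, rx61_max = rx61_max,
            ca50 = ca50, hill_b = hill_b, rate_ceiling = rate_ceiling,
            rx34_variant = switch(rx34_variant, strain = 0L, kappa = 1L),
            rx34_kappa = rx34_kappa,
            rx45_variant = switch(rx45_variant, detach = 0L, printed = 1L),
            rt12_coeff = rt12_coeff, rt23 = rt23, rt34 = rt34, rt41 = rt41,
            Kt1_coeff = Kt1_coeff, Kt2 = Kt2, Kt3 = Kt3,
            coop_factor = coop_factor,
            coop_on_rt41 = as.integer(isTRUE(coop_on_rt41)),
            coop_state_lo = as.integer(min(coop_states)),
            coop_state_hi = as.integer(max(coop_states)))
  # axial offset minimizing the weak-state strain energy: used for pairing
  p$dx_star <- optimize(function(dx) xb_strain_energy(dx, p)$U_W,
                        c(0, p$r_W + 25))$minimum
  structure(p, class = "kinetic_params")
}

# weak/strong strain energies at axial offset dx with fixed radial span
xb_strain_energy <- function(dx, params) {
  r <- sqrt(params$xb_span^2 + dx^2)
  th <- atan2(params$xb_span, dx)
  list(r = r, theta = th,
       U_W = 0.5 * params$k_r * (r - params$r_W)^2 +
             0.5 * params$k_theta * (th - params$theta_W)^2,
       U_S = 0.5 * params$k_r * (r - params$r_S)^2 +
             0.5 * params$k_theta * (th - params$theta_S)^2)
}

#' Calcium transient parameters
#'
#' Parametric intracellular calcium transient
#' `ca(t) = ca_dia + (ca_sys - ca_dia) * g(t)` with the normalised shape
#' `g(t) = exp(-b (t^a - t_p)^2 / w^2)` rescaled so that `g = 0` at the
#' stimulus (`t = 0`) and `g = 1` at its peak (`t^a = t_p`). The asymmetry
#' exponent `a < 1` makes decay slower than the upstroke; the diastolic and
#' systolic concentrations are anchored by the pCa bounds.
#'
#' @param pca_dia,pca_sys diastolic and systolic pCa anchors.
#' @param a asymmetry exponent.
#' @param t_peak time to peak, s (converted internally to `t_p = t_peak^a`).
#' @param w width parameter (units of `s^a`).
#' @param b scale constant.
#' @return object of class `ca_params`.
#' @export
ca_params <- function(pca_dia = 7, pca_sys = 6, a = 0.25,
                      t_peak = 0.03, w = 0.15, b = 1) {
  if (pca_sys >= pca_dia)
    stop("ca_params: systolic pCa must be below diastolic pCa")
  if (a <= 0 || t_peak <= 0 || w <= 0 || b <= 0)
    stop("ca_params: shape parameters must be positive")
  structure(list(pca_dia = pca_dia, pca_sys = pca_sys, a = a,
                 t_peak = t_peak, t_p = t_peak^a, w = w, b = b),
            class = "ca_params")
}

#' Full simulation configuration
#'
#' Bundles the lattice geometry, kinetic constants and calcium transient, plus
#' the time grid (1 ms steps over 1 s by default).
#'
#' @param lattice a [lattice_config()].
#' @param kinetics a [kinetic_params()].
#' @param calcium a [ca_params()].
#' @param dt_ms time step, ms.
#' @param duration_s simulated span, s.
#' @param mech_tol,mech_max_iter force-balance fixed-point tolerance (nm) and
#'   iteration cap.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(lattice = lattice_config(),
                       kinetics = kinetic_params(),
                       calcium = ca_params(),
                       dt_ms = 1, duration_s = 1,
                       mech_tol = 1e-4, mech_max_iter = 100L) {
  stopifnot(inherits(lattice, "lattice_config"),
            inherits(kinetics, "kinetic_params"),
            inherits(calcium, "ca_params"),
            dt_ms > 0, duration_s > 0)
  structure(list(lattice = lattice, kinetics = kinetics, calcium = calcium,
                 dt_ms = dt_ms, duration_s = duration_s,
                 mech_tol = mech_tol, mech_max_iter = as.integer(mech_max_iter)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Half-sarcomere simulation configuration\n")
  cat(sprintf("  lattice: %d thick x %d nodes, %d thin x %d nodes, hsl %.0f nm\n",
              x$lattice$n_thick, x$lattice$nodes_per_thick,
              x$lattice$n_thin, x$lattice$nodes_per_thin,
              x$lattice$half_sarcomere_length))
  cat(sprintf("  time grid: %.0f ms over %.2f s\n",
              x$dt_ms, x$duration_s))
  cat(sprintf("  calcium: pCa %.1f -> %.1f, t_peak %.0f ms\n",
              x$calcium$pca_dia, x$calcium$pca_sys, 1000 * x$calcium$t_peak))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' Serialises a [sim_config()] to a YAML file and back. Only fields that
#' differ from the defaults need to be present in the file.
#'
#' @param path file path.
#' @param config a `sim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  plain <- list(
    lattice = unclass(config$lattice),
    kinetics = unclass(config$kinetics),
    calcium = unclass(config$calcium),
    dt_ms = config$dt_ms, duration_s = config$duration_s,
    mech_tol = config$mech_tol, mech_max_iter = config$mech_max_iter)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lat <- do.call(lattice_config, raw$lattice[names(raw$lattice) %in%
                                             names(formals(lattice_config))])
  kin_raw <- raw$kinetics
  # stored angles are radians and variants integers; restore directly
  kin <- kinetic_params()
  for (nm in names(kin_raw)) kin[[nm]] <- kin_raw[[nm]]
  kin$dx_star <- optimize(function(dx) xb_strain_energy(dx, kin)$U_W,
                          c(0, kin$r_W + 25))$minimum
  class(kin) <- "kinetic_params"
  calc <- do.call(ca_params, raw$calcium[names(raw$calcium) %in%
                                         names(formals(ca_params))])
  sim_config(lattice = lat, kinetics = kin, calcium = calc,
             dt_ms = raw$dt_ms %||% 1, duration_s = raw$duration_s %||% 1,
             mech_tol = raw$mech_tol %||% 1e-4,
             mech_max_iter = raw$mech_max_iter %||% 100L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
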