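#' Crossbridge cycle rates at a given strain
#'
#' Evaluates the full set of crossbridge transition rates (1/ms) at one or
#' more axial head-to-site offsets and a calcium concentration, with optional
#' rate-factor multipliers. Forward rates follow the strain-dependent laws
#' `rx12 = tau exp(-U_W)`, `rx23 = A (1 + tanh(B + C (U_W - U_S)))`, the
#' configured `rx34`/`rx45` variants, `rx51 = H`, plus the DRX<->SRX pair;
#' reverse rates are derived by detailed balance from the free energies, so
#' `rx21 = rx12 exp(G2 - G1)` etc. Structurally forbidden transitions
#' (`rx15`, `rx54`) are identically zero. All rates are clipped at the
#' configured ceiling.
#'
#' @param dx axial offsets, nm (vectorised).
#' @param ca calcium concentration, M (enters only `rx61`).
#' @param params a [kinetic_params()].
#' @param factors a [rate_factors()] vector (defaults to all 1).
#' @return matrix with one row per offset and the ten named rates.
#' @export
xb_cycle_rates <- function(dx, ca = 1e-7, params = kinetic_params(),
                           factors = rate_factors()) {
  factors <- rate_factors(factors)
  cpp_xb_rates(as.numeric(dx), ca, unclass(params),
               as.numeric(factors[c("rx12", "rx23", "rx34", "rx45", "rx16")]))
}

#' Forward crossbridge rates from energies
#'
#' The strain dependence of the cycle enters only through the weak/strong
#' strain energies and the axial strong-state force; this helper evaluates
#' the five forward rate laws directly from those quantities.
#'
#' @param U_W,U_S strain energies, kT.
#' @param F_S axial strong-state force, kT/nm.
#' @param params a [kinetic_params()].
#' @return named vector `rx12, rx23, rx34, rx45, rx51` in 1/ms.
#' @export
xb_forward_rates <- function(U_W, U_S, F_S, params = kinetic_params()) {
  stopifnot(is.finite(U_W), is.finite(U_S), is.finite(F_S))
  clip <- function(x) pmin(pmax(x, 0), params$rate_ceiling)
  rx12 <- clip(params$tau * exp(-U_W))
  rx23 <- clip(params$A * (1 + tanh(params$B + params$C * (U_W - U_S))))
  rx34 <- if (params$rx34_variant == 1L) {
    clip(params$D * (1 + tanh(params$rx34_kappa * F_S)))
  } else {
    clip(params$D * (1 + tanh(exp(-pmin(F_S, 30)))))
  }
  rx45 <- if (params$rx45_variant == 1L) {
    clip(params$E * pmax(0, U_S + params$dG_ATP + exp(-pmin(F_S, 7))))
  } else {
    clip(params$E * pmax(0, U_S - params$dG_ATP + exp(-pmin(F_S, 7))))
  }
  c(rx12 = rx12, rx23 = rx23, rx34 = rx34, rx45 = rx45, rx51 = clip(params$H))
}

#' Detailed-balance reverse rate
#'
#' `r_ji = r_ij exp(G_j - G_i)`, so the stationary occupancies of an isolated
#' reversible pair satisfy the Boltzmann ratio
#' `pi_j / pi_i = r_ij / r_ji = exp(G_i - G_j)` (the lower free-energy state
#' is favoured).
#'
#' @param r_fwd forward rate (>= 0).
#' @param G_i,G_j free energies of the source and destination states, kT.
#' @return reverse rate, same units as `r_fwd`.
#' @export
reverse_rate <- function(r_fwd, G_i, G_j) {
  if (any(r_fwd < 0)) stop("reverse_rate: forward rate must be non-negative")
  r_fwd * exp(G_j - G_i)
}

#' DRX/SRX exchange rates
#'
#' `rx16` (DRX -> SRX) is calcium independent; `rx61` rises from its resting
#' baseline to `rx61_max` with a Hill dependence on calcium, so that in
#' resting muscle the two rates are equal (50/s each) and the SRX pool holds
#' about half the heads.
#'
#' @param ca calcium concentration, M (vectorised).
#' @param params a [kinetic_params()].
#' @return matrix with columns `rx16`, `rx61` in 1/ms.
#' @export
srx_rates <- function(ca, params = kinetic_params()) {
  stopifnot(all(ca > 0))
  cb <- ca^params$hill_b
  rx61 <- params$rx61_base + (params$rx61_max - params$rx61_base) *
    cb / (params$ca50^params$hill_b + cb)
  cbind(rx16 = rep(params$rx16, length(ca)), rx61 = rx61)
}

#' Thin filament activation rates
#'
#' Forward and reverse rates (1/ms) of the four-state activation chain at a
#' calcium concentration. `rt12` is proportional to calcium; reverse rates
#' derive from the printed equilibrium constants (`rt21 = rt12 / (Kt1 [Ca])`,
#' in which calcium cancels; `rt32 = rt23 / Kt2`; `rt43 = rt34 / Kt3`);
#' `rt41` is forward-only (`rt14 = 0`). With an activated nearest neighbour
#' the activation-direction forward rates are multiplied by the cooperativity
#' factor (x100), reverse rates unchanged.
#'
#' @param ca calcium concentration, M.
#' @param neighbor_active logical cooperativity flag.
#' @param params a [kinetic_params()].
#' @param factors a [rate_factors()] vector.
#' @return named vector `rt12, rt21, rt23, rt32, rt34, rt43, rt41`.
#' @export
thin_rates <- function(ca, neighbor_active = FALSE,
                       params = kinetic_params(),
                       factors = rate_factors()) {
  stopifnot(ca > 0)
  factors <- rate_factors(factors)
  cpp_thin_rates(ca, isTRUE(neighbor_active), unclass(params),
                 as.numeric(factors[c("rt12", "rt23", "rt34", "rt41")]))
}

#' Parametric calcium transient
#'
#' Evaluates the transient of [ca_params()] on a time grid. The concentration
#' is bounded between the diastolic and systolic anchors, equals the
#' diastolic level at the stimulus and peaks exactly where the shape
#' exponent vanishes (`t^a = t_p`).
#'
#' @param t time, s (vectorised; typically in `[0, 1]`).
#' @param params a [ca_params()].
#' @return data frame with `t`, `ca` (M) and `pca`.
#' @export
ca_transient <- function(t, params = ca_params()) {
  g <- exp(-params$b * (t^params$a - params$t_p)^2 / params$w^2)
  g0 <- exp(-params$b * (0 - params$t_p)^2 / params$w^2)
  gn <- pmin(1, pmax(0, (g - g0) / (1 - g0)))
  ca_dia <- 10^(-params$pca_dia)
  ca_sys <- 10^(-params$pca_sys)
  ca <- ca_dia + (ca_sys - ca_dia) * gn
  if (any(!is.finite(ca)))
    stop("ca_transient: parameters produce a non-finite transient")
  data.frame(t = t, ca = ca, pca = -log10(ca))
}

#' Fit the calcium transient shape to a measured trace
#'
#' Least-squares recovery of the three shape parameters (asymmetry `a`, time
#' to peak, width) from a sampled transient, holding the pCa anchors fixed.
#' Mirrors the workflow of calibrating the model transient against a
#' ratiometric measurement whose absolute scale is anchored separately.
#'
#' @param t time, s.
#' @param ca measured concentration, M.
#' @param params starting values, a [ca_params()].
#' @return fitted [ca_params()].
#' @export
fit_ca_transient <- function(t, ca, params = ca_params()) {
  obj <- function(p) {
    pr <- tryCatch(ca_params(pca_dia = params$pca_dia,
                             pca_sys = params$pca_sys,
                             a = p[1], t_peak = p[2], w = p[3],
                             b = params$b),
                   error = function(e) NULL)
    if (is.null(pr)) return(1e12)
    sum((ca_transient(t, pr)$ca - ca)^2)
  }
  fit <- optim(c(params$a, params$t_peak, params$w), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  ca_params(pca_dia = params$pca_dia, pca_sys = params$pca_sys,
            a = fit$par[1], t_peak = fit$par[2], w = fit$par[3],
            b = params$b)
}

#' Rate factor vector
#'
#' The nine multiplicative factors applied to the baseline rates
#' (`rx12, rx23, rx34, rx45, rx16, rt12, rt23, rt34, rt41`), the inference
#' target. Factors live in the prior box `[0.1, 100]` and are handled on the
#' log10 scale throughout the inference machinery.
#'
#' @param x named numeric vector (missing names default to 1), a single value
#'   recycled to all nine, or an existing `rate_factors` object.
#' @param check_bounds enforce the prior box.
#' @return named numeric vector of class `rate_factors`.
#' @export
rate_factors <- function(x = NULL, check_bounds = TRUE) {
  out <- setNames(rep(1, length(FACTOR_NAMES)), FACTOR_NAMES)
  if (!is.null(x)) {
    if (length(x) == 1 && is.null(names(x))) {
      out[] <- x
    } else if (is.null(names(x))) {
      if (length(x) != length(FACTOR_NAMES))
        stop("rate_factors: unnamed input must have length 9")
      out[] <- x
    } else {
      bad <- setdiff(names(x), FACTOR_NAMES)
      if (length(bad)) stop("rate_factors: unknown rate name ", bad[1])
      out[names(x)] <- x
    }
  }
  if (any(!is.finite(out)) || any(out <= 0))
    stop("rate_factors: factors must be strictly positive")
  if (check_bounds && (any(out < 0.1 - 1e-12) || any(out > 100 + 1e-9)))
    stop("rate_factors: factors must lie in the prior range [0.1, 100]")
  structure(out, class = c("rate_factors", "numeric"))
}

#' Apply rate factors to named baseline rates
#'
#' Multiplies each named baseline rate by its factor; rates without a factor
#' are untouched. Derived reverse rates inherit the scaled forward rate
#' through the detailed-balance / equilibrium-constant formulas, which is how
#' the simulator applies them internally.
#'
#' @param base named numeric vector of baseline rates.
#' @param factors a [rate_factors()] vector.
#' @return scaled named vector.
#' @export
apply_rate_factors <- function(base, factors = rate_factors()) {
  factors <- rate_factors(factors)
  stopifnot(!is.null(names(base)))
  hit <- intersect(names(base), names(factors))
  base[hit] <- base[hit] * as.numeric(factors[hit])
  base
}

#' Plot the cycle rates against axial head-site separation
#'
#' Strain dependence of the crossbridge forward and reverse rates across the
#' axial offset range, on a log rate axis, at a fixed calcium concentration
#' (the DRX/SRX pair is flat in strain but calcium dependent).
#'
#' @param params a [kinetic_params()].
#' @param ca calcium concentration, M (default pCa 4).
#' @param dx axial offset grid, nm.
#' @param factors a [rate_factors()] vector.
#' @export
plot_rate_curves <- function(params = kinetic_params(), ca = 1e-4,
                             dx = seq(0, 30, by = 0.1),
                             factors = rate_factors()) {
  rr <- xb_cycle_rates(dx, ca, params, factors)
  keep <- colnames(rr)
  matplot(dx, pmax(rr, 1e-8), type = "l", lty = 1, log = "y",
          col = seq_along(keep), xlab = "axial separation (nm)",
          ylab = "rate (1/ms)")
  legend("topright", keep, lty = 1, col = seq_along(keep),
         bty = "n", cex = 0.7, ncol = 2)
  invisible(rr)
}
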