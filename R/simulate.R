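#' Simulate an isometric twitch
#'
#' Runs the calcium-driven half-sarcomere simulation: states are initialized
#' from the per-head and per-site stationary distributions at the resting
#' calcium level, then at every time step the transition rates are evaluated
#' at the current geometry and calcium, converted to transition probabilities
#' through the matrix exponential, sampled, and the elastic force balance is
#' re-solved. The Z-disc boundary force divided by the model cross-sectional
#' area gives stress in mN/mm^2.
#'
#' @param factors a [rate_factors()] vector (all 1 for the baseline model).
#' @param config a [sim_config()] (or an [hs_lattice()] to reuse a built
#'   lattice).
#' @param seed integer seed; with identical `(factors, config, seed)` the
#'   trace is bit-reproducible.
#' @param replicates number of independent replicates averaged into the
#'   returned trace (their seeds derive deterministically from `seed`).
#' @param ca optional explicit calcium vector (M, one entry per step),
#'   overriding the configured transient — e.g. a held constant level.
#' @param log_states record per-step state occupancy counts (averaged over
#'   replicates).
#' @return a `twitch_trace`: data frame with `time` (s), `stress` (total,
#'   mN/mm^2), `active_stress` (passive baseline subtracted) and `ca` (M),
#'   with metadata in attributes (`factors`, `seed`, `replicates`,
#'   `passive_stress`, and `occupancy` when logged).
#' @export
simulate_twitch <- function(factors = rate_factors(), config = sim_config(),
                            seed = 1L, replicates = 1L, ca = NULL,
                            log_states = FALSE) {
  lattice <- if (inherits(config, "hs_lattice")) config else hs_lattice(config)
  config <- lattice$config
  factors <- rate_factors(factors)
  if (is.null(ca)) {
    tgrid <- seq(0, config$duration_s - config$dt_ms / 1000,
                 by = config$dt_ms / 1000)
    ca <- ca_transient(tgrid, config$calcium)$ca
  } else {
    tgrid <- (seq_along(ca) - 1) * config$dt_ms / 1000
  }
  stopifnot(replicates >= 1)
  res <- cpp_simulate(lattice$geom, unclass(config$kinetics),
                      as.numeric(factors), as.numeric(ca), config$dt_ms,
                      as.integer(replicates), as.numeric(seed),
                      isTRUE(log_states), FALSE,
                      config$mech_tol, config$mech_max_iter)
  # boundary force is in pN; area in mm^2; 1 pN = 1e-9 mN
  scale <- 1e-9 / hs_area(config)
  passive <- res$passive_force * scale
  out <- data.frame(time = tgrid,
                    stress = res$force_mean * scale,
                    active_stress = res$force_mean * scale - passive,
                    ca = ca)
  attr(out, "factors") <- factors
  attr(out, "seed") <- seed
  attr(out, "replicates") <- as.integer(replicates)
  attr(out, "passive_stress") <- passive
  attr(out, "n_heads") <- res$n_heads
  attr(out, "n_sites") <- res$n_sites
  if (log_states) {
    attr(out, "occupancy") <- list(
      crossbridge = res$xb_counts / res$n_heads,
      thin = res$site_counts / res$n_sites)
  }
  class(out) <- c("twitch_trace", "data.frame")
  out
}

#' Average independent twitch replicates
#'
#' Pointwise mean of `n` independently seeded twitches at one rate-factor
#' combination — the unit of the training corpus (the reference protocol
#' averages 50).
#'
#' @inheritParams simulate_twitch
#' @param n replicate count (default 50).
#' @export
average_replicates <- function(factors = rate_factors(),
                               config = sim_config(), n = 50L, seed = 1L,
                               ...) {
  simulate_twitch(factors = factors, config = config, seed = seed,
                  replicates = n, ...)
}

#' @export
print.twitch_trace <- function(x, ...) {
  cat(sprintf("Isometric twitch: %d points, dt %.3g s, %d replicate(s)\n",
              nrow(x), diff(x$time[1:2]), attr(x, "replicates")))
  cat(sprintf("  peak active stress %.2f mN/mm^2 (passive %.2f)\n",
              max(x$active_stress), attr(x, "passive_stress")))
  invisible(x)
}

#' @export
plot.twitch_trace <- function(x, active = TRUE, ...) {
  y <- if (active) x$active_stress else x$stress
  plot(x$time, y, type = "l", xlab = "time (s)",
       ylab = if (active) "active stress (mN/mm²)" else "stress (mN/mm²)",
       ...)
  invisible(x)
}

#' Twitch summary statistics
#'
#' Peak stress, time to peak, time to 50% of peak on the rise and time to 50%
#' relaxation, all relative to the start of activation (the stimulus at
#' t = 0), with linear interpolation between samples. Computed on the
#' baseline-subtracted (active) stress by default.
#'
#' @param trace a `twitch_trace` (or any data frame with `time` and a stress
#'   column).
#' @param active use `active_stress` rather than total stress.
#' @return object of class `twitch_summary`: `peak_stress` (mN/mm^2),
#'   `t_peak`, `t50_rising`, `t50_falling` (ms).
#' @export
twitch_summary <- function(trace, active = TRUE) {
  y <- if (active && !is.null(trace$active_stress)) trace$active_stress
       else trace$stress
  t_ms <- trace$time * 1000
  peak <- max(y)
  if (!is.finite(peak) || peak <= 0 || sd(y) == 0)
    stop("twitch_summary: trace has no positive excursion (no twitch)")
  ip <- which.max(y)
  half <- peak / 2
  cross_up <- which(y[-1] >= half & y[-length(y)] < half)
  cross_up <- cross_up[cross_up < ip]
  if (!length(cross_up))
    stop("twitch_summary: no rising half-peak crossing (no twitch)")
  i <- cross_up[1]
  t50r <- t_ms[i] + (half - y[i]) / (y[i + 1] - y[i]) * (t_ms[i + 1] - t_ms[i])
  cross_dn <- which(y[-1] < half & y[-length(y)] >= half)
  cross_dn <- cross_dn[cross_dn >= ip]
  t50f <- if (length(cross_dn)) {
    j <- cross_dn[1]
    t_ms[j] + (y[j] - half) / (y[j] - y[j + 1]) * (t_ms[j + 1] - t_ms[j])
  } else NA_real_
  structure(list(peak_stress = peak, t_peak = t_ms[ip],
                 t50_rising = t50r, t50_falling = t50f),
            class = "twitch_summary")
}

#' @export
print.twitch_summary <- function(x, ...) {
  cat(sprintf("peak stress %.2f mN/mm^2 | t_peak %.1f ms | t50 rise %.1f ms | t50 fall %.1f ms\n",
              x$peak_stress, x$t_peak, x$t50_rising, x$t50_falling))
  invisible(x)
}

#' State occupancy fractions over time
#'
#' Per-step occupancy fractions of the six crossbridge states and four thin
#' filament states from a simulation run with `log_states = TRUE`. Fractions
#' sum to one at every step; the bound fraction aggregates states 2-4 and the
#' SRX fraction is state 6.
#'
#' @param trace a `twitch_trace` simulated with `log_states = TRUE`.
#' @return list with matrices `crossbridge` (T x 6) and `thin` (T x 4), plus
#'   convenience vectors `bound` and `srx`.
#' @export
state_occupancy <- function(trace) {
  occ <- attr(trace, "occupancy")
  if (is.null(occ))
    stop("state_occupancy: simulation was run without state logging ",
         "(set log_states = TRUE)")
  list(crossbridge = occ$crossbridge, thin = occ$thin,
       bound = rowSums(occ$crossbridge[, 2:4, drop = FALSE]),
       srx = occ$crossbridge[, 6])
}

#' Write / read a twitch trace as delimited text
#'
#' Two-column (plus calcium) tab-separated file with a `# key: value`
#' metadata header sufficient to regenerate the trace.
#'
#' @param trace a `twitch_trace`.
#' @param path file path.
#' @export
write_twitch <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fac <- attr(trace, "factors")
  writeLines(c(
    sprintf("# factors: %s", paste(sprintf("%s=%g", names(fac), fac),
                                   collapse = " ")),
    sprintf("# seed: %s", attr(trace, "seed")),
    sprintf("# replicates: %d", attr(trace, "replicates")),
    sprintf("# passive_stress: %.10g", attr(trace, "passive_stress"))), con)
  write.table(as.data.frame(trace)[, c("time", "stress", "active_stress")],
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_twitch
#' @export
read_twitch <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: *", "", kv)
  }
  if (!is.null(meta$factors)) {
    parts <- strsplit(strsplit(meta$factors, " +")[[1]], "=")
    fac <- setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                    vapply(parts, `[`, "", 1))
    attr(df, "factors") <- rate_factors(fac)
  }
  if (!is.null(meta$seed)) attr(df, "seed") <- as.numeric(meta$seed)
  if (!is.null(meta$replicates))
    attr(df, "replicates") <- as.integer(meta$replicates)
  if (!is.null(meta$passive_stress))
    attr(df, "passive_stress") <- as.numeric(meta$passive_stress)
  class(df) <- c("twitch_trace", "data.frame")
  df
}
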