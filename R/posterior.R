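#' Probability-probability calibration curve
#'
#' For every validation record the marginal posterior CDF is evaluated at the
#' true factor (the fraction of posterior samples below the truth, with
#' randomized tie-breaking); the PP curve is the empirical CDF of those
#' values across records. A perfectly calibrated estimator gives the
#' diagonal: the truth falls inside the X% credible region X% of the time.
#' Points above the diagonal indicate under-confidence, below it
#' over-confidence.
#'
#' @param model a fitted [cvae()].
#' @param dataset a split `twitch_dataset`; its validation records are used
#'   (standardized internally with the model's training statistics).
#' @param n_samples posterior draws per record.
#' @param levels grid of claimed credible levels.
#' @param seed RNG seed.
#' @param records optional cap on the number of validation records.
#' @return object of class `pp_curve`: list with `levels`, per-factor
#'   `coverage` matrix, and the raw per-record CDF values (`u`).
#' @export
pp_curve <- function(model, dataset, n_samples = 1000L,
                     levels = seq(0, 1, by = 0.02), seed = 1L,
                     records = NULL) {
  stopifnot(inherits(model, "cvae"), inherits(dataset, "twitch_dataset"))
  if (is.null(dataset$split)) stop("pp_curve: dataset has no validation split")
  va <- which(dataset$split == "validation")
  if (!length(va)) stop("pp_curve: empty validation set")
  if (!is.null(records)) va <- va[seq_len(min(records, length(va)))]
  std <- dataset$standardized
  u <- matrix(NA_real_, length(va), length(model$vary),
              dimnames = list(NULL, model$vary))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (i in seq_along(va)) {
    tr <- dataset$traces[va[i], ]
    if (std) tr <- unstandardize_trace(tr, dataset$stats)
    ps <- predict(model, as.numeric(tr), n = n_samples,
                  seed = cpp_record_seed(seed, i))
    truth <- log10(dataset$factors[va[i], model$vary])
    for (j in seq_along(model$vary)) {
      s <- ps[, j]
      u[i, j] <- (sum(s < truth[j]) + runif(1) * sum(s == truth[j])) /
        length(s)
    }
  }
  coverage <- apply(u, 2, function(col)
    vapply(levels, function(l) mean(col <= l), 0))
  structure(list(levels = levels, coverage = coverage, u = u,
                 n_records = length(va)),
            class = "pp_curve")
}

#' @export
print.pp_curve <- function(x, ...) {
  dev <- apply(abs(x$coverage - x$levels), 2, max)
  cat(sprintf("PP calibration over %d validation records\n", x$n_records))
  cat("  max |coverage - level| per factor:\n")
  print(round(dev, 3))
  invisible(x)
}

#' @export
plot.pp_curve <- function(x, ...) {
  matplot(x$levels, x$coverage, type = "l", lty = 1,
          xlab = "claimed credible level",
          ylab = "empirical coverage", ...)
  abline(0, 1, lty = 2)
  legend("topleft", colnames(x$coverage), lty = 1,
         col = seq_len(ncol(x$coverage)), bty = "n")
  invisible(x)
}

#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' The classical two-sample KS distance between per-factor posterior samples,
#' signed by which empirical CDF is larger at the maximising point: negative
#' when the reference ("control") CDF is the smaller one there. Large |KS|
#' flags the factors that differ most between two conditions.
#'
#' @param samples_a reference (control) samples: `posterior_samples`, matrix
#'   or vector.
#' @param samples_b comparison samples.
#' @return named vector of signed statistics in `[-1, 1]`, one per shared
#'   column (single unnamed value for vector input).
#' @export
signed_ks <- function(samples_a, samples_b) {
  one <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    Fa <- ecdf(a)(xs)
    Fb <- ecdf(b)(xs)
    i <- which.max(abs(Fa - Fb))
    Fa[i] - Fb[i]
  }
  if (is.null(dim(samples_a))) return(one(as.numeric(samples_a),
                                          as.numeric(samples_b)))
  shared <- intersect(colnames(samples_a), colnames(samples_b))
  if (!length(shared)) stop("signed_ks: no shared factor columns")
  vapply(shared, function(nm) one(samples_a[, nm], samples_b[, nm]), 0)
}

#' Corner summary of a posterior sample
#'
#' Numeric companion of the corner plot: per-factor 1-D kernel density
#' estimates and marginal modes, all pairwise 2-D kernel densities, and the
#' joint peak — the draw with maximal product-Gaussian KDE density (Scott's
#' bandwidth on the log10 scale), refined by a few mean-shift ascent steps.
#'
#' @param samples a `posterior_samples` (n x d, log10 scale; n >= 100).
#' @param grid_n grid size for the densities.
#' @return object of class `corner_summary`: `peak` (named log10 vector and
#'   `peak_factors` on the natural scale), `marginal_modes`, `marginals`
#'   (list of density objects), `pairs` (list of 2-D KDE grids).
#' @export
corner_summary <- function(samples, grid_n = 64) {
  X <- unclass(samples)
  if (is.null(dim(X)) || nrow(X) < 100)
    stop("corner_summary: need at least 100 posterior draws")
  d <- ncol(X); n <- nrow(X)
  nms <- colnames(X)
  sdv <- apply(X, 2, sd)
  degenerate <- sdv < 1e-12
  if (any(degenerate))
    warning("corner_summary: degenerate (zero-variance) dimension(s): ",
            paste(nms[degenerate], collapse = ", "))
  h <- ifelse(degenerate, 1e-6, sdv * n^(-1 / (d + 4)))  # Scott's rule

  # joint KDE density at each sample (product Gaussian kernel)
  dens <- numeric(n)
  Xs <- sweep(X, 2, h, "/")
  for (i in seq_len(n)) {
    dl <- -0.5 * rowSums(sweep(Xs, 2, Xs[i, ], "-")^2)
    dens[i] <- nn_logsumexp(matrix(dl, 1))
  }
  peak <- X[which.max(dens), ]
  # mean-shift refinement on the same kernel
  for (it in 1:10) {
    w <- exp(-0.5 * rowSums(sweep(Xs, 2, peak / h, "-")^2))
    new <- colSums(X * w) / sum(w)
    if (max(abs(new - peak)) < 1e-8) break
    peak <- new
  }
  names(peak) <- nms

  marginals <- lapply(seq_len(d), function(j)
    if (degenerate[j]) NULL else density(X[, j]))
  names(marginals) <- nms
  modes <- vapply(seq_len(d), function(j) {
    if (degenerate[j]) return(X[1, j])
    md <- marginals[[j]]
    md$x[which.max(md$y)]
  }, 0)
  names(modes) <- nms

  pairs <- list()
  if (d >= 2) {
    for (a in 1:(d - 1)) for (b in (a + 1):d) {
      if (degenerate[a] || degenerate[b]) next
      pairs[[paste(nms[a], nms[b], sep = ":")]] <-
        MASS::kde2d(X[, a], X[, b], n = grid_n)
    }
  }
  structure(list(peak = peak, peak_factors = 10^peak,
                 marginal_modes = modes, marginals = marginals,
                 pairs = pairs, degenerate = degenerate),
            class = "corner_summary")
}

#' @export
print.corner_summary <- function(x, ...) {
  cat("Posterior peak (rate factors, natural scale):\n")
  print(round(x$peak_factors, 4))
  cat("Marginal modes (log10):\n")
  print(round(x$marginal_modes, 3))
  invisible(x)
}

#' Corner plot of a posterior sample
#'
#' Grid of pairwise 2-D kernel density contours (lower triangle) and 1-D
#' marginals (diagonal) on log10 axes spanning the prior box, with the joint
#' peak marked.
#'
#' @param x a `posterior_samples`.
#' @param truth optional named log10 vector marked on the panels.
#' @param ... unused.
#' @export
plot.posterior_samples <- function(x, truth = NULL, ...) {
  cs <- corner_summary(x)
  X <- unclass(x)
  d <- ncol(X); nms <- colnames(X)
  lb <- attr(x, "log_bounds")
  lims <- if (is.null(lb)) matrix(c(-1, 2), 2, d) else lb
  op <- par(mfrow = c(d, d), mar = c(2, 2, 0.5, 0.5), oma = c(2, 2, 0, 0))
  on.exit(par(op))
  for (i in 1:d) for (j in 1:d) {
    if (j > i) { plot.new(); next }
    if (i == j) {
      md <- cs$marginals[[i]]
      if (is.null(md)) plot.new()
      else {
        plot(md, main = "", xlab = "", ylab = "", xlim = lims[, i])
        abline(v = cs$peak[i], col = "darkgreen")
        if (!is.null(truth)) abline(v = truth[nms[i]], col = "red", lty = 2)
      }
    } else {
      kd <- cs$pairs[[paste(nms[j], nms[i], sep = ":")]]
      plot(X[, j], X[, i], pch = ".", col = "grey60",
           xlim = lims[, j], ylim = lims[, i], xlab = "", ylab = "")
      if (!is.null(kd)) contour(kd, add = TRUE, drawlabels = FALSE)
      points(cs$peak[j], cs$peak[i], pch = 19, col = "darkgreen")
      if (!is.null(truth))
        points(truth[nms[j]], truth[nms[i]], pch = 19, col = "red")
    }
    if (i == d) mtext(nms[j], 1, line = 2, cex = 0.7)
    if (j == 1) mtext(nms[i], 2, line = 2, cex = 0.7)
  }
  invisible(cs)
}

#' Build hybrid rate factors
#'
#' Replaces the named coordinates of a control factor combination with the
#' values inferred for a variant — e.g. grafting the calcium-affinity rates
#' (`rt12`, `rt41`) of a desensitized variant onto an otherwise-control
#' parameter set. Simulating the result gives the "hybrid" twitch.
#'
#' @param control_peak control [rate_factors()] (e.g. a posterior peak).
#' @param variant_peak variant factors supplying the swapped coordinates.
#' @param swap names to take from the variant (default the two
#'   calcium-affinity rates).
#' @export
hybrid_factors <- function(control_peak, variant_peak,
                           swap = c("rt12", "rt41")) {
  control <- rate_factors(control_peak, check_bounds = FALSE)
  variant <- rate_factors(variant_peak, check_bounds = FALSE)
  bad <- setdiff(swap, FACTOR_NAMES)
  if (length(bad)) stop("hybrid_factors: unknown rate name ", bad[1])
  control[swap] <- variant[swap]
  rate_factors(control, check_bounds = FALSE)
}

#' Thick-filament intervention inference
#'
#' The therapeutic-intervention workflow: freeze the thin filament rate
#' factors at a given (e.g. hybrid) combination, train a reduced CVAE over
#' the remaining thick filament factors on a corpus generated with those
#' rates frozen, infer the posterior conditioned on a target (control)
#' twitch, and simulate the posterior peak as the proposed intervention.
#'
#' @param hybrid a [rate_factors()] vector supplying the frozen coordinates.
#' @param target_trace the target twitch the intervention should reproduce.
#' @param thick_names factors allowed to vary (default the five thick
#'   filament rates).
#' @param config a [sim_config()] used for corpus generation and the final
#'   simulation.
#' @param n_combos,replicates corpus size.
#' @param cvae_cfg a [cvae_config()].
#' @param center centre the varied prior box on the hybrid values.
#' @param n posterior sample size.
#' @param seed master seed.
#' @param dataset optionally reuse a pre-generated frozen corpus (its frozen
#'   set must match).
#' @return list: `posterior` (samples over thick factors), `peak` (full
#'   9-vector with frozen thin rates), `intervention` (simulated twitch at
#'   the peak), `model`, `dataset`.
#' @export
infer_intervention <- function(hybrid, target_trace,
                               thick_names = c("rx12", "rx23", "rx34",
                                               "rx45", "rx16"),
                               config = sim_config(),
                               n_combos = 500L, replicates = 8L,
                               cvae_cfg = cvae_config(),
                               center = FALSE, n = 5000L, seed = 1L,
                               dataset = NULL) {
  hybrid <- rate_factors(hybrid, check_bounds = FALSE)
  if (!length(thick_names)) {
    # nothing left to infer: the intervention is the input itself
    tw <- simulate_twitch(hybrid, config = config, seed = seed,
                          replicates = replicates)
    return(list(posterior = NULL, peak = hybrid, intervention = tw,
                model = NULL, dataset = NULL))
  }
  frozen_names <- setdiff(FACTOR_NAMES, thick_names)
  freeze <- as.numeric(hybrid[frozen_names])
  names(freeze) <- frozen_names
  if (is.null(dataset)) {
    dataset <- generate_dataset(n_combos, config = config,
                                replicates = replicates, seed = seed,
                                vary = thick_names, freeze = freeze,
                                center = if (center) hybrid else NULL)
  } else {
    if (is.null(dataset$freeze) ||
        !identical(sort(names(dataset$freeze)), sort(frozen_names)) ||
        any(abs(dataset$freeze[frozen_names] - freeze) > 1e-9))
      stop("infer_intervention: dataset frozen set does not match the request")
  }
  dataset <- split_dataset(dataset, max(0.05, 1 / nrow(dataset$traces)),
                           seed = seed)
  dataset <- standardize_dataset(dataset)
  model <- cvae(dataset, cvae_cfg)
  post <- predict(model, target_trace, n = n, seed = seed)
  cs <- corner_summary(post)
  peak <- hybrid
  peak[thick_names] <- cs$peak_factors[thick_names]
  tw <- simulate_twitch(rate_factors(peak, check_bounds = FALSE),
                        config = config, seed = seed,
                        replicates = replicates)
  list(posterior = post, peak = peak, intervention = tw,
       model = model, dataset = dataset)
}
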