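#' Sample rate factors from the log-uniform prior
#'
#' Draws i.i.d. multiplicative rate factors from a log-uniform distribution
#' over the prior box (default `(0.1, 100)` per coordinate). Coordinates can
#' be frozen at fixed values, and the box can be recentred on a supplied
#' factor combination (same log width, shifted, clipped to the global range),
#' which is how reduced / intervention-focused corpora are drawn.
#'
#' @param n number of draws.
#' @param bounds length-2 prior range for every varied coordinate.
#' @param seed integer seed (R RNG stream; reproducible).
#' @param vary names of varied coordinates (default all nine).
#' @param freeze named vector of coordinates held fixed at given values.
#' @param center optional named factor vector on which to centre the varied
#'   box (geometric centre of `bounds` maps to `center`).
#' @return n x 9 matrix of factors (natural scale), one [rate_factors()] row
#'   each; attributes `log_bounds` (2 x 9 matrix of per-coordinate log10
#'   bounds) and `vary`.
#' @export
sample_rate_factors <- function(n, bounds = c(0.1, 100), seed = 1L,
                                vary = FACTOR_NAMES, freeze = NULL,
                                center = NULL) {
  if (n < 1) stop("sample_rate_factors: n must be >= 1")
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop("sample_rate_factors: invalid bounds")
  vary <- match.arg(vary, FACTOR_NAMES, several.ok = TRUE)
  if (!is.null(freeze)) {
    bad <- setdiff(names(freeze), FACTOR_NAMES)
    if (length(bad)) stop("sample_rate_factors: unknown frozen name ", bad[1])
    vary <- setdiff(vary, names(freeze))
  }
  lb <- matrix(rep(log10(bounds), length(FACTOR_NAMES)), nrow = 2,
               dimnames = list(c("lo", "hi"), FACTOR_NAMES))
  if (!is.null(center)) {
    center <- rate_factors(center)
    mid <- mean(log10(bounds))
    for (nm in vary) {
      shift <- log10(center[[nm]]) - mid
      lo <- max(log10(0.1), lb["lo", nm] + shift)
      hi <- min(log10(100), lb["hi", nm] + shift)
      lb[, nm] <- c(lo, hi)
    }
  }
  out <- matrix(1, n, length(FACTOR_NAMES),
                dimnames = list(NULL, FACTOR_NAMES))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (nm in vary)
    out[, nm] <- 10^runif(n, lb["lo", nm], lb["hi", nm])
  if (!is.null(freeze)) for (nm in names(freeze)) out[, nm] <- freeze[[nm]]
  attr(out, "log_bounds") <- lb
  attr(out, "vary") <- vary
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# fold an arbitrary numeric seed into the valid integer range
as_seed_int <- function(x) as.integer(abs(as.numeric(x)) %% 2147483646) + 1L

#' Derived per-record simulation seed
#'
#' Deterministic hash of (master seed, record index): every record of a
#' corpus can be regenerated standalone, bit-identically, without running the
#' whole batch.
#'
#' @param master_seed corpus master seed.
#' @param index record index (1-based).
#' @return numeric seed.
#' @export
record_seed <- function(master_seed, index) {
  vapply(index, function(i) cpp_record_seed(as.numeric(master_seed),
                                            as.numeric(i)), 0)
}

#' Generate a training corpus of (rate factors, mean twitch) pairs
#'
#' For each sampled factor combination, simulates `replicates` independent
#' twitches and stores their pointwise mean stress trace. Record `i` uses the
#' derived seed [record_seed()]`(seed, i)`, so generation is embarrassingly
#' parallel and resumable: any subset of records can be (re)computed
#' independently and is bit-identical to the batch result.
#'
#' @param n_combos number of factor combinations.
#' @param config a [sim_config()].
#' @param replicates twitches averaged per record (reference protocol: 50).
#' @param seed master seed (drives both factor sampling and simulation).
#' @param vary,freeze,center passed to [sample_rate_factors()].
#' @param active store baseline-subtracted (active) stress.
#' @param progress print progress every 500 records.
#' @return a `twitch_dataset`: list with `traces` (n x T matrix, mN/mm^2),
#'   `factors` (n x 9, natural scale), `log_bounds`, `vary`, `time`, and
#'   generation metadata. Unstandardized; see [standardize_dataset()].
#' @export
generate_dataset <- function(n_combos, config = sim_config(),
                             replicates = 50L, seed = 1L,
                             vary = FACTOR_NAMES, freeze = NULL,
                             center = NULL, active = TRUE,
                             progress = FALSE) {
  stopifnot(n_combos >= 1)
  lattice <- hs_lattice(config)
  fac <- sample_rate_factors(n_combos, seed = seed, vary = vary,
                             freeze = freeze, center = center)
  tgrid <- seq(0, config$duration_s - config$dt_ms / 1000,
               by = config$dt_ms / 1000)
  ca <- ca_transient(tgrid, config$calcium)$ca
  traces <- matrix(NA_real_, n_combos, length(tgrid))
  for (i in seq_len(n_combos)) {
    tw <- simulate_twitch(rate_factors(fac[i, ]), config = lattice,
                          seed = record_seed(seed, i),
                          replicates = replicates, ca = ca)
    traces[i, ] <- if (active) tw$active_stress else tw$stress
    if (progress && i %% 500 == 0)
      message(sprintf("generate_dataset: %d / %d", i, n_combos))
  }
  structure(list(traces = traces, factors = fac,
                 log_bounds = attr(fac, "log_bounds"),
                 vary = attr(fac, "vary"),
                 time = tgrid, seed = seed,
                 replicates = as.integer(replicates),
                 active = active, freeze = freeze,
                 standardized = FALSE, split = NULL),
            class = "twitch_dataset")
}

#' @export
print.twitch_dataset <- function(x, ...) {
  cat(sprintf("Twitch corpus: %d records x %d timepoints, %d replicate(s) each\n",
              nrow(x$traces), ncol(x$traces), x$replicates))
  cat(sprintf("  varied factors: %s\n", paste(x$vary, collapse = ", ")))
  if (!is.null(x$freeze))
    cat(sprintf("  frozen: %s\n",
                paste(sprintf("%s=%g", names(x$freeze), x$freeze),
                      collapse = ", ")))
  cat(sprintf("  standardized: %s | split: %s\n", x$standardized,
              if (is.null(x$split)) "none" else
                sprintf("%d train / %d validation", sum(x$split == "train"),
                        sum(x$split == "validation"))))
  invisible(x)
}

#' Train/validation split
#'
#' Seed-reproducible disjoint and exhaustive split; the default validation
#' fraction is 1%.
#'
#' @param dataset a `twitch_dataset`.
#' @param validation_fraction fraction held out (0 < f < 1).
#' @param seed integer seed.
#' @export
split_dataset <- function(dataset, validation_fraction = 0.01, seed = 1L) {
  stopifnot(inherits(dataset, "twitch_dataset"))
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("split_dataset: validation fraction must lie in (0, 1)")
  n <- nrow(dataset$traces)
  n_val <- max(1L, round(n * validation_fraction))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  val <- sample.int(n, n_val)
  dataset$split <- rep("train", n)
  dataset$split[val] <- "validation"
  dataset
}

#' Standardize a corpus with training-split statistics
#'
#' Subtracts the global mean and divides by the global standard deviation of
#' the *training* traces (scalar statistics over all training timepoints, or
#' per-timepoint vectors), and maps factors to the unit box via the prior
#' log10 bounds. The stored statistics are the ones applied to validation
#' records and to any inference-time target trace — never their own.
#'
#' @param dataset a split `twitch_dataset` (an unsplit corpus is treated as
#'   all-training).
#' @param per_timepoint use per-timepoint mean/sd vectors instead of scalars.
#' @return the dataset with standardized `traces`, `factors_unit`, and stored
#'   `stats`.
#' @export
standardize_dataset <- function(dataset, per_timepoint = FALSE) {
  stopifnot(inherits(dataset, "twitch_dataset"))
  if (dataset$standardized) return(dataset)
  tr_idx <- if (is.null(dataset$split)) seq_len(nrow(dataset$traces))
            else which(dataset$split == "train")
  if (!length(tr_idx)) stop("standardize_dataset: empty training split")
  tr <- dataset$traces[tr_idx, , drop = FALSE]
  if (per_timepoint) {
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, sd)
  } else {
    mu <- mean(tr)
    sdv <- sd(as.numeric(tr))
  }
  if (any(sdv == 0) || any(!is.finite(sdv)))
    stop("standardize_dataset: zero-variance traces cannot be standardized")
  dataset$traces <- standardize_trace(dataset$traces,
                                      list(mean = mu, sd = sdv))
  dataset$factors_unit <- factors_to_unit(dataset$factors, dataset$log_bounds)
  dataset$stats <- list(mean = mu, sd = sdv, per_timepoint = per_timepoint)
  dataset$standardized <- TRUE
  dataset
}

#' Apply / invert stored standardization statistics
#'
#' @param x trace matrix (or vector).
#' @param stats list with `mean` and `sd` (scalars or per-timepoint vectors).
#' @export
standardize_trace <- function(x, stats) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' @rdname standardize_trace
#' @export
unstandardize_trace <- function(x, stats) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  sweep(sweep(x, 2, stats$sd, "*"), 2, stats$mean, "+")
}

# factors (natural scale) -> unit box via per-coordinate log10 bounds
factors_to_unit <- function(factors, log_bounds) {
  out <- log10(factors)
  for (nm in colnames(out)) {
    lo <- log_bounds["lo", nm]; hi <- log_bounds["hi", nm]
    out[, nm] <- if (hi > lo) (out[, nm] - lo) / (hi - lo) else 0.5
  }
  out
}

unit_to_factors <- function(unit, log_bounds) {
  out <- unit
  for (nm in colnames(out)) {
    lo <- log_bounds["lo", nm]; hi <- log_bounds["hi", nm]
    out[, nm] <- 10^(lo + out[, nm] * (hi - lo))
  }
  out
}

#' Persist a corpus
#'
#' Single-file native serialization of the dataset object (traces, factors,
#' split labels, statistics, provenance); [export_record()] writes any single
#' record back out as a plain twitch TSV.
#'
#' @param dataset a `twitch_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "twitch_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- readRDS(path)
  stopifnot(inherits(out, "twitch_dataset"))
  out
}

#' @rdname write_dataset
#' @param index record index.
#' @export
export_record <- function(dataset, index, path) {
  stopifnot(inherits(dataset, "twitch_dataset"),
            index >= 1, index <= nrow(dataset$traces))
  if (dataset$standardized)
    stop("export_record: export records before standardization")
  df <- data.frame(time = dataset$time,
                   stress = dataset$traces[index, ],
                   active_stress = dataset$traces[index, ])
  attr(df, "factors") <- rate_factors(dataset$factors[index, ])
  attr(df, "seed") <- record_seed(dataset$seed, index)
  attr(df, "replicates") <- dataset$replicates
  attr(df, "passive_stress") <- 0
  class(df) <- c("twitch_trace", "data.frame")
  write_twitch(df, path)
}
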