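#' Build a CTMC rate matrix
#'
#' Assembles a rate matrix Q from non-negative off-diagonal transition rates,
#' setting each diagonal entry so that the row sums to zero (conservation).
#'
#' @param rates square matrix of off-diagonal rates (diagonal ignored), 1/ms.
#' @return matrix Q with zero row sums.
#' @export
rate_matrix <- function(rates) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rate_matrix: rates must be square")
  off <- rates; diag(off) <- 0
  if (any(off < 0)) stop("rate_matrix: negative transition rate")
  Q <- off
  diag(Q) <- -rowSums(off)
  Q
}

#' Transition probabilities over a time step
#'
#' `P = expm(Q dt)` via scaling-and-squaring with a Pade approximant. P is
#' stochastic for any admissible Q and dt: rows sum to one, `dt = 0` gives
#' the identity, and multi-step paths through intermediate states get
#' non-zero probability even where the direct rate is zero.
#'
#' @param Q rate matrix (zero row sums).
#' @param dt time step, ms (>= 0).
#' @return stochastic matrix P.
#' @export
transition_matrix <- function(Q, dt) {
  Q <- as.matrix(Q)
  if (any(!is.finite(Q))) stop("transition_matrix: non-finite rate matrix")
  if (dt < 0) stop("transition_matrix: dt must be non-negative")
  if (max(abs(rowSums(Q))) > 1e-8 * max(1, max(abs(Q))))
    stop("transition_matrix: rows of Q must sum to zero")
  cpp_expm(Q, dt)
}

#' Sample a state transition
#'
#' Cumulative inversion of one row of a stochastic matrix: the new state is
#' the first index at which the running row sum exceeds the uniform draw
#' (ascending state order). Deterministic given `(P, state, u)`.
#'
#' @param P stochastic matrix.
#' @param state current state index (1-based).
#' @param u uniform draw in `[0, 1)`.
#' @return new state index.
#' @export
sample_transition <- function(P, state, u) {
  if (u < 0 || u >= 1) stop("sample_transition: u must lie in [0, 1)")
  cs <- cumsum(P[state, ])
  new <- which(u < cs)[1]
  if (is.na(new)) new <- ncol(P)
  new
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`. Used to initialize head and site states
#' at the resting calcium concentration; equals any row of
#' `transition_matrix(Q, dt)` in the large-dt limit. If Q is reducible the
#' stationary distribution is not unique; the closed communicating classes
#' are then detected and an equal-weight mixture of their stationary
#' distributions is returned with a warning.
#'
#' @param Q rate matrix.
#' @return probability vector `pi` with `pi %*% Q = 0`.
#' @export
stationary_distribution <- function(Q) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  # reachability on the directed graph of positive rates
  adj <- Q > 0; diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0 | reach
  classes <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (classes[i] == 0L) {
      cl <- cl + 1L
      mutual <- which(reach[i, ] & reach[, i])
      classes[mutual] <- cl
    }
  }
  closed <- vapply(seq_len(cl), function(c) {
    members <- which(classes == c)
    !any(Q[members, -members, drop = FALSE] > 0)
  }, logical(1))
  if (sum(closed) > 1L) {
    warning("stationary_distribution: reducible rate matrix; ",
            "returning an equal-weight mixture over its closed classes")
    pi <- numeric(n)
    for (c in which(closed)) {
      members <- which(classes == c)
      pi[members] <- cpp_stationary(Q[members, members, drop = FALSE]) /
        sum(closed)
    }
    return(pi)
  }
  as.numeric(cpp_stationary(Q))
}
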