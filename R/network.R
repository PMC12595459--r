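#' Construct a synaptic state from a factor tensor
#'
#' A `synaptic_state` bundles the N x N x z nonnegative factor tensor `u`
#' (entry `u[i, j, k]` is component `k` of the connection from neuron `j` to
#' neuron `i`), the derived weight matrix `w_ij = prod_k u_ijk`, and the
#' per-neuron inhibitory currents. The factor tensor is the source of truth;
#' weights are materialized on demand with [state_weights()]. Component
#' `k = 1` is the volatile plasticity tag targeted by synaptic noise.
#'
#' @param u N x N x z array (or N x N matrix for z = 1) of nonnegative factors.
#' @param I_inh length-N vector of nonnegative inhibitory currents.
#' @return An object of class `synaptic_state` with elements `u`, `I_inh`,
#'   `N`, `z`.
#' @export
synaptic_state <- function(u, I_inh) {
  if (is.matrix(u)) u <- array(u, dim = c(dim(u), 1L))
  if (length(dim(u)) != 3L || dim(u)[1] != dim(u)[2])
    stop_input("u must be an N x N x z array")
  if (any(u < 0)) stop_input("factors must be nonnegative")
  N <- dim(u)[1]
  if (length(I_inh) != N) stop_input("I_inh must have length N")
  if (any(I_inh < 0)) stop_input("I_inh must be nonnegative")
  for (k in seq_len(dim(u)[3])) diag(u[, , k]) <- 0
  structure(list(u = u, I_inh = as.numeric(I_inh), N = N, z = dim(u)[3]),
            class = "synaptic_state")
}

# Build an aligned state (u_ijk = w^(1/z)) from a weight matrix.
state_from_weights <- function(w, I_inh, z = 1L) {
  if (any(w < 0)) stop_input("weights must be nonnegative")
  z <- as.integer(z)
  u <- array(w^(1 / z), dim = c(nrow(w), ncol(w), z))
  synaptic_state(u, I_inh)
}

#' @export
print.synaptic_state <- function(x, ...) {
  w <- state_weights(x)
  cat(sprintf("synaptic_state: N = %d neurons, z = %d factor(s), density = %.3f\n",
              x$N, x$z, connection_density(x)))
  cat(sprintf("  mean live weight = %.4g, mean I_inh = %.4g\n",
              mean(w[w > 0]), mean(x$I_inh)))
  invisible(x)
}

#' Materialize the weight matrix from a factor tensor
#'
#' Computes `w_ij = prod_k u_ijk` (elementwise product over the component
#' axis). A zero in any component zeroes the weight: a pruned component
#' removes the whole connection.
#'
#' @param u an N x N x z factor array, an N x N matrix (z = 1), or a
#'   `synaptic_state`.
#' @return The N x N nonnegative weight matrix with zero diagonal.
#' @export
weights_from_factors <- function(u) {
  if (inherits(u, "synaptic_state")) u <- u$u
  if (is.matrix(u)) u <- array(u, dim = c(dim(u), 1L))
  if (any(u < 0)) stop_input("factors must be nonnegative")
  w <- u[, , 1L]
  z <- dim(u)[3]
  if (z > 1L) for (k in 2:z) w <- w * u[, , k]
  w
}

#' @rdname weights_from_factors
#' @param state a `synaptic_state`.
#' @export
state_weights <- function(state) weights_from_factors(state$u)

#' One synchronous update of the network dynamics
#'
#' All neurons update in parallel: `I'_i = sum_j w_ij s_j - I_inh_i`, and
#' `s'_i = 1` iff `I'_i > 0` (strict threshold, so a zero input leaves the
#' neuron silent).
#'
#' @param s length-N binary state vector.
#' @param state a `synaptic_state`.
#' @return A list with the new binary state `s` and input currents `I`.
#' @export
update_step <- function(s, state) {
  stopifnot(inherits(state, "synaptic_state"))
  if (length(s) != state$N) stop_input("state vector has wrong length")
  I <- as.numeric(state_weights(state) %*% s) - state$I_inh
  list(s = as.numeric(I > 0), I = I)
}

#' Run recall dynamics from a cue
#'
#' Iterates [update_step()] for `steps` synchronous sweeps starting from the
#' cue (the cue is applied once, then the network evolves freely).
#'
#' @param state a `synaptic_state`.
#' @param cue length-N binary vector.
#' @param steps number of update steps (>= 1).
#' @return A list with `S`, a `(steps + 1) x N` matrix of states (first row is
#'   the cue), and `I`, a `steps x N` matrix of input currents.
#' @export
recall <- function(state, cue, steps = 10L) {
  if (steps < 1) stop_input("steps must be >= 1")
  w <- state_weights(state)
  N <- state$N
  S <- matrix(0, steps + 1L, N)
  Im <- matrix(0, steps, N)
  S[1L, ] <- cue
  s <- as.numeric(cue)
  for (t in seq_len(steps)) {
    I <- as.numeric(w %*% s) - state$I_inh
    s <- as.numeric(I > 0)
    S[t + 1L, ] <- s
    Im[t, ] <- I
  }
  list(S = S, I = Im)
}

#' Centered overlap between a network state and a pattern
#'
#' `m = sum_i (s_i - f)(xi_i - f) / (N f (1 - f))`, so that `m = 1` for a
#' perfect recall at `f = 0.5` and `m ~ 0` for states unrelated to the
#' pattern.
#'
#' @param s binary state vector.
#' @param xi binary target pattern.
#' @param f coding level used for centering, in (0, 1) exclusive.
#' @return A similarity score in `[-1, 1]` (for `f = 0.5`).
#' @export
overlap <- function(s, xi, f) {
  if (length(s) != length(xi)) stop_input("s and xi must have equal length")
  if (f <= 0 || f >= 1) stop_input("overlap undefined for degenerate coding level")
  sum((s - f) * (xi - f)) / (length(s) * f * (1 - f))
}

#' Fraction of live connections
#'
#' @param state a `synaptic_state` (or weight matrix).
#' @param floor relative pruning floor: a weight counts as live when it
#'   exceeds `floor` times the mean positive weight.
#' @return Fraction of off-diagonal weights above the floor.
#' @export
connection_density <- function(state, floor = 1e-3) {
  w <- if (inherits(state, "synaptic_state")) state_weights(state) else state
  off <- w[row(w) != col(w)]
  pos <- off[off > 0]
  if (length(pos) == 0) return(0)
  mean(off > floor * mean(pos))
}
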