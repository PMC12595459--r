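#' Generate a set of random binary activity patterns
#'
#' Draws `M` patterns over `N` neurons with i.i.d. Bernoulli(`f`) entries.
#' Each pattern is one row of the returned matrix; entry `(mu, i)` is 1 when
#' neuron `i` is active in pattern `mu`. The coding level `f` is the
#' probability that a neuron is active and is restricted to `0 < f <= 0.5`
#' (sparse or balanced codes).
#'
#' @param N number of neurons (>= 2).
#' @param M number of patterns (>= 1).
#' @param f coding level, in (0, 0.5].
#' @param seed integer seed; the same seed always yields the same set.
#' @return An object of class `pattern_set`: a list with elements `xi`
#'   (M x N binary matrix), `N`, `M`, `f`, `alpha = M/N` and `seed`.
#' @examples
#' p <- generate_patterns(N = 100, M = 10, f = 0.5, seed = 1)
#' p$alpha
#' @export
generate_patterns <- function(N, M, f, seed = NULL) {
  if (!is.numeric(N) || N < 2) stop_input("N must be >= 2")
  if (!is.numeric(M) || M < 1) stop_input("M must be >= 1")
  if (!is.numeric(f) || f <= 0 || f > 0.5)
    stop_input("coding level f must satisfy 0 < f <= 0.5")
  N <- as.integer(N); M <- as.integer(M)
  xi <- with_seed(seed, matrix(as.numeric(stats::runif(M * N) < f), M, N))
  pattern_set(xi, f, seed = seed)
}

#' Construct a pattern set from an existing binary matrix
#'
#' @param xi M x N matrix with entries in {0, 1} (rows are patterns).
#' @param f coding level the patterns were drawn at.
#' @param seed optional seed recorded as metadata.
#' @return A `pattern_set` object.
#' @export
pattern_set <- function(xi, f, seed = NULL) {
  xi <- as.matrix(xi)
  if (!all(xi %in% c(0, 1))) stop_input("pattern entries must be 0 or 1")
  if (!is.numeric(f) || f <= 0 || f > 0.5)
    stop_input("coding level f must satisfy 0 < f <= 0.5")
  structure(
    list(xi = xi, N = ncol(xi), M = nrow(xi), f = f,
         alpha = nrow(xi) / ncol(xi), seed = seed),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: M = %d patterns, N = %d neurons, f = %g, alpha = %.3f\n",
              x$M, x$N, x$f, x$alpha))
  invisible(x)
}

#' Imprint patterns as fixed points with a nonnegative Hebbian rule
#'
#' One-shot autoassociative storage emulating wake-phase learning: weights are
#' set with a clipped covariance rule,
#' `w_ij = (1/N) * max(0, sum_mu (xi_i - f)(xi_j - f))`, autapses are removed
#' (`w_ii = 0`), and each neuron's inhibitory current is placed at the
#' midpoint between its lowest "active" input and highest "silent" input
#' across patterns, so that every pattern is a (fragile) fixed point whenever
#' such a separating threshold exists. The weight is then factorized into `z`
#' aligned subsynaptic components `u_ijk = w_ij^(1/z)`.
#'
#' Patterns that cannot be stabilized by this rule (no separating threshold
#' for some neuron) are reported via a warning and recorded in the
#' `"stability"` attribute; they are not silently accepted.
#'
#' @param patterns a `pattern_set`.
#' @param z number of multiplicative synaptic components (>= 1).
#' @return A `synaptic_state` whose attribute `"stability"` holds the
#'   M x N stability report at creation time.
#' @seealso [stability_report()], [misalign_factors()]
#' @export
imprint_patterns <- function(patterns, z = 1L) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (z < 1) stop_input("z must be >= 1")
  xi <- patterns$xi
  N <- patterns$N
  cxi <- xi - patterns$f
  w <- pmax(crossprod(cxi), 0) / N   # N x N, Sum_mu (xi_i - f)(xi_j - f), clipped
  diag(w) <- 0
  I_inh <- fit_thresholds(w, patterns)
  state <- state_from_weights(w, I_inh, z = z)
  rep <- stability_report(state, patterns)
  n_bad <- sum(!rep)
  if (n_bad > 0)
    warning(sprintf("imprinting left %d pattern-neuron conditions unstable (load may exceed the imprinting rule's capacity)", n_bad))
  attr(state, "stability") <- rep
  state
}

# Midpoint threshold rule: for each neuron, I_inh between the lowest input
# among patterns where the neuron is active and the highest input among
# patterns where it is silent. Falls back gracefully when a neuron is active
# (or silent) in every pattern, and returns a nonnegative vector.
fit_thresholds <- function(w, patterns) {
  xi <- patterns$xi
  h <- w %*% t(xi)                       # N x M inputs per pattern
  N <- nrow(h)
  on <- t(xi) == 1                       # N x M
  I_inh <- numeric(N)
  for (i in seq_len(N)) {
    hi <- h[i, ]
    min_on <- suppressWarnings(min(hi[on[i, ]]))
    max_off <- suppressWarnings(max(hi[!on[i, ]]))
    I_inh[i] <-
      if (!is.finite(min_on)) max_off + max(max_off, 1) * 1e-6  # never active
      else if (!is.finite(max_off)) min_on / 2                  # always active
      else (min_on + max_off) / 2
  }
  pmax(I_inh, 0)
}

#' Check which stored patterns are fixed points of the dynamics
#'
#' Applies one synchronous update step starting from each pattern and compares
#' the result with the pattern itself, using the strict-threshold convention
#' (a neuron fires only when its input exceeds zero).
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set`.
#' @return An M x N logical matrix; entry `(mu, i)` is `TRUE` when neuron `i`
#'   reproduces its target state in pattern `mu`.
#' @export
stability_report <- function(state, patterns) {
  stopifnot(inherits(state, "synaptic_state"), inherits(patterns, "pattern_set"))
  if (state$N != patterns$N) stop_input("state and patterns disagree on N")
  w <- state_weights(state)
  I <- w %*% t(patterns$xi) - state$I_inh   # N x M
  t(I > 0) == (patterns$xi == 1)
}

#' Randomly misalign the subsynaptic factors of a state
#'
#' Multiplies every factor independently by a log-normal variate,
#' `u_ijk <- u_ijk * exp(eps)`, `eps ~ N(0, sdlog^2)`, so the components of a
#' synapse no longer agree. Weights change accordingly; inhibitory thresholds
#' are refit with the midpoint rule so that patterns remain fixed points where
#' possible. Used to probe the emergent re-alignment of factors during
#' consolidation.
#'
#' @param state a `synaptic_state`.
#' @param patterns the stored `pattern_set` (for threshold refitting).
#' @param sdlog standard deviation of the log-perturbation.
#' @param seed integer seed.
#' @return A `synaptic_state` with misaligned factors.
#' @export
misalign_factors <- function(state, patterns, sdlog = 0.5, seed = NULL) {
  stopifnot(inherits(state, "synaptic_state"))
  u <- state$u
  live <- u > 0
  u[live] <- with_seed(seed,
    u[live] * exp(stats::rnorm(sum(live), sd = sdlog)))
  out <- synaptic_state(u, state$I_inh)
  out$I_inh <- fit_thresholds(state_weights(out), patterns)
  out
}
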