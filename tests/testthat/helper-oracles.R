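# Independent max-margin oracles for tiny per-neuron problems, solved in the
# dual (dimension = number of patterns), kept fully separate from the
# package's consolidation path.
#
# Problem: max over w >= 0, th >= 0 of  min_mu y_mu (w.xi_mu - th) / ||w||
# with y_mu = 2 xi_i^mu - 1 and the autapse column removed.

# Given w, the optimal threshold is the midpoint between the lowest "on"
# input and the highest "off" input (1-D exact maximization).
.kappa_of_w <- function(xi, y, w, norm) {
  if (all(w <= 0)) return(-Inf)
  h <- drop(xi %*% w)
  on <- y > 0
  min_on <- if (any(on)) min(h[on]) else Inf
  max_off <- if (any(!on)) max(h[!on]) else -Inf
  th <- if (!is.finite(min_on)) max(max_off, 0) + 1
        else if (!is.finite(max_off)) max(min_on / 2, 0)
        else max((min_on + max_off) / 2, 0)
  den <- if (norm == "l2") sqrt(sum(w^2)) else sum(w)
  min(y * (h - th)) / den
}

# L2 max margin via the concave dual
#   g(alpha) = sum(a) - 0.5 ||[sum_mu a y xi]_+||^2 - [(-y'a)_+]^2 / (2 eps)
# maximized with multi-start L-BFGS-B; primal w = [sum a y xi]_+.
l2_margin_oracle <- function(xi, y) {
  M <- nrow(xi)
  Xy <- xi * y
  starts <- c(list(rep(0.1, M), rep(1, M), rep(5, M)),
              lapply(1:8, function(s) {
                set.seed(s); stats::runif(M, 0, 4)
              }))
  best_k <- -Inf; best_w <- NULL
  for (eps in c(1e-3, 1e-5, 1e-7)) for (a0 in starts) {
    o <- stats::optim(a0,
      function(a) {
        v <- drop(crossprod(Xy, a)); s <- -sum(a * y)
        -(sum(a) - 0.5 * sum(pmax(v, 0)^2) - max(s, 0)^2 / (2 * eps))
      },
      function(a) {
        v <- drop(crossprod(Xy, a)); s <- -sum(a * y)
        -(1 - drop(Xy %*% pmax(v, 0)) + (max(s, 0) / eps) * y)
      },
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = 20000, factr = 1e2))
    w <- pmax(drop(crossprod(Xy, o$par)), 0)
    k <- .kappa_of_w(xi, y, w, "l2")
    if (k > best_k) { best_k <- k; best_w <- w }
  }
  list(kappa = best_k, w = best_w)
}

# L1 max margin: the dual is the LP
#   max sum(a)  s.t.  a >= 0, y'a >= 0, (xi y)' a <= 1 per weight,
# solved exactly by enumerating vertices of the M-dimensional feasible set.
l1_margin_oracle <- function(xi, y) {
  M <- nrow(xi)
  Xy <- xi * y
  G <- rbind(-diag(M), -matrix(y, 1), t(Xy))
  h <- c(rep(0, M), 0, rep(1, ncol(xi)))
  combs <- utils::combn(nrow(G), M)
  best <- -Inf
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    Gi <- G[idx, , drop = FALSE]
    if (abs(det(Gi)) < 1e-12) next
    a <- drop(solve(Gi, h[idx]))
    if (all(G %*% a <= h + 1e-9)) best <- max(best, sum(a))
  }
  if (!is.finite(best) || best <= 0) return(NULL)
  list(kappa = 1 / best)
}

# Oracle margin for neuron i of a pattern set (autapse excluded); NULL when
# the neuron's problem is degenerate (active or silent in every pattern).
margin_oracle_neuron <- function(patterns, i, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  n_on <- sum(patterns$xi[, i])
  if (n_on == 0 || n_on == patterns$M) return(NULL)
  xi <- patterns$xi[, -i, drop = FALSE]
  y <- 2 * patterns$xi[, i] - 1
  if (norm == "l2") l2_margin_oracle(xi, y) else l1_margin_oracle(xi, y)
}

# Achieved margin of the consolidated state for neuron i, same normalization.
achieved_margin_neuron <- function(state, patterns, i, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  w <- state_weights(state)[i, ]
  y <- 2 * patterns$xi[, i] - 1
  den <- if (norm == "l2") sqrt(sum(w^2)) else sum(w)
  min(y * (patterns$xi %*% w - state$I_inh[i])) / den
}
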