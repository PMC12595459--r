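#' Configuration for the consolidation algorithm
#'
#' @param cycles number of replay cycles (>= 1).
#' @param eta dimensionless expression budget per neuron and cycle: the total
#'   amount of plasticity expressed after each replay cycle. Internally the
#'   budget is converted to the units of the factor tensor (see Details).
#' @param beta0 initial gating sharpness, expressed in units of the inverse
#'   median margin: at cycle 0 each neuron uses
#'   `beta_i = beta0 / median_mu |I_i^mu|`, so `beta0 = 1` places the gate's
#'   e-fold at the typical margin.
#' @param beta_growth multiplicative annealing factor per cycle (>= 1). As
#'   `beta` grows, expression concentrates on the weakest pattern, turning the
#'   soft argmin into hard support-vector selection.
#' @param beta_max cap on the total annealing factor (`beta` never exceeds
#'   `beta_max` times its initial value). Keeping the selection finitely
#'   sharp averages expression over the near-degenerate support set at
#'   convergence, which avoids weight flicker from single-pattern steps.
#' @param prune_floor relative weight below which a connection counts as
#'   pruned in diagnostics (fraction of the mean live weight).
#' @param max_unstable_cycles abort when some pattern stays unstable for more
#'   than this many consecutive cycles (default `Inf`: never abort, allowing
#'   consolidation to start from fragile or slightly unstable states).
#' @param settle_frac fraction of the final cycles used as the settling
#'   window for the stationary-support density: a connection counts as
#'   pruned when its weight touches exact zero at any cycle in the window.
#'   Because expression proceeds in finite steps, weights at the boundary of
#'   the nonnegativity constraint flicker between zero and a fraction of one
#'   step; membership of the stationary support (never clipped during
#'   settling) separates them from genuine small weights at any step size.
#' @param record_margins if `TRUE`, store the per-neuron minimum margin at
#'   every cycle (cycles x N matrix) in the diagnostics.
#' @param seed integer seed (the algorithm itself is deterministic; the seed
#'   is recorded for provenance and used by stochastic callers).
#' @details The expression budget is defined in relative units so that a
#'   given `eta` produces steps of comparable relative size for any `z`: the
#'   per-neuron budget in factor units is `eta * u_scale^(2 - z)` with
#'   `u_scale = sqrt(U0 / (N z))` the RMS factor value at cycle 0. For
#'   two-factor synapses the plasticity signal is already proportional to the
#'   factors, so the budget is exactly `eta`.
#' @return A `consolidation_config` list.
#' @export
consolidation_config <- function(cycles = 400L, eta = 0.05, beta0 = 1,
                                 beta_growth = 1.02, beta_max = 100,
                                 prune_floor = 1e-3, settle_frac = 0.1,
                                 max_unstable_cycles = Inf,
                                 record_margins = FALSE, seed = NULL) {
  if (cycles < 1) stop_input("cycles must be >= 1")
  if (eta <= 0) stop_input("eta must be > 0")
  if (beta0 <= 0) stop_input("beta0 must be > 0")
  if (beta_growth < 1) stop_input("beta_growth must be >= 1")
  if (beta_max < 1) stop_input("beta_max must be >= 1")
  structure(list(cycles = as.integer(cycles), eta = eta, beta0 = beta0,
                 beta_growth = beta_growth, beta_max = beta_max,
                 prune_floor = prune_floor, settle_frac = settle_frac,
                 max_unstable_cycles = max_unstable_cycles,
                 record_margins = record_margins, seed = seed),
            class = "consolidation_config")
}

#' Plasticity gating function
#'
#' `g(I) = sign(I) * exp(-beta * |I|)`, with `sign(0) = -1` to match the
#' strict firing threshold (a neuron with zero input stays silent, so
#' plasticity pushes its input further below threshold). Patterns whose
#' margin `|I|` is small (weak memories) induce the most plasticity; strong,
#' familiar memories induce almost none.
#'
#' @param I input current(s) at recall of a pattern.
#' @param beta sharpness parameter (> 0), recycled against `I`.
#' @return Signed gating value(s) in `[-1, 1]`.
#' @export
gate <- function(I, beta) {
  if (any(beta <= 0)) stop_input("beta must be > 0")
  ifelse(I > 0, 1, -1) * exp(-beta * abs(I))
}

#' Per-neuron learning rate from the accumulated gate magnitude
#'
#' `G = eta / sum_mu |g|`: the learning rate is regulated so that the total
#' amount of expression per cycle, `sum_mu G |g|`, equals the budget `eta`
#' exactly. Combined with the exponential gate this acts as a soft argmin:
#' `G * g_mu = eta * sign_mu * softmax(-beta |I|)_mu`.
#'
#' @param gate_abs_sum accumulated `sum_mu |g_i|` per neuron (>= 0).
#' @param eta expression budget (scalar or per-neuron vector).
#' @return Per-neuron learning rate; 0 where the accumulated signal
#'   underflows to zero.
#' @export
learning_rate <- function(gate_abs_sum, eta) {
  if (any(gate_abs_sum < 0)) stop_input("gate_abs_sum must be >= 0")
  out <- eta / gate_abs_sum
  out[!is.finite(out)] <- 0
  out
}

# Ratio tensor r_ijk = w_ij / u_ijk used by the plasticity signal
# delta u_ijk = g_i * xi_j * r_ijk (the gradient of w with respect to u_k).
# Conventions: for z = 1 the ratio is identically 1 off the diagonal, so a
# pruned single-component weight can regrow; for z >= 2 the ratio is 0
# wherever u_ijk = 0, making pruning absorbing.
factor_ratios <- function(u) {
  N <- dim(u)[1]; z <- dim(u)[3]
  r <- array(0, dim(u))
  if (z == 1L) {
    r[, , 1L] <- 1
  } else if (z == 2L) {
    r[, , 1L] <- u[, , 2L] * (u[, , 1L] > 0)
    r[, , 2L] <- u[, , 1L] * (u[, , 2L] > 0)
  } else {
    for (k in seq_len(z)) {
      prod_other <- matrix(1, N, dim(u)[2])
      for (kk in seq_len(z)) if (kk != k) prod_other <- prod_other * u[, , kk]
      r[, , k] <- prod_other * (u[, , k] > 0)
    }
  }
  if (N == dim(u)[2])                     # autapse exclusion (square tensors)
    for (k in seq_len(z)) diag(r[, , k]) <- 0
  r
}

#' Replay all patterns and accumulate plasticity signals
#'
#' For each pattern `mu`, the network state is set to the pattern
#' (reinstatement), the input currents `I_i^mu = sum_j w_ij xi_j^mu - I_inh_i`
#' are computed, and the per-factor plasticity signal
#' `delta u_ijk = g_i(I_i^mu) * xi_j^mu * (w_ij / u_ijk)` is accumulated,
#' with `delta = 0` wherever `u_ijk = 0` (for `z >= 2`). The sign of the
#' gate is carried by the neuron's own reinstated activity
#' (`+` when `s_i = xi_i^mu = 1`, `-` when silent), which coincides with
#' `sign(I)` whenever reinstatement succeeds. Neurons whose thresholded
#' response disagrees with the pattern (failed reinstatement) are flagged.
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set`.
#' @param beta gating sharpness, scalar or per-neuron vector.
#' @return A list with `delta` (N x N x z accumulated signal), `g` (N x M
#'   gate values), `I` (N x M currents), `gate_abs_sum`, `gate_sum`
#'   (per-neuron accumulators), and `failed` (logical N x M reinstatement
#'   failures).
#' @export
replay_cycle <- function(state, patterns, beta) {
  stopifnot(inherits(state, "synaptic_state"), inherits(patterns, "pattern_set"))
  xi <- patterns$xi
  w <- state_weights(state)
  I <- w %*% t(xi) - state$I_inh                 # N x M
  # sign from the reinstated state s_i = xi_i^mu (replay sets the network to
  # the pattern); the gate decays with the signed margin, which equals |I|
  # whenever reinstatement succeeds
  y <- 2 * t(xi) - 1
  g <- y * exp(pmin(-beta * (y * I), 700))   # capped against overflow
  r <- factor_ratios(state$u)
  gx <- g %*% xi                                  # N x N: Sum_mu g_i xi_j
  z <- state$z
  delta <- array(0, dim(state$u))
  for (k in seq_len(z)) delta[, , k] <- gx * r[, , k]
  list(delta = delta, g = g, I = I,
       gate_abs_sum = rowSums(abs(g)), gate_sum = rowSums(g),
       failed = (I > 0) != (t(xi) == 1))
}

#' Express accumulated plasticity and apply homeostatic scaling
#'
#' The three closing steps of a replay cycle: (a) each factor is incremented
#' by `G_i * sum_mu delta u_ijk` and clipped at zero (clipping implements the
#' nonnegativity constraint; for `z >= 2` a clipped component prunes the
#' connection permanently); (b) the inhibitory current is adjusted by
#' `-G_i * sum_mu g_i` (the bias-term analogue of the factor update), clipped
#' at zero; (c) each live neuron's incoming factors are rescaled
#' multiplicatively so that `sum_jk u_ijk^2` returns to its reference value
#' `U0_i`, which preserves all surviving weight ratios.
#'
#' @param state a `synaptic_state`.
#' @param accumulated result of [replay_cycle()] on the same state.
#' @param G per-neuron learning rate from [learning_rate()].
#' @param U0 per-neuron target factor norm (squared sum); defaults to the
#'   state's current norm.
#' @return The updated `synaptic_state`; neurons whose entire factor row has
#'   died are reported in the `"dead"` attribute.
#' @export
express_and_scale <- function(state, accumulated, G, U0 = NULL) {
  u <- state$u
  z <- state$z
  if (is.null(U0)) U0 <- factor_norms(u)
  for (k in seq_len(z)) u[, , k] <- pmax(0, u[, , k] + G * accumulated$delta[, , k])
  I_inh <- pmax(0, state$I_inh - G * accumulated$gate_sum)
  n2 <- factor_norms(u)
  dead <- n2 <= 0
  lam <- ifelse(dead, 1, sqrt(U0 / n2))
  u <- u * as.numeric(lam)   # recycles along the postsynaptic (first) axis
  out <- synaptic_state(u, I_inh)
  attr(out, "dead") <- dead
  out
}

# Per-neuron squared factor norm Sum_{j,k} u_ijk^2.
factor_norms <- function(u) {
  n2 <- rowSums(u[, , 1L]^2)
  z <- dim(u)[3]
  if (z > 1L) for (k in 2:z) n2 <- n2 + rowSums(u[, , k]^2)
  n2
}

#' Per-neuron signal-to-noise ratio of the weakest pattern
#'
#' `SNR_i = min_mu |I_i^mu| / sqrt(sum_j w_ij^q)`. The exponent `q` selects
#' the noise model: `q = 2` for neural noise (state flips) and `q = 2 - 2/z`
#' for intrinsic synaptic noise on the volatile component of a `z`-factor
#' synapse. Consolidation with `z` components maximizes the SNR at
#' `q = 2/z`.
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set`.
#' @param q noise-scaling exponent in (0, 2].
#' @param signed if `TRUE`, use the signed margin
#'   `min_mu (2 xi - 1) I_i^mu` (negative for unstable patterns) instead of
#'   `min_mu |I|`.
#' @return Per-neuron SNR vector; neurons with an empty weight row get SNR 0
#'   and are flagged in the `"dead"` attribute.
#' @export
snr <- function(state, patterns, q = 2 / state$z, signed = FALSE) {
  if (q <= 0 || q > 2) stop_input("q must be in (0, 2]")
  w <- state_weights(state)
  I <- w %*% t(patterns$xi) - state$I_inh
  m <- if (signed) {
    apply((2 * t(patterns$xi) - 1) * I, 1, min)
  } else {
    apply(abs(I), 1, min)
  }
  wq <- w^q
  wq[w <= 0] <- 0
  den <- sqrt(rowSums(wq))
  out <- ifelse(den > 0, m / den, 0)
  attr(out, "dead") <- den <= 0
  out
}

#' Consolidate stored patterns by replay
#'
#' Runs the full three-step consolidation loop — replay with gated plasticity
#' induction, budgeted expression, multiplicative homeostatic scaling — for
#' `config$cycles` cycles, annealing the gating sharpness geometrically. Each
#' neuron independently climbs toward the maximum-margin configuration of its
#' incoming factors under a fixed factor norm; with `z` components this is
#' equivalent to margin maximization of the weights under an L(2/z)
#' constraint, so `z >= 2` additionally prunes connections.
#'
#' Internally the per-pattern expression weights `G_i g_i(I_i^mu)` are
#' computed in their softmax form
#' `eta_i * sign(I) * exp(-beta|I| - max)/sum(exp(...))`, which is
#' algebraically identical to composing [replay_cycle()], [learning_rate()]
#' and [express_and_scale()] but remains well defined when `beta` has grown
#' so large that individual gate values underflow.
#'
#' @param state a `synaptic_state` (typically from [imprint_patterns()]).
#' @param patterns the stored `pattern_set`.
#' @param config a [consolidation_config()].
#' @param neurons optional vector of postsynaptic neuron indices to
#'   consolidate. Because each neuron optimizes its incoming factors
#'   independently, restricting to a measured subset yields the same
#'   per-neuron ensemble at a fraction of the cost; used for large-N density
#'   estimates. When a proper subset is given, the returned `state` is
#'   `NULL` and the row-block results are in `diagnostics` (`rows`,
#'   `u_rows`, `I_inh_rows`).
#' @return A list of class `consolidation_result` with elements `state` (the
#'   consolidated `synaptic_state`) and `diagnostics`, a list holding the
#'   per-cycle summary data frame (`per_cycle`: minimum and mean margins,
#'   SNR at `q = 2/z`, connection density, factor misalignment, expression
#'   magnitude, unstable-condition count), the reference norms `U0`, the
#'   per-neuron budgets and initial sharpness, the stationary-support
#'   density `density_settled`, and the dead-neuron flags.
#' @export
consolidate <- function(state, patterns, config = consolidation_config(),
                        neurons = NULL) {
  stopifnot(inherits(state, "synaptic_state"), inherits(patterns, "pattern_set"),
            inherits(config, "consolidation_config"))
  xi <- patterns$xi
  N <- state$N; z <- state$z; M <- patterns$M
  rows <- if (is.null(neurons)) seq_len(N) else sort(unique(as.integer(neurons)))
  if (any(rows < 1 | rows > N)) stop_input("neurons out of range")
  full <- length(rows) == N
  n_r <- length(rows)

  xiT <- t(xi)[rows, , drop = FALSE]              # n_r x M
  sgn_target <- 2 * xiT - 1
  u <- state$u[rows, , , drop = FALSE]
  I_inh <- state$I_inh[rows]
  q_opt <- 2 / z
  mask <- matrix(1, n_r, N)                       # excludes autapses
  mask[cbind(seq_len(n_r), rows)] <- 0

  U0 <- factor_norms(u)
  if (any(U0 <= 0))
    stop_input("consolidation requires every neuron to have at least one live input")
  u_scale <- sqrt(U0 / (N * z))
  eta_i <- config$eta * u_scale^(2 - z)           # budget in factor units

  # initial sharpness: beta0 in units of the inverse median margin
  w <- weights_from_factors(u)
  I <- tcrossprod(w, xi) - I_inh                  # n_r x M
  med <- apply(abs(I), 1, stats::median)
  med[med <= 0] <- mean(abs(I))
  beta_base <- config$beta0 / med
  beta <- beta_base

  cycles <- config$cycles
  per_cycle <- data.frame(
    cycle = seq_len(cycles), min_margin = NA_real_, min_abs_margin = NA_real_,
    snr_mean = NA_real_, density = NA_real_, misalignment = NA_real_,
    mean_factor = NA_real_, expression = NA_real_, n_unstable = NA_integer_)
  margins <- if (config$record_margins) matrix(NA_real_, cycles, n_r) else NULL
  dead <- rep(FALSE, n_r)
  unstable_streak <- 0L
  settle_start <- cycles - max(1L, ceiling(config$settle_frac * cycles)) + 1L
  touched_zero <- matrix(FALSE, n_r, N)
  offdiag <- mask == 1

  for (cycle in seq_len(cycles)) {
    w <- weights_from_factors(u)
    I <- tcrossprod(w, xi) - I_inh                # n_r x M
    marg <- sgn_target * I                        # signed margin; = |I| when stable
    absI <- abs(I)

    # stable soft-argmin expression weights over the signed margin:
    # omega = eta * sign * softmax(-beta * margin); identical to the |I| form
    # whenever every pattern sits on its correct side
    X <- -beta * marg
    X <- X - row_max(X)
    P <- exp(X)
    P <- P / rowSums(P)
    omega <- (eta_i * !dead) * sgn_target * P     # n_r x M

    gx <- (omega %*% xi) * mask                   # n_r x N: Sum_mu omega xi_j
    r <- factor_ratios(u)
    expr_mag <- 0
    for (k in seq_len(z)) {
      dk <- gx * r[, , k]
      expr_mag <- expr_mag + sum(abs(dk))
      u[, , k] <- pmax(0, u[, , k] + dk)
    }
    I_inh <- pmax(0, I_inh - rowSums(omega))

    n2 <- factor_norms(u)
    newly_dead <- n2 <= 0 & !dead
    if (any(newly_dead)) dead <- dead | newly_dead
    lam <- ifelse(dead, 1, sqrt(U0 / n2))
    u <- u * as.numeric(lam)

    # ---- diagnostics ----
    if (cycle >= settle_start) {
      w_now <- weights_from_factors(u)
      touched_zero <- touched_zero | (w_now == 0)
    }
    mm <- apply(marg, 1, min)
    wq <- w^q_opt; wq[w <= 0] <- 0
    den <- sqrt(rowSums(wq))
    mabs <- apply(absI, 1, min)
    fm <- factor_misalignment(u, offdiag)
    n_unst <- sum((I > 0) != (xiT == 1))
    w_off <- w[offdiag]
    pos <- w_off[w_off > 0]
    dens <- if (length(pos)) mean(w_off > config$prune_floor * mean(pos)) else 0
    per_cycle[cycle, -1L] <- c(
      min(mm[!dead]), mean(mabs[!dead]),
      mean(ifelse(den > 0, mabs / den, 0)[!dead]),
      dens, fm["misalignment"], fm["mean_factor"], expr_mag, n_unst)
    if (config$record_margins) margins[cycle, ] <- mm

    unstable_streak <- if (n_unst > 0) unstable_streak + 1L else 0L
    if (unstable_streak > config$max_unstable_cycles) {
      diag_out <- list(per_cycle = per_cycle[seq_len(cycle), ], U0 = U0,
                       eta_i = eta_i, beta0_i = beta_base,
                       dead = dead, margins = margins)
      stop(errorCondition(
        sprintf("pattern stability lost for more than %d consecutive cycles (cycle %d)",
                config$max_unstable_cycles, cycle),
        class = c("synconsol_divergence", "synconsol_error"),
        diagnostics = diag_out))
    }
    beta <- pmin(beta * config$beta_growth, beta_base * config$beta_max)
  }

  out_state <- NULL
  if (full) {
    out_state <- synaptic_state(u, I_inh)
    attr(out_state, "dead") <- dead
  }
  structure(list(
    state = out_state,
    diagnostics = list(per_cycle = per_cycle, U0 = U0, eta_i = eta_i,
                       beta0_i = beta_base, dead = dead,
                       density_settled = mean(!touched_zero[offdiag]),
                       rows = rows,
                       u_rows = if (!full) u, I_inh_rows = if (!full) I_inh,
                       margins = margins, config = config)),
    class = "consolidation_result")
}

# Mean pairwise factor discrepancy (max_k u - min_k u) over live synapses,
# plus the mean live factor value, for alignment diagnostics. `offdiag` is
# the logical mask of admissible (non-autapse) entries.
factor_misalignment <- function(u, offdiag = NULL) {
  z <- dim(u)[3]
  if (is.null(offdiag)) {
    offdiag <- matrix(TRUE, dim(u)[1], dim(u)[2])
    diag(offdiag) <- FALSE
  }
  w_live <- u[, , 1L] > 0
  if (z > 1L) for (k in 2:z) w_live <- w_live & (u[, , k] > 0)
  w_live <- w_live & offdiag
  if (!any(w_live)) return(c(misalignment = 0, mean_factor = 0))
  if (z == 1L) {
    return(c(misalignment = 0, mean_factor = mean(u[, , 1L][w_live])))
  }
  umin <- u[, , 1L]; umax <- u[, , 1L]; usum <- u[, , 1L]
  for (k in 2:z) {
    umin <- pmin(umin, u[, , k]); umax <- pmax(umax, u[, , k])
    usum <- usum + u[, , k]
  }
  c(misalignment = mean((umax - umin)[w_live]),
    mean_factor = mean(usum[w_live] / z))
}

#' @export
print.consolidation_result <- function(x, ...) {
  pc <- x$diagnostics$per_cycle
  last <- pc[nrow(pc), ]
  cat(sprintf("consolidation_result: %d cycles, final density %.3f, final min margin %.4g\n",
              nrow(pc), last$density, last$min_margin))
  cat(sprintf("  mean SNR(q = 2/z) %.4g, misalignment/mean factor %.3g\n",
              last$snr_mean,
              if (last$mean_factor > 0) last$misalignment / last$mean_factor else NA))
  invisible(x)
}
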