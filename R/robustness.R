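#' Apply neural noise to a binary state
#'
#' Each bit is flipped independently with probability `f_noise`, modelling
#' distorted cues or unreliable firing.
#'
#' @param s binary state vector.
#' @param f_noise per-bit flip probability in [0, 0.5].
#' @param seed integer seed.
#' @return The perturbed binary vector.
#' @export
apply_neural_noise <- function(s, f_noise, seed = NULL) {
  if (f_noise < 0 || f_noise > 0.5) stop_input("f_noise must be in [0, 0.5]")
  if (f_noise == 0) return(s)
  flip <- with_seed(seed, stats::runif(length(s)) < f_noise)
  ifelse(flip, 1 - s, s)
}

#' Apply intrinsic synaptic noise to the volatile component
#'
#' Adds white noise to the volatile tag `u_ij1` of every live connection:
#' `u_ij1 <- max(0, u_ij1 + eps)`, `eps ~ N(0, sd^2)`. Other components are
#' untouched, so on aligned synapses the induced weight perturbation scales
#' as `w^(1 - 1/z)`: additive for single-component synapses, proportional to
#' `sqrt(w)` for two-factor synapses.
#'
#' @param state a `synaptic_state`.
#' @param sigma_noise noise level. When `relative = TRUE` (default), the
#'   standard deviation is `sigma_noise` times the mean live volatile
#'   component, which makes levels comparable across states with different
#'   weight scales; when `FALSE` it is absolute.
#' @param relative interpret `sigma_noise` relative to the mean live `u1`.
#' @param seed integer seed.
#' @return The perturbed `synaptic_state`.
#' @export
apply_synaptic_noise <- function(state, sigma_noise, relative = TRUE, seed = NULL) {
  if (sigma_noise < 0) stop_input("sigma_noise must be >= 0")
  if (sigma_noise == 0) return(state)
  u <- state$u
  u1 <- u[, , 1L]
  live <- u1 > 0
  sd_abs <- if (relative) sigma_noise * mean(u1[live]) else sigma_noise
  u1[live] <- with_seed(seed,
    pmax(0, u1[live] + stats::rnorm(sum(live), sd = sd_abs)))
  u[, , 1L] <- u1
  synaptic_state(u, state$I_inh)
}

#' Predicted input-fluctuation scale for a pattern
#'
#' The standard deviation of the input-current fluctuation of each neuron,
#' up to the noise amplitude: `sqrt(sum_j s_j w_ij^q)` with `q = 2` for
#' neural noise and `q = 2 - 2/z` for synaptic noise on aligned factors
#' (for `z = 1` synaptic noise, `q = 0` counts live active inputs).
#'
#' @param state a `synaptic_state`.
#' @param pattern binary activity vector the network is in.
#' @param kind `"neural"` or `"synaptic"`.
#' @return Per-neuron noise scale vector.
#' @export
input_fluctuation_scale <- function(state, pattern, kind = c("neural", "synaptic")) {
  kind <- match.arg(kind)
  w <- state_weights(state)
  q <- if (kind == "neural") 2 else 2 - 2 / state$z
  wq <- w^q
  wq[w <= 0] <- 0           # 0^0 := 0 for absent connections
  sqrt(as.numeric(wq %*% pattern))
}

#' Highest tolerated noise level in recall tests
#'
#' Scans noise levels and, at each level, runs randomized recall tests:
#' for neural noise the cue is a noise-corrupted pattern; for synaptic noise
#' the cue is clean but the volatile components carry a fresh quenched
#' perturbation per test. A test succeeds when the final overlap with the
#' target pattern after `steps` synchronous sweeps reaches
#' `overlap_threshold`. The tolerated level is the largest scanned level
#' whose success fraction is at least `success_threshold`; the scan is
#' refined by bisection between the last passing and first failing level.
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set`.
#' @param kind `"neural"` (flip probability) or `"synaptic"` (relative
#'   noise on the volatile component, see [apply_synaptic_noise()]).
#' @param trials recall tests per level (patterns are cycled through).
#' @param levels initial grid of noise levels; defaults to 11 levels spanning
#'   [0, 0.5] (neural) or [0, 2] (synaptic).
#' @param refine number of bisection refinements of the tolerance boundary.
#' @param success_threshold required success fraction (default 0.9).
#' @param overlap_threshold final-overlap criterion for a successful recall.
#' @param steps recall sweeps per test.
#' @param seed integer seed.
#' @return A list with `level` (tolerated level), `level_se` (bootstrap
#'   standard error over trials), and `curve`, a data frame of
#'   (level, success, n) sorted by level.
#' @export
tolerated_noise <- function(state, patterns, kind = c("neural", "synaptic"),
                            trials = 100L, levels = NULL, refine = 3L,
                            success_threshold = 0.9, overlap_threshold = 0.95,
                            steps = 10L, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(levels))
    levels <- if (kind == "neural") seq(0, 0.5, length.out = 11L)
              else seq(0, 2, length.out = 11L)
  levels <- sort(unique(levels))
  f <- patterns$f

  run_level <- function(level, seed_off) {
    succ <- logical(trials)
    for (t in seq_len(trials)) {
      mu <- ((t - 1L) %% patterns$M) + 1L
      xi_mu <- patterns$xi[mu, ]
      s_trial <- child_seed(seed, seed_off + t)
      if (kind == "neural") {
        cue <- apply_neural_noise(xi_mu, level, seed = s_trial)
        st <- state
      } else {
        cue <- xi_mu
        st <- apply_synaptic_noise(state, level, seed = s_trial)
      }
      S <- recall(st, cue, steps = steps)$S
      succ[t] <- overlap(S[nrow(S), ], xi_mu, f) >= overlap_threshold
    }
    succ
  }

  outcomes <- list()
  curve <- data.frame(level = numeric(0), success = numeric(0), n = integer(0))
  eval_level <- function(level, off) {
    s <- run_level(level, off)
    outcomes[[as.character(level)]] <<- s
    curve <<- rbind(curve, data.frame(level = level, success = mean(s), n = trials))
    mean(s)
  }
  for (i in seq_along(levels)) eval_level(levels[i], i * 10000L)

  passed <- curve$level[curve$success >= success_threshold]
  failed <- curve$level[curve$success < success_threshold]
  lo <- if (length(passed)) max(passed) else 0
  hi_cand <- failed[failed > lo]
  hi <- if (length(hi_cand)) min(hi_cand) else max(levels)
  if (hi > lo) {
    for (r in seq_len(refine)) {
      mid <- (lo + hi) / 2
      p <- eval_level(mid, 100000L + r * 10000L)
      if (p >= success_threshold) lo <- mid else hi <- mid
    }
  }
  curve <- curve[order(curve$level), ]
  rownames(curve) <- NULL

  # bootstrap the tolerated level over trial outcomes
  lv <- curve$level
  outc <- do.call(cbind, lapply(as.character(lv), function(k) outcomes[[k]]))
  boot_tol <- with_seed(child_seed(seed, 999L) %||% NULL, {
    vapply(seq_len(200L), function(b) {
      idx <- sample.int(trials, trials, replace = TRUE)
      p <- colMeans(outc[idx, , drop = FALSE])
      ok <- lv[p >= success_threshold]
      if (length(ok)) max(ok) else 0
    }, numeric(1))
  })
  list(level = lo, level_se = stats::sd(boot_tol), curve = curve)
}
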