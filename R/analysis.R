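#' Fluctuation-scaling exponent of synaptic strength changes
#'
#' Forms all `(w(t), dw = w(t + dt_lag) - w(t))` pairs from a trajectory
#' table, splits them into potentiation (`dw > 0`) and depression (`dw < 0`)
#' branches, and estimates the exponent `x` of the power law
#' `<|dw|> ~ w^x` in each branch. The default estimator sorts pairs by `w`,
#' applies a centered moving average to `(log w, log |dw|)` and fits a line
#' to the averaged curve by least squares; `method = "raw"` regresses the raw
#' log-pairs directly, and `method = "rmsd"` fits the running root mean
#' square deviation. Standard errors come from a bootstrap over synapses
#' (not time points), respecting within-synapse autocorrelation.
#'
#' Pairs where either endpoint is zero are excluded (the power law concerns
#' fluctuations of existing synapses; pruning events are studied separately
#' with [pruning_vs_weight()]).
#'
#' @param table a `trajectory_table`.
#' @param dt_lag lag in time units; defaults to the sampling interval.
#' @param n_boot bootstrap replicates (>= 2).
#' @param window moving-average width in pairs (odd).
#' @param method estimator variant.
#' @param seed integer seed for the bootstrap.
#' @return A `scaling_fit` data frame with one row per branch: `branch`,
#'   `slope`, `slope_se`, `intercept`, `n_pairs`, plus `window`, `n_boot`
#'   and `method` attributes. Branches with fewer pairs than `window` are
#'   skipped with a warning.
#' @export
fluctuation_scaling <- function(table, dt_lag = NULL, n_boot = 100L,
                                window = 101L, method = c("moving", "raw", "rmsd"),
                                seed = NULL) {
  method <- match.arg(method)
  if (n_boot < 2) stop_input("n_boot must be >= 2")
  md <- attr(table, "metadata") %||% list()
  if (is.null(dt_lag)) dt_lag <- md$dt %||% min(diff(sort(unique(table$time))))

  pairs <- lag_pairs(table, dt_lag)
  branches <- list(potentiation = pairs[pairs$dw > 0, ],
                   depression = pairs[pairs$dw < 0, ])
  fit_one <- function(pp) {
    if (nrow(pp) < max(window, 3L)) return(NULL)
    branch_slope(log(pp$w), log(abs(pp$dw)), pp$dw, window, method)
  }
  res <- list()
  for (b in names(branches)) {
    pp <- branches[[b]]
    fit <- fit_one(pp)
    if (is.null(fit)) {
      warning(sprintf("branch '%s' has fewer pairs (%d) than the window; skipped",
                      b, nrow(pp)))
      next
    }
    boot <- with_seed(child_seed(seed, match(b, names(branches))), {
      ids <- unique(pairs$synapse_id)
      split_idx <- split(seq_len(nrow(pp)), pp$synapse_id)
      vapply(seq_len(n_boot), function(i) {
        take <- sample(ids, length(ids), replace = TRUE)
        idx <- unlist(split_idx[as.character(take)], use.names = FALSE)
        if (length(idx) < max(window, 3L)) return(NA_real_)
        sub <- pp[idx, ]
        branch_slope(log(sub$w), log(abs(sub$dw)), sub$dw, window, method)["slope"]
      }, numeric(1))
    })
    res[[b]] <- data.frame(branch = b, slope = fit[["slope"]],
                           slope_se = stats::sd(boot, na.rm = TRUE),
                           intercept = fit[["intercept"]], n_pairs = nrow(pp))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, window = window, n_boot = n_boot, method = method,
            dt_lag = dt_lag, class = c("scaling_fit", "data.frame"))
}

# All (w(t), dw) pairs at the requested lag, zeros excluded.
lag_pairs <- function(table, dt_lag) {
  times <- sort(unique(table$time))
  step <- min(diff(times))
  k <- round(dt_lag / step)
  if (k < 1 || abs(k * step - dt_lag) > 1e-8 * max(step, 1))
    stop_input("dt_lag must be a positive multiple of the sampling interval")
  W <- trajectory_matrix(table)
  nt <- nrow(W)
  if (nt <= k) stop_input("trajectory too short for the requested lag")
  w0 <- W[seq_len(nt - k), , drop = FALSE]
  w1 <- W[(k + 1L):nt, , drop = FALSE]
  keep <- w0 > 0 & w1 > 0
  data.frame(
    synapse_id = rep(as.integer(colnames(W)), each = nt - k)[as.vector(keep)],
    w = w0[keep], dw = (w1 - w0)[keep])
}

branch_slope <- function(lw, labs_dw, dw, window, method) {
  ord <- order(lw)
  lw <- lw[ord]
  if (method == "raw") {
    fit <- stats::lm.fit(cbind(1, lw), labs_dw[ord])
    return(c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]]))
  }
  y <- if (method == "moving") labs_dw[ord] else dw[ord]^2
  w_avg <- running_mean(lw, window)
  y_avg <- if (method == "moving") running_mean(y, window)
           else 0.5 * log(running_mean(y, window))   # log RMS deviation
  fit <- stats::lm.fit(cbind(1, w_avg), y_avg)
  c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
}

# Centered running mean with full windows only.
running_mean <- function(x, window) {
  n <- length(x)
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= n) return(mean(x))
  cs <- cumsum(c(0, x))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

#' Coefficient of variation of weight norms across time
#'
#' For each exponent `q` in a grid, computes the population norm
#' `||w(t)||_q = (sum_j w_j(t)^q)^(1/q)` at every time point and its
#' coefficient of variation (sd/mean) over time. Under multiplicative
#' homeostatic scaling that conserves the mass `sum_j w_j^(2/z)`, the CV is
#' minimized near `q_min = 2/z`, so `q_min` reads out the number of synaptic
#' factors from population data.
#'
#' @param table a `trajectory_table` on a common time grid (pruned synapses
#'   contribute zeros).
#' @param q_grid exponents to scan.
#' @param n_boot bootstrap replicates over synapses for the `q_min` standard
#'   error.
#' @param seed integer seed.
#' @return A list of class `norm_cv_result`: `q_grid`, `cv`, `cv_rank`
#'   (ranked to [0, 1]), `q_min`, `q_min_se`.
#' @export
norm_cv <- function(table, q_grid = seq(0.25, 3, by = 0.25), n_boot = 1000L,
                    seed = NULL) {
  W <- trajectory_matrix(table)
  if (nrow(W) < 2) stop_format("need at least two time points")
  nq <- length(q_grid)
  n <- ncol(W)
  cv_of <- function(norms) stats::sd(norms) / mean(norms)
  Xq <- lapply(q_grid, function(q) {
    X <- W^q
    X[W <= 0] <- 0
    X
  })
  cv <- vapply(seq_len(nq), function(iq)
    cv_of(rowSums(Xq[[iq]])^(1 / q_grid[iq])), numeric(1))
  q_min <- q_grid[which.min(cv)]

  q_min_se <- NA_real_
  if (n_boot >= 2) {
    # multinomial counts implement column resampling as one matrix product
    cnts <- with_seed(child_seed(seed, 1L),
                      stats::rmultinom(n_boot, n, rep(1 / n, n)))
    q_min_boot <- {
      cv_boot <- matrix(0, nq, n_boot)
      for (iq in seq_len(nq)) {
        norms <- (Xq[[iq]] %*% cnts)^(1 / q_grid[iq])
        cv_boot[iq, ] <- apply(norms, 2, cv_of)
      }
      q_grid[apply(cv_boot, 2, which.min)]
    }
    q_min_se <- stats::sd(q_min_boot)
  }
  structure(list(q_grid = q_grid, cv = cv,
                 cv_rank = (rank(cv) - 1) / (nq - 1),
                 q_min = q_min, q_min_se = q_min_se),
            class = "norm_cv_result")
}

#' @export
print.norm_cv_result <- function(x, ...) {
  cat(sprintf("norm_cv_result: q_min = %g (SE %.3g), CV range [%.3g, %.3g]\n",
              x$q_min, x$q_min_se, min(x$cv), max(x$cv)))
  invisible(x)
}

#' Pruning probability as a function of initial weight
#'
#' Bins the synapses that existed before consolidation by their initial
#' weight and reports the fraction pruned afterwards per bin, together with
#' a logistic regression of the pruning indicator on log-weight.
#'
#' @param before,after weight matrices (or `synaptic_state`s) of matching
#'   shape.
#' @param bins number of quantile bins.
#' @param floor absolute weight below which a connection counts as pruned;
#'   defaults to `1e-3` times the mean initial live weight.
#' @return A list with `by_bin` (data frame: bin center, pruning probability,
#'   count) and `slope` (logistic slope on log-weight, negative when strong
#'   synapses survive preferentially), plus the fitted `glm`.
#' @export
pruning_vs_weight <- function(before, after, bins = 8L, floor = NULL) {
  wb <- if (inherits(before, "synaptic_state")) state_weights(before) else before
  wa <- if (inherits(after, "synaptic_state")) state_weights(after) else after
  if (!all(dim(wb) == dim(wa))) stop_input("weight matrices must match in shape")
  off <- row(wb) != col(wb)
  if (is.null(floor)) floor <- 1e-3 * mean(wb[off & wb > 0])
  exists_before <- off & wb > floor
  w0 <- wb[exists_before]
  pruned <- wa[exists_before] <= floor

  brk <- unique(stats::quantile(w0, probs = seq(0, 1, length.out = bins + 1L)))
  bin <- cut(w0, brk, include.lowest = TRUE)
  by_bin <- data.frame(
    w_mid = as.numeric(tapply(w0, bin, stats::median)),
    p_prune = as.numeric(tapply(pruned, bin, mean)),
    n = as.integer(table(bin)))

  slope <- NA_real_
  fit <- NULL
  if (!any(pruned) || all(pruned)) {
    warning("degenerate pruning outcome; logistic slope undefined")
  } else {
    fit <- stats::glm(pruned ~ log(w0), family = stats::binomial())
    slope <- stats::coef(fit)[["log(w0)"]]
  }
  list(by_bin = by_bin, slope = slope, fit = fit, floor = floor)
}

# Graded recall responses: rectified input current of every neuron in every
# stored pattern, a proxy for graded output activity.
pattern_responses <- function(state, patterns, rectify = TRUE) {
  w <- state_weights(state)
  I <- w %*% t(patterns$xi) - state$I_inh
  if (rectify) pmax(I, 0) else I
}

#' Graded neuron responses to a set of stimuli
#'
#' Logistic readout of the input currents,
#' `r = 1 / (1 + exp(-I / temperature))`, interpolating between the binary
#' threshold output (`temperature -> 0`) and a linear readout. Used for
#' tuning-curve analyses, where a graded output is needed to compare
#' responses to familiar and novel stimuli.
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set` of stimuli (stored or novel).
#' @param temperature smoothness of the activation in current units;
#'   defaults to one tenth of the mean absolute current, a sharp but graded
#'   readout.
#' @return N x M matrix of responses in (0, 1).
#' @export
graded_responses <- function(state, patterns, temperature = NULL) {
  I <- state_weights(state) %*% t(patterns$xi) - state$I_inh
  if (is.null(temperature)) temperature <- 0.1 * mean(abs(I))
  if (temperature <= 0) stop_input("temperature must be > 0")
  1 / (1 + exp(-I / temperature))
}

#' Connectivity as a function of response correlation
#'
#' Computes, for every directed neuron pair, the Pearson correlation of their
#' graded recall responses across patterns (total excitatory input current as
#' an activity proxy), bins pairs by correlation, and reports per bin the
#' fraction of pre-existing connections that survive consolidation and the
#' mean surviving strength (max-normalized). Neurons with constant responses
#' are excluded from the correlation.
#'
#' @param state_before,state_after `synaptic_state`s before/after
#'   consolidation.
#' @param patterns the stored `pattern_set`.
#' @param bins number of correlation bins.
#' @param floor absolute pruning floor (default as in [pruning_vs_weight()]).
#' @return A data frame with one row per bin: `cor_mid`, `p_connected`,
#'   `mean_strength`, `n`.
#' @export
response_correlation_connectivity <- function(state_before, state_after,
                                              patterns, bins = 6L,
                                              floor = NULL) {
  wb <- state_weights(state_before)
  wa <- state_weights(state_after)
  off <- row(wb) != col(wb)
  if (is.null(floor)) floor <- 1e-3 * mean(wb[off & wb > 0])
  R <- pattern_responses(state_after, patterns)
  keep <- apply(R, 1, stats::sd) > 0
  C <- matrix(NA_real_, nrow(wb), nrow(wb))
  C[keep, keep] <- stats::cor(t(R[keep, , drop = FALSE]))
  sel <- off & wb > floor & !is.na(C)
  cc <- C[sel]
  surv <- wa[sel] > floor
  wsurv <- wa[sel]

  brk <- unique(stats::quantile(cc, probs = seq(0, 1, length.out = bins + 1L)))
  bin <- cut(cc, brk, include.lowest = TRUE)
  ms <- as.numeric(tapply(ifelse(surv, wsurv, NA), bin,
                          function(x) mean(x, na.rm = TRUE)))
  ms <- ms / max(ms, na.rm = TRUE)
  data.frame(cor_mid = as.numeric(tapply(cc, bin, stats::median)),
             p_connected = as.numeric(tapply(surv, bin, mean)),
             mean_strength = ms,
             n = as.integer(table(bin)))
}

#' Tuning sparseness of a response matrix
#'
#' Selectivity index `S = (1 - a) / (1 - 1/n)` with
#' `a = (sum r / n)^2 / (sum r^2 / n)` computed along the chosen axis and
#' averaged over the other: 0 when all responses along the axis are equal,
#' approaching 1 when responses concentrate on a single entry.
#'
#' @param responses nonnegative matrix, neurons x stimuli (or
#'   neurons x time points).
#' @param axis `"stimuli"` computes sparseness of each neuron's tuning
#'   across columns; `"neurons"` computes sparseness of each column's
#'   population response across rows; `"time"` is an alias for `"stimuli"`
#'   with columns read as time points.
#' @return Mean sparseness in [0, 1]; all-zero response vectors are excluded
#'   and their count reported in the `"n_excluded"` attribute.
#' @export
tuning_sparseness <- function(responses, axis = c("stimuli", "neurons", "time")) {
  axis <- match.arg(axis)
  r <- as.matrix(responses)
  if (any(r < 0)) stop_input("responses must be nonnegative")
  if (axis == "neurons") r <- t(r)
  if (ncol(r) < 2) stop_input("need at least 2 entries along the axis")
  s1 <- rowMeans(r)
  s2 <- rowMeans(r^2)
  ok <- s2 > 0
  if (!any(ok)) stop_input("all response vectors are zero")
  a <- s1[ok]^2 / s2[ok]
  S <- (1 - a) / (1 - 1 / ncol(r))
  structure(mean(S), n_excluded = sum(!ok))
}

#' Per-pattern SNR and its change under consolidation
#'
#' The SNR of a pattern is the weakest signed neuron margin normalized by
#' that neuron's noise term: `min_i (2 xi_i - 1) I_i^mu / sqrt(sum_j w_ij^q)`.
#' `pattern_snr_change` evaluates it at two states (same `q`) and regresses
#' the change on the initial value; under consolidation weakly encoded
#' patterns gain the most, giving a negative slope, while longer replay
#' shifts the whole curve upward.
#'
#' @param state a `synaptic_state`.
#' @param patterns a `pattern_set`.
#' @param q noise exponent in (0, 2].
#' @return `pattern_snr`: per-pattern SNR vector.
#' @export
pattern_snr <- function(state, patterns, q = 2 / state$z) {
  if (q <= 0 || q > 2) stop_input("q must be in (0, 2]")
  w <- state_weights(state)
  I <- w %*% t(patterns$xi) - state$I_inh         # N x M
  m <- (2 * t(patterns$xi) - 1) * I
  wq <- w^q
  wq[w <= 0] <- 0
  den <- sqrt(rowSums(wq))
  ok <- den > 0
  apply(m[ok, , drop = FALSE] / den[ok], 2, min)
}

#' @rdname pattern_snr
#' @param state_start,state_end states before and after consolidation.
#' @return `pattern_snr_change`: a list with `table` (data frame of
#'   `snr_start`, `snr_end`, `delta` per pattern), `slope` and `intercept`
#'   of the regression of `delta` on `snr_start`.
#' @export
pattern_snr_change <- function(state_start, state_end, patterns,
                               q = 2 / state_start$z) {
  s0 <- pattern_snr(state_start, patterns, q)
  s1 <- pattern_snr(state_end, patterns, q)
  tab <- data.frame(pattern = seq_along(s0), snr_start = s0, snr_end = s1,
                    delta = s1 - s0)
  fit <- stats::lm(delta ~ snr_start, data = tab)
  list(table = tab, slope = stats::coef(fit)[["snr_start"]],
       intercept = stats::coef(fit)[["(Intercept)"]])
}
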