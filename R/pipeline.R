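#' Numerically estimate the critical storage load
#'
#' Bisects over the load `alpha = M/N` for the largest load at which
#' consolidation still stabilizes every pattern (final minimum signed margin
#' positive for all neurons). This is a numerical stand-in for the
#' theoretical sign-constrained capacity and is used to normalize load
#' schedules.
#'
#' @param N network size.
#' @param f coding level.
#' @param z number of synaptic components.
#' @param config a [consolidation_config()] used for the trial
#'   consolidations.
#' @param bracket initial `c(lo, hi)` load bracket; `lo` must be feasible.
#' @param tol bisection tolerance on alpha.
#' @param neurons optional measured-neuron subset passed to [consolidate()].
#' @param seed integer seed.
#' @return A list with `alpha_c` (estimate), `evaluations` (data frame of
#'   alpha, converged).
#' @export
estimate_capacity <- function(N, f, z = 1L, config = consolidation_config(),
                              bracket = c(0.1, 2), tol = 0.05, neurons = NULL,
                              seed = 1L) {
  evals <- data.frame(alpha = numeric(0), converged = logical(0))
  feasible <- function(alpha) {
    M <- max(1L, round(alpha * N))
    p <- generate_patterns(N, M, f, seed = child_seed(seed, M))
    st <- suppressWarnings(imprint_patterns(p, z = z))
    res <- consolidate(st, p, config, neurons = neurons)
    pc <- res$diagnostics$per_cycle
    ok <- pc$min_margin[nrow(pc)] > 0
    evals <<- rbind(evals, data.frame(alpha = alpha, converged = ok))
    ok
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!feasible(lo)) stop_input("lower bracket is already infeasible")
  while (feasible(hi)) {
    lo <- hi
    hi <- hi * 1.5
    if (hi > 10) break
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  list(alpha_c = lo, evaluations = evals)
}

#' Final connection density across a load schedule
#'
#' Consolidates freshly generated and imprinted pattern sets at each load and
#' records the resulting connection density. Loads at which consolidation
#' fails to stabilize all patterns are reported as non-converged.
#'
#' @param N network size.
#' @param f coding level.
#' @param z number of synaptic components.
#' @param alphas vector of loads `M/N`.
#' @param config a [consolidation_config()].
#' @param neurons optional measured-neuron subset passed to [consolidate()].
#' @param seed integer seed.
#' @return Data frame with `alpha`, `density` (end-of-run floor density),
#'   `density_settled` (stationary-support density), `min_margin`,
#'   `converged`.
#' @export
density_vs_load <- function(N, f, z, alphas, config = consolidation_config(),
                            neurons = NULL, seed = 1L) {
  rows <- lapply(seq_along(alphas), function(i) {
    alpha <- alphas[i]
    M <- max(1L, round(alpha * N))
    p <- generate_patterns(N, M, f, seed = child_seed(seed, 100L + i))
    st <- suppressWarnings(imprint_patterns(p, z = z))
    res <- consolidate(st, p, config, neurons = neurons)
    pc <- res$diagnostics$per_cycle
    last <- pc[nrow(pc), ]
    data.frame(alpha = alpha, density = last$density,
               density_settled = res$diagnostics$density_settled,
               min_margin = last$min_margin,
               converged = last$min_margin > 0)
  })
  do.call(rbind, rows)
}

#' Minimum single-component connection density near capacity
#'
#' Convenience experiment: estimates the critical load for `z = 1`, steps
#' loads up toward it, consolidates at each, and returns the minimum
#' connection density over the converged loads, averaged over seeds. For
#' single-component (z = 1) weights this minimum approaches 1/2: at
#' capacity, maximum-margin solutions under a sign constraint leave half of
#' the weights at zero.
#'
#' @param N network size.
#' @param f coding level.
#' @param seeds integer seeds to average over.
#' @param load_fractions fractions of the estimated capacity to scan.
#' @param config a [consolidation_config()].
#' @param capacity_N network size for the capacity search (the critical load
#'   depends only weakly on N; a smaller search network keeps the experiment
#'   affordable).
#' @param capacity_config optionally lighter config for the capacity search.
#' @param n_measured number of measured postsynaptic neurons per run (their
#'   incoming-weight problems are independent and identically distributed,
#'   so a subset estimates the density ensemble without consolidating every
#'   row).
#' @return A list with `density` (mean over seeds of the minimum
#'   stationary-support density over loads), `per_seed` data frame, and
#'   `alpha_c`.
#' @export
density_floor_experiment <- function(N = 500L, f = 0.5, seeds = 1:3,
                                     load_fractions = c(0.75, 0.95),
                                     config = consolidation_config(
                                       cycles = 2200L, eta = 0.02,
                                       beta_growth = 1.01, beta_max = 1e4),
                                     capacity_N = 250L,
                                     capacity_config = NULL,
                                     n_measured = 150L) {
  if (is.null(capacity_config))
    capacity_config <- consolidation_config(
      cycles = 1200L, eta = config$eta, beta_growth = config$beta_growth,
      beta_max = config$beta_max)
  cap <- estimate_capacity(capacity_N, f, z = 1L, config = capacity_config,
                           bracket = c(0.2, 0.6), tol = 0.1, seed = seeds[1])
  per_seed <- lapply(seeds, function(s) {
    neurons <- with_seed(child_seed(s, 17L),
                         sample.int(N, min(n_measured, N)))
    dl <- density_vs_load(N, f, z = 1L, alphas = load_fractions * cap$alpha_c,
                          config = config, neurons = neurons, seed = s)
    dl$seed <- s
    dl
  })
  per_seed <- do.call(rbind, per_seed)
  conv <- per_seed[per_seed$converged, ]
  dens <- if (nrow(conv)) {
    min_by_seed <- tapply(conv$density_settled, conv$seed, min)
    mean(min_by_seed)
  } else NA_real_
  list(density = dens, per_seed = per_seed, alpha_c = cap$alpha_c)
}

#' Run a full wake/sleep experiment
#'
#' Orchestrates the end-to-end protocol: generate patterns, imprint them
#' (wake: dense, fragile storage), consolidate (sleep: sparse, robust
#' storage), then run the robustness and trajectory analyses on the
#' before/after states. When `out_dir` is given, all tables and states are
#' written as TSV together with a JSON manifest (inputs, seed, file
#' checksums) so a run can be reproduced bit for bit.
#'
#' @param N,M,f,z network and pattern parameters.
#' @param config a [consolidation_config()].
#' @param noise_kinds robustness assays to run (`"neural"`, `"synaptic"`).
#' @param trials recall trials per noise level.
#' @param out_dir optional output directory.
#' @param seed global seed, propagated to every stochastic stage.
#' @return A list with `patterns`, `state_pre`, `state_post`, `result`
#'   (consolidation result), `tolerance` (per noise kind), `analyses`
#'   (pruning and response-correlation tables), and `manifest`.
#' @export
run_wake_sleep <- function(N = 200L, M = 20L, f = 0.5, z = 2L,
                           config = consolidation_config(),
                           noise_kinds = c("neural", "synaptic"),
                           trials = 50L, out_dir = NULL, seed = 1L) {
  patterns <- generate_patterns(N, M, f, seed = child_seed(seed, 1L))
  state_pre <- suppressWarnings(imprint_patterns(patterns, z = z))
  result <- consolidate(state_pre, patterns, config)
  state_post <- result$state

  tolerance <- lapply(stats::setNames(nm = noise_kinds), function(kind)
    tolerated_noise(state_post, patterns, kind = kind, trials = trials,
                    seed = child_seed(seed, 2L + match(kind, noise_kinds))))
  analyses <- list(
    pruning = pruning_vs_weight(state_pre, state_post),
    response_correlation =
      response_correlation_connectivity(state_pre, state_post, patterns),
    snr_change = pattern_snr_change(state_pre, state_post, patterns))

  manifest <- list(
    run_id = sprintf("wake_sleep_N%d_M%d_z%d_seed%s", N, M, z, as.character(seed)),
    seed = seed, N = N, M = M, f = f, z = z,
    config = unclass(config)[c("cycles", "eta", "beta0", "beta_growth",
                               "prune_floor")],
    density_pre = connection_density(state_pre),
    density_post = connection_density(state_post),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_patterns(patterns, file.path(out_dir, "patterns.tsv"))
    write_state(state_pre, file.path(out_dir, "state_pre.tsv"))
    write_state(state_post, file.path(out_dir, "state_post.tsv"))
    utils::write.table(result$diagnostics$per_cycle,
                       file.path(out_dir, "diagnostics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (kind in noise_kinds)
      utils::write.table(tolerance[[kind]]$curve,
                         file.path(out_dir, sprintf("tolerance_%s.tsv", kind)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$files <- lapply(stats::setNames(files, basename(files)),
                             function(fp) unname(tools::md5sum(fp)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(patterns = patterns, state_pre = state_pre, state_post = state_post,
       result = result, tolerance = tolerance, analyses = analyses,
       manifest = manifest)
}
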