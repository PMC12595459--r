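# Shared fixtures, built in code at test time.

# Small pattern set + imprinted state, cached per (N, M, f, z, seed).
fixture_cache <- new.env(parent = emptyenv())

fixture_imprinted <- function(N, M, f = 0.5, z = 1L, seed = 42L) {
  key <- paste(N, M, f, z, seed, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    p <- generate_patterns(N, M, f, seed = seed)
    st <- suppressWarnings(imprint_patterns(p, z = z))
    fixture_cache[[key]] <- list(patterns = p, state = st)
  }
  fixture_cache[[key]]
}

# Consolidated state cache (configs are deterministic).
fixture_consolidated <- function(N, M, f = 0.5, z = 1L, seed = 42L,
                                 cycles = 800L, eta = 0.01,
                                 beta_growth = 1.003, ...) {
  key <- paste("cons", N, M, f, z, seed, cycles, eta, beta_growth, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fx <- fixture_imprinted(N, M, f, z, seed)
    res <- consolidate(fx$state, fx$patterns,
                       consolidation_config(cycles = cycles, eta = eta,
                                            beta_growth = beta_growth, ...))
    fixture_cache[[key]] <- list(patterns = fx$patterns, pre = fx$state,
                                 res = res, post = res$state)
  }
  fixture_cache[[key]]
}

# Exact power-law trajectory fixture: |dw| = c * w^x by construction, with
# alternating signs; strengths chosen on a log grid.
power_law_table <- function(x = 0.7, c0 = 0.01, n = 400, seed = 1L) {
  set.seed(seed)
  w0 <- 10^stats::runif(n, -2, 1)
  dw <- c0 * w0^x * ifelse(seq_len(n) %% 2 == 0, 1, -1)
  w1 <- pmax(w0 + dw, 1e-9)
  trajectory_table(
    data.frame(synapse_id = rep(seq_len(n), each = 2),
               time = rep(c(0, 0.5), n),
               strength = as.vector(rbind(w0, w1))),
    metadata = list(dt = 0.5))
}
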