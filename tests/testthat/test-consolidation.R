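test_that("gate matches its closed form and limits", {
  expect_equal(gate(log(2), 1), 0.5)
  expect_equal(gate(-log(2), 1), -0.5)
  expect_equal(gate(0, 1), -1)        # silent at threshold: pushed below
  expect_equal(gate(50, 2), exp(-100))
  expect_lt(abs(gate(1e6, 1)), 1e-300)   # strong memories: no plasticity
  expect_error(gate(1, 0), class = "synconsol_error")
})

test_that("learning rate normalizes total expression to the budget", {
  # single pattern: G * |g| = eta exactly
  g <- gate(0.3, 2)
  expect_equal(learning_rate(abs(g), eta = 0.7) * abs(g), 0.7)
  # two patterns with equal margins share the budget equally
  gs <- gate(c(0.4, -0.4), 1.5)
  G <- learning_rate(sum(abs(gs)), eta = 1)
  expect_equal(G * abs(gs), c(0.5, 0.5))
  # underflowed accumulation gives a zero rate, not Inf
  expect_identical(learning_rate(0, 1), 0)
})

test_that("soft-argmin identity: G * g equals eta * softmax(-beta * margin)", {
  fx <- fixture_imprinted(40, 4, seed = 40)   # fully stable imprint
  st <- fx$state; p <- fx$patterns
  beta <- 3 / median(abs(replay_cycle(st, p, 1)$I))
  acc <- replay_cycle(st, p, beta)
  eta <- 0.37
  G <- learning_rate(acc$gate_abs_sum, eta)
  # all patterns stable after imprinting, so margin = |I| and the expression
  # weights are an exact softmax over -beta |I|
  expect_true(all(stability_report(st, p)))
  softmax <- exp(-beta * abs(acc$I))
  softmax <- softmax / rowSums(softmax)
  expect_equal(abs(G * acc$g), eta * softmax, tolerance = 1e-12)
  expect_equal(rowSums(abs(G * acc$g)), rep(eta, 40))
})

test_that("one consolidation cycle equals replay -> learning rate -> expression", {
  fx <- fixture_imprinted(30, 3, z = 2)
  st <- fx$state; p <- fx$patterns
  cfg <- consolidation_config(cycles = 1, eta = 0.02, beta0 = 1,
                              beta_growth = 1)
  res <- consolidate(st, p, cfg)

  beta_i <- res$diagnostics$beta0_i
  acc <- replay_cycle(st, p, beta_i)
  G <- learning_rate(acc$gate_abs_sum, res$diagnostics$eta_i)
  manual <- express_and_scale(st, acc, G)
  expect_equal(res$state$u, manual$u, tolerance = 1e-12)
  expect_equal(res$state$I_inh, manual$I_inh, tolerance = 1e-12)
})

test_that("expression conserves the per-neuron factor norm and weight ratios", {
  fx <- fixture_imprinted(40, 4, z = 2)
  st <- fx$state; p <- fx$patterns
  U0 <- apply(st$u^2, 1, sum)
  res <- consolidate(st, p, consolidation_config(cycles = 50, eta = 0.02,
                                                 beta_growth = 1.01))
  U1 <- apply(res$state$u^2, 1, sum)
  expect_equal(U1, U0, tolerance = 1e-10)

  # homeostatic scaling alone preserves ratios of surviving weights exactly:
  # scale a state's factors per neuron and compare weight ratios
  lam <- runif(40, 0.5, 2)
  u_scaled <- st$u * lam
  w0 <- state_weights(st); w1 <- weights_from_factors(u_scaled)
  live <- w0 > 0
  ratio <- w1[live] / w0[live]
  expect_equal(ratio, (lam^st$z)[row(w0)[live]], tolerance = 1e-12)
})

test_that("replay signal reduces to the perceptron direction for z = 1", {
  fx <- fixture_imprinted(25, 3, z = 1)
  st <- fx$state; p <- fx$patterns
  acc <- replay_cycle(st, p, beta = 2)
  manual <- matrix(0, 25, 25)
  for (mu in 1:3) {
    g_mu <- acc$g[, mu]
    manual <- manual + outer(g_mu, p$xi[mu, ])
  }
  diag(manual) <- 0
  expect_equal(acc$delta[, , 1], manual, tolerance = 1e-12)
  # a silent presynaptic neuron contributes nothing
  silent <- which(colSums(p$xi) == 0)
  if (length(silent)) expect_true(all(acc$delta[, silent, 1] == 0))
})

test_that("for z >= 2, pruned synapses never regrow", {
  fx <- fixture_imprinted(30, 3, z = 2)
  st <- fx$state
  st$u[2, 5, ] <- 0
  st <- synaptic_state(st$u, st$I_inh)
  res <- consolidate(st, fx$patterns,
                     consolidation_config(cycles = 200, eta = 0.02,
                                          beta_growth = 1.01))
  expect_true(all(res$state$u[2, 5, ] == 0))
  # and more generally: the set of zero weights only grows
  w0 <- state_weights(st); w1 <- state_weights(res$state)
  expect_true(all(w1[w0 == 0] == 0))
})

test_that("consolidation increases the optimized SNR and the minimum margin", {
  for (z in c(1L, 2L)) {
    fx <- fixture_consolidated(60, 6, z = z, cycles = 600)
    q <- 2 / z
    snr_pre <- snr(fx$pre, fx$patterns, q)
    snr_post <- snr(fx$post, fx$patterns, q)
    expect_gt(mean(snr_post - snr_pre), 0)
    expect_gt(mean(snr_post >= snr_pre), 0.9)
    # stability is preserved with a larger margin
    expect_true(all(stability_report(fx$post, fx$patterns)))
    pc <- fx$res$diagnostics$per_cycle
    expect_gt(pc$min_margin[nrow(pc)], 0)

    # min-SNR trend non-decreasing over the final half (1% tolerance)
    half <- pc$snr_mean[(nrow(pc) / 2):nrow(pc)]
    expect_gt(half[length(half)], max(half) * 0.99)
  }
})

test_that("SNR obeys its scaling law and arithmetic", {
  fx <- fixture_imprinted(30, 3)
  p <- fx$patterns
  s1 <- snr(fx$state, p, q = 1)
  lam <- 2.5
  st2 <- synaptic_state(fx$state$u * lam, fx$state$I_inh * lam)
  s2 <- snr(st2, p, q = 1)
  expect_equal(s2, lam^(1 - 1 / 2) * s1, tolerance = 1e-10)
  expect_equal(snr(st2, p, q = 2), snr(fx$state, p, q = 2), tolerance = 1e-10)

  # single-synapse arithmetic: w = 4, margin 2, q = 1 -> SNR = 1
  u <- array(0, c(2, 2, 1)); u[1, 2, 1] <- 4
  st <- synaptic_state(u, c(2, 0))
  ps <- pattern_set(matrix(c(1, 1), 1), f = 0.5)
  expect_equal(snr(st, ps, q = 1)[1], 2 / 2)
  expect_error(snr(st, ps, q = 3), class = "synconsol_error")
})

test_that("misaligned factors re-align during consolidation", {
  fx <- fixture_imprinted(50, 5, z = 2)
  stm <- misalign_factors(fx$state, fx$patterns, sdlog = 0.5, seed = 9)
  res <- consolidate(stm, fx$patterns,
                     consolidation_config(cycles = 1500, eta = 0.01,
                                          beta_growth = 1.003))
  pc <- res$diagnostics$per_cycle
  rel <- pc$misalignment / pc$mean_factor
  expect_gt(rel[1], 0.2)
  expect_lt(rel[nrow(pc)], 0.03)
  # decay is monotone in the cycle average
  cum <- cumsum(rel) / seq_along(rel)
  expect_true(all(diff(cum) <= 1e-9))
})
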