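test_that("simulator output is reproducible, nonnegative, and well-formed", {
  tab <- simulate_synapses(n = 50, z = 2, T_total = 6, dt = 0.5, seed = 3)
  tab2 <- simulate_synapses(n = 50, z = 2, T_total = 6, dt = 0.5, seed = 3)
  expect_identical(tab, tab2)
  expect_true(all(tab$strength >= 0))
  expect_equal(nrow(tab), 50 * 13)
  md <- attr(tab, "metadata")
  expect_equal(md$z, 2)
  # times strictly increasing per synapse
  expect_true(all(tapply(tab$time, tab$synapse_id, function(x) all(diff(x) > 0))))
})

test_that("pruning is absorbing for multi-factor synapses", {
  tab <- simulate_synapses(n = 200, z = 2, sigma = 0.5, w0_meanlog = -2,
                           T_total = 24, dt = 0.5, seed = 5)
  hit <- tapply(tab$strength, tab$synapse_id, function(w) {
    iz <- which(w == 0)
    length(iz) == 0 || all(w[iz[1]:length(w)] == 0)
  })
  expect_true(all(hit))
  # with this much noise on small weights some synapses must actually prune
  expect_gt(sum(tapply(tab$strength, tab$synapse_id, function(w) any(w == 0))), 0)
})

test_that("homeostatic mode conserves the population mass exactly", {
  for (z in c(1L, 2L)) {
    tab <- simulate_synapses(n = 100, z = z, sigma = 0.05, T_total = 12,
                             dt = 0.5, homeostatic = TRUE, seed = 9)
    W <- matrix(tab$strength, nrow = 25)   # time x synapse (column-major)
    mass_t <- rowSums(W^(2 / z))
    expect_equal(max(abs(mass_t / mass_t[1] - 1)), 0, tolerance = 1e-10)
    # the matching norm has zero CV across time
    nr <- norm_cv(tab, q_grid = c(0.5, 1, 2 / z, 2), n_boot = 0)
    expect_equal(nr$cv[match(2 / z, nr$q_grid)], 0, tolerance = 1e-12)
  }
})

test_that("volatility scale of weight changes follows 1 - 1/z", {
  # z = 1: additive noise, change magnitude independent of weight
  t1 <- simulate_synapses(n = 400, z = 1, sigma = 0.05, T_total = 24,
                          dt = 0.5, seed = 2)
  f1 <- fluctuation_scaling(t1, n_boot = 20, window = 51, seed = 1)
  expect_true(all(abs(f1$slope) < 0.15))
  # z = 2: multiplicative in sqrt(w)
  t2 <- simulate_synapses(n = 400, z = 2, sigma = 0.05, T_total = 24,
                          dt = 0.5, seed = 2)
  f2 <- fluctuation_scaling(t2, n_boot = 20, window = 51, seed = 1)
  expect_true(all(abs(f2$slope - 0.5) < 0.1))
})
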