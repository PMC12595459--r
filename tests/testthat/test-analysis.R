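test_that("fluctuation scaling recovers an exact power law on all estimators", {
  tab <- power_law_table(x = 0.7, n = 400)
  for (m in c("moving", "raw")) {
    fit <- fluctuation_scaling(tab, n_boot = 10, window = 51, method = m, seed = 1)
    expect_equal(nrow(fit), 2L)
    expect_equal(fit$slope, c(0.7, 0.7), tolerance = 1e-6)
  }
  fit_rmsd <- fluctuation_scaling(tab, n_boot = 10, window = 51,
                                  method = "rmsd", seed = 1)
  expect_equal(fit_rmsd$slope, c(0.7, 0.7), tolerance = 0.05)
})

test_that("fluctuation scaling is invariant under global rescaling", {
  tab <- simulate_synapses(n = 200, z = 2, T_total = 12, dt = 0.5, seed = 4)
  tab_scaled <- trajectory_table(
    transform(as.data.frame(tab), strength = strength * 37),
    metadata = attr(tab, "metadata"))
  f1 <- fluctuation_scaling(tab, n_boot = 5, window = 51, seed = 2)
  f2 <- fluctuation_scaling(tab_scaled, n_boot = 5, window = 51, seed = 2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("bootstrap standard errors are reproducible and sane", {
  tab <- simulate_synapses(n = 300, z = 2, T_total = 24, dt = 0.5, seed = 6)
  f1 <- fluctuation_scaling(tab, n_boot = 30, seed = 11)
  f2 <- fluctuation_scaling(tab, n_boot = 30, seed = 11)
  expect_identical(f1, f2)
  expect_true(all(f1$slope_se > 0 & f1$slope_se < 0.3))
})

test_that("norm CV identifies conserved norms and flat spectra", {
  # construction: total strength conserved -> q_min = 1 with zero CV
  set.seed(2)
  n <- 60; tpts <- 20
  W <- matrix(rlnorm(n * tpts), tpts, n)
  W <- W / rowSums(W)                   # sum w = const across time
  tab <- trajectory_table(data.frame(
    synapse_id = rep(seq_len(n), each = tpts),
    time = rep(seq_len(tpts) * 0.5, n),
    strength = as.vector(W)))
  res <- norm_cv(tab, q_grid = seq(0.25, 3, 0.25), n_boot = 50, seed = 1)
  expect_equal(res$q_min, 1)
  expect_equal(res$cv[res$q_grid == 1], 0, tolerance = 1e-12)
  expect_equal(res$cv_rank[res$q_grid == 1], 0)

  # i.i.d. global rescaling factors out of every norm -> flat CV curve
  lam <- exp(rnorm(tpts, sd = 0.3))
  W2 <- matrix(rlnorm(n), tpts, n, byrow = TRUE) * lam
  tab2 <- trajectory_table(data.frame(
    synapse_id = rep(seq_len(n), each = tpts),
    time = rep(seq_len(tpts) * 0.5, n),
    strength = as.vector(W2)))
  res2 <- norm_cv(tab2, n_boot = 0)
  expect_lt(diff(range(res2$cv)), 1e-10)
})

test_that("tuning sparseness matches closed-form endpoints", {
  # uniform responses -> 0
  expect_equal(as.numeric(tuning_sparseness(matrix(3, 5, 8))), 0)
  # one-hot responses -> 1
  onehot <- diag(6) * 2.5
  expect_equal(as.numeric(tuning_sparseness(onehot)), 1)
  # intermediate case against the direct formula
  r <- matrix(c(1, 2, 3, 4), 1)
  a <- mean(r)^2 / mean(r^2)
  expect_equal(as.numeric(tuning_sparseness(r)), (1 - a) / (1 - 1 / 4))
  # all-zero rows are excluded and counted
  rz <- rbind(c(0, 0, 0), c(1, 0, 0))
  s <- tuning_sparseness(rz)
  expect_equal(attr(s, "n_excluded"), 1L)
  expect_error(tuning_sparseness(matrix(-1, 2, 2)), class = "synconsol_error")
})

test_that("pruning analysis handles degenerate and generic outcomes", {
  set.seed(5)
  w <- matrix(rlnorm(400), 20, 20); diag(w) <- 0
  # unchanged weights: zero pruning probability everywhere
  expect_warning(res_same <- pruning_vs_weight(w, w, bins = 4))
  expect_true(all(res_same$by_bin$p_prune == 0))
  # everything pruned: probability one
  expect_warning(res_all <- pruning_vs_weight(w, w * 0, bins = 4))
  expect_true(all(res_all$by_bin$p_prune == 1))
  # weight-dependent pruning gives a negative logistic slope
  wa <- w * (matrix(runif(400), 20, 20) < plogis(log(w + 1e-12)))
  res <- pruning_vs_weight(w, wa, bins = 5)
  expect_lt(res$slope, 0)
})

test_that("pattern SNR change is zero for identical states", {
  fx <- fixture_imprinted(60, 5)
  out <- pattern_snr_change(fx$state, fx$state, fx$patterns, q = 2)
  expect_true(all(out$table$delta == 0))
})
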