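test_that("generated patterns are Bernoulli(f), reproducible, and sized", {
  p <- generate_patterns(N = 100, M = 10, f = 0.5, seed = 7)
  expect_equal(dim(p$xi), c(10, 100))
  expect_true(all(p$xi %in% c(0, 1)))
  expect_equal(p$alpha, 0.1)
  expect_lt(abs(mean(p$xi) - 0.5), 3 * sqrt(0.25 / 1000))

  # same seed -> identical; different seed -> different
  p2 <- generate_patterns(100, 10, 0.5, seed = 7)
  expect_identical(p$xi, p2$xi)
  p3 <- generate_patterns(100, 10, 0.5, seed = 8)
  expect_false(identical(p$xi, p3$xi))

  # load arithmetic of a sparse set
  ps <- generate_patterns(N = 1000, M = 440, f = 0.05, seed = 1)
  expect_equal(ps$alpha, 0.44)
  expect_lt(abs(mean(ps$xi) - 0.05), 3 * sqrt(0.05 * 0.95 / (440 * 1000)))

  # chi-square goodness of fit of ones count across several seeds
  pvals <- vapply(1:5, function(s) {
    x <- generate_patterns(200, 20, 0.3, seed = s)$xi
    n1 <- sum(x)
    stats::binom.test(n1, length(x), p = 0.3)$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.01 / 5)
})

test_that("coding-level contract is enforced", {
  expect_error(generate_patterns(10, 2, f = 0.6), class = "synconsol_error")
  expect_error(generate_patterns(10, 2, f = 0), class = "synconsol_error")
  expect_error(generate_patterns(1, 2, f = 0.5), class = "synconsol_error")
})

test_that("imprinting stores patterns as fixed points with nonnegative weights", {
  # single pattern: trivially a fixed point
  p1 <- pattern_set(matrix(c(1, 0, 1, 0, 1, 0), 1), f = 0.5)
  s1 <- imprint_patterns(p1)
  expect_true(all(stability_report(s1, p1)))

  fx <- fixture_imprinted(100, 5, 0.5, z = 1)
  rep <- stability_report(fx$state, fx$patterns)
  expect_true(all(rep))
  w <- state_weights(fx$state)
  expect_true(all(w >= 0))
  expect_true(all(diag(w) == 0))

  # factorization is exact for any z
  fz <- fixture_imprinted(50, 3, 0.5, z = 3)
  expect_equal(weights_from_factors(fz$state$u),
               state_weights(fixture_imprinted(50, 3, 0.5, z = 1)$state),
               tolerance = 1e-12)

  # dynamics one step from each pattern reproduce the pattern
  for (mu in 1:5) {
    out <- update_step(fx$patterns$xi[mu, ], fx$state)
    expect_equal(out$s, fx$patterns$xi[mu, ])
  }
})

test_that("imprinting reports unstable patterns instead of silently accepting", {
  p <- generate_patterns(50, 45, 0.5, seed = 3)   # load beyond the Hebbian rule
  expect_warning(st <- imprint_patterns(p), "unstable")
  expect_false(all(attr(st, "stability")))
})

test_that("stability report follows the strict-threshold convention", {
  # zero weights with positive inhibition: only silent targets are stable
  p <- pattern_set(rbind(c(1, 0, 1), c(0, 1, 1)), f = 0.5)
  st <- synaptic_state(array(0, c(3, 3, 1)), I_inh = rep(0.5, 3))
  rep <- stability_report(st, p)
  expect_identical(unname(rep), p$xi == 0)
  # zero input with zero inhibition is still silent (Theta(0) = 0)
  st0 <- synaptic_state(array(0, c(3, 3, 1)), I_inh = rep(0, 3))
  expect_identical(unname(stability_report(st0, p)), p$xi == 0)
})
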