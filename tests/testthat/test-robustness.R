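test_that("neural noise flips bits at the requested rate", {
  s <- rep(c(0, 1), 500)
  expect_identical(apply_neural_noise(s, 0, seed = 1), s)
  s2 <- apply_neural_noise(s, 0.2, seed = 1)
  expect_true(all(s2 %in% c(0, 1)))
  d <- mean(s2 != s)
  expect_lt(abs(d - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
  # f_noise = 0.5: output independent of input (hamming ~ 1/2 regardless)
  s3 <- apply_neural_noise(s, 0.5, seed = 2)
  expect_lt(abs(mean(s3 != s) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(apply_neural_noise(s, 0.6), class = "synconsol_error")
})

test_that("synaptic noise hits only the volatile component of live synapses", {
  fx <- fixture_imprinted(40, 4, z = 2)
  st <- fx$state
  expect_identical(apply_synaptic_noise(st, 0), st)
  pert <- apply_synaptic_noise(st, 0.3, seed = 7)
  expect_identical(pert$u[, , 2], st$u[, , 2])      # stable component untouched
  expect_true(all(pert$u >= 0))
  dead <- st$u[, , 1] == 0
  expect_true(all(pert$u[, , 1][dead] == 0))        # absent synapses stay absent

  # first-order weight perturbation on aligned two-factor synapses ~ eps*sqrt(w)
  sigma <- 1e-4
  pert2 <- apply_synaptic_noise(st, sigma, relative = FALSE, seed = 8)
  w0 <- state_weights(st); w1 <- state_weights(pert2)
  live <- w0 > 0
  dw <- (w1 - w0)[live]
  ratio <- abs(dw) / sqrt(w0[live])
  eps <- abs(pert2$u[, , 1] - st$u[, , 1])[live]
  expect_equal(ratio, eps, tolerance = 1e-2)
})

test_that("input fluctuation scale matches its closed forms", {
  fx <- fixture_imprinted(30, 3, z = 2)
  w <- state_weights(fx$state)
  s <- fx$patterns$xi[1, ]
  expect_equal(input_fluctuation_scale(fx$state, s, "neural"),
               sqrt(as.numeric((w^2) %*% s)))
  expect_equal(input_fluctuation_scale(fx$state, s, "synaptic"),
               sqrt(as.numeric(w %*% s)))          # q = 2 - 2/2 = 1
  # z = 1 synaptic: q = 0 counts live active inputs
  f1 <- fixture_imprinted(30, 3, z = 1)
  w1 <- state_weights(f1$state)
  expect_equal(input_fluctuation_scale(f1$state, s, "synaptic"),
               sqrt(as.numeric((w1 > 0) %*% s)))
})

test_that("tolerated noise reporting: fragile imprints, monotone success curve", {
  fx <- fixture_consolidated(100, 6, z = 1, cycles = 600)
  tol <- tolerated_noise(fx$post, fx$patterns, "neural", trials = 40,
                         levels = seq(0, 0.5, 0.1), refine = 2, seed = 3)
  expect_true(all(diff(tol$curve$level) > 0))
  expect_gte(tol$level, 0)
  # success at zero noise is perfect for a consolidated state
  expect_equal(tol$curve$success[tol$curve$level == 0], 1)
  # measured curve is non-increasing up to sampling error
  expect_true(all(diff(tol$curve$success) <= 0.15))

  # a merely imprinted state tolerates (almost) no synaptic noise relative
  # to its consolidated counterpart
  tol_pre <- tolerated_noise(fx$pre, fx$patterns, "synaptic", trials = 40,
                             levels = seq(0, 2, 0.5), refine = 2, seed = 3)
  tol_post <- tolerated_noise(fx$post, fx$patterns, "synaptic", trials = 40,
                              levels = seq(0, 2, 0.5), refine = 2, seed = 3)
  expect_gt(tol_post$level, tol_pre$level)
})
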