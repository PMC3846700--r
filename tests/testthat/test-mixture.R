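test_that("mixture posteriors equal HMM posteriors with identical rows", {
  for (s in 1:5) {
    d <- random_dataset(500, R = 2L, seed = 100 + s)
    m <- random_model(R = 2L, seed = s)
    pi1 <- runif(1, 0.1, 0.9)
    logB <- emission_loglik(d, m$emissions)
    A <- rbind(c(1 - pi1, pi1), c(1 - pi1, pi1))
    fb <- forward_backward(logB, A, c(1 - pi1, pi1))
    mix <- hmmchip:::mixture_e_step(logB, pi1)
    expect_equal(fb$posterior, mix$posterior, tolerance = 1e-10)
    expect_equal(fb$loglik, mix$loglik, tolerance = 1e-8)
  }
})

test_that("mixture EM recovers the mixing proportion", {
  # iid states at the stationary enriched fraction of the benchmark chain
  pi_true <- 3 / 13
  cfg <- sim_config(
    n_probes = 10000, n_replicates = 2,
    A = rbind(c(1 - pi_true, pi_true), c(1 - pi_true, pi_true)),
    intercepts = c(0, 0), slopes = c(0.6, 0.99), sigma2 = c(0.7, 0.75),
    seed = 17
  )
  sim <- simulate_probes(cfg)
  fit <- hmmchip(sim$data, spatial = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - pi_true), 0.03)
  expect_equal(fit$model$emissions$slopes[2, ], c(0.99, 0.99),
               tolerance = 0.05, ignore_attr = TRUE)
  # mixture loglik trajectory is non-decreasing too
  expect_true(all(diff(fit$loglik_trajectory) > -1e-8))
  # stored degenerate transition matrix has both rows (1 - pi, pi)
  expect_equal(fit$model$A[1, ], fit$model$A[2, ], tolerance = 1e-12)
})

test_that("a collapsing mixing proportion is floored and flagged", {
  # every probe comes from the non-enriched component, and the fit starts
  # with a vanishing enriched proportion: pi is driven to the boundary,
  # floored at 1e-6, and the fit is flagged as not converged
  cfg <- sim_config(
    n_probes = 2000, n_replicates = 2,
    A = rbind(c(1, 0), c(1, 0)),  # chain never leaves the non-enriched state
    intercepts = c(0, 0), slopes = c(0.6, 0.99), sigma2 = c(0.7, 0.75),
    seed = 23, initial_state_rule = "fixed"
  )
  sim <- simulate_probes(cfg)
  expect_true(all(sim$true_states == 0))
  init <- hmm_model(
    eta = c(1 - 1e-7, 1e-7), A = matrix(0.5, 2, 2),
    emissions = emission_params(rbind(c(0, 0), c(0, 0)),
                                rbind(c(0.6, 0.6), c(0.99, 0.99)),
                                c(0.7, 0.75))
  )
  fit <- hmmchip(sim$data, spatial = FALSE, init = init, max_iter = 25)
  expect_gte(fit$pi, 1e-6)
  expect_lt(fit$pi, 0.05)
  expect_false(fit$converged)
})

test_that("posterior combination rules are element-wise min and max", {
  p <- list(c(0.3, 0.1, 0.9), c(0.8, 0.5, 0.2))
  expect_equal(combine_posteriors(p, "min"), c(0.3, 0.1, 0.2))
  expect_equal(combine_posteriors(p, "max"), c(0.8, 0.5, 0.9))
  # historical labels map union -> min, intersection -> max
  expect_equal(combine_posteriors(p, "union"), combine_posteriors(p, "min"))
  expect_equal(combine_posteriors(p, "intersection"),
               combine_posteriors(p, "max"))
  # single replicate: identity under either rule
  expect_equal(combine_posteriors(p[1], "min"), p[[1]])
  expect_equal(combine_posteriors(p[1], "max"), p[[1]])
  # three replicates
  q <- list(0.1, 0.5, 0.9)
  expect_equal(combine_posteriors(q, "min"), 0.1)
  expect_equal(combine_posteriors(q, "max"), 0.9)
  expect_error(combine_posteriors(list()), "non-empty")
  expect_error(combine_posteriors(list(1:2 / 10, 1:3 / 10)), "same length")
})

test_that("combined posteriors bound the per-replicate posteriors", {
  set.seed(31)
  p <- list(runif(50), runif(50), runif(50))
  lo <- combine_posteriors(p, "min")
  hi <- combine_posteriors(p, "max")
  for (v in p) {
    expect_true(all(lo <= v))
    expect_true(all(v <= hi))
  }
})
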