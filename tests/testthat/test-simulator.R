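test_that("simulation is reproducible from its seed and varies across seeds", {
  cfg <- scenario_config(1, n_probes = 500, seed = 11)
  s1 <- simulate_probes(cfg)
  s2 <- simulate_probes(cfg)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$true_states, s2$true_states)
  s3 <- simulate_probes(scenario_config(1, n_probes = 500, seed = 12))
  expect_false(identical(s1$data$y, s3$data$y))
})

test_that("scenario configurations carry the benchmark parameters", {
  c1 <- scenario_config(1, n_probes = 100, seed = 1)
  expect_equal(c1$slopes, rbind(c(0.6, 0.6), c(0.99, 0.99)),
               ignore_attr = TRUE)
  expect_equal(c1$sigma2, c(0.7, 0.75))
  expect_equal(c1$A, rbind(c(0.97, 0.03), c(0.1, 0.9)), ignore_attr = TRUE)
  expect_equal(c1$n_replicates, 2L)
  c2 <- scenario_config(2, n_probes = 100, seed = 1)
  expect_equal(c2$slopes, rbind(c(0.5, 0.5), c(0.65, 0.65)),
               ignore_attr = TRUE)
  expect_error(scenario_config(3), "1 or 2")
})

test_that("hidden chain matches its stationary law and transition matrix", {
  sim <- simulate_probes(scenario_config(1, n_probes = 100000, seed = 4))
  z <- sim$true_states
  # stationary enriched fraction of the chain: 0.03 / (0.03 + 0.1) = 3/13
  expect_lt(abs(mean(z) - 3 / 13), 0.01)
  # empirical transition frequencies
  from <- z[-length(z)]; to <- z[-1]
  for (i in 0:1) for (j in 0:1) {
    emp <- mean(to[from == i] == j)
    expect_lt(abs(emp - sim$config$A[i + 1, j + 1]), 0.01)
  }
})

test_that("emission noise has the configured variance and zero mean", {
  sim <- simulate_probes(scenario_config(1, n_probes = 100000, seed = 9))
  cfg <- sim$config
  z <- sim$true_states
  for (r in 1:2) {
    resid <- sim$data$y[, r] - cfg$intercepts[z + 1, r] -
      cfg$slopes[z + 1, r] * sim$data$x[, r]
    expect_lt(abs(mean(resid)), 0.02)
    expect_lt(abs(var(resid) / cfg$sigma2[r] - 1), 0.02)
  }
  # log-Input values honor the configured uniform range
  expect_gte(min(sim$data$x), 8)
  expect_lte(max(sim$data$x), 14)
})

test_that("multi-chromosome output is ordered and restarts the chain", {
  sim <- simulate_probes(sim_config(
    n_probes = 1000, n_replicates = 1, A = rbind(c(0.9, 0.1), c(0.2, 0.8)),
    intercepts = c(0, 1), slopes = c(0.5, 1), sigma2 = 0.5, seed = 2,
    n_chromosomes = 4
  ))
  expect_equal(length(unique(sim$data$probes$chromosome)), 4L)
  expect_equal(nrow(sim$data$probes), 1000L)
  pos <- split(sim$data$probes$position, sim$data$probes$chromosome)
  expect_true(all(vapply(pos, function(p) all(diff(p) > 0), logical(1))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(1, 1, diag(2), c(0, 0), c(0.5, 1), 1), ">= 2")
  expect_error(sim_config(10, 1, diag(2), c(0, 0), c(0.5, 1), -1),
               "positive")
  expect_error(sim_config(10, 1, rbind(c(0.5, 0.6), c(0.5, 0.5)),
                          c(0, 0), c(0.5, 1), 1), "row-stochastic")
  expect_error(sim_config(10, 1, diag(2), c(0, 0), c(0.5, 1), 1,
                          x_dist = list(family = "uniform", min = 3,
                                        max = 2)), "min < max")
  expect_error(sim_config(10, 1, diag(2), c(0, 0), c(0.5, 1), 1,
                          x_dist = list(family = "cauchy")), "unknown")
})
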