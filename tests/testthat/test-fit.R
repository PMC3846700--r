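test_that("one EM iteration matches the brute-force E/M-step oracle", {
  d <- random_dataset(5, R = 2L, seed = 42)
  m <- random_model(R = 2L, seed = 9)
  oracle <- em_one_iteration_brute(d, m)
  # oracle slopes keep state 1 steeper here, so no relabeling occurs
  fit <- hmmchip(d, init = m, tol = 1e-300, max_iter = 1L)
  expect_equal(fit$model$emissions$intercepts, oracle$intercepts,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$model$emissions$slopes, oracle$slopes,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$model$emissions$sigma2, oracle$sigma2, tolerance = 1e-9)
  expect_equal(fit$model$A, oracle$A, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$model$eta, oracle$eta, tolerance = 1e-9)
  expect_equal(fit$loglik_trajectory,
               c(oracle$loglik_before, oracle$loglik_after),
               tolerance = 1e-9)
  expect_equal(fit$posterior, oracle$posterior_after[, 2], tolerance = 1e-9)
})

test_that("log-likelihood trajectory is non-decreasing from any start", {
  d <- random_dataset(300, R = 2L, seed = 15)
  for (s in 1:8) {
    fit <- hmmchip(d, init = random_model(R = 2L, seed = s), max_iter = 40L)
    expect_true(all(diff(fit$loglik_trajectory) > -1e-8))
    expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  }
})

test_that("enriched state carries the larger mean slope after relabeling", {
  sim <- simulate_probes(scenario_config(1, n_probes = 3000, seed = 2))
  init <- pca_init(sim$data)
  # deliberately swap the init so state 0 starts steeper
  init$emissions$slopes <- init$emissions$slopes[2:1, ]
  init$emissions$intercepts <- init$emissions$intercepts[2:1, ]
  fit <- hmmchip(sim$data, init = init)
  sl <- fit$model$emissions$slopes
  expect_gt(mean(sl[2, ]), mean(sl[1, ]))
  # posterior follows the labels: enriched probes get high posteriors
  expect_gt(mean(fit$posterior[sim$true_states == 1]), 0.9)
  expect_lt(mean(fit$posterior[sim$true_states == 0]), 0.1)
})

test_that("chromosome order does not affect the fit", {
  sim <- simulate_probes(sim_config(
    n_probes = 900, n_replicates = 2,
    A = rbind(c(0.95, 0.05), c(0.1, 0.9)),
    intercepts = c(0, 0), slopes = c(0.5, 0.9), sigma2 = c(0.7, 0.75),
    seed = 8, n_chromosomes = 3
  ))
  d <- sim$data
  perm <- order(match(d$probes$chromosome, c("chr3", "chr1", "chr2")))
  d2 <- probe_dataset(d$probes$probe_id[perm], d$probes$chromosome[perm],
                      d$probes$position[perm], d$x[perm, ], d$y[perm, ])
  f1 <- hmmchip(d, init = pca_init(d))
  f2 <- hmmchip(d2, init = pca_init(d2))
  expect_equal(f1$model$emissions$slopes, f2$model$emissions$slopes,
               tolerance = 1e-8)
  expect_equal(f1$model$A, f2$model$A, tolerance = 1e-8)
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-8)
  # same probes, same posteriors (up to the permutation)
  m <- match(d$probes$probe_id, d2$probes$probe_id)
  expect_equal(f1$posterior, f2$posterior[m], tolerance = 1e-8)
})

test_that("fitted parameters recover the generating model", {
  sim <- simulate_probes(scenario_config(1, n_probes = 10000, seed = 31))
  fit <- hmmchip(sim$data)
  expect_true(fit$converged)
  expect_equal(fit$model$emissions$slopes[1, ], c(0.6, 0.6),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(fit$model$emissions$slopes[2, ], c(0.99, 0.99),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(fit$model$emissions$sigma2, c(0.7, 0.75), tolerance = 0.08)
  expect_true(all(abs(fit$model$A - rbind(c(0.97, 0.03), c(0.1, 0.9)))
                  < 0.03))
})

test_that("degenerate inputs raise informative errors", {
  d <- random_dataset(50, R = 1L, seed = 3)
  expect_error(hmmchip(d, tol = -1), "tol")
  expect_error(hmmchip(d, max_iter = 0), "max_iter")
  # constant log-Input: PCA initialization is undefined
  dc <- probe_dataset(sprintf("p%02d", 1:20), rep("c1", 20), 1:20 * 10L,
                      matrix(5, 20), matrix(rnorm(20), 20))
  expect_error(hmmchip(dc), "degenerate")
})

test_that("accessor methods are consistent with the fit", {
  sim <- simulate_probes(scenario_config(1, n_probes = 1500, seed = 5))
  fit <- hmmchip(sim$data)
  co <- coef(fit)
  expect_equal(unname(co$slopes), fit$model$emissions$slopes,
               ignore_attr = TRUE)
  expect_equal(dim(residuals(fit)), dim(sim$data$y))
  expect_equal(residuals(fit), sim$data$y - fitted(fit))
  pr <- predict(fit)
  expect_equal(pr$posterior_enriched, fit$posterior)
  expect_equal(pr$status, classify_probes(fit$posterior, fit$alpha))
  # prediction on new data at fixed parameters, then on the training data
  sim2 <- simulate_probes(scenario_config(1, n_probes = 500, seed = 6))
  pr2 <- predict(fit, newdata = sim2$data)
  expect_equal(nrow(pr2), 500L)
  expect_true(all(pr2$posterior_enriched >= 0 & pr2$posterior_enriched <= 1))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 13L)  # 5R + 3 with R = 2
  s <- summary(fit)
  expect_equal(s$n_enriched, sum(fit$posterior > 1 - fit$alpha))
})
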