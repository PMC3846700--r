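# Independent brute-force oracles used to validate the dynamic-programming
# and EM code paths. These enumerate all 2^T hidden-state paths, so they are
# only usable for tiny T, and deliberately share no code with the package
# internals.

# posteriors, summed pairwise expectations and log-likelihood by full
# path enumeration
fb_brute <- function(logB, A, eta) {
  Tn <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lp <- apply(paths, 1L, function(z) {
    v <- log(eta[z[1L]]) + logB[1L, z[1L]]
    if (Tn > 1L)
      for (t in 2:Tn) v <- v + log(A[z[t - 1L], z[t]]) + logB[t, z[t]]
    v
  })
  M <- max(lp)
  w <- exp(lp - M)
  tot <- sum(w)
  post <- matrix(0, Tn, 2L)
  for (t in seq_len(Tn))
    for (k in 1:2) post[t, k] <- sum(w[paths[, t] == k]) / tot
  xi <- matrix(0, 2L, 2L)
  if (Tn > 1L)
    for (t in seq_len(Tn - 1L))
      for (i in 1:2)
        for (j in 1:2)
          xi[i, j] <- xi[i, j] +
            sum(w[paths[, t] == i & paths[, t + 1L] == j]) / tot
  list(posterior = post, xi_sum = xi, loglik = M + log(tot))
}

# emission log-density matrix computed independently of the package
logB_brute <- function(x, y, a, b, s2) {
  Tn <- nrow(as.matrix(x))
  out <- matrix(0, Tn, 2L)
  for (z in 1:2)
    for (r in seq_len(ncol(as.matrix(x))))
      out[, z] <- out[, z] +
        dnorm(as.matrix(y)[, r],
              a[z, r] + b[z, r] * as.matrix(x)[, r], sqrt(s2[r]), log = TRUE)
  out
}

# one full EM iteration (brute-force E-step, weighted lm() M-step) for a
# single-chromosome dataset
em_one_iteration_brute <- function(data, model) {
  em <- model$emissions
  logB <- logB_brute(data$x, data$y, em$intercepts, em$slopes, em$sigma2)
  e <- fb_brute(logB, model$A, model$eta)
  R <- data$n_replicates
  a <- b <- matrix(NA_real_, 2L, R)
  s2 <- numeric(R)
  for (r in seq_len(R)) {
    rss <- 0
    for (z in 1:2) {
      f <- lm(data$y[, r] ~ data$x[, r], weights = e$posterior[, z])
      a[z, r] <- coef(f)[1L]
      b[z, r] <- coef(f)[2L]
      rss <- rss + sum(e$posterior[, z] *
                         (data$y[, r] - a[z, r] - b[z, r] * data$x[, r])^2)
    }
    s2[r] <- rss / nrow(data$x)
  }
  A_new <- e$xi_sum / rowSums(e$xi_sum)
  eta_new <- e$posterior[1L, ]
  # log-likelihood and posteriors under the updated parameters
  logB2 <- logB_brute(data$x, data$y, a, b, s2)
  e2 <- fb_brute(logB2, A_new, eta_new)
  post <- e2$posterior
  # same label-identification rule as the package: enriched = steeper slope
  if (mean(b[2L, ]) < mean(b[1L, ])) {
    a <- a[2:1, , drop = FALSE]
    b <- b[2:1, , drop = FALSE]
    A_new <- A_new[2:1, 2:1]
    eta_new <- rev(eta_new)
    post <- post[, 2:1, drop = FALSE]
  }
  list(intercepts = a, slopes = b, sigma2 = s2, A = A_new, eta = eta_new,
       loglik_before = e$loglik, loglik_after = e2$loglik,
       posterior_after = post)
}

# small random dataset on one chromosome (not from the package simulator)
random_dataset <- function(Tn, R = 2L, seed = 1L) {
  set.seed(seed)
  x <- matrix(runif(Tn * R, 8, 14), Tn, R)
  y <- matrix(rnorm(Tn * R, 0.7 * x, 1), Tn, R)
  probe_dataset(sprintf("p%03d", seq_len(Tn)), rep("chrA", Tn),
                seq_len(Tn) * 10L, x, y)
}

random_model <- function(R = 2L, seed = 1L) {
  set.seed(seed)
  p <- runif(2, 0.05, 0.95)
  A <- rbind(c(1 - p[1], p[1]), c(p[2], 1 - p[2]))
  eta <- c(0.5, 0.5)
  hmm_model(eta, A, emission_params(
    intercepts = matrix(runif(2 * R, -1, 1), 2L, R),
    slopes = rbind(runif(R, 0.3, 0.6), runif(R, 0.8, 1.2)),
    sigma2 = runif(R, 0.5, 1.5)
  ))
}
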