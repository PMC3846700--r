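#' Fit the two-state regression HMM (or mixture) to ChIP-chip probes
#'
#' The model classifies probes as enriched or non-enriched by jointly
#' modeling, across all biological replicates, the log-IP intensity as a
#' linear regression of the log-Input intensity with state-specific intercept
#' and slope and a per-replicate variance shared by both states. With
#' `spatial = TRUE` (the default) the hidden states form a first-order Markov
#' chain along each chromosome, so that runs of adjacent enriched probes
#' reinforce each other; with `spatial = FALSE` the chain is replaced by a
#' single mixing proportion `pi` of enriched probes and probes are treated as
#' independent. All parameters are estimated by the Baum-Welch algorithm
#' (EM); the E-step uses a scaled forward-backward recursion per chromosome
#' with statistics pooled across chromosomes, and the M-step consists of
#' posterior-weighted least-squares regressions per state and replicate,
#' pooled residual variances, and transition (or mixing) updates from the
#' expected counts.
#'
#' After fitting, states are relabeled if needed so that state 1 (enriched)
#' has the larger replicate-averaged slope: enriched probes show a steeper
#' IP-versus-Input relationship.
#'
#' @param data a [probe_dataset].
#' @param spatial logical; model spatial dependence between adjacent probes
#'   (hidden Markov chain) or not (independence mixture).
#' @param init an [hmm_model] of starting values; default [pca_init()] of
#'   `data`. For the mixture the initial mixing proportion is `init$eta[2]`.
#' @param alpha default classification level stored in the fit: a probe is
#'   declared enriched when its enriched posterior probability exceeds
#'   `1 - alpha` (see [classify_probes]).
#' @param tol EM convergence tolerance: relative change in log-likelihood.
#' @param max_iter maximum number of EM iterations.
#' @param verbose print the log-likelihood at each iteration.
#'
#' @return An object of class `hmmchip` with components `model` (the fitted
#'   [hmm_model]; for the mixture, `model$A` has both rows equal to
#'   `(1 - pi, pi)` and `pi` is stored separately), `posterior` (per-probe
#'   enriched posterior probability), `loglik_trajectory` (one value per EM
#'   iteration plus the final log-likelihood; non-decreasing), `converged`,
#'   `n_iter`, `alpha`, `data` and `call`. Methods: `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `residuals`, `fitted`, `plot`, `simulate`.
#'
#' @examples
#' sim <- simulate_probes(scenario_config(1, n_probes = 2000, seed = 7))
#' fit <- hmmchip(sim$data)
#' fit
#' head(predict(fit))
#' @seealso [pca_init()], [classify_probes()], [simulate_probes()],
#'   [benchmark_scenario()]
#' @export
hmmchip <- function(data, spatial = TRUE, init = NULL, alpha = 0.01,
                    tol = 1e-6, max_iter = 500L, verbose = FALSE) {
  stopifnot(inherits(data, "probe_dataset"))
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (is.null(init)) init <- pca_init(data)
  stopifnot(inherits(init, "hmm_model"))
  if (ncol(init$emissions$slopes) != data$n_replicates)
    stop("init has the wrong number of replicates")
  cl <- match.call()

  blocks <- chromosome_blocks(data)
  params <- init$emissions
  A <- init$A
  eta <- init$eta
  pi1 <- init$eta[2L]

  trajectory <- numeric(0)
  converged <- FALSE
  iter <- 0L
  boundary <- FALSE
  repeat {
    logB <- emission_loglik(data, params)
    if (spatial) {
      es <- e_step(logB, blocks, A, eta)
    } else {
      es <- mixture_e_step(logB, pi1)
    }
    trajectory <- c(trajectory, es$loglik)
    if (verbose)
      message(sprintf("iteration %d: log-likelihood %.6f", iter, es$loglik))
    n <- length(trajectory)
    if (n > 1L &&
        abs(trajectory[n] - trajectory[n - 1L]) <=
          tol * abs(trajectory[n - 1L])) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L

    # M-step
    params <- m_step_emissions(data, es$posterior)
    if (spatial) {
      A <- es$xi_sum / rowSums(es$xi_sum)
      eta <- colMeans(es$firsts)
      eta <- eta / sum(eta)
    } else {
      pi1 <- mean(es$posterior[, 2L])
      if (pi1 < 1e-6) { pi1 <- 1e-6; boundary <- TRUE }
      if (pi1 > 1 - 1e-6) { pi1 <- 1 - 1e-6; boundary <- TRUE }
      eta <- c(1 - pi1, pi1)
      A <- rbind(eta, eta, deparse.level = 0)
    }
  }
  posterior2 <- es$posterior

  # label identification: enriched state has the larger mean slope
  if (mean(params$slopes[2L, ]) < mean(params$slopes[1L, ])) {
    params$intercepts <- params$intercepts[2:1, , drop = FALSE]
    params$slopes <- params$slopes[2:1, , drop = FALSE]
    A <- A[2:1, 2:1]
    eta <- rev(eta)
    pi1 <- 1 - pi1
    posterior2 <- posterior2[, 2:1, drop = FALSE]
  }
  if (boundary) converged <- FALSE

  out <- list(
    call = cl, spatial = spatial,
    model = hmm_model(eta = eta, A = A, emissions = params),
    pi = if (spatial) NULL else pi1,
    posterior = posterior2[, 2L],
    loglik_trajectory = trajectory,
    converged = converged, n_iter = iter,
    alpha = alpha, data = data
  )
  class(out) <- "hmmchip"
  out
}

# posterior-weighted M-step for the regression-Gaussian emissions:
# per state/replicate weighted least squares, variance pooled over both
# states per replicate (shared-variance parameterization)
m_step_emissions <- function(data, post, sigma2_floor = 1e-8) {
  R <- data$n_replicates
  Tn <- nrow(post)
  wsum <- colSums(post)
  if (any(wsum < 1e-8))
    stop(component_collapse_error(wsum))
  a <- b <- matrix(NA_real_, 2L, R)
  sigma2 <- numeric(R)
  for (r in seq_len(R)) {
    x <- data$x[, r]; y <- data$y[, r]
    rss <- 0
    for (z in 1:2) {
      w <- post[, z]
      sw <- wsum[z]
      xbar <- sum(w * x) / sw
      ybar <- sum(w * y) / sw
      sxx <- sum(w * (x - xbar)^2)
      if (sxx < 1e-12)
        stop("degenerate weighted regression: no log-Input spread in state ",
             z - 1L, ", replicate ", r)
      b[z, r] <- sum(w * (x - xbar) * (y - ybar)) / sxx
      a[z, r] <- ybar - b[z, r] * xbar
      rss <- rss + sum(w * (y - a[z, r] - b[z, r] * x)^2)
    }
    sigma2[r] <- rss / Tn
    if (sigma2[r] < sigma2_floor) {
      warning("variance estimate floored at ", sigma2_floor,
              " in replicate ", r)
      sigma2[r] <- sigma2_floor
    }
  }
  emission_params(a, b, sigma2)
}

component_collapse_error <- function(wsum) {
  structure(
    class = c("hmmchip_component_collapse", "error", "condition"),
    list(message = sprintf(
      paste0("component collapse: total posterior weight of a state ",
             "underflowed (weights %.3g, %.3g)"), wsum[1], wsum[2]),
      call = sys.call(-1))
  )
}

# E-step of the independence mixture: posteriors proportional to
# prior x emission density, computed via log-sum-exp
mixture_e_step <- function(logB, pi1) {
  lp <- cbind(logB[, 1L] + log1p(-pi1), logB[, 2L] + log(pi1))
  m <- pmax(lp[, 1L], lp[, 2L])
  e <- exp(lp - m)
  tot <- e[, 1L] + e[, 2L]
  post <- e / tot
  list(posterior = post, loglik = sum(log(tot) + m),
       xi_sum = NULL, firsts = NULL)
}
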