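#' Forward-backward recursion for a two-state chain
#'
#' Computes, for one ordered observation sequence, the per-position posterior
#' state probabilities, the summed pairwise transition expectations
#' (sum over t of xi_t) and the log-likelihood of the sequence, using a
#' scaled recursion that is stable for sequences of millions of probes.
#'
#' @param loglik_matrix numeric `T x 2` matrix of emission log-densities
#'   (e.g. from [emission_loglik]).
#' @param A 2 x 2 row-stochastic transition matrix.
#' @param eta length-2 initial state distribution.
#' @return A list with `posterior` (`T x 2`, rows sum to 1), `xi_sum`
#'   (2 x 2 matrix of summed pairwise expectations) and `loglik`.
#' @export
forward_backward <- function(loglik_matrix, A, eta) {
  loglik_matrix <- as.matrix(loglik_matrix)
  if (ncol(loglik_matrix) != 2L || nrow(loglik_matrix) < 1L)
    stop("loglik_matrix must be a T x 2 matrix with T >= 1")
  if (any(!is.finite(loglik_matrix)))
    stop("emission log-densities must be finite")
  check_stochastic(as.matrix(A), as.numeric(eta))
  .fb_scaled(loglik_matrix, as.matrix(A), as.numeric(eta))
}

# E-step over all chromosomes of a dataset: per-chromosome forward-backward
# with statistics pooled. Returns concatenated posteriors (dataset order),
# pooled xi_sum, total loglik, and the matrix of first-probe posteriors
# (one row per chromosome) used to re-estimate eta.
e_step <- function(logB, blocks, A, eta) {
  post <- matrix(NA_real_, nrow(logB), 2L)
  xi_sum <- matrix(0, 2L, 2L)
  loglik <- 0
  firsts <- matrix(NA_real_, length(blocks), 2L)
  for (i in seq_along(blocks)) {
    idx <- blocks[[i]]
    fb <- .fb_scaled(logB[idx, , drop = FALSE], A, eta)
    post[idx, ] <- fb$posterior
    xi_sum <- xi_sum + fb$xi_sum
    loglik <- loglik + fb$loglik
    firsts[i, ] <- fb$posterior[1L, ]
  }
  list(posterior = post, xi_sum = xi_sum, loglik = loglik, firsts = firsts)
}
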