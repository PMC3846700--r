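#' Regression-Gaussian emission parameters
#'
#' Emission distributions of the two hidden states. Given state z, the log-IP
#' intensity of probe t in replicate r is Gaussian with mean
#' `a[z, r] + b[z, r] * x[t, r]` and variance `sigma2[r]`; replicates are
#' conditionally independent, so the joint emission density is the product
#' over replicates. The variance is per replicate and shared by both states.
#'
#' @param intercepts 2 x R numeric matrix `a` (rows: state 0 = non-enriched,
#'   state 1 = enriched).
#' @param slopes 2 x R numeric matrix `b`.
#' @param sigma2 numeric vector of R positive variances.
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(intercepts, slopes, sigma2) {
  intercepts <- rbind(intercepts)[, , drop = FALSE]
  slopes <- rbind(slopes)[, , drop = FALSE]
  sigma2 <- as.numeric(sigma2)
  if (!identical(dim(intercepts), dim(slopes)) || nrow(intercepts) != 2L)
    stop("intercepts and slopes must be 2 x R matrices")
  if (length(sigma2) != ncol(slopes))
    stop("sigma2 must have one entry per replicate")
  if (any(!is.finite(c(intercepts, slopes, sigma2))) || any(sigma2 <= 0))
    stop("emission parameters must be finite with sigma2 > 0")
  structure(list(intercepts = intercepts, slopes = slopes, sigma2 = sigma2),
            class = "emission_params")
}

#' Emission log-density matrix
#'
#' Evaluates, for every probe and both states, the log of the product-Gaussian
#' emission density of the observed log-IP signals given the log-Input
#' signals.
#'
#' @param data a [probe_dataset].
#' @param params an [emission_params] whose replicate dimension matches
#'   `data`.
#' @return A numeric `T x 2` matrix of log-densities (columns: state 0,
#'   state 1).
#' @export
emission_loglik <- function(data, params) {
  stopifnot(inherits(data, "probe_dataset"), inherits(params, "emission_params"))
  R <- data$n_replicates
  if (ncol(params$slopes) != R)
    stop("replicate dimension of params does not match the dataset")
  sd_r <- sqrt(params$sigma2)
  out <- matrix(0, nrow(data$x), 2L)
  for (z in 1:2) {
    for (r in seq_len(R)) {
      mu <- params$intercepts[z, r] + params$slopes[z, r] * data$x[, r]
      out[, z] <- out[, z] + dnorm(data$y[, r], mu, sd_r[r], log = TRUE)
    }
  }
  out
}

#' Emission log-density of a single probe
#'
#' Convenience scalar form of [emission_loglik] for one probe record.
#'
#' @param x,y numeric vectors of the probe's log-Input and log-IP intensities,
#'   one entry per replicate.
#' @param state 0 (non-enriched) or 1 (enriched).
#' @param params an [emission_params].
#' @return The log emission density (a scalar).
#' @examples
#' p <- emission_params(rbind(0, 0), rbind(1, 1.5), 1)
#' emission_logdensity(0, 0, state = 0, p)  # log(1/sqrt(2*pi))
#' @export
emission_logdensity <- function(x, y, state, params) {
  stopifnot(inherits(params, "emission_params"))
  if (!state %in% c(0, 1)) stop("state must be 0 or 1")
  R <- ncol(params$slopes)
  if (length(x) != R || length(y) != R)
    stop("x and y must have one entry per replicate of params")
  z <- state + 1L
  mu <- params$intercepts[z, ] + params$slopes[z, ] * x
  sum(dnorm(y, mu, sqrt(params$sigma2), log = TRUE))
}

#' Two-state hidden Markov model specification
#'
#' Bundles the initial state distribution, the 2 x 2 transition matrix and the
#' regression-Gaussian emission parameters.
#'
#' @param eta length-2 initial state distribution (non-enriched, enriched).
#' @param A 2 x 2 row-stochastic transition matrix.
#' @param emissions an [emission_params].
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(eta, A, emissions) {
  eta <- as.numeric(eta)
  A <- as.matrix(A)
  check_stochastic(A, eta)
  stopifnot(inherits(emissions, "emission_params"))
  structure(list(eta = eta, A = A, emissions = emissions), class = "hmm_model")
}

check_stochastic <- function(A, eta) {
  if (!identical(dim(A), c(2L, 2L)) || any(!is.finite(A)) ||
      any(A < 0) || any(A > 1) || any(abs(rowSums(A) - 1) > 1e-8))
    stop("A must be a 2 x 2 row-stochastic matrix")
  if (length(eta) != 2L || any(!is.finite(eta)) || any(eta < 0) ||
      abs(sum(eta) - 1) > 1e-8)
    stop("eta must be a length-2 probability distribution")
  invisible(TRUE)
}
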