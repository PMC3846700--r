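#' Principal-component starting values for EM
#'
#' Derives initial regression lines from the first principal axis of each
#' replicate's (log-Input, log-IP) point cloud: the base slope is the ratio of
#' the leading eigenvector's IP-loading to its Input-loading and the base
#' intercept passes the line through the centroid. The two states start from
#' the base line with the slope perturbed symmetrically (divided and
#' multiplied by `slope_split_factor`) so that EM can pull the populations
#' apart; replicate variances start at the residual variance about the base
#' line. All transition entries and both initial-state probabilities are set
#' to 0.5, reflecting the absence of prior biological information.
#'
#' @param data a [probe_dataset] with at least 3 probes.
#' @param slope_split_factor multiplicative perturbation (> 1) separating the
#'   two initial state slopes; default 1.1.
#' @return An [hmm_model] usable as `init` for [hmmchip()].
#' @examples
#' sim <- simulate_probes(scenario_config(1, n_probes = 500, seed = 1))
#' pca_init(sim$data)
#' @export
pca_init <- function(data, slope_split_factor = 1.1) {
  stopifnot(inherits(data, "probe_dataset"))
  if (nrow(data$x) < 3L) stop("PCA initialization needs at least 3 probes")
  if (!is.numeric(slope_split_factor) || slope_split_factor <= 1)
    stop("slope_split_factor must be > 1")
  R <- data$n_replicates
  a0 <- b0 <- numeric(R)
  s2 <- numeric(R)
  for (r in seq_len(R)) {
    x <- data$x[, r]; y <- data$y[, r]
    if (var(x) < 1e-12)
      stop("degenerate point cloud: log-Input values are constant in replicate ", r)
    # first principal axis of the centered (not standardized) cloud
    S <- cov(cbind(x, y))
    v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    if (abs(v[1L]) < 1e-12)
      stop("first principal axis is vertical in replicate ", r,
           ": slope undefined")
    b0[r] <- v[2L] / v[1L]
    a0[r] <- mean(y) - b0[r] * mean(x)
    s2[r] <- mean((y - a0[r] - b0[r] * x)^2)
    if (s2[r] < 1e-8) s2[r] <- 1e-8
  }
  em <- emission_params(
    intercepts = rbind(a0, a0, deparse.level = 0),
    slopes = rbind(b0 / slope_split_factor, b0 * slope_split_factor,
                   deparse.level = 0),
    sigma2 = s2
  )
  hmm_model(eta = c(0.5, 0.5), A = matrix(0.5, 2, 2), emissions = em)
}
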