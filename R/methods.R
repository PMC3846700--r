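#' @export
print.hmmchip <- function(x, ...) {
  cat(if (x$spatial) "Two-state regression HMM fit (spatial dependence)\n"
      else "Two-component regression mixture fit (spatial independence)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  R <- x$data$n_replicates
  cat(sprintf("%d probes, %d replicate(s); EM %s in %d iteration(s), log-likelihood %.3f\n",
              nrow(x$data$probes), R,
              if (x$converged) "converged" else "did NOT converge",
              x$n_iter, logLik(x)))
  em <- x$model$emissions
  for (r in seq_len(R))
    cat(sprintf(
      "  replicate %d: non-enriched y = %.3f + %.3f x, enriched y = %.3f + %.3f x, sigma2 = %.3f\n",
      r, em$intercepts[1, r], em$slopes[1, r],
      em$intercepts[2, r], em$slopes[2, r], em$sigma2[r]))
  if (x$spatial) {
    cat("Transition matrix (rows: from non-enriched, enriched):\n")
    print(round(x$model$A, 4))
  } else {
    cat(sprintf("Mixing proportion of enriched probes: pi = %.4f\n", x$pi))
  }
  n_enr <- sum(x$posterior > 1 - x$alpha)
  cat(sprintf("%d probe(s) enriched at alpha = %g (posterior > %g)\n",
              n_enr, x$alpha, 1 - x$alpha))
  invisible(x)
}

#' @export
summary.hmmchip <- function(object, alpha = object$alpha, ...) {
  status <- classify_probes(object$posterior, alpha)
  out <- list(
    fit = object, alpha = alpha,
    n_enriched = sum(status == "enriched"),
    n_probes = length(status),
    posterior_quartiles = stats::quantile(object$posterior,
                                          c(0, .25, .5, .75, 1)),
    loglik = logLik(object)
  )
  class(out) <- "summary.hmmchip"
  out
}

#' @export
print.summary.hmmchip <- function(x, ...) {
  print(x$fit)
  cat("\nEnriched posterior probability quartiles:\n")
  print(signif(x$posterior_quartiles, 4))
  cat(sprintf("Enriched calls at alpha = %g: %d / %d (%.2f%%)\n",
              x$alpha, x$n_enriched, x$n_probes,
              100 * x$n_enriched / x$n_probes))
  invisible(x)
}

#' @export
coef.hmmchip <- function(object, ...) {
  em <- object$model$emissions
  R <- ncol(em$slopes)
  out <- list(intercepts = em$intercepts, slopes = em$slopes,
              sigma2 = em$sigma2)
  dimnames(out$intercepts) <- dimnames(out$slopes) <-
    list(c("non-enriched", "enriched"), paste0("rep", seq_len(R)))
  names(out$sigma2) <- paste0("rep", seq_len(R))
  if (object$spatial) {
    out$A <- object$model$A
    dimnames(out$A) <- list(c("non-enriched", "enriched"),
                            c("non-enriched", "enriched"))
    out$eta <- object$model$eta
  } else {
    out$pi <- object$pi
  }
  out
}

#' @export
logLik.hmmchip <- function(object, ...) {
  ll <- object$loglik_trajectory[length(object$loglik_trajectory)]
  R <- object$data$n_replicates
  # 2 states x R x (a, b) + R variances + chain (2 free transitions + eta) or pi
  df <- 5L * R + if (object$spatial) 3L else 1L
  structure(ll, df = df, nobs = nrow(object$data$probes), class = "logLik")
}

#' Posterior probabilities and statuses of probes
#'
#' Returns, for the training probes or for new probes evaluated at the
#' fitted parameters, the enriched posterior probability and the
#' enriched/non-enriched status at level `alpha`.
#'
#' @param object a fitted [hmmchip] model.
#' @param newdata optionally, a [probe_dataset] with the same number of
#'   replicates; posteriors are computed by a fresh E-step at the fitted
#'   parameters (no re-estimation).
#' @param alpha classification level; defaults to the level stored in the
#'   fit.
#' @param ... unused.
#' @return A data frame with columns `probe_id`, `chromosome`, `position`,
#'   `posterior_enriched` and `status`.
#' @export
predict.hmmchip <- function(object, newdata = NULL, alpha = object$alpha,
                            ...) {
  if (is.null(newdata)) {
    probes <- object$data$probes
    post <- object$posterior
  } else {
    stopifnot(inherits(newdata, "probe_dataset"))
    logB <- emission_loglik(newdata, object$model$emissions)
    if (object$spatial) {
      es <- e_step(logB, chromosome_blocks(newdata), object$model$A,
                   object$model$eta)
    } else {
      es <- mixture_e_step(logB, object$pi)
    }
    probes <- newdata$probes
    post <- es$posterior[, 2L]
  }
  data.frame(probes, posterior_enriched = post,
             status = classify_probes(post, alpha),
             stringsAsFactors = FALSE)
}

#' @export
fitted.hmmchip <- function(object, ...) {
  em <- object$model$emissions
  p1 <- object$posterior
  R <- object$data$n_replicates
  out <- matrix(NA_real_, nrow(object$data$x), R)
  for (r in seq_len(R)) {
    mu0 <- em$intercepts[1, r] + em$slopes[1, r] * object$data$x[, r]
    mu1 <- em$intercepts[2, r] + em$slopes[2, r] * object$data$x[, r]
    out[, r] <- (1 - p1) * mu0 + p1 * mu1
  }
  colnames(out) <- paste0("rep", seq_len(R))
  out
}

#' @export
residuals.hmmchip <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Diagnostic plots for a fitted probe-enrichment model
#'
#' `which = "fit"` draws, per replicate, the (log-Input, log-IP) cloud
#' colored by status at the stored `alpha` with both state regression
#' lines; `which = "loglik"` draws the EM log-likelihood trajectory.
#'
#' @param x a fitted [hmmchip] model.
#' @param which `"fit"` or `"loglik"`.
#' @param max_points maximum number of probes drawn per replicate (random
#'   thinning keeps plots responsive on large arrays).
#' @param ... passed to [graphics::plot].
#' @export
plot.hmmchip <- function(x, which = c("fit", "loglik"), max_points = 5000L,
                         ...) {
  which <- match.arg(which)
  if (which == "loglik") {
    plot(seq_along(x$loglik_trajectory), x$loglik_trajectory, type = "b",
         xlab = "EM iteration", ylab = "log-likelihood", ...)
    return(invisible(x))
  }
  em <- x$model$emissions
  R <- x$data$n_replicates
  status <- classify_probes(x$posterior, x$alpha)
  old <- par(mfrow = c(1, R)); on.exit(par(old))
  idx <- seq_len(nrow(x$data$x))
  if (length(idx) > max_points) idx <- sort(sample(idx, max_points))
  for (r in seq_len(R)) {
    plot(x$data$x[idx, r], x$data$y[idx, r],
         col = ifelse(status[idx] == "enriched", "red", "grey30"),
         pch = 20, cex = 0.4, xlab = "log-Input", ylab = "log-IP",
         main = paste("replicate", r), ...)
    abline(em$intercepts[1, r], em$slopes[1, r], col = "grey30", lwd = 2)
    abline(em$intercepts[2, r], em$slopes[2, r], col = "red", lwd = 2)
    legend("topleft", c("non-enriched", "enriched"),
           col = c("grey30", "red"), lty = 1, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Simulate new datasets from a fitted model
#'
#' Draws datasets from the fitted generative model: the hidden chain from
#' the fitted transition matrix (or i.i.d. states from `pi` for the
#' mixture), log-Input values resampled from the training data, and log-IP
#' values from the fitted state regressions plus Gaussian noise.
#'
#' @param object a fitted [hmmchip] model.
#' @param nsim number of datasets.
#' @param seed integer seed (required, for reproducibility).
#' @param n_probes probes per simulated dataset; defaults to the training
#'   size.
#' @param ... unused.
#' @return A list of `nsim` objects as returned by [simulate_probes()].
#' @export
simulate.hmmchip <- function(object, nsim = 1, seed = NULL,
                             n_probes = nrow(object$data$probes), ...) {
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  em <- object$model$emissions
  cfg <- sim_config(
    n_probes = n_probes, n_replicates = object$data$n_replicates,
    A = object$model$A, intercepts = em$intercepts, slopes = em$slopes,
    sigma2 = em$sigma2,
    x_dist = list(family = "empirical", values = object$data$x),
    initial_state_rule = "stationary", seed = seed
  )
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg$seed <- seed + i - 1L
    out[[i]] <- simulate_probes(cfg)
  }
  if (nsim == 1L) out[[1L]] else out
}
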