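#' Classify probes from enriched posterior probabilities
#'
#' A probe is declared enriched when its posterior probability of the
#' enriched state is strictly greater than `1 - alpha`, where `alpha` is
#' chosen by the user; this thresholding rule controls the proportion of
#' misclassified probes at level `alpha`.
#'
#' @param posterior numeric vector of enriched posterior probabilities in
#'   \[0, 1\].
#' @param alpha classification level in (0, 1); e.g. `alpha = 0.01` calls a
#'   probe enriched only when its posterior exceeds 0.99.
#' @return A character vector of statuses, `"enriched"` or `"non-enriched"`.
#' @examples
#' classify_probes(c(0.995, 0.99, 0.2), alpha = 0.01)
#' @export
classify_probes <- function(posterior, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  posterior <- as.numeric(posterior)
  if (any(!is.finite(posterior)) || any(posterior < 0) || any(posterior > 1))
    stop("posterior probabilities must lie in [0, 1]")
  ifelse(posterior > 1 - alpha, "enriched", "non-enriched")
}

#' Combine per-replicate posterior probabilities
#'
#' When the single-replicate mixture model is fitted to each biological
#' replicate separately, the per-probe posteriors can be summarized across
#' replicates by their minimum or maximum. Thresholding the minimum calls a
#' probe enriched only if every replicate supports it stringently
#' (historically labeled the "union" summary), thresholding the maximum
#' lets any single replicate drive the call (the "intersection" summary).
#'
#' @param posteriors a list of numeric posterior vectors, one per replicate,
#'   all of the same length.
#' @param rule `"min"` or `"max"` (aliases `"union"` = min,
#'   `"intersection"` = max).
#' @return A numeric vector of combined posteriors.
#' @examples
#' combine_posteriors(list(c(0.3, 0.9), c(0.8, 0.5)), "min")
#' @export
combine_posteriors <- function(posteriors, rule = c("min", "max", "union",
                                                    "intersection")) {
  rule <- match.arg(rule)
  rule <- switch(rule, union = "min", intersection = "max", rule)
  if (!is.list(posteriors) || length(posteriors) == 0L)
    stop("posteriors must be a non-empty list of numeric vectors")
  n <- unique(vapply(posteriors, length, integer(1)))
  if (length(n) != 1L)
    stop("all posterior vectors must have the same length")
  m <- do.call(cbind, posteriors)
  if (rule == "min") apply(m, 1L, min) else apply(m, 1L, max)
}
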