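#' ROC curve of an enrichment caller against simulation truth
#'
#' Sweeps every distinct posterior value as a classification threshold
#' (probe called enriched when its posterior is >= the threshold) and
#' reports the false/true positive rates along the curve and the area under
#' it by the trapezoidal rule.
#'
#' @param posterior numeric vector of enriched posterior probabilities (any
#'   monotone score works; the ROC is invariant to monotone transforms).
#' @param truth 0/1 vector (or logical) of true states, same length; both
#'   classes must be present.
#' @return A list of class `roc_result` with `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr` (non-decreasing, from 0 to 1) and
#'   `auc`.
#' @examples
#' roc_curve(c(.9, .8, .3, .1), c(1, 1, 0, 0))$auc  # 1: perfect separation
#' @export
roc_curve <- function(posterior, truth) {
  truth <- as.integer(truth)
  if (length(posterior) != length(truth))
    stop("posterior and truth must have the same length")
  if (!all(truth %in% c(0L, 1L))) stop("truth must be 0/1")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain both classes")
  ord <- order(posterior, decreasing = TRUE)
  s <- posterior[ord]; t <- truth[ord]
  # cumulative counts at each distinct score (ties grouped)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(t)[last_of_tie]
  fp <- cumsum(1L - t)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last_of_tie]),
                 fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold(s), AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Post-classification error rates against simulation truth
#'
#' Counts the confusion table of enriched/non-enriched calls versus true
#' states and reports the false positive rate `FP / (FP + TN)` and true
#' positive rate `TP / (TP + FN)`.
#'
#' @param status character vector of `"enriched"`/`"non-enriched"` calls
#'   (or a logical/0-1 vector, `TRUE`/1 = enriched).
#' @param truth 0/1 vector of true states, same length.
#' @return A list of class `classification_rates`: `false_positive_rate`,
#'   `true_positive_rate`, and counts `n_tp`, `n_fp`, `n_fn`, `n_tn`.
#' @export
classification_rates <- function(status, truth) {
  truth <- as.integer(truth)
  if (is.character(status)) {
    called <- status == "enriched"
  } else {
    called <- as.logical(status)
  }
  if (length(called) != length(truth))
    stop("status and truth must have the same length")
  if (!all(truth %in% c(0L, 1L))) stop("truth must be 0/1")
  n_tp <- sum(called & truth == 1L)
  n_fp <- sum(called & truth == 0L)
  n_fn <- sum(!called & truth == 1L)
  n_tn <- sum(!called & truth == 0L)
  structure(list(
    false_positive_rate = if (n_fp + n_tn > 0) n_fp / (n_fp + n_tn) else 0,
    true_positive_rate = if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else 0,
    n_tp = n_tp, n_fp = n_fp, n_fn = n_fn, n_tn = n_tn
  ), class = "classification_rates")
}

#' @export
print.classification_rates <- function(x, ...) {
  cat(sprintf("FPR = %.4g (FP %d / N %d), TPR = %.4g (TP %d / P %d)\n",
              x$false_positive_rate, x$n_fp, x$n_fp + x$n_tn,
              x$true_positive_rate, x$n_tp, x$n_tp + x$n_fn))
  invisible(x)
}

#' Benchmark the spatial HMM against the mixture callers on simulations
#'
#' For each seed: simulates the chosen scenario, fits (i) the spatial HMM
#' jointly on both replicates, (ii) the joint multi-replicate independence
#' mixture, and (iii) the single-replicate mixture per replicate with
#' posteriors combined by the min rule ("union" summary) and by the max
#' rule ("intersection" summary); classifies probes at level `alpha`; and
#' computes false/true positive rates and ROC AUC against the simulation
#' truth. Rates are averaged over seeds.
#'
#' @param which scenario, 1 or 2 (see [scenario_config()]).
#' @param n_probes probes per simulated dataset.
#' @param alpha classification level (probe enriched when its posterior
#'   exceeds 1 - alpha).
#' @param seeds integer vector of simulation seeds (one dataset per seed).
#' @param tol,max_iter EM control passed to [hmmchip()].
#' @return A data frame of class `hmmchip_benchmark` with one row per
#'   method (`hmm`, `mix_joint`, `mix_union`, `mix_inter`) and columns
#'   `fpr`, `tpr`, `auc` (means over seeds) plus `fpr_se`, `tpr_se`,
#'   `auc_se` (standard errors). The per-seed results are kept in
#'   `attr(, "per_seed")`.
#' @examples
#' \donttest{
#' benchmark_scenario(1, n_probes = 2000, alpha = 0.01, seeds = 1:3)
#' }
#' @export
benchmark_scenario <- function(which, n_probes = 10000L, alpha = 0.01,
                               seeds = 1:10, tol = 1e-6, max_iter = 500L) {
  if (length(seeds) < 1L) stop("at least one seed is required")
  methods <- c("hmm", "mix_joint", "mix_union", "mix_inter")
  per_seed <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_probes(scenario_config(which, n_probes = n_probes,
                                           seed = seeds[i]))
    truth <- sim$true_states
    post <- list()
    fit_h <- hmmchip(sim$data, spatial = TRUE, tol = tol,
                     max_iter = max_iter)
    post$hmm <- fit_h$posterior
    fit_m <- hmmchip(sim$data, spatial = FALSE, tol = tol,
                     max_iter = max_iter)
    post$mix_joint <- fit_m$posterior
    reps <- lapply(seq_len(sim$data$n_replicates), function(r)
      hmmchip(replicate_view(sim$data, r), spatial = FALSE, tol = tol,
              max_iter = max_iter)$posterior)
    post$mix_union <- combine_posteriors(reps, "min")
    post$mix_inter <- combine_posteriors(reps, "max")

    per_seed[[i]] <- do.call(rbind, lapply(methods, function(m) {
      rates <- classification_rates(classify_probes(post[[m]], alpha), truth)
      data.frame(seed = seeds[i], method = m,
                 fpr = rates$false_positive_rate,
                 tpr = rates$true_positive_rate,
                 auc = roc_curve(post[[m]], truth)$auc,
                 stringsAsFactors = FALSE)
    }))
  }
  per_seed <- do.call(rbind, per_seed)
  agg <- function(v) tapply(per_seed[[v]], per_seed$method, mean)[methods]
  se <- function(v) tapply(per_seed[[v]], per_seed$method,
                           function(z) stats::sd(z) / sqrt(length(z)))[methods]
  out <- data.frame(method = methods, fpr = agg("fpr"), tpr = agg("tpr"),
                    auc = agg("auc"), fpr_se = se("fpr"), tpr_se = se("tpr"),
                    auc_se = se("auc"), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "per_seed") <- per_seed
  attr(out, "alpha") <- alpha
  attr(out, "scenario") <- which
  class(out) <- c("hmmchip_benchmark", "data.frame")
  out
}

#' Write a benchmark table to a delimited file
#'
#' @param bench a benchmark table from [benchmark_scenario()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(bench, path) {
  write.table(as.data.frame(bench), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
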