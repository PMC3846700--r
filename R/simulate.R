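#' Specify a generative model for synthetic ChIP-chip data
#'
#' Builds the full configuration of the simulator: a hidden two-state
#' first-order Markov chain along the probes and, given the states,
#' per-replicate log-IP intensities drawn as a state-specific linear
#' regression of the log-Input intensity plus Gaussian noise.
#'
#' @param n_probes total number of probes T (>= 2).
#' @param n_replicates number of biological replicates R (>= 1).
#' @param A 2 x 2 row-stochastic transition matrix of the hidden chain.
#' @param intercepts,slopes 2 x R matrices (rows: non-enriched, enriched); a
#'   length-2 vector is recycled across replicates.
#' @param sigma2 length-R vector of positive noise variances.
#' @param x_dist distribution of the log-Input values: a list with `family`
#'   `"uniform"` (`min`, `max`), `"normal"` (`mean`, `sd`) or `"empirical"`
#'   (`values`, a numeric pool resampled with replacement). Default: uniform
#'   on \[8, 14\], a plausible log2-intensity range for tiling arrays.
#' @param initial_state_rule `"stationary"` (stationary distribution of `A`;
#'   default), `"uniform"`, or `"fixed"` (start in the non-enriched state).
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @param n_chromosomes number of synthetic chromosomes the probes are split
#'   across (near-equal blocks, 35-bp probe spacing).
#' @return An object of class `sim_config`.
#' @seealso [scenario_config()] for the two benchmark scenarios.
#' @export
sim_config <- function(n_probes, n_replicates, A, intercepts, slopes, sigma2,
                       x_dist = list(family = "uniform", min = 8, max = 14),
                       initial_state_rule = c("stationary", "uniform",
                                              "fixed"),
                       seed = 1L, n_chromosomes = 1L) {
  n_probes <- as.integer(n_probes)
  n_replicates <- as.integer(n_replicates)
  if (n_probes < 2L) stop("n_probes must be >= 2")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  expand <- function(m) {
    m <- rbind(m)
    if (ncol(m) == 1L) m <- m[, rep(1L, n_replicates), drop = FALSE]
    if (nrow(m) != 2L || ncol(m) != n_replicates)
      stop("intercepts and slopes must be 2 x n_replicates")
    m
  }
  if (length(intercepts) == 2L) intercepts <- cbind(as.numeric(intercepts))
  if (length(slopes) == 2L) slopes <- cbind(as.numeric(slopes))
  intercepts <- expand(intercepts)
  slopes <- expand(slopes)
  sigma2 <- as.numeric(sigma2)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, n_replicates)
  if (length(sigma2) != n_replicates || any(sigma2 <= 0))
    stop("sigma2 must be n_replicates positive variances")
  check_stochastic(as.matrix(A), c(0.5, 0.5))
  validate_x_dist(x_dist)
  structure(list(
    n_probes = n_probes, n_replicates = n_replicates, A = as.matrix(A),
    intercepts = intercepts, slopes = slopes, sigma2 = sigma2,
    x_dist = x_dist, initial_state_rule = match.arg(initial_state_rule),
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes)
  ), class = "sim_config")
}

validate_x_dist <- function(x_dist) {
  if (!is.list(x_dist) || is.null(x_dist$family))
    stop("x_dist must be a list with a 'family' element")
  switch(x_dist$family,
    uniform = {
      if (!is.numeric(x_dist$min) || !is.numeric(x_dist$max) ||
          x_dist$min >= x_dist$max)
        stop("uniform x_dist needs min < max")
    },
    normal = {
      if (!is.numeric(x_dist$mean) || !is.numeric(x_dist$sd) ||
          x_dist$sd <= 0)
        stop("normal x_dist needs a positive sd")
    },
    empirical = {
      if (!is.numeric(x_dist$values) || length(x_dist$values) == 0L)
        stop("empirical x_dist needs a non-empty numeric pool")
    },
    stop("unknown x_dist family: ", x_dist$family)
  )
  invisible(TRUE)
}

#' Benchmark scenario configurations
#'
#' The two standard simulation scenarios for comparing enrichment callers:
#' scenario 1 has well-separated non-enriched and enriched populations
#' (slopes 0.6 and 0.99, identical in both replicates) and scenario 2 has
#' overlapping populations (slopes 0.5 and 0.65). Both use two replicates
#' with noise variances 0.7 and 0.75, transition matrix rows (0.97, 0.03)
#' and (0.1, 0.9), zero intercepts, log-Input values uniform on \[8, 14\]
#' and the stationary initial-state distribution (enriched fraction
#' 3/13 at stationarity).
#'
#' @param which scenario number, 1 or 2.
#' @param n_probes number of probes; default 10000.
#' @param seed integer seed.
#' @return A [sim_config].
#' @examples
#' cfg <- scenario_config(1, n_probes = 1000, seed = 42)
#' sim <- simulate_probes(cfg)
#' mean(sim$true_states)  # about 3/13
#' @export
scenario_config <- function(which, n_probes = 10000L, seed = 1L) {
  if (length(which) != 1L || !which %in% c(1, 2))
    stop("which must be 1 or 2")
  slopes <- if (which == 1) c(0.6, 0.99) else c(0.5, 0.65)
  sim_config(
    n_probes = n_probes, n_replicates = 2L,
    A = matrix(c(0.97, 0.1, 0.03, 0.9), 2L, 2L),
    intercepts = c(0, 0), slopes = slopes, sigma2 = c(0.7, 0.75),
    seed = seed
  )
}

#' Simulate a synthetic ChIP-chip dataset
#'
#' Draws the hidden enrichment states from the configured Markov chain
#' (restarted independently on each synthetic chromosome), the log-Input
#' intensities from the configured distribution, and the log-IP intensities
#' from the state-specific regressions plus Gaussian noise.
#'
#' @param config a [sim_config].
#' @return A list of class `sim_dataset` with `data` (a [probe_dataset]),
#'   `true_states` (0/1 vector, in `data` order) and `config`.
#' @examples
#' sim <- simulate_probes(scenario_config(1, n_probes = 200, seed = 3))
#' table(sim$true_states)
#' @export
simulate_probes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Tn <- config$n_probes
  R <- config$n_replicates
  A <- config$A

  eta <- switch(config$initial_state_rule,
    stationary = stationary_distribution(A),
    uniform = c(0.5, 0.5),
    fixed = c(1, 0)
  )

  # chromosome blocks of near-equal size, chain restarted per chromosome
  n_chr <- max(1L, min(config$n_chromosomes, Tn %/% 2L))
  sizes <- diff(round(seq(0, Tn, length.out = n_chr + 1L)))
  z <- integer(0)
  for (s in sizes) {
    zc <- integer(s)
    zc[1L] <- sample.int(2L, 1L, prob = eta) - 1L
    if (s > 1L) {
      u <- runif(s - 1L)
      for (t in 2:s) zc[t] <- if (u[t - 1L] < A[zc[t - 1L] + 1L, 2L]) 1L else 0L
    }
    z <- c(z, zc)
  }

  x <- matrix(draw_x(config$x_dist, Tn * R), Tn, R)
  y <- matrix(NA_real_, Tn, R)
  for (r in seq_len(R)) {
    mu <- config$intercepts[z + 1L, r] + config$slopes[z + 1L, r] * x[, r]
    y[, r] <- mu + rnorm(Tn, 0, sqrt(config$sigma2[r]))
  }

  chrom <- rep(paste0("chr", seq_len(n_chr)), sizes)
  position <- unlist(lapply(sizes, function(s) 1L + 35L * (seq_len(s) - 1L)),
                     use.names = FALSE)
  data <- probe_dataset(
    probe_id = sprintf("probe_%06d", seq_len(Tn)),
    chromosome = chrom, position = position, input = x, ip = y
  )
  structure(list(data = data, true_states = z, config = config),
            class = "sim_dataset")
}

draw_x <- function(x_dist, n) {
  switch(x_dist$family,
    uniform = runif(n, x_dist$min, x_dist$max),
    normal = rnorm(n, x_dist$mean, x_dist$sd),
    empirical = sample(as.numeric(x_dist$values), n, replace = TRUE)
  )
}

#' Stationary distribution of a 2 x 2 transition matrix
#'
#' Solves pi A = pi for the two-state chain in closed form.
#'
#' @param A 2 x 2 row-stochastic matrix.
#' @return Length-2 stationary probabilities (non-enriched, enriched).
#' @export
stationary_distribution <- function(A) {
  check_stochastic(as.matrix(A), c(0.5, 0.5))
  p01 <- A[1L, 2L]; p10 <- A[2L, 1L]
  if (p01 + p10 == 0) return(c(0.5, 0.5))  # two absorbing states
  c(p10, p01) / (p01 + p10)
}

#' Write a simulated dataset to per-replicate probe files
#'
#' Writes one tab-delimited file per replicate in the layout
#' [read_replicates()] expects, plus a truth sidecar
#' (`<prefix>_truth.tsv`: probe_id, true_state).
#'
#' @param sim a `sim_dataset` from [simulate_probes()].
#' @param prefix output path prefix; files are named
#'   `<prefix>_rep<r>.tsv`.
#' @return Invisibly, the vector of replicate file paths.
#' @export
write_simulated <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_dataset"))
  paths <- character(sim$data$n_replicates)
  for (r in seq_len(sim$data$n_replicates)) {
    paths[r] <- paste0(prefix, "_rep", r, ".tsv")
    df <- data.frame(sim$data$probes,
                     input = sim$data$x[, r], ip = sim$data$y[, r])
    write.table(df, paths[r], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- data.frame(probe_id = sim$data$probes$probe_id,
                      true_state = sim$true_states)
  write.table(truth, paste0(prefix, "_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
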