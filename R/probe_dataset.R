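#' Assemble probes and replicate signals into a probe dataset
#'
#' A `probe_dataset` holds the probes of a tiling-array experiment, ordered by
#' genomic position within each chromosome, together with the paired
#' (log-Input, log-IP) intensities of every biological replicate. Chromosomes
#' are treated as separate observation sequences by the spatial model: the
#' Markov chain links directly adjacent probes of the same chromosome only,
#' while one parameter set is shared genome-wide.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chromosome character vector, same length as `probe_id`.
#' @param position integer vector of 1-based genomic positions (base pairs).
#' @param input numeric matrix (probes x replicates) of log-Input intensities;
#'   a plain vector is taken as a single replicate.
#' @param ip numeric matrix of log-IP intensities, same shape as `input`.
#'
#' @details Records are re-ordered by position within each chromosome
#'   (chromosome blocks keep their order of first appearance). Non-finite
#'   signal values are rejected — there is no imputation — and duplicated
#'   positions within a chromosome are an error because adjacency would be
#'   undefined.
#'
#' @return An object of class `probe_dataset`: a list with elements `probes`
#'   (data frame of probe_id, chromosome, position), `x` and `y` (numeric
#'   probes x replicates matrices of log-Input and log-IP intensities) and
#'   `n_replicates`.
#' @examples
#' d <- probe_dataset(paste0("p", 1:4), rep("chr1", 4), c(10, 40, 70, 100),
#'                    input = matrix(rnorm(8, 11), 4),
#'                    ip    = matrix(rnorm(8, 11), 4))
#' d
#' @export
probe_dataset <- function(probe_id, chromosome, position, input, ip) {
  input <- as.matrix(input)
  ip <- as.matrix(ip)
  storage.mode(input) <- "double"
  storage.mode(ip) <- "double"
  n <- length(probe_id)
  if (n == 0L) stop("probe dataset is empty")
  if (length(chromosome) != n || length(position) != n)
    stop("probe_id, chromosome and position must have the same length")
  if (nrow(input) != n || nrow(ip) != n)
    stop("signal matrices must have one row per probe")
  if (ncol(input) != ncol(ip))
    stop("input and ip must have the same number of replicate columns")
  if (ncol(input) < 1L) stop("at least one replicate is required")
  if (anyDuplicated(probe_id)) stop("duplicated probe_id values")
  if (!all(is.finite(input)) || !all(is.finite(ip)))
    stop("non-finite signal values are not allowed (no imputation is done)")
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("positions must be integers >= 1")

  chromosome <- as.character(chromosome)
  # stable ordering: chromosome blocks in order of first appearance,
  # positions strictly increasing within each block
  chr_levels <- unique(chromosome)
  ord <- order(match(chromosome, chr_levels), position)
  probe_id <- as.character(probe_id)[ord]
  chromosome <- chromosome[ord]
  position <- position[ord]
  input <- input[ord, , drop = FALSE]
  ip <- ip[ord, , drop = FALSE]

  dup <- unlist(lapply(split(position, factor(chromosome, chr_levels)),
                       function(p) any(duplicated(p))), use.names = FALSE)
  if (any(dup))
    stop("duplicated positions within a chromosome: probe ordering undefined")

  structure(list(
    probes = data.frame(probe_id = probe_id, chromosome = chromosome,
                        position = position, stringsAsFactors = FALSE),
    x = input, y = ip, n_replicates = ncol(input)
  ), class = "probe_dataset")
}

#' @export
print.probe_dataset <- function(x, ...) {
  cat(sprintf("probe_dataset: %d probes, %d replicate(s), %d chromosome(s)\n",
              nrow(x$probes), x$n_replicates,
              length(unique(x$probes$chromosome))))
  print(head(cbind(x$probes,
                   input = x$x[seq_len(min(6L, nrow(x$x))), 1L],
                   ip = x$y[seq_len(min(6L, nrow(x$y))), 1L])))
  invisible(x)
}

#' @export
dim.probe_dataset <- function(x) c(nrow(x$probes), x$n_replicates)

# indices of each chromosome block, in dataset order
chromosome_blocks <- function(data) {
  chr <- data$probes$chromosome
  split(seq_along(chr), factor(chr, unique(chr)))
}

#' Extract a single-replicate view of a probe dataset
#'
#' Restricts a multi-replicate dataset to one replicate, e.g. to fit the
#' classical single-replicate mixture model to each replicate separately
#' before combining the per-replicate posteriors.
#'
#' @param data a [probe_dataset].
#' @param r replicate index in `1:data$n_replicates`.
#' @return A `probe_dataset` with `n_replicates = 1`.
#' @export
replicate_view <- function(data, r) {
  stopifnot(inherits(data, "probe_dataset"))
  r <- as.integer(r)
  if (r < 1L || r > data$n_replicates) stop("replicate index out of range")
  out <- data
  out$x <- data$x[, r, drop = FALSE]
  out$y <- data$y[, r, drop = FALSE]
  out$n_replicates <- 1L
  out
}
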