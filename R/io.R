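#' Read per-replicate probe files into a probe dataset
#'
#' Each biological replicate lives in its own delimited text file with a
#' header row and (at least) five columns: probe identifier, chromosome,
#' 1-based genomic position, log-Input intensity and log-IP intensity.
#' Files are aligned by probe identifier — row order may differ between
#' files — and must describe exactly the same probes with identical
#' chromosome/position annotation.
#'
#' @param paths character vector of file paths, one per replicate.
#' @param columns named character vector mapping the five roles to the
#'   column names used in the files; defaults to
#'   `c(probe_id = "probe_id", chromosome = "chromosome",
#'   position = "position", input = "input", ip = "ip")`.
#' @param sep field delimiter (default tab).
#' @return A [probe_dataset] with one replicate per file, probes sorted by
#'   position within chromosome.
#' @export
read_replicates <- function(paths,
                            columns = c(probe_id = "probe_id",
                                        chromosome = "chromosome",
                                        position = "position",
                                        input = "input", ip = "ip"),
                            sep = "\t") {
  if (length(paths) < 1L) stop("at least one replicate file is required")
  roles <- c("probe_id", "chromosome", "position", "input", "ip")
  if (!all(roles %in% names(columns)) || anyDuplicated(columns[roles]))
    stop("columns must map the five roles ",
         paste(roles, collapse = ", "), " to distinct column names")
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    df <- read.delim(p, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(unname(columns[roles]), names(df))
    if (length(missing))
      stop("file ", p, " lacks required column(s): ",
           paste(missing, collapse = ", "))
    out <- df[, unname(columns[roles])]
    names(out) <- roles
    for (v in c("input", "ip")) {
      val <- suppressWarnings(as.numeric(out[[v]]))
      bad <- which(is.na(val) & !is.na(out[[v]]))
      if (length(bad))
        stop("file ", p, ": non-numeric ", v, " value at data line ",
             bad[1L])
      out[[v]] <- val
    }
    out
  })

  ref <- tabs[[1L]]
  for (i in seq_along(tabs)[-1L]) {
    only_ref <- setdiff(ref$probe_id, tabs[[i]]$probe_id)
    only_i <- setdiff(tabs[[i]]$probe_id, ref$probe_id)
    if (length(only_ref) || length(only_i))
      stop("replicate files disagree on probe sets; e.g. ",
           paste(head(c(only_ref, only_i), 5L), collapse = ", "))
    m <- match(ref$probe_id, tabs[[i]]$probe_id)
    tabs[[i]] <- tabs[[i]][m, ]
    if (!identical(tabs[[i]]$chromosome, ref$chromosome) ||
        !identical(as.integer(tabs[[i]]$position), as.integer(ref$position)))
      stop("replicate file ", paths[i],
           " disagrees on chromosome/position annotation")
  }
  probe_dataset(
    probe_id = ref$probe_id, chromosome = ref$chromosome,
    position = ref$position,
    input = do.call(cbind, lapply(tabs, `[[`, "input")),
    ip = do.call(cbind, lapply(tabs, `[[`, "ip"))
  )
}

#' Write per-probe posterior probabilities and statuses
#'
#' Writes the classifier output — one row per probe with its enriched
#' conditional probability and enriched/non-enriched status — as a
#' tab-delimited file with header
#' `probe_id chromosome position posterior_enriched status`. Posteriors are
#' written with 8 significant digits so a write/read round trip preserves
#' them to at least 6 significant digits.
#'
#' @param results a data frame as returned by [predict.hmmchip()] (columns
#'   `probe_id`, `chromosome`, `position`, `posterior_enriched`, `status`).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  cols <- c("probe_id", "chromosome", "position", "posterior_enriched",
            "status")
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data frame")
  if (!all(cols %in% names(results)))
    stop("results must have columns ", paste(cols, collapse = ", "))
  out <- results[, cols]
  out$posterior_enriched <- sprintf("%.8g", out$posterior_enriched)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results file written by [write_results()]
#'
#' @param path file path.
#' @return A data frame with the five result columns.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export enriched probes as a BED6 track
#'
#' Writes the enriched probes only, as 0-based half-open intervals
#' `[position - 1, position - 1 + probe_length)`, with the probe identifier
#' as name, `round(1000 * posterior)` as score and `"."` strand — ready for
#' a genome browser. Probe positions in result tables are 1-based.
#'
#' @param results a data frame as for [write_results()].
#' @param probe_length probe length in base pairs (>= 1).
#' @param path output BED file path.
#' @return Invisibly, the number of enriched probes written.
#' @export
export_bed <- function(results, probe_length, path) {
  probe_length <- as.integer(probe_length)
  if (is.na(probe_length) || probe_length < 1L)
    stop("probe_length must be >= 1")
  enr <- results[results$status == "enriched", , drop = FALSE]
  bed <- data.frame(
    chrom = enr$chromosome,
    start = enr$position - 1L,
    end = enr$position - 1L + probe_length,
    name = enr$probe_id,
    score = round(1000 * enr$posterior_enriched),
    strand = rep(".", nrow(enr))
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(nrow(bed))
}
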