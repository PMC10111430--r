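#' Sites significantly methylated in every replicate
#'
#' Exact (chrom, pos, strand) intersection of the significant calls of two
#' or more replicate methylomes.  A site absent from a replicate's table
#' (e.g. unmapped in that replicate) counts as not significant there.
#'
#' @param call_sets A list of two or more call `data.frame`s from
#'   [call_methylation()] (or any `data.frame` with `chrom`, `pos`,
#'   `strand` and logical `significant` columns).
#' @return A `data.frame` of shared site keys (`chrom`, `pos`, `strand`),
#'   ordered by (chrom, pos, strand).
#' @export
intersect_significant <- function(call_sets) {
  if (length(call_sets) < 2) stop("need at least two call sets")
  keys <- lapply(call_sets, .significant_keys)
  shared <- Reduce(intersect, keys)
  .keys_to_df(sort(shared))
}

.significant_keys <- function(calls) {
  if (!"significant" %in% names(calls)) {
    stop("call set lacks a 'significant' column")
  }
  sub <- calls[calls$significant %in% TRUE, , drop = FALSE]
  paste(sub$chrom, sub$pos, sub$strand, sep = "\r")
}

.keys_to_df <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                   strand = parts[, 3], stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
}

#' Shared-site counts at every replicate-subset stringency
#'
#' For every subset of replicates of size 2..k, the number of sites
#' significant in all members of the subset.  Subsets are enumerated
#' deterministically ([utils::combn()] order, sizes ascending).
#'
#' @param call_sets Named (or unnamed) list of call sets.
#' @return A `data.frame` with columns `subset` (comma-separated member
#'   names), `size`, `shared_count`.
#' @export
stringency_sweep <- function(call_sets) {
  k <- length(call_sets)
  if (k < 2) stop("need at least two call sets")
  nm <- names(call_sets)
  if (is.null(nm) || any(nm == "")) nm <- paste0("set", seq_len(k))
  keys <- lapply(call_sets, .significant_keys)
  rows <- list()
  for (size in 2:k) {
    sets <- utils::combn(k, size, simplify = FALSE)
    for (idx in sets) {
      shared <- Reduce(intersect, keys[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(nm[idx], collapse = ","),
        size = size,
        shared_count = length(shared),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Significant-site counts per chromosome
#'
#' @param calls A call set, or a site-key `data.frame` from
#'   [intersect_significant()] (every row then counts as significant).
#' @param chromosomes Optional chromosome names to report (zeros included
#'   for chromosomes with no sites).
#' @return A `data.frame` with columns `chrom` and `count`, plus an
#'   attached `total` attribute equal to `sum(count)`.
#' @export
per_chromosome_counts <- function(calls, chromosomes = NULL) {
  sub <- if ("significant" %in% names(calls)) {
    calls[calls$significant %in% TRUE, , drop = FALSE]
  } else {
    calls
  }
  if (is.null(chromosomes)) chromosomes <- sort(unique(calls$chrom))
  counts <- table(factor(sub$chrom, levels = chromosomes))
  out <- data.frame(chrom = chromosomes, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$count)
  out
}
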