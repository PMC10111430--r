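#' Read a per-base depth track
#'
#' Expects the three-column TSV emitted by `samtools depth -a`
#' (chromosome, 1-based position, depth), which includes positions with
#' zero aligned reads.
#'
#' @param path Path to the TSV (no header, or a header naming the three
#'   columns `chrom`, `pos`, `depth`).
#' @return A `data.frame` with columns `chrom`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("chrom", "pos", "depth")
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  if (any(df$depth < 0)) stop("negative depth values")
  df
}

#' Median and mean depth over an interval
#'
#' @param track Depth track (see [read_depth_track()]), a single
#'   chromosome unless `chrom` is given.
#' @param start,end 1-based inclusive interval bounds (orientation is
#'   irrelevant; they are swapped if reversed).
#' @param chrom Chromosome to restrict to, required for multi-chromosome
#'   tracks.
#' @return A list with `median` and `mean` depth.
#' @export
interval_depth_summary <- function(track, start, end, chrom = NULL) {
  if (!is.null(chrom)) {
    track <- track[track$chrom == chrom, , drop = FALSE]
  } else if (length(unique(track$chrom)) > 1) {
    stop("track covers several chromosomes; pass chrom")
  }
  if (start > end) { tmp <- start; start <- end; end <- tmp }
  if (start < min(track$pos) || end > max(track$pos)) {
    stop("interval [", start, ", ", end, "] outside the depth track")
  }
  d <- track$depth[track$pos >= start & track$pos <= end]
  list(median = stats::median(d), mean = mean(d))
}

#' Gene presence/absence verdict from relative depth
#'
#' A gene is declared absent (e.g. knocked out) when its median depth
#' falls below `absent_ratio_threshold` times the chromosome-wide median.
#' The default 0.10 cleanly separates a deleted gene (ratio near 0.01)
#' from an intact one (ratio near 0.9).
#'
#' @param gene_summary,chrom_summary Lists with a `median` field, as from
#'   [interval_depth_summary()].
#' @param absent_ratio_threshold Ratio below which the gene is absent.
#' @return A list with `verdict` (`"present"`, `"absent"`, or
#'   `"indeterminate"` with a warning when the chromosome median is zero)
#'   and `ratio`.
#' @export
presence_verdict <- function(gene_summary, chrom_summary,
                             absent_ratio_threshold = 0.10) {
  if (chrom_summary$median <= 0) {
    warning("chromosome median depth is zero; verdict indeterminate")
    return(list(verdict = "indeterminate", ratio = NA_real_))
  }
  ratio <- gene_summary$median / chrom_summary$median
  list(verdict = if (ratio < absent_ratio_threshold) "absent" else "present",
       ratio = ratio)
}
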