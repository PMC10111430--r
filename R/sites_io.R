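#' Read a genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each FASTA header as the chromosome
#' name, so names match the `chrom` column of count tables.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.required_minimal <- c("chrom", "pos", "strand", "context",
                       "meth_reads", "total_reads")

.valid_contexts <- c("CG", "CHG", "CHH", "unknown")

#' Read a per-cytosine bisulfite count table
#'
#' Parses either the package's minimal six-column dialect or the native
#' output of BSMAP's `methratio.py`.  One row is one strand-aware cytosine:
#' `meth_reads` counts unconverted (C) reads and `unmeth_reads` converted
#' (T) reads.  Minus-strand cytosines carry the plus-strand coordinate of
#' the position, matching how genome browsers and the upstream extractor
#' report them.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect `"minimal"` (columns `chrom`, `pos`, `strand`, `context`,
#'   `meth_reads`, `total_reads`; extra columns are ignored) or
#'   `"methratio"` (native `methratio.py` columns `chr`, `pos`, `strand`,
#'   `context`, `C_count`, `CT_count`, optionally `eff_CT_count`).
#' @param use_eff_ct For the methratio dialect only: use the rounded
#'   `eff_CT_count` column as the read total instead of `CT_count`.
#'   Default `FALSE`, matching the plain T/(C+T) accounting.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `meth_reads`, `unmeth_reads`, sorted by (chrom, pos, strand).
#' @export
read_count_table <- function(path, dialect = c("minimal", "methratio"),
                             use_eff_ct = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("count table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (dialect == "minimal") {
    missing_cols <- setdiff(.required_minimal, names(raw))
    if (length(missing_cols) > 0) {
      stop("minimal dialect requires columns: ",
           paste(missing_cols, collapse = ", "))
    }
    df <- data.frame(chrom = raw$chrom,
                     pos = .parse_count(raw$pos, path, "pos"),
                     strand = raw$strand,
                     context = raw$context,
                     meth_reads = .parse_count(raw$meth_reads, path, "meth_reads"),
                     total = .parse_count(raw$total_reads, path, "total_reads"),
                     stringsAsFactors = FALSE)
  } else {
    needed <- c("chr", "pos", "strand", "context", "C_count", "CT_count")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols) > 0) {
      stop("methratio dialect requires columns: ",
           paste(missing_cols, collapse = ", "))
    }
    if (use_eff_ct && !"eff_CT_count" %in% names(raw)) {
      stop("use_eff_ct = TRUE but no eff_CT_count column present")
    }
    total <- if (use_eff_ct) {
      as.integer(round(as.numeric(raw$eff_CT_count)))
    } else {
      .parse_count(raw$CT_count, path, "CT_count")
    }
    df <- data.frame(chrom = raw$chr,
                     pos = .parse_count(raw$pos, path, "pos"),
                     strand = raw$strand,
                     context = .normalize_context(raw$context),
                     meth_reads = .parse_count(raw$C_count, path, "C_count"),
                     total = total,
                     stringsAsFactors = FALSE)
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stop("parse error in ", path, " line ", bad_strand[1] + 1L,
         ": strand must be '+' or '-'")
  }
  bad_pos <- which(df$pos < 1L)
  if (length(bad_pos) > 0) {
    stop("parse error in ", path, " line ", bad_pos[1] + 1L,
         ": pos must be >= 1")
  }
  under <- which(df$total < df$meth_reads)
  if (length(under) > 0) {
    stop("validation error in ", path, " line ", under[1] + 1L,
         ": total_reads < meth_reads")
  }
  df$context[!df$context %in% .valid_contexts] <- "unknown"
  records <- data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
                        context = df$context, meth_reads = df$meth_reads,
                        unmeth_reads = df$total - df$meth_reads,
                        stringsAsFactors = FALSE)
  dup <- duplicated(records[c("chrom", "pos", "strand")])
  if (any(dup)) {
    stop("duplicate (chrom, pos, strand) rows in ", path,
         ", first at line ", which(dup)[1] + 1L)
  }
  records <- records[order(records$chrom, records$pos, records$strand), ,
                     drop = FALSE]
  rownames(records) <- NULL
  records
}

.parse_count <- function(x, path, col) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v < 0 | v != floor(v))
  if (length(bad) > 0) {
    stop("parse error in ", path, " line ", bad[1] + 1L,
         ": column '", col, "' must be a non-negative integer, got '",
         x[bad[1]], "'")
  }
  as.integer(v)
}

# methratio emits e.g. "CHH"/"CHG"/"CG" already, but tolerate lowercase.
.normalize_context <- function(x) {
  x <- toupper(x)
  x[x == "CPG"] <- "CG"
  x
}

#' Write a count table in the minimal dialect
#'
#' @param records Count-table `data.frame` as returned by
#'   [read_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(records, path) {
  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    strand = records$strand, context = records$context,
                    meth_reads = records$meth_reads,
                    total_reads = records$meth_reads + records$unmeth_reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign the sequence context of a cytosine
#'
#' Context is read 5'->3' on the cytosine's own strand: `CG` when the next
#' base is G, `CHG` when the next base is H (A, C or T) and the base after
#' is G, `CHH` otherwise, and `unknown` within 2 bp of a contig end or when
#' an adjacent base is N.  For a minus-strand cytosine (a G on the plus
#' strand at the same coordinate) the two bases are the complements of the
#' plus-strand bases at `pos - 1` and `pos - 2`.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param chrom Chromosome name (scalar).
#' @param pos 1-based position(s) of the cytosine, plus-strand coordinates.
#' @param strand `"+"` or `"-"`, recycled against `pos`.
#' @return Character vector of contexts.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  chars <- .chrom_chars(genome, chrom)
  n <- length(chars)
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (any(pos < 1L | pos > n)) stop("pos outside chromosome ", chrom)
  base <- chars[pos]
  expected <- ifelse(strand == "+", "C", "G")
  if (any(base != expected)) {
    bad <- which(base != expected)[1]
    stop("base at ", chrom, ":", pos[bad], " is not a cytosine on strand ",
         strand[bad], " (found ", base[bad], " on the plus strand)")
  }
  .context_from_chars(chars, pos, strand)
}

# Vectorised context core over one chromosome's character vector.
.context_from_chars <- function(chars, pos, strand) {
  n <- length(chars)
  plus <- strand == "+"
  i1 <- ifelse(plus, pos + 1L, pos - 1L)
  i2 <- ifelse(plus, pos + 2L, pos - 2L)
  ok1 <- i1 >= 1L & i1 <= n
  ok2 <- i2 >= 1L & i2 <= n
  b1 <- b2 <- rep(NA_character_, length(pos))
  b1[ok1] <- chars[i1[ok1]]
  b2[ok2] <- chars[i2[ok2]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  b1[!plus] <- unname(comp[b1[!plus]])
  b2[!plus] <- unname(comp[b2[!plus]])
  ctx <- rep("unknown", length(pos))
  known <- !is.na(b1) & !is.na(b2) & b1 %in% names(comp) & b2 %in% names(comp)
  is_cg <- known & b1 == "G"
  is_chg <- known & b1 != "G" & b2 == "G"
  is_chh <- known & b1 != "G" & b2 != "G"
  ctx[is_cg] <- "CG"
  ctx[is_chg] <- "CHG"
  ctx[is_chh] <- "CHH"
  ctx
}

.chrom_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

#' GC content of the window around a site
#'
#' Percent G+C across `pos - flank` to `pos + flank` inclusive (201 bp at
#' the default flank of 100; the site base itself is included).  Windows
#' that would run off the chromosome are truncated with a warning and the
#' percentage computed over the shortened window.  The window is defined on
#' the plus strand and is strand-agnostic: G+C content is identical on the
#' reverse complement.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param pos 1-based site position(s).
#' @param flank Flank size in bp on each side (default 100).
#' @return Numeric vector of GC percentages.
#' @export
gc_window <- function(genome, chrom, pos, flank = 100L) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- genome[[chrom]]
  n <- length(seq)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > n)) stop("pos outside chromosome ", chrom)
  lo <- pos - flank
  hi <- pos + flank
  if (any(lo < 1L | hi > n)) {
    warning("gc_window truncated at chromosome bounds for ",
            sum(lo < 1L | hi > n), " site(s); window length adjusted")
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, n)
  }
  vapply(seq_along(pos), function(i) {
    w <- Biostrings::subseq(seq, lo[i], hi[i])
    gc <- sum(Biostrings::letterFrequency(w, c("G", "C")))
    100 * gc / (hi[i] - lo[i] + 1L)
  }, numeric(1))
}

#' Write methylation calls to TSV or BED
#'
#' The TSV format round-trips: it contains the minimal count-table columns
#' (so [read_count_table()] can re-ingest it) plus the call annotations.
#' BED output converts the 1-based inclusive positions to 0-based
#' half-open intervals; the score column holds the methylation ratio
#' scaled to 0-1000.
#'
#' @param calls Call `data.frame` from [call_methylation()] (TSV accepts
#'   any record `data.frame` with the minimal columns).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- calls
    out$total_reads <- calls$meth_reads + calls$unmeth_reads
    keep <- c("chrom", "pos", "strand", "context", "meth_reads",
              "total_reads",
              intersect(c("ratio", "ci_lower", "ci_upper", "p_raw",
                          "q_adj", "significant"), names(calls)))
    utils::write.table(out[keep], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    score <- if ("ratio" %in% names(calls)) {
      as.integer(round(1000 * ifelse(is.na(calls$ratio), 0, calls$ratio)))
    } else {
      rep(0L, nrow(calls))
    }
    bed <- data.frame(chrom = calls$chrom,
                      start = calls$pos - 1L,
                      end = calls$pos,
                      name = calls$context,
                      score = score,
                      strand = calls$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a TSV written by [write_calls()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with record columns plus any call annotations.
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$unmeth_reads <- df$total_reads - df$meth_reads
  if ("significant" %in% names(df)) df$significant <- as.logical(df$significant)
  df
}
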