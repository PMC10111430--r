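#' Find palindromic (inverted repeat) regions genome-wide
#'
#' A palindrome is an interval whose left arm is the exact reverse
#' complement of its right arm, the two separated by a loop of 0 to
#' `max_loop` bases.  Reported structures are maximal: arms cannot be
#' extended outward (the flanking pair does not complement) and the loop
#' is minimal (its flanks do not pair), so each interval carries its
#' longest-arm decomposition.  Such regions can fold into hairpins when
#' single-stranded during bisulfite treatment, shielding stem cytosines
#' from conversion.
#'
#' @param genome A [Biostrings::DNAStringSet], named character vector of
#'   chromosome sequences, or a single string.
#' @param min_length Minimum total length `2 * arm + loop` (default 19).
#' @param min_arm Minimum arm length in bp (default 8, must be >= 2).
#' @param max_loop Maximum loop length in bp (default 10).
#' @param mismatches Allowed arm mismatches; only exact arms
#'   (`mismatches = 0`) are supported.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `arm_len`, `loop_len`, `total_len`, sorted by
#'   (chrom, start, end).
#' @seealso [remove_nested()], [annotate_sites()]
#' @export
find_palindromes <- function(genome, min_length = 19L, min_arm = 8L,
                             max_loop = 10L, mismatches = 0L) {
  if (mismatches != 0) {
    stop("only exact-arm matching (mismatches = 0) is implemented")
  }
  if (min_arm < 2) stop("min_arm must be >= 2")
  if (min_length < 2 * min_arm) {
    stop("configuration error: min_length < 2 * min_arm")
  }
  if (max_loop < 0) stop("max_loop must be >= 0")
  seqs <- .as_chrom_strings(genome)
  out <- lapply(names(seqs), function(chrom) {
    m <- .scan_palindromes_cpp(seqs[[chrom]], as.integer(min_length),
                               as.integer(min_arm), as.integer(max_loop))
    if (nrow(m) == 0) return(NULL)
    df <- as.data.frame(m)
    df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
    df$chrom <- chrom
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), arm_len = integer(0),
                      loop_len = integer(0))
  }
  out$total_len <- out$end - out$start + 1L
  out <- out[c("chrom", "start", "end", "arm_len", "loop_len", "total_len")]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_chrom_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.list(toupper(as.character(genome)))
  } else if (is.character(genome)) {
    seqs <- as.list(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet or character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  seqs
}

#' Remove nested palindromes
#'
#' Drops every palindrome whose interval is a proper subset of another
#' palindrome's interval on the same chromosome, leaving only the longest
#' structures; identical intervals are deduplicated.
#'
#' @param palindromes Output of [find_palindromes()].
#' @return The filtered `data.frame`, sorted by (chrom, start).
#' @export
remove_nested <- function(palindromes) {
  if (nrow(palindromes) == 0) return(palindromes)
  keep <- unlist(lapply(split(seq_len(nrow(palindromes)),
                              palindromes$chrom), function(idx) {
    s <- palindromes$start[idx]
    e <- palindromes$end[idx]
    ord <- order(s, -e)
    s <- s[ord]; e <- e[ord]; idx <- idx[ord]
    dup <- duplicated(data.frame(s, e))
    # after sorting by (start asc, end desc), an interval is properly
    # contained iff some earlier interval reaches at least as far right
    prev_max_end <- c(-Inf, cummax(e)[-length(e)])
    contained <- e <= prev_max_end & !dup
    # equal-start deduplication: dup rows are identical intervals
    idx[!(contained | dup)]
  }), use.names = FALSE)
  out <- palindromes[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile summary of palindrome lengths
#'
#' @param palindromes Output of [find_palindromes()] or [remove_nested()].
#' @return A list with `overall` (named quantile vector: min, quartiles,
#'   max) and `per_chromosome` (a `data.frame` of the same summaries by
#'   chromosome).  Empty input returns an empty summary.
#' @export
length_quantiles <- function(palindromes) {
  if (nrow(palindromes) == 0) {
    return(list(overall = stats::setNames(numeric(0), character(0)),
                per_chromosome = data.frame()))
  }
  q <- function(x) stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1))
  per <- do.call(rbind, lapply(split(palindromes$total_len,
                                     palindromes$chrom), q))
  list(overall = q(palindromes$total_len),
       per_chromosome = data.frame(chrom = rownames(per), per,
                                   n = as.integer(table(palindromes$chrom)[rownames(per)]),
                                   row.names = NULL, check.names = FALSE))
}

#' Classify sites as hairpin stem, loop, or outside palindromes
#'
#' Stem positions lie inside either arm (double-stranded in the folded
#' hairpin, shielded from bisulfite); loop positions lie strictly between
#' the arms (single-stranded, converted normally).  A site overlapping
#' several retained palindromes is assigned to the longest one.
#'
#' @param sites A `data.frame` with `chrom`, `pos` (and optionally
#'   `strand`; classification is strand-agnostic since a palindrome folds
#'   on both strands).
#' @param palindromes Nested-removed palindromes (see [remove_nested()]).
#' @return `sites` with columns `status` (`"stem"`, `"loop"`, `"outside"`)
#'   and `palindrome` (row index into `palindromes`, `NA` outside).
#' @export
annotate_sites <- function(sites, palindromes) {
  status <- rep("outside", nrow(sites))
  pal_idx <- rep(NA_integer_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    pi <- which(palindromes$chrom == chrom)
    if (length(pi) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], width = 1L),
      IRanges::IRanges(palindromes$start[pi], palindromes$end[pi]))
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # longest palindrome wins when several overlap a site
    len <- palindromes$total_len[pi][sh]
    ord <- order(qh, -len)
    first <- !duplicated(qh[ord])
    qh <- qh[ord][first]; sh <- sh[ord][first]
    pal_idx[si[qh]] <- pi[sh]
  }
  inside <- !is.na(pal_idx)
  if (any(inside)) {
    p <- palindromes[pal_idx[inside], ]
    pos <- sites$pos[inside]
    in_left <- pos <= p$start + p$arm_len - 1L
    in_right <- pos >= p$end - p$arm_len + 1L
    status[inside] <- ifelse(in_left | in_right, "stem", "loop")
  }
  out <- sites
  out$status <- status
  out$palindrome <- pal_idx
  out
}

#' Palindrome overlap of shared methylcytosines, by stringency
#'
#' For every subset of replicates of size 2..k: the shared significant
#' sites, how many fall inside a palindrome (stem or loop), and the
#' percentage.  Mirrors the observation that the in-palindrome fraction
#' rises with intersection stringency when hairpin protection, not true
#' methylation, drives the calls.
#'
#' @param call_sets Named list of call sets (see [call_methylation()]).
#' @param palindromes Nested-removed palindromes.
#' @return A `data.frame` with columns `subset`, `size`, `common_mC`,
#'   `in_palindrome`, `percent` (`NA` when a subset shares no sites).
#' @export
overlap_stringency_table <- function(call_sets, palindromes) {
  sweep <- stringency_sweep(call_sets)
  k <- length(call_sets)
  nm <- names(call_sets)
  if (is.null(nm) || any(nm == "")) nm <- paste0("set", seq_len(k))
  names(call_sets) <- nm
  in_pal <- integer(nrow(sweep))
  for (i in seq_len(nrow(sweep))) {
    members <- strsplit(sweep$subset[i], ",", fixed = TRUE)[[1]]
    shared <- intersect_significant(call_sets[members])
    if (nrow(shared) == 0) next
    ann <- annotate_sites(shared, palindromes)
    in_pal[i] <- sum(ann$status != "outside")
  }
  data.frame(subset = sweep$subset, size = sweep$size,
             common_mC = sweep$shared_count, in_palindrome = in_pal,
             percent = ifelse(sweep$shared_count > 0,
                              100 * in_pal / sweep$shared_count, NA_real_),
             stringsAsFactors = FALSE)
}

#' Palindrome census and site GC content for a reference assembly
#'
#' Runs the full palindrome screen (find, then nested removal) on a genome
#' FASTA and, optionally, reports the GC window percentage at given sites.
#' Intended for reproducing genome-level summaries on a locally available
#' reference assembly; the palindrome count is sensitive to `min_length`,
#' `min_arm` and `max_loop`, which are therefore exposed.
#'
#' @param fasta Path to the assembly FASTA.
#' @param sites Optional `data.frame` with `chrom` and `pos` for GC
#'   windows.
#' @inheritParams find_palindromes
#' @param flank GC window flank (default 100 bp).
#' @return A list with `palindromes` (nested-removed `data.frame`),
#'   `n_palindromes`, `length_quantiles`, and `site_gc` (`NULL` when no
#'   sites given).
#' @export
reference_genome_census <- function(fasta, sites = NULL, min_length = 19L,
                                    min_arm = 8L, max_loop = 10L,
                                    flank = 100L) {
  genome <- read_genome(fasta)
  pals <- remove_nested(find_palindromes(genome, min_length = min_length,
                                         min_arm = min_arm,
                                         max_loop = max_loop))
  site_gc <- NULL
  if (!is.null(sites)) {
    site_gc <- sites
    site_gc$gc_percent <- unlist(lapply(seq_len(nrow(sites)), function(i) {
      gc_window(genome, sites$chrom[i], sites$pos[i], flank = flank)
    }))
  }
  list(palindromes = pals, n_palindromes = nrow(pals),
       length_quantiles = length_quantiles(pals), site_gc = site_gc)
}
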