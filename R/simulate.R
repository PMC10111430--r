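#' Configuration for the bisulfite-count simulator
#'
#' Defaults emulate the study conditions this package targets: a strongly
#' AT-rich genome (77\% A+T), planted palindromes of 19-80 bp, a
#' per-cytosine depth around 30x, a bisulfite conversion failure rate of
#' 0.005 (conversion 99.5\%), zero true methylation, and hairpin-stem
#' protection that leaves ~30\% of reads unconverted at stem cytosines
#' while loop cytosines convert normally.
#'
#' @param n_chrom Number of chromosomes (default 6).
#' @param chrom_length Length of each chromosome in bp (default 1e5).
#' @param at_fraction Genomic A+T fraction (default 0.77).
#' @param n_palindromes Palindromes planted per chromosome (default 5).
#' @param pal_length_range Total planted palindrome length range
#'   (default `c(19, 80)`).
#' @param pal_min_arm Minimum planted arm length (default 8).
#' @param pal_max_loop Maximum planted loop length (default 10).
#' @param depth_mean Mean per-cytosine depth; scalar or one value per
#'   replicate (default 30).
#' @param depth_size Negative-binomial size (dispersion) of depth;
#'   larger is closer to Poisson (default 10).
#' @param epsilon Conversion failure probability; scalar or per replicate
#'   (default 0.005).
#' @param rho Per-read escape probability at hairpin-stem cytosines.  A
#'   scalar applies one protection level to every stem; a length-2 vector
#'   is a range from which each stem site draws its own level once (shared
#'   across replicates, since protection is a property of the structure).
#'   Default `c(0.15, 0.5)`, emulating the observed spread of stem-site
#'   methylation ratios.
#' @param mu True methylation level: scalar applied to all cytosines
#'   (default 0), or a `data.frame` with `chrom`, `pos`, `strand`, `mu`
#'   overriding the scalar at listed sites.
#' @param n_replicates Number of replicate methylomes (default 4).
#' @param spikein_length Length of the unmethylated spike-in sequence
#'   (default 48000 bp, lambda-like).
#' @param spikein_gc GC fraction of the spike-in (default 0.5,
#'   lambda-like).
#' @param seed RNG seed; a fixed seed makes all outputs byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 6L, chrom_length = 1e5, at_fraction = 0.77,
                       n_palindromes = 5L, pal_length_range = c(19L, 80L),
                       pal_min_arm = 8L, pal_max_loop = 10L,
                       depth_mean = 30, depth_size = 10, epsilon = 0.005,
                       rho = c(0.15, 0.5), mu = 0, n_replicates = 4L,
                       spikein_length = 48000L, spikein_gc = 0.5,
                       seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, all(rho >= 0), all(rho <= 1),
            length(rho) %in% 1:2,
            at_fraction > 0, at_fraction < 1,
            pal_length_range[1] >= 19, pal_length_range[2] >= pal_length_range[1],
            n_replicates >= 1)
  if (n_palindromes * (pal_length_range[2] + 2L) > chrom_length / 2) {
    stop("configuration error: requested palindrome mass exceeds chromosome capacity")
  }
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 at_fraction = at_fraction,
                 n_palindromes = as.integer(n_palindromes),
                 pal_length_range = as.integer(pal_length_range),
                 pal_min_arm = as.integer(pal_min_arm),
                 pal_max_loop = as.integer(pal_max_loop),
                 depth_mean = depth_mean, depth_size = depth_size,
                 epsilon = epsilon, rho = rho, mu = mu,
                 n_replicates = as.integer(n_replicates),
                 spikein_length = as.integer(spikein_length),
                 spikein_gc = spikein_gc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.random_bases <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.revcomp_chars <- function(x) {
  rev(unname(c(A = "T", T = "A", C = "G", G = "C")[x]))
}

#' Generate a synthetic AT-rich genome with planted palindromes
#'
#' Background bases are i.i.d. at the configured A+T fraction; palindromes
#' with exact reverse-complement arms are planted at non-overlapping,
#' uniformly chosen loci.  A 50\%-GC spike-in sequence (no planted
#' structure) is generated alongside.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` and `spikein`
#'   ([Biostrings::DNAStringSet]s), `truth` (a list with the planted
#'   `palindromes` `data.frame`), and `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  gc <- 1 - config$at_fraction
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- character(config$n_chrom)
  planted <- list()
  for (ci in seq_along(chroms)) {
    chars <- .random_bases(config$chrom_length, gc)
    occupied <- rep(FALSE, config$chrom_length)
    for (p in seq_len(config$n_palindromes)) {
      total <- sample(seq(config$pal_length_range[1],
                          config$pal_length_range[2]), 1)
      loops <- seq(total %% 2L, min(config$pal_max_loop,
                                    total - 2L * config$pal_min_arm), by = 2L)
      loop <- if (length(loops) == 1) loops else sample(loops, 1)
      arm <- (total - loop) / 2L
      placed <- FALSE
      for (try in 1:200) {
        start <- sample(config$chrom_length - total + 1L, 1)
        # 1 bp margin so neighbouring plants cannot fuse
        span <- max(1L, start - 1L):min(config$chrom_length, start + total)
        if (any(occupied[span])) next
        left <- .random_bases(arm, gc)
        loop_seq <- if (loop > 0) .random_bases(loop, gc) else character(0)
        chars[start:(start + total - 1L)] <-
          c(left, loop_seq, .revcomp_chars(left))
        occupied[span] <- TRUE
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = chroms[ci], start = start, end = start + total - 1L,
          arm_len = arm, loop_len = loop, total_len = total,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place palindrome ", p, " on ", chroms[ci])
    }
    seqs[ci] <- paste(chars, collapse = "")
  }
  spike <- paste(.random_bases(config$spikein_length, config$spikein_gc),
                 collapse = "")
  pal_df <- do.call(rbind, planted)
  if (is.null(pal_df)) {
    pal_df <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), arm_len = integer(0),
                         loop_len = integer(0), total_len = integer(0))
  }
  pal_df <- pal_df[order(pal_df$chrom, pal_df$start), , drop = FALSE]
  rownames(pal_df) <- NULL
  list(genome = Biostrings::DNAStringSet(stats::setNames(seqs, chroms)),
       spikein = Biostrings::DNAStringSet(c(spikein = spike)),
       truth = list(palindromes = pal_df),
       config = config)
}

#' Enumerate all cytosines of a genome on both strands
#'
#' Plus-strand cytosines are C bases; minus-strand cytosines are G bases
#' reported at their plus-strand coordinate.  Contexts are assigned from
#' the sequence.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return A `data.frame` with `chrom`, `pos`, `strand`, `context`,
#'   sorted by (chrom, pos, strand).
#' @export
cytosine_sites <- function(genome) {
  seqs <- .as_chrom_strings(genome)
  out <- lapply(names(seqs), function(chrom) {
    chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    plus <- which(chars == "C")
    minus <- which(chars == "G")
    df <- data.frame(
      chrom = chrom,
      pos = c(plus, minus),
      strand = c(rep("+", length(plus)), rep("-", length(minus))),
      stringsAsFactors = FALSE)
    df$context <- .context_from_chars(chars, df$pos, df$strand)
    df
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-site truth: stem / loop / outside relative to the planted
# palindromes, plus the true methylation level.
.site_truth <- function(sites, sim) {
  ann <- annotate_sites(sites, sim$truth$palindromes)
  mu <- sim$config$mu
  if (is.data.frame(mu)) {
    key <- paste(ann$chrom, ann$pos, ann$strand)
    mkey <- paste(mu$chrom, mu$pos, mu$strand)
    lvl <- rep(0, nrow(ann))
    hit <- match(key, mkey)
    lvl[!is.na(hit)] <- mu$mu[hit[!is.na(hit)]]
    ann$mu <- lvl
  } else {
    ann$mu <- mu
  }
  ann
}

#' Simulate bisulfite count tables for every replicate
#'
#' Per cytosine, depth is negative-binomial and the unconverted read
#' count is Binomial(depth, pi) with
#' \eqn{\pi = \mu + (1-\mu)(\epsilon + (1-\epsilon)\rho \cdot 1[\mathrm{stem}])}:
#' true methylation \eqn{\mu}, conversion failure \eqn{\epsilon}, and
#' per-read hairpin escape \eqn{\rho} at planted stem cytosines only.
#' Spike-in cytosines use \eqn{\pi = \epsilon}.
#'
#' @param sim Output of [simulate_genome()].
#' @return `sim` extended with `replicates` and `spikein_counts` (lists of
#'   count `data.frame`s, one per replicate) and `truth$sites` (the
#'   per-cytosine ledger with `status` and `mu`).
#' @export
simulate_counts <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1L)
  sites <- .site_truth(cytosine_sites(sim$genome), sim)
  spike_sites <- cytosine_sites(sim$spikein)
  depth_mean <- rep_len(config$depth_mean, config$n_replicates)
  epsilon <- rep_len(config$epsilon, config$n_replicates)
  is_stem <- sites$status == "stem"
  # per-site protection level, fixed across replicates
  rho_site <- numeric(nrow(sites))
  rho_site[is_stem] <- if (length(config$rho) == 2) {
    stats::runif(sum(is_stem), config$rho[1], config$rho[2])
  } else {
    config$rho
  }
  sites$rho <- rho_site
  replicates <- spikes <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    eps <- epsilon[r]
    pi <- sites$mu + (1 - sites$mu) * (eps + (1 - eps) * rho_site)
    depth <- stats::rnbinom(nrow(sites), size = config$depth_size,
                            mu = depth_mean[r])
    meth <- stats::rbinom(nrow(sites), depth, pi)
    replicates[[r]] <- data.frame(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, meth_reads = meth,
      unmeth_reads = depth - meth, stringsAsFactors = FALSE)
    sdepth <- stats::rnbinom(nrow(spike_sites), size = config$depth_size,
                             mu = depth_mean[r])
    smeth <- stats::rbinom(nrow(spike_sites), sdepth, eps)
    spikes[[r]] <- data.frame(
      chrom = spike_sites$chrom, pos = spike_sites$pos,
      strand = spike_sites$strand, context = spike_sites$context,
      meth_reads = smeth, unmeth_reads = sdepth - smeth,
      stringsAsFactors = FALSE)
  }
  names(replicates) <- names(spikes) <-
    paste0("rep", seq_len(config$n_replicates))
  sim$truth$sites <- sites
  sim$replicates <- replicates
  sim$spikein_counts <- spikes
  sim
}

#' Simulate a full synthetic methylome experiment
#'
#' Genome generation plus count simulation; optionally writes all outputs
#' (FASTA, per-replicate and spike-in count TSVs, truth ledgers) to a
#' directory.  Identical configs produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return The simulation object (see [simulate_counts()]), invisibly
#'   carrying `dir` when files were written.
#' @export
simulate_methylome <- function(config, dir = NULL) {
  sim <- simulate_counts(simulate_genome(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    Biostrings::writeXStringSet(sim$spikein, file.path(dir, "spikein.fa"))
    for (r in seq_along(sim$replicates)) {
      write_count_table(sim$replicates[[r]],
                        file.path(dir, sprintf("rep%d.counts.tsv", r)))
      write_count_table(sim$spikein_counts[[r]],
                        file.path(dir, sprintf("rep%d.spikein.tsv", r)))
    }
    utils::write.table(sim$truth$palindromes,
                       file.path(dir, "truth.palindromes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$sites, file.path(dir, "truth.sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sim$dir <- dir
  }
  sim
}

#' Simulate counts for a flat set of cytosines (no genome)
#'
#' Lightweight generator for calibration experiments: `n_sites`
#' unmethylated cytosines at a given depth model, conversion failure rate
#' and optional uniform stem protection.
#'
#' @param n_sites Number of cytosines.
#' @param depth_mean,depth_size Negative-binomial depth model.
#' @param epsilon Conversion failure probability.
#' @param rho Per-read protection probability applied to every site
#'   (default 0).
#' @param seed RNG seed.
#' @return A count `data.frame` in the standard record format.
#' @export
simulate_site_counts <- function(n_sites, depth_mean = 30, depth_size = 10,
                                 epsilon = 0.005, rho = 0, seed = 1L) {
  set.seed(seed)
  pi <- epsilon + (1 - epsilon) * rho
  depth <- stats::rnbinom(n_sites, size = depth_size, mu = depth_mean)
  meth <- stats::rbinom(n_sites, depth, pi)
  data.frame(chrom = "sim", pos = seq_len(n_sites), strand = "+",
             context = "CHH", meth_reads = meth,
             unmeth_reads = depth - meth, stringsAsFactors = FALSE)
}

#' Run the whole pipeline on simulated data and score it against truth
#'
#' Calls methylation in every replicate against its own spike-in null,
#' intersects significant sites, scans the simulated genome for
#' palindromes, and compares the results with the simulator's ground
#' truth.
#'
#' @param config A [sim_config()] with at least two replicates.
#' @param min_length,min_arm,max_loop Palindrome-scan parameters
#'   (defaults 19 / 8 / 10).
#' @return A list with `calls`, `shared` (k-way shared site keys),
#'   `palindromes` (found, nested-removed), `overlap`
#'   (stringency table), and `metrics`:
#'   `stem_purity` (fraction of k-way shared calls at planted stem
#'   cytosines), `stem_recall`, per-replicate `conversion` (estimated
#'   rate, true rate, and whether the truth lies inside the Wilson 95\%
#'   interval of the pooled spike-in proportion), and
#'   `depth_ratio_spearman` (rank correlation of coverage vs ratio among
#'   significant calls, pooled over replicates).
#' @export
end_to_end_recovery <- function(config, min_length = 19L, min_arm = 8L,
                                max_loop = 10L) {
  if (config$n_replicates < 2) stop("need at least two replicates")
  sim <- simulate_methylome(config)
  calls <- vector("list", config$n_replicates)
  conv <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    conv[[r]] <- estimate_conversion_rate(sim$spikein_counts[[r]])
    calls[[r]] <- call_methylation(sim$replicates[[r]], conv[[r]])
  }
  names(calls) <- names(sim$replicates)
  shared <- intersect_significant(calls)
  pals <- remove_nested(find_palindromes(sim$genome, min_length = min_length,
                                         min_arm = min_arm,
                                         max_loop = max_loop))
  overlap <- overlap_stringency_table(calls, pals)
  truth <- sim$truth$sites
  stem_key <- paste(truth$chrom, truth$pos, truth$strand)[truth$status == "stem"]
  shared_key <- paste(shared$chrom, shared$pos, shared$strand)
  epsilon <- rep_len(config$epsilon, config$n_replicates)
  conversion <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    est <- conv[[r]]
    ci <- wilson_interval(est$ct_count - est$t_count, est$ct_count)
    data.frame(replicate = r, estimated_rate = est$rate,
               true_rate = 100 * (1 - epsilon[r]),
               truth_in_wilson_ci = epsilon[r] >= ci$lower &
                 epsilon[r] <= ci$upper)
  }))
  sig <- do.call(rbind, lapply(calls, function(x) {
    x[x$significant, c("coverage", "ratio")]
  }))
  spearman <- if (nrow(sig) >= 3) {
    stats::cor(sig$coverage, sig$ratio, method = "spearman")
  } else {
    NA_real_
  }
  metrics <- list(
    stem_purity = if (nrow(shared) > 0) mean(shared_key %in% stem_key)
                  else NA_real_,
    stem_recall = if (length(stem_key) > 0) mean(stem_key %in% shared_key)
                  else NA_real_,
    n_shared = nrow(shared),
    conversion = conversion,
    depth_ratio_spearman = spearman)
  list(sim = sim, calls = calls, shared = shared, palindromes = pals,
       overlap = overlap, metrics = metrics)
}
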