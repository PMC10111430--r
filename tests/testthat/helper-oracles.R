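# Independent brute-force oracles and fixture builders used across tests.

fixture_path <- function(name) {
  system.file("extdata", name, package = "hairpincall", mustWork = TRUE)
}

read_cluster_fixture <- function(which = c("plus", "minus")) {
  which <- match.arg(which)
  utils::read.delim(fixture_path(sprintf("chr4_cluster_%s.tsv", which)),
                    stringsAsFactors = FALSE)
}

read_bsp_counts <- function() {
  utils::read.delim(fixture_path("bsp_site_counts.tsv"),
                    stringsAsFactors = FALSE)
}

read_robust_sites <- function() {
  utils::read.delim(fixture_path("robust_sites.tsv"),
                    stringsAsFactors = FALSE)
}

# Deterministic clone matrix from per-site methylated-clone counts: the
# first `meth_clones` clones carry the methylation at each position.
clone_matrix_from_counts <- function(counts, condition) {
  sub <- counts[counts$condition == condition, , drop = FALSE]
  sub <- sub[order(sub$position), , drop = FALSE]
  n <- sub$total_clones[1]
  states <- vapply(seq_len(nrow(sub)), function(j) {
    c(rep(1L, sub$meth_clones[j]), rep(0L, n - sub$meth_clones[j]))
  }, integer(n))
  clone_matrix(states, sub$position, condition = condition)
}

# Wilson bounds by solving the score-inversion quadratic
# (1 + z^2/n) p^2 - (2 phat + z^2/n) p + phat^2 = 0 directly.
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  a <- 1 + z^2 / n
  b <- -(2 * phat + z^2 / n)
  cc <- phat^2
  disc <- sqrt(b^2 - 4 * a * cc)
  sort(c((-b - disc) / (2 * a), (-b + disc) / (2 * a)))
}

# Explicit term-by-term upper binomial tail.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Benjamini-Hochberg step-up from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# Interval-major exhaustive palindrome scan: for every interval of length
# >= min_len, compute the maximal consecutive arm from the outer ends,
# then filter on arm length, loop length and outward maximality.
# Independent of the package's centre-expansion algorithm.
oracle_palindromes <- function(seq, min_len = 19, min_arm = 8,
                               max_loop = 10) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  cchars <- unname(comp[chars])
  cchars[is.na(cchars)] <- "?"
  n <- length(chars)
  res <- list()
  for (L in max(min_len, 2 * min_arm):n) {
    ns <- n - L + 1
    if (ns < 1) break
    s <- seq_len(ns)
    e <- s + L - 1L
    arm <- integer(ns)
    alive <- rep(TRUE, ns)
    for (d in 0:(L %/% 2 - 1)) {
      alive <- alive & (chars[s + d] == cchars[e - d])
      arm[alive] <- d + 1L
      if (!any(alive)) break
    }
    l <- L - 2L * arm
    out_max <- s == 1L | e == n
    mid <- which(!out_max)
    if (length(mid) > 0) {
      out_max[mid] <- chars[s[mid] - 1L] != cchars[e[mid] + 1L]
    }
    keep <- arm >= min_arm & l <= max_loop & out_max
    if (any(keep)) {
      res[[length(res) + 1L]] <- data.frame(
        start = s[keep], end = e[keep],
        arm_len = arm[keep], loop_len = l[keep])
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      arm_len = integer(0), loop_len = integer(0))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs O(n^2) nested filter.
nested_oracle <- function(pals) {
  n <- nrow(pals)
  dup <- duplicated(pals[c("chrom", "start", "end")])
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (pals$chrom[i] == pals$chrom[j] &&
          pals$start[j] <= pals$start[i] && pals$end[i] <= pals$end[j] &&
          (pals$start[j] < pals$start[i] || pals$end[j] > pals$end[i])) {
        drop[i] <- TRUE
      }
    }
  }
  out <- pals[!(drop | dup), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.23) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  pos <- sort(sample(1e6, n))
  data.frame(chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
             pos = pos,
             strand = sample(c("+", "-"), n, replace = TRUE),
             context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
             meth_reads = rbinom(n, 30, 0.1),
             unmeth_reads = rbinom(n, 30, 0.8),
             stringsAsFactors = FALSE)
}

# A call-set data.frame with the given site keys flagged significant.
call_set_of <- function(sites) {
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             significant = TRUE, stringsAsFactors = FALSE)
}
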