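#' Methylation ratio of a cytosine
#'
#' Fraction of reads supporting methylation: `meth / (meth + unmeth)`.
#' Zero-coverage sites return `NA`; the coverage filter in
#' [call_methylation()] removes them from testing.
#'
#' @param meth_reads Unconverted (C) read counts.
#' @param unmeth_reads Converted (T) read counts.
#' @return Numeric vector of ratios in \[0, 1\] (`NA` at zero coverage).
#' @export
methylation_ratio <- function(meth_reads, unmeth_reads) {
  total <- meth_reads + unmeth_reads
  ifelse(total > 0, meth_reads / total, NA_real_)
}

#' Wilson score interval for a binomial proportion
#'
#' Bounds obtained by inverting the score test:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#' with \eqn{z} the two-sided normal quantile for the confidence level
#' (1.959964 at 95\%).  Vectorised over `meth_reads` / `total_reads`.
#'
#' @param meth_reads Successes (unconverted reads), `0 <= meth <= total`.
#' @param total_reads Trials (total reads), `>= 1`.
#' @param confidence Confidence level, default 0.95.
#' @return A `data.frame` with columns `lower` and `upper`.
#' @export
wilson_interval <- function(meth_reads, total_reads, confidence = 0.95) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  if (any(meth_reads < 0) || any(meth_reads > total_reads)) {
    stop("meth_reads must be between 0 and total_reads")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n <- total_reads
  p <- meth_reads / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lower <- pmax(0, (centre - half) / denom)
  upper <- pmin(1, (centre + half) / denom)
  # exact endpoints at the boundary counts (guards float residue)
  lower[meth_reads == 0] <- 0
  upper[meth_reads == n] <- 1
  data.frame(lower = lower, upper = upper)
}

#' Estimate the bisulfite conversion rate from a spike-in
#'
#' Pools converted (T) and total (C+T) read counts over every cytosine of
#' the unmethylated spike-in control and reports
#' \eqn{100 \cdot T / (C+T)} percent.  The complement,
#' `failure_prob`, is the per-read probability of a false-positive C under
#' the null and feeds the binomial test in [call_methylation()].
#'
#' @param spikein_records Count table of the spike-in (see
#'   [read_count_table()]).
#' @return An object of class `conversion_estimate` with fields `t_count`,
#'   `ct_count`, `rate` (percent) and `failure_prob`.
#' @export
estimate_conversion_rate <- function(spikein_records) {
  t_count <- sum(spikein_records$unmeth_reads)
  ct_count <- t_count + sum(spikein_records$meth_reads)
  if (ct_count == 0) stop("spike-in has zero coverage; cannot estimate the conversion null")
  rate <- 100 * t_count / ct_count
  structure(list(t_count = t_count, ct_count = ct_count,
                 rate = rate, failure_prob = 1 - rate / 100),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf("Bisulfite conversion: %.2f%% (%d T of %d C+T reads); failure prob %.3g\n",
              x$rate, x$t_count, x$ct_count, x$failure_prob))
  invisible(x)
}

#' One-sided binomial tail probability of non-conversion
#'
#' \eqn{P(X \ge k \mid n, \epsilon)} where \eqn{k} is the unconverted
#' read count, \eqn{n} the coverage and \eqn{\epsilon} the conversion
#' failure probability.  Exact (no normal approximation).  `meth = 0`
#' returns 1 by construction.
#'
#' @param meth_reads Observed unconverted counts.
#' @param total_reads Coverage.
#' @param failure_prob Conversion failure probability in \[0, 1\].
#' @return Numeric vector of tail probabilities.
#' @export
binomial_nonconversion_pvalue <- function(meth_reads, total_reads,
                                          failure_prob) {
  if (any(failure_prob < 0 | failure_prob > 1)) {
    stop("failure_prob must lie in [0, 1]")
  }
  if (any(meth_reads > total_reads)) stop("meth_reads must not exceed total_reads")
  stats::pbinom(meth_reads - 1, total_reads, failure_prob,
                lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni, via
#' [stats::p.adjust()].
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted values, same length and order as the input.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Call methylated cytosines against the conversion-failure null
#'
#' Every input record receives a call row: methylation ratio, Wilson
#' confidence bounds, the one-sided binomial tail probability under the
#' spike-in null, the multiple-testing-adjusted value (computed over all
#' tested sites, i.e. those meeting the coverage floor), and a
#' significance flag
#' `coverage >= min_coverage & ci_lower >= min_ci_lower & q_adj < alpha`.
#'
#' @param records Count table (see [read_count_table()]).
#' @param conversion A `conversion_estimate` from the matched replicate's
#'   spike-in (or any object with a `failure_prob` field).
#' @param min_coverage Coverage floor for testing (default 4).
#' @param min_ci_lower Wilson lower-bound floor for calling (default 0.05).
#' @param alpha Significance level on the adjusted value (default 0.05).
#' @param method Multiple-testing method, `"BH"` or `"bonferroni"`.
#' @param confidence Wilson confidence level (default 0.95).
#' @return The input `data.frame` with columns `coverage`, `ratio`,
#'   `ci_lower`, `ci_upper`, `p_raw`, `q_adj`, `significant` appended.
#' @export
call_methylation <- function(records, conversion, min_coverage = 4L,
                             min_ci_lower = 0.05, alpha = 0.05,
                             method = c("BH", "bonferroni"),
                             confidence = 0.95) {
  method <- match.arg(method)
  eps <- conversion$failure_prob
  if (is.null(eps)) stop("conversion must carry a failure_prob field")
  out <- records
  cov <- records$meth_reads + records$unmeth_reads
  out$coverage <- cov
  out$ratio <- methylation_ratio(records$meth_reads, records$unmeth_reads)
  out$ci_lower <- out$ci_upper <- NA_real_
  covered <- cov > 0
  if (any(covered)) {
    ci <- wilson_interval(records$meth_reads[covered], cov[covered],
                          confidence)
    out$ci_lower[covered] <- ci$lower
    out$ci_upper[covered] <- ci$upper
  }
  out$p_raw <- NA_real_
  out$p_raw[covered] <- binomial_nonconversion_pvalue(
    records$meth_reads[covered], cov[covered], eps)
  tested <- cov >= min_coverage
  out$q_adj <- NA_real_
  out$q_adj[tested] <- adjust_pvalues(out$p_raw[tested], method)
  out$significant <- tested &
    !is.na(out$ci_lower) & out$ci_lower >= min_ci_lower &
    !is.na(out$q_adj) & out$q_adj < alpha
  out
}

#' Genome-average methylation level
#'
#' \eqn{100 \cdot \sum N_m / \sum (N_m + N_{nm})} pooled over all records
#' (pooled counts, not a mean of per-site ratios).
#'
#' @param records Count table.
#' @param by_chrom If `TRUE`, return a per-chromosome `data.frame` instead
#'   of the pooled scalar.
#' @return Percent methylation (scalar, or per-chromosome `data.frame`).
#' @export
genome_average_methylation <- function(records, by_chrom = FALSE) {
  if (by_chrom) {
    meth <- tapply(records$meth_reads, records$chrom, sum)
    tot <- tapply(records$meth_reads + records$unmeth_reads,
                  records$chrom, sum)
    if (any(tot == 0)) stop("a chromosome has zero total coverage")
    return(data.frame(chrom = names(meth),
                      percent = 100 * as.numeric(meth) / as.numeric(tot),
                      row.names = NULL))
  }
  tot <- sum(records$meth_reads) + sum(records$unmeth_reads)
  if (tot == 0) stop("zero total coverage")
  100 * sum(records$meth_reads) / tot
}

#' Histogram of methylation levels at called sites
#'
#' Counts of significant methylcytosines per ratio bin (default 10\% bins:
#' 0-10, 10-20, ..., 90-100) per sequence context, restricted to a
#' coverage band.
#'
#' @param calls Output of [call_methylation()].
#' @param bin_width Bin width in percent (default 10).
#' @param min_cov,max_cov Coverage band (default 4-1000 reads).
#' @return A `data.frame` with columns `context`, `bin`, `count`.
#' @export
methylation_level_histogram <- function(calls, bin_width = 10,
                                        min_cov = 4L, max_cov = 1000L) {
  keep <- calls$significant & calls$coverage >= min_cov &
    calls$coverage <= max_cov
  sub <- calls[keep, , drop = FALSE]
  breaks <- seq(0, 100, by = bin_width)
  bins <- cut(100 * sub$ratio, breaks = breaks, include.lowest = TRUE)
  contexts <- intersect(.valid_contexts, unique(calls$context))
  tab <- table(factor(sub$context, levels = contexts), bins)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("context", "bin", "count")
  df
}
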