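#' Construct a BSP clone matrix
#'
#' Targeted bisulfite PCR (BSP) sequences individual cloned molecules of a
#' converted amplicon; each clone reports a binary methylation state at
#' every cytosine position.
#'
#' @param states Binary matrix, clones in rows and cytosine positions in
#'   columns (0 = converted, 1 = methylated).
#' @param positions 1-based genomic coordinates of the cytosines, strictly
#'   increasing, one per column.
#' @param condition Condition label, e.g. `"vegetative"` or `"developed"`.
#' @param contexts Optional per-position sequence contexts.
#' @param amplicon Optional list/vector with `chrom`, `start`, `end`,
#'   `strand` of the amplicon.
#' @return An object of class `clone_matrix`.
#' @export
clone_matrix <- function(states, positions, condition,
                         contexts = NULL, amplicon = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) stop("clone states must be 0/1")
  if (length(positions) != ncol(states)) {
    stop("one position per state column required")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (!is.null(amplicon)) {
    if (any(positions < as.integer(amplicon[["start"]])) ||
        any(positions > as.integer(amplicon[["end"]]))) {
      stop("positions must lie within the amplicon")
    }
  }
  structure(list(states = states, positions = as.integer(positions),
                 condition = condition, contexts = contexts,
                 amplicon = amplicon),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("BSP clone matrix: %d clones x %d cytosines (%s)\n",
              nrow(x$states), ncol(x$states), x$condition))
  invisible(x)
}

#' Read BSP clone calls from a long-format TSV
#'
#' Expected columns: `clone`, `condition`, `position`, `state` (0/1).
#' Positions absent for a clone are taken as unmethylated (0): the long
#' format typically lists methylated positions exhaustively but converted
#' ones sparsely.
#'
#' @param path Path to the TSV.
#' @return A named list of [clone_matrix()] objects, one per condition.
#' @export
read_clone_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("clone", "condition", "position", "state")
  if (!all(needed %in% names(df))) {
    stop("clone table requires columns: ", paste(needed, collapse = ", "))
  }
  if (!all(df$state %in% c(0, 1))) stop("state column must be 0/1")
  lapply(split(df, df$condition), function(sub) {
    positions <- sort(unique(sub$position))
    clones <- unique(sub$clone)
    states <- matrix(0L, nrow = length(clones), ncol = length(positions),
                     dimnames = list(clones, positions))
    states[cbind(match(sub$clone, clones),
                 match(sub$position, positions))] <- as.integer(sub$state)
    clone_matrix(states, positions, condition = sub$condition[1])
  })
}

#' Per-site methylation frequency across clones
#'
#' @param matrix A [clone_matrix()].
#' @return A `data.frame` with columns `position`, `meth_clones`,
#'   `total_clones`, `percent`.
#' @export
per_site_frequency <- function(matrix) {
  meth <- colSums(matrix$states)
  total <- nrow(matrix$states)
  if (total < 1) stop("clone matrix has no clones")
  data.frame(position = matrix$positions,
             meth_clones = as.integer(meth),
             total_clones = total,
             percent = 100 * meth / total,
             row.names = NULL)
}

#' Pooled methylation frequency at one position across conditions
#'
#' @param matrices A list of two or more [clone_matrix()] objects that all
#'   cover `position`.
#' @param position The cytosine coordinate to pool.
#' @return Pooled percent methylated clones.
#' @export
combined_frequency <- function(matrices, position) {
  if (length(matrices) < 2) stop("need at least two clone matrices")
  counts <- vapply(matrices, function(m) {
    j <- match(position, m$positions)
    if (is.na(j)) stop("position ", position, " absent from a clone matrix")
    c(sum(m$states[, j]), nrow(m$states))
  }, numeric(2))
  100 * sum(counts[1, ]) / sum(counts[2, ])
}

#' Chi-square goodness-of-fit between conditions at one site
#'
#' Tests whether the observed methylated/converted clone counts in one
#' condition are consistent with the methylation proportion of a reference
#' condition: expected counts are the observed total split by the
#' reference proportion, and \eqn{\chi^2 = \sum (O - E)^2 / E} over the
#' two cells with 1 degree of freedom.  No continuity correction.
#'
#' @param reference `(meth, total)` clone counts of the reference
#'   condition; its proportion must be strictly inside (0, 1).
#' @param observed `(meth, total)` clone counts of the tested condition.
#' @return A list with `statistic`, `df` (1), `p.value`, `expected`.
#' @export
chisq_gof_condition <- function(reference, observed) {
  rm <- reference[1]; rt <- reference[2]
  om <- observed[1]; ot <- observed[2]
  if (rt < 1 || ot < 1) stop("totals must be >= 1")
  pr <- rm / rt
  if (pr <= 0 || pr >= 1) {
    stop("reference proportion must lie strictly in (0, 1): expected cell would be zero")
  }
  expected <- c(meth = ot * pr, unmeth = ot * (1 - pr))
  obs <- c(meth = om, unmeth = ot - om)
  statistic <- sum((obs - expected)^2 / expected)
  list(statistic = statistic, df = 1L,
       p.value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' One-way ANOVA with Tukey HSD across sites
#'
#' Treats each site as a group and its per-dataset methylation ratios as
#' observations, asking whether any site's mean ratio differs; Tukey's
#' honestly-significant-difference test (studentized range) then adjusts
#' all pairwise site comparisons at the stated family level.
#'
#' @param ratios Long `data.frame` with columns `site`, `dataset`,
#'   `ratio`.  `NA` ratios are dropped; sites left with fewer than two
#'   observations are excluded with a warning.
#' @param conf_level Family-wise confidence level for Tukey intervals
#'   (default 0.95).
#' @return A list with `f_statistic`, `p.value`, `tukey` (a `data.frame`
#'   of pairwise comparisons: `pair`, `diff`, `lwr`, `upr`, `p_adj`), and
#'   the fitted `aov` object.
#' @export
anova_tukey_site_comparison <- function(ratios, conf_level = 0.95) {
  df <- ratios[stats::complete.cases(ratios[c("site", "ratio")]), ,
               drop = FALSE]
  n_obs <- table(df$site)
  thin <- names(n_obs)[n_obs < 2]
  if (length(thin) > 0) {
    warning("excluding site(s) with fewer than two observations: ",
            paste(thin, collapse = ", "))
    df <- df[!df$site %in% thin, , drop = FALSE]
  }
  if (length(unique(df$site)) < 2) stop("need at least two sites")
  df$site <- factor(df$site)
  fit <- stats::aov(ratio ~ site, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$site
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(f_statistic = tab[["F value"]][1], p.value = tab[["Pr(>F)"]][1],
       tukey = tukey, fit = fit)
}

#' Lollipop-style plot of a BSP clone matrix
#'
#' One horizontal line per clone, one circle per cytosine, filled when
#' methylated; circle colour encodes sequence context when available.
#'
#' @param x A [clone_matrix()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clone_matrix <- function(x, ...) {
  nc <- nrow(x$states)
  np <- ncol(x$states)
  ctx_col <- c(CG = "red3", CHG = "blue3", CHH = "green4",
               unknown = "grey40")
  cols <- if (is.null(x$contexts)) rep("grey20", np) else ctx_col[x$contexts]
  graphics::plot(range(x$positions), c(0.5, nc + 0.5), type = "n",
                 xlab = "genomic position", ylab = "clone",
                 main = paste("BSP clones,", x$condition), ...)
  for (i in seq_len(nc)) {
    graphics::segments(min(x$positions), i, max(x$positions), i,
                       col = "grey80")
    filled <- x$states[i, ] == 1
    graphics::points(x$positions, rep(i, np), pch = 21,
                     bg = ifelse(filled, cols, "white"), col = cols)
  }
  invisible(x)
}
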