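---
title: "Calling 5-methylcytosine against a conversion-failure null, and screening hairpin artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 5-methylcytosine against a conversion-failure null, and screening hairpin artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpincall)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads an unmethylated cytosine as
T and a 5-methylcytosine (5mC) as C. In genomes where methylation is very
rare — the motivating system is the AT-rich (~77% A+T) social amoeba
genome, where fewer than 0.05% of cytosines ever reach significance — the
signal of interest sits at the same order of magnitude as the chemistry's
failure rate: roughly 0.5% of reads at a truly unmethylated cytosine still
report C because the bisulfite reaction did not convert them. Any calling
procedure must therefore test each cytosine *against that failure rate*,
not against zero, and anything that systematically inhibits conversion
becomes a reproducible false positive.

One such inhibitor is DNA secondary structure. Bisulfite deaminates
cytosine only in single-stranded DNA. A palindromic region (an inverted
repeat: left arm, optional loop, right arm equal to the reverse complement
of the left arm) can re-anneal onto itself after denaturation and fold
into a hairpin. Cytosines in the double-stranded stem are then partially
shielded from conversion, while loop cytosines remain single-stranded and
convert normally. The package implements the full analysis built around
this observation: per-cytosine calling, cross-replicate intersection,
genome-wide palindrome detection with stem/loop classification, targeted
clone-level (BSP) statistics, read-depth knockout verification, and a
simulator that reproduces the statistical structure of such an experiment.

## The calling model

For a cytosine covered by $n = N_m + N_{nm}$ reads with $N_m$ unconverted,
the methylation ratio is $\hat p = N_m / n$, and the genome-wide average is
the pooled $100\,\Sigma N_m / \Sigma(N_m+N_{nm})$ — pooling counts rather
than averaging ratios, so deep sites weigh in proportion to their
evidence.

Conversion failure is estimated from an unmethylated spike-in (lambda
phage in the motivating experiment): the rate is $100\,T/(C{+}T)$ pooled
over every spike-in cytosine, and its complement $\epsilon$ is the
per-read probability of a false C under the null. Pooling across the whole
spike-in, per replicate, is deliberate: per-site rates at 30x depth would
have enormous relative error for an event with probability 0.005.

A site is called methylated when all three of the following hold:

1. **Coverage**: $n \ge 4$ uniquely mapped reads (sites below the floor
   are never tested);
2. **Effect size**: the lower bound of the Wilson 95% score interval for
   $\hat p$ is at least 0.05 — this keeps single-read artifacts at
   moderately covered sites out regardless of p-value, and is the binding
   filter in practice;
3. **Significance**: the one-sided binomial tail
   $P(X \ge N_m \mid n, \epsilon)$, corrected for multiple testing over
   all tested sites (Benjamini–Hochberg at $\alpha = 0.05$ by default),
   falls below $\alpha$.

The test is one-sided by construction: under a conversion-failure null
only an *excess* of unconverted reads is evidence of anything. The tail is
computed exactly (`pbinom`), never by normal approximation — at
$\epsilon = 0.005$ and $n \approx 30$ the normal approximation is useless.
The Wilson interval uses $z = 1.959964$ at the default 95% level, which
reproduces every published bound we use as a check to three decimals
(e.g. 4 of 13 reads $\to$ lower bound 0.127). Ratio $0$ gives
$P = 1$ exactly, and the interval endpoints are exact at the boundary
counts ($0$ of $n$ → lower 0, $n$ of $n$ → upper 1).

Defaults and knobs: `min_coverage = 4` reads, `min_ci_lower = 0.05`
(a proportion), `alpha = 0.05`, `method = "BH"` (or `"bonferroni"`). The
correction method and level behind the original analysis are not
documented; both are exposed, and both are counted over the tested sites
of one replicate, which matches per-replicate calling followed by
intersection.

```{r wilson}
wilson_interval(c(4, 19, 14, 12), c(13, 62, 32, 25))
```

## Robust sites and stringency

A *robust site* is one significant in every replicate methylome, keyed by
exact (chromosome, position, strand) — a site absent from one replicate's
mapping output counts as not significant there, since absence of evidence
cannot support a robust call. `stringency_sweep()` and
`overlap_stringency_table()` enumerate every replicate subset of size
2..k; if hairpin protection rather than biology drives the calls, the
fraction of shared calls inside palindromes rises with stringency, because
stem protection replicates across experiments while sporadic conversion
failures do not.

## Palindrome detection and stem/loop classification

`find_palindromes()` reports maximal exact inverted repeats: arms cannot
be extended outward, and each interval carries its longest-arm (minimal
loop) decomposition. Defaults are a minimum total length of 19 bp,
minimum arm of 8 bp and maximum loop of 10 bp. The total-length floor
comes from the original screen; the arm and loop bounds are this package's
own defaults, chosen because an unlimited loop makes every sequence
trivially "palindromic" and an 8-bp exact stem is roughly the shortest
double helix that is plausibly stable during the conversion reaction. A
genome-wide palindrome count is quite sensitive to all three parameters,
which is why they are exposed rather than fixed. Arms are exact-match
only; mismatch-tolerant arms are rejected with an error rather than
silently approximated. Nested palindromes are removed (`remove_nested()`),
keeping only outermost structures, before any site annotation.

Classification is purely geometric: a site inside either arm is `stem`,
strictly between the arms `loop`, otherwise `outside`; a site covered by
several retained palindromes is assigned to the longest. Thermodynamic
folding is intentionally out of scope — the geometric stem/loop partition
is what the downstream statistics need, and the loop observation (loop
cytosines convert normally) is a geometric claim.

The implementation is a centre-expansion scan in C++; the test suite pins
it, parameter combination by parameter combination, to an independent
interval-major brute-force enumeration in R, and verifies every reported
arm by reverse-complement identity.

## BSP clone statistics

Clone-level bisulfite PCR gives a binary clones x positions matrix per
condition. Per-site frequencies are percent methylated clones; pooling
across conditions pools clone counts. The between-condition test is a
goodness-of-fit chi-square: expected counts are the observed condition's
total split by the *reference* condition's proportion, two cells, 1 df, no
continuity correction. This exact construction — not a 2x2 test of
independence — reproduces both published test statistics we use as checks
(chi-square 0.03 with P = 0.8567, and 0.408 with P = 0.52282).

The cross-dataset comparison treats each site as a group and its
methylation ratios across datasets (WGBS replicates and BSP conditions) as
observations in a one-way ANOVA with Tukey HSD post hoc comparisons. This
follows the tabulated analysis it mirrors, and is knowingly a
simplification: the "observations" are not balanced, independent draws of
equal precision (they are ratios with very different denominators), so the
ANOVA should be read as a descriptive separation of the target site from
its neighbours rather than a calibrated inference.

## Knockout verification

`presence_verdict()` compares the median read depth over a gene interval
with the chromosome-wide median; a gene is absent when the ratio falls
below 0.10. The threshold separates the two regimes observed in practice
(about 0.009 for a deleted gene, 0.86 for an intact one) by an order of
magnitude on each side, and is configurable.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: six chromosomes
(100 kb each at desk scale), 77% A+T, planted palindromes of 19–80 bp
with exact arms, negative-binomial depth with mean 30 and size 10,
conversion failure $\epsilon = 0.005$, zero true methylation, four
replicates, and a separate 48-kb 50%-GC spike-in (lambda-like in size and
composition). Observed counts follow
$\pi = \mu + (1-\mu)\,(\epsilon + (1-\epsilon)\,\rho\,\mathbf{1}[\text{stem}])$
per read: protection acts per molecule, which is the simplest mechanism
compatible with the partial (0.14–0.5) stem ratios seen in practice, as
opposed to all-or-nothing shielding.

Stem protection $\rho$ is drawn once per stem site from $U(0.15, 0.5)$
and shared across replicates, because protection is a property of the
structure, not of the experiment. The range mirrors the observed spread of
stem-site ratios; a scalar `rho` is accepted for calibration experiments
that need one uniform level. This heterogeneity matters: it is what makes
the depth–ratio anticorrelation among called sites (weakly protected sites
only reach significance when deeply covered; shallow calls need high
ratios) reproducible rather than a borderline artifact.

Not emulated: read-level errors, PCR duplicates, mapping bias,
strand-specific conversion differences, overdispersion beyond the
negative-binomial depth model, and real hairpin thermodynamics (planted
palindromes are protected by fiat; found-but-unplanted background
palindromes are not). Passing the simulation suite therefore demonstrates
the statistical machinery — type-I control, intersection logic, stem
purity and recovery, conversion-rate estimation — under the stated
generative model, not the chemistry of any particular experiment.

```{r sim, eval = FALSE}
rec <- end_to_end_recovery(sim_config(seed = 1))
rec$metrics$stem_purity          # fraction of 4-way shared calls at stems
rec$overlap                      # in-palindrome % by stringency
```

## Numerical and scale choices

* Coordinates are 1-based inclusive everywhere internally; BED export
  converts to 0-based half-open. Minus-strand cytosines carry plus-strand
  coordinates, so published positions can be used verbatim as keys.
* Published ratios are matched after rounding half away from zero to the
  printed precision.
* The methratio dialect uses `C_count / CT_count` by default (matching the
  T/(C+T) conversion formula); the effective-CT denominator is available
  via `use_eff_ct = TRUE` since the original accounting is not documented.
* Test problem sizes are chosen for desk-scale determinism: 100 kb
  chromosomes, 50,000-site null panels over ten seeds for type-I control,
  1000 seeded runs for Wilson-coverage of the conversion estimate (the
  interval's exact coverage at that problem size is 94.9%, so a small run
  count would make the 93% acceptance bar a coin flip on Monte Carlo
  noise), and 2-kb sequences for the exhaustive palindrome oracle.
* Degenerate inputs: zero-coverage sites are retained on ingest and
  excluded by the coverage rule; empty call sets intersect to the empty
  set; an empty palindrome set yields 0% overlap at every stringency; a
  zero chromosome median yields an indeterminate knockout verdict with a
  warning.

## Known limitations

* The genome-wide palindrome census depends strongly on `min_arm` and
  `max_loop`, which the original screen does not pin down; reproducing a
  specific published count requires parameter exploration
  (`reference_genome_census()` exposes exactly that).
* The ANOVA treats heteroscedastic ratios as exchangeable observations
  (see above).
* Conversion failure is modelled as homogeneous per replicate; real
  libraries show context- and position-dependent failure that the null
  does not capture.
* The intersection is exact-key only; sites lost to mapping in one
  replicate can never become robust, which is conservative by design.
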