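---
title: "Identifying downstream regulators from a knockdown time course: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying downstream regulators from a knockdown time course: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

## The scientific question

When a master regulator — here modelled on an oncogenic fusion
transcription factor silenced by inducible shRNA — is knocked down, the
genes it represses rise and the genes it activates fall. The rising
("de-repressed") genes are of particular interest because transcriptional
repression by an activating fusion protein is usually indirect: some
intermediate factor, itself suppressed by the regulator, does the work.
`regulonscan` implements the in-silico strategy for finding that
intermediate factor:

1. **Differential expression over a knockdown time course.** Each later
   time point is contrasted against the 0 h baseline with an
   empirical-Bayes moderated t-test and Benjamini–Hochberg correction.
2. **Promoter annotation.** Conserved transcription-factor binding sites
   (TFBS) are counted within strand-aware 1 kb windows upstream of each
   gene's transcription start site (TSS), using UCSC-dialect gene-model
   and TFBS tables.
3. **The binned motif–logFC correlation.** Genes are ordered by log2
   fold change and split into 100 equally sized bins; for each motif, its
   per-bin hit total is Pearson-correlated with the per-bin mean logFC.
   A motif whose binding factor mediates the de-repression shows a large
   positive r; here the forkhead-box (FOX) motifs are the expected hit.
4. **Gene-set overlap.** Threshold-defined gene sets (e.g. "logFC > 1,
   P < 0.05 after knockdown" vs "activated by the candidate factor") are
   compared with exact hypergeometric upper-tail probabilities.
5. **In-vivo growth statistics.** Two-arm tumor growth curves are
   compared with a distribution-free permutation test on a whole-curve
   summary, plus per-day exact rank-sum tests.

Every stage can be exercised on synthetic data with planted ground
truth, so the statistical behaviour of the pipeline (type-I error,
power, recovery of a planted regulon) is testable without any external
download.

## The moderated t-test

For gene $g$ with group sizes $n_A, n_B$, pooled residual variance
$s_g^2$ on $d_g = n_A + n_B - 2$ degrees of freedom, and prior
$(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\bar x_B - \bar x_A}{\tilde s_g \sqrt{1/n_A + 1/n_B}},$$

with two-sided p-values from a t distribution on $d_0 + d_g$ degrees of
freedom. When not supplied, $(d_0, s_0^2)$ are estimated by a moment
method on $\log s_g^2$: under the scaled-F marginal model,
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ has mean
$\log s_0^2 - \psi(d_0/2) + \log(d_0/2)$ and variance
$\psi'(d_g/2) + \psi'(d_0/2)$, so $d_0$ is recovered through the
inverse trigamma and $s_0^2$ from the mean. If the observed variance of
$e_g$ does not exceed $\psi'(d_g/2)$, the prior degrees of freedom are
taken as infinite and all genes share $s_0^2$. The estimator is
injectable for testing: $d_0 = 0$ reproduces the classical
pooled-variance t exactly, $d_0 = \infty$ gives complete shrinkage. The
test suite cross-checks both the hyperparameter fit and the whole
statistic chain against the reference empirical-Bayes implementation in
`limma`.

Whether the published thresholds of the form "P < 0.05" refer to raw or
BH-adjusted p-values is ambiguous in this literature; since methods
sections typically state that *all* p-values were BH-corrected, the
package defaults `p_kind` to `"adjusted"` everywhere a gene-set rule is
built, with `"raw"` one switch away.

## Probe filtering and gene collapse

Microarray pipelines first drop probe sets that are low everywhere and
then keep one "most informative" probe set per gene. The original
detection-call algorithms live in external packages and are not part of
this method, so `filter_low_expression()` implements a transparent
value/fraction rule: keep features with value ≥ `min_value` (default:
the 20th percentile of the pooled value distribution) in at least
`min_fraction` of samples (default 1, i.e. features low in *every*
sample are removed). "Most informative" is likewise undefined in the
source material; `collapse_to_genes()` uses the interquartile range
across samples — a robust spread measure — with ties broken by the
lexicographically smallest feature id so the collapse is deterministic.

## Promoter windows and counting rules

UCSC tables are 0-based half-open, and that convention is preserved
end to end. The TSS of a + strand transcript is `txStart` and of a −
strand transcript `txEnd` (UCSC stores `txStart < txEnd` regardless of
strand), so the 1 kb promoter windows are `[txStart-1000, txStart)` and
`[txEnd, txEnd+1000)` respectively, clipped at coordinate 0 for
chromosome-start genes. Because the analysis is per gene while the
tables are per transcript, windows of transcripts sharing a gene symbol
on the same chromosome are merged into a union of intervals (a
`"first"`-transcript mode exists for comparison).

"Within 1 kb upstream" does not define how a partially overlapping site
is treated. The default membership rule assigns a site to a gene when
its midpoint, `floor((start+end)/2)`, lies in one of the gene's
intervals: each site then counts at most once per gene and the rule is
insensitive to site length. `"contained"` (whole site inside) and
`"any"` (any overlap) are available as `rule =` alternatives. Interval
arithmetic (merging and overlap queries) is delegated to `IRanges`;
the test suite verifies all three rules against a quadratic brute-force
scan.

## The binned correlation statistic

`bin_by_logfc()` sorts genes ascending by logFC (ties broken by gene
label) and cuts them into `n_bins = 100` contiguous bins. When the gene
count is not divisible by the bin count, the remainder genes go one
each to the *lowest*-logFC bins — a documented, deterministic
convention; bin sizes never differ by more than one. Per motif, the
per-bin **sums** of hits are correlated with the per-bin mean logFC;
with equal bin sizes, sums and means give identical Pearson r (asserted
numerically in the tests), so the choice is immaterial. A motif with
identical counts everywhere has an undefined correlation, reported as
`NA` rather than 0 so that "no variation" can never masquerade as "no
enrichment". The headline contrast is 36 h vs 0 h — the time point at
which nuclear translocation of the candidate factor becomes visible —
but correlations are computed and written for every contrast.

The statistic measures association, not marginal abundance: permuting
the gene labels of the count matrix (breaking the gene↔logFC link)
collapses the planted motif's |r| into the background band, and the
test suite asserts this.

## Hypergeometric overlaps

Gene sets are defined by strict inequalities exactly as thresholds are
printed ("logFC > 1" excludes 1). The upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeometric}(N, K, n)$ is computed
term by term in log space via `lchoose` and summed smallest-first from
the tail, so overlaps remain distinguishable down to the smallest
magnitudes double precision can represent (≈1e-300; verified at
$1/\binom{1000}{500} \approx 3.7\times10^{-300}$). The published
analysis never states the universe size $N$; the package defaults to
the genes surviving filtering in the active run and lets the caller
override it. At the published figure of 8154 post-filter features the
three reported overlaps (94/306, 94/208, 58/184 against the 973-gene
knockdown signature) all fall below $10^{-10}$, and the conclusion is
insensitive to any plausible universe between ~8000 and 20000.

## Growth-curve statistics

The permutation statistic is a design choice, since "a distribution-free
permutation test" does not pin one down. The default is
$T = |\mathrm{AUC}(\text{treated}) - \mathrm{AUC}(\text{control})|$
where each arm's curve is the per-day mean of $\log(v+1)$ over the
animals measured that day and the AUC is trapezoidal over days measured
in both arms. Log volumes make the statistic scale-stable
(a common rescaling of all volumes nearly cancels for $v \gg 1$; the
$+1$ guards zero volumes), and a whole-curve AUC uses every day rather
than a single endpoint. `"final"` (last common day) and `"rank"`
(summed per-day standardized rank statistics) are available by flag.
The p-value uses the add-one convention
$p = (1 + \#\{T_{perm} \ge T_{obs}\})/(1 + B)$, so $p \ge 1/(B+1)$ and
the test is never anti-conservative by construction. Missing days
restrict the common-day grid and per-day means are taken over available
animals; nothing is imputed.

Per-day comparisons use a two-sample rank-sum test: the arms are
independent animals, so the two-sample form is the correct one even
where a paired ("signed rank") test is named in passing. For
$n_A + n_B \le 12$ the p-value is exact by full enumeration of label
assignments over the observed (average-rank) tie pattern, without mid-p;
larger samples use the normal approximation with tie correction and a
0.5 continuity correction. The exact branch matches `wilcox.test(...,
exact = TRUE)` to 1e-12 on tie-free data; exact and approximate
branches agree to ≈0.01 at $n_A = n_B = 6$ for tail and moderate
p-values (the worst mid-range discrepancy of the continuity-corrected
approximation is ≈0.014).

## What the synthetic generators emulate — and what they do not

`simulate_timecourse()` reproduces the *design* of an inducible
knockdown course: five time points (0, 18, 36, 53, 72 h), replicated
arrays, a fraction of genes falling (regulator-activated) and a
fraction rising (regulator-repressed) with a configurable effect
trajectory. The published course only names its time grid; since the
knockdown is described as already effective at the first later time
point, the default ramp is the neutral linear interpolation from 0 at
baseline to the full `effect_logfc` (default 1.5 log2 units, a typical
strong knockdown response) at 72 h. Noise is homoscedastic Gaussian on
the log2 scale (`noise_sd = 0.5`, in the range of between-replicate
array variability); real arrays have intensity-dependent variance,
probe effects and correlated batches, so passing tests demonstrate the
statistics behave correctly under the model, not that the model captures
every microarray artifact.

`simulate_promoter_landscape()` plants enrichment at the *count* level:
motif hits per promoter are Poisson with rate `lambda_background = 1`
everywhere except the planted motif in regulon genes
(`lambda_planted = 3`); emitted TFBS records are placed uniformly,
wholly inside the primary promoter window, on one synthetic chromosome
with TSS spacing that keeps neighbouring windows disjoint. Conserved
TFBS rates of about 1 per kb per motif family and a ~3× enrichment in
true target promoters are in the range seen in genome browser tracks.
No sequence is generated and no conservation scoring is emulated; real
promoter landscapes have overlapping genes, clustered sites and GC
structure that the generator deliberately omits. A
`transcripts_per_gene > 1` mode emits TSS-shifted isoforms to exercise
window merging.

`simulate_growth_curves()` grows each tumor exponentially from
`v0_mm3 = 100` (the enrolment threshold of orthotopic xenograft
protocols) at `growth_rate_per_day = 0.15`, multiplies the treated
arm's rate by `treatment_multiplier` (default 0.5, a strong treatment
effect), and applies multiplicative lognormal noise with coefficient of
variation 0.2 — typical for caliper volume measurement. Default arms of
10 animals measured every third day to day 21 mirror the published
two-week treatment window with follow-up.

All generators draw from their own seeded RNG stream, so adding one
generator call never perturbs another's output, and identical configs
give bit-identical results.

## Numerical and degenerate-input choices

- Ties in gene collapse, binning, and motif ranking are always broken
  lexicographically, never by input order, so results are permutation
  invariant (asserted for sample-column permutation of the expression
  matrix).
- All-equal logFC values produce a valid (arbitrary but deterministic)
  contiguous binning.
- A gene group with zero residual variance everywhere falls back to a
  fixed prior with a logged message rather than producing NaN
  statistics; a zero-variance gene with zero logFC gets $t = 0$,
  $p = 1$.
- Empty TFBS files parse to empty record lists; rejected rows
  (inverted spans, unparseable strands) are counted in warnings, never
  silently dropped.
- Windows that would extend below coordinate 0 are clipped, not
  discarded.
- BH adjustment delegates to `stats::p.adjust(method = "BH")` behind a
  validating wrapper; the step-up definition is verified directly in
  the tests.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to make their
statistical assertions sharp while keeping the suite quick to iterate:
2000 genes × 51 motifs × 50 seeds for planted-motif recovery, 10000
null genes for type-I calibration, 200 seeds for permutation-null
uniformity and 50 seeds at 999 permutations for power, and the complete
(N ≤ 60) grid for the hypergeometric oracle. The whole suite runs in
under a minute on one core.

## Known limitations

- The expression model is the final log2 matrix; probe-level
  preprocessing, normalization and batch correction are out of scope
  and assumed done upstream.
- Motif identities are opaque strings; TRANSFAC matrix variants of one
  factor (e.g. `V$FOXO1_01` vs `_02`) are not grouped, matching the
  per-matrix granularity of the upstream tables.
- Per-motif correlations carry no multiple-testing calibration — the
  statistic is a ranking device, as in the original analysis; the
  label-permutation null is available for calibration but is not part
  of the headline pipeline.
- The mixed linear model sometimes fitted to log tumor volumes is an
  off-the-shelf analysis and deliberately not reimplemented here.
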