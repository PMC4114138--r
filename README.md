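# regulonscan

Tools for finding the transcription factor behind a *repressive*
sub-signature of a master regulator. The motivating setting is Ewing
sarcoma, where the EWS-FLI1 fusion oncoprotein acts mostly as a direct
activator: the genes that *rise* when it is knocked down are largely
repressed indirectly, through some intermediate factor that EWS-FLI1
itself suppresses (FOXO1, as it turns out). `regulonscan` implements the
computational side of that hunt for anyone with (i) a knockdown
expression time course, (ii) UCSC-style gene-model and conserved-TFBS
tables, and optionally (iii) two-arm tumor growth curves:

- **Differential expression** of each later time point against 0 h with
  an empirical-Bayes moderated t-test. Per gene,
  `t = logFC / (s̃ √(1/nA + 1/nB))` with posterior variance
  `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, prior `(d₀, s₀²)` estimated from the
  data by a log-variance moment fit, and Benjamini–Hochberg correction.
- **Promoter motif counting** in strand-aware 1 kb upstream windows
  (0-based half-open UCSC coordinates, per-gene window union across
  transcripts, midpoint membership rule).
- **The binned motif–logFC correlation**: genes ordered by logFC, cut
  into 100 equally sized bins, per-bin motif-hit sums Pearson-correlated
  with per-bin mean logFC. Motifs of the mediating factor surface with
  the largest r.
- **Hypergeometric overlap tests** between threshold-defined gene sets,
  exact in log space: `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`.
- **Growth-curve statistics**: a distribution-free permutation test on
  the between-arm AUC difference of mean log-volume curves, and exact
  per-day rank-sum tests.
- **Seeded synthetic-data generators** (knockdown course with planted
  activated/repressed genes, promoter landscape with a Poisson-enriched
  planted regulon, exponential tumor growth with lognormal noise) so the
  whole pipeline is testable against known ground truth.

## Worked example

A fully synthetic run with a planted regulon (seed 42):

```r
library(regulonscan)

sim  <- simulate_timecourse(sim_config(seed = 42, n_genes = 2000))
land <- simulate_promoter_landscape(sim$truth, promoter_sim_config(seed = 43))

ctr <- timecourse_contrasts(sim$expression)        # 18, 36, 53, 72 h vs 0 h
mc  <- correlate_motifs(land$planted_counts, ctr[["36"]], n_bins = 100)
head(rank_motifs(mc), 3)
#>   motif_rank    motif_id pearson_r n_bins_used
#> 1          1  V$FOXO1_01 0.6473803         100
#> 2          2 V$BG0022_01 0.2405050         100
#> 3          3 V$BG0008_01 0.1754391         100
```

The planted motif (`V$FOXO1_01`, Poisson rate 3 in regulon promoters vs
1 elsewhere) tops the ranking with r = 0.65, far above the ~0.2
background band — the synthetic analogue of FOX motifs standing out in
the repressed signature.

Gene sets and overlaps, here against the planted truth at 72 h:

```r
up <- define_gene_set(ctr[["72"]], gene_set_rule("up", 1, 0.05), "up_72h")
truthset <- structure(list(label = "planted_repressed",
                           members = sim$truth$repressed_genes),
                      class = "gene_set")
overlap_analysis(list(up, truthset), universe = ctr[["72"]]$gene)$pairs
#>    set_a             set_b    N   K   n   k expected_k       p_hyper
#> 1 up_72h planted_repressed 2000 127 200 123       12.7 2.060294e-136
```

123 of the 127 genes called up (logFC > 1, adjusted P < 0.05) are truly
planted regulon members, against 12.7 expected by chance. At published
scale the same statistic gives, for a 94-gene overlap between a 306-gene
and a 973-gene set in an 8154-feature universe:

```r
hypergeometric_upper_tail(8154, 973, 306, 94)
#> [1] 2.87258e-19
```

Growth curves with a halved growth rate in the treated arm:

```r
gc <- simulate_growth_curves(growth_sim_config(seed = 44))
curve_permutation_test(gc, n_permutations = 999, seed = 45)$p_value
#> [1] 0.001
```

`run_pipeline(run_config(out_dir = "out", seed = 7))` chains all stages
(simulate → diffexpr → motifcount → correlate → overlap → growth),
writes every intermediate table plus a `report.json`, and is
byte-reproducible for a fixed seed.

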