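# nalcnscreen

Candidate accessory-subunit screening for the NALCN sodium leak channel in
*Drosophila*.

The NALCN channel (encoded by *na*, *narrow abdomen*) leaks Na⁺ at rest and
sets the excitability of rhythmically firing neurons; disrupting it alters
diurnal locomotor patterns and social clustering. Identifying the channel's
accessory subunits is a comparative-genomics and behavioral-genetics
problem, and this package implements the four lines of evidence used to
link a candidate gene (such as the fly homolog of yeast Mid1) to the
channel:

1. **Co-expression screen** — Pearson correlation of `log10(RPKM + 1)`
   profiles across a tissue panel and a developmental series; candidates
   ranked by mean correlation with the reference gene.
2. **Conservation profiling** — per-column scores `1 − H/ln 20` (Shannon
   entropy of residue frequencies, gaps excluded) on majority-gap-stripped
   alignments; cysteine-motif tracking through gapped reference
   coordinates; a permutation test for whether a region (the cysteine-rich
   Mid1 domain) is more conserved than the rest of the protein.
3. **Diurnal activity analysis** — Trikinetics-style monitor files →
   24-h inactivity filter → 30-min rebinning → 48-bin daily profiles →
   mixed two-way repeated-measures ANOVA with per-bin genotype contrasts,
   plus light/dark and anticipation indices.
4. **Social-space analysis** — nearest-neighbor distances per chamber
   snapshot, half-open 5-mm histograms, and the Social Space Index

   SSI = %flies in bin 1 (0–5 mm) − %flies in bin 2 (5–10 mm),

   compared across genotypes by one-way repeated-measures ANOVA with
   Dunnett's many-to-one post-hoc (replicates as blocks).

The repeated-measures ANOVAs, Dunnett's test (Monte-Carlo multivariate-t
adjustment), and the permutation framework are implemented from first
principles and cross-validated in the test suite against `stats::aov`,
`multcomp`, and direct numerical integration.

Synthetic-data generators emulate every input modality — Matérn-style
clustered arenas with a hard core, Poisson activity counts around a
rhythmic rate curve, co-regulated log-normal RPKM profiles, gapped
alignments with planted cysteine motifs — so the whole pipeline runs and is
verifiable with no external data.

## Worked example

Screen a planted 4-gene co-expression module, then detect a simulated
social-clustering deficit:

```r
library(nalcnscreen)

tis <- simulate_expression(expression_sim_config(n_samples = 29, seed = 11),
                           "tissue")
dev <- simulate_expression(expression_sim_config(n_samples = 30, seed = 12),
                           "developmental")
head(rank_candidates(list(pairwise_correlation(tis),
                          pairwise_correlation(dev)), "na"), 5)
#>      gene r_tissue r_developmental mean_r rank
#> 1    mid1    0.864          0.9198  0.892    1
#> 2   unc79    0.854          0.8671  0.860    2
#> 3   unc80    0.805          0.9101  0.858    3
#> 4 gene_14    0.132          0.2492  0.190    4
#> 5 gene_20    0.111          0.0912  0.101    5
```

The three planted partners (`mid1`, `unc79`, `unc80`) rank above all 20
independent genes, with tissue and developmental correlations ≈ 0.9 — the
pattern that marks a candidate as co-regulated with the channel.

```r
# 8 replicate chambers per genotype, 5 captures each; the "kd" genotype
# clusters more weakly (cluster_strength 0.5 vs 2)
ctrl <- vapply(1:8, function(i) mean(vapply(1:5, function(k)
  snapshot_ssi(simulate_arena(arena_sim_config(cluster_strength = 2,
                                               seed = 10 * i + k))),
  numeric(1))), numeric(1))
kd <- vapply(1:8, function(i) mean(vapply(1:5, function(k)
  snapshot_ssi(simulate_arena(arena_sim_config(cluster_strength = 0.5,
                                               seed = 900 + 10 * i + k))),
  numeric(1))), numeric(1))
res <- compare_genotypes(
  data.frame(genotype = rep(c("control", "kd"), each = 8),
             replicate = rep(1:8, 2), ssi = c(ctrl, kd)),
  control = "control")
res$means
#>   genotype  mean  sem n
#> 1  control 25.06 3.20 8
#> 2       kd -7.06 3.74 8
res$dunnett
#> Dunnett many-to-one comparisons vs 'control' (alpha = 0.05)
#>  level   diff    se      t df     p_raw     p_adj significant
#>     kd -32.12 5.385 -5.966  7 0.0005612 0.0005612        TRUE
```

The control chambers aggregate (SSI ≈ +25, i.e. far more flies within 5 mm
of a neighbor than in the 5–10 mm shell), the weakly clustering genotype
sits near the spatial-randomness baseline (SSI slightly negative), and the
difference of −32 SSI points is significant after Dunnett adjustment.

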