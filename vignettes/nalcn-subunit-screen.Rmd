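---
title: "Screening candidate NALCN accessory subunits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate NALCN accessory subunits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nalcnscreen)
```

## The scientific problem

The NALCN sodium leak channel sets the resting excitability of rhythmically
firing neurons, and its loss in *Drosophila* (the *narrow abdomen*, *na*,
gene) disturbs diurnal locomotor patterns and social clustering. The channel
is regulated through accessory proteins, and a long-standing question is
which genes encode them. One candidate family is the animal homologs of the
yeast protein Mid1 — proteins sharing only a cysteine-rich C-terminal region
(the "Mid1 domain", two clusters of five cysteines each) with their fungal
counterparts.

`nalcnscreen` implements the four lines of evidence used to tie such a
candidate to the channel:

1. **Co-expression** — if two genes encode subunits of one complex, their
   expression should co-vary across tissues and developmental stages.
2. **Conservation profiling** — a functionally critical domain should be
   more conserved than the rest of the protein, and its anchor residues
   (the cysteines) should be near-invariant across homologs.
3. **Diurnal locomotor activity** — neuronal knockdown of a true partner
   should phenocopy channel knockdown: reduced morning activity and blunted
   anticipation of the light/dark transitions.
4. **Social space** — knockdown should reduce the Social Space Index (SSI),
   a clustering phenotype robust to general locomotor impairment.

Every stage consumes standard file formats (TSV RPKM tables, aligned FASTA,
Trikinetics-style monitor files, coordinate CSVs), and every stage has a
synthetic-data generator that emulates its input, so the full pipeline can
be exercised and validated without any external download.

## Co-expression screen

Profiles are RPKM values over either a tissue panel (29 samples in the
emulated design) or a developmental series (30 samples). We correlate
`log10(RPKM + offset)` profiles with Pearson's r. The offset (default 1)
handles exact zeros; the log scale is the natural one for RPKM data, whose
dynamic range spans several decades. The 8-level equal-width binning of the
log range (`bin_expression()`) reproduces the display convention of the
public expression browsers; it is available for sensitivity checks
(`use_bins = TRUE` in `pairwise_correlation()`) but correlations default to
the continuous log values — binning discards information and the binned
representation exists for plotting, not inference. Candidates are ranked by
the mean of tissue and developmental r with the reference gene, ties broken
lexicographically so results are reproducible.

Zero-variance (never-expressed) genes cannot carry a correlation
coefficient; they are flagged explicitly rather than silently dropped or
propagated as NaN.

The generator plants a co-regulated module by giving each module gene a
shared latent log10 profile plus independent Gaussian noise, with the latent
scale chosen as `noise_sd * sqrt(rho / (1 - rho))` so the expected pairwise
correlation equals `module_rho` by construction. With `module_rho = 0.9`,
`noise_sd = 0.3` log10 units, a 4-gene module among 20 independent genes is
recovered at the top of the ranking in effectively every run — mirroring the
qualitative claim the screen is meant to support (the candidate ranks with
the known subunits).

## Conservation profiling

Alignments are consumed, not computed (any aligner can produce the input
FASTA). Three steps:

* **Majority-gap stripping.** Columns with gap fraction *strictly* greater
  than 0.5 are removed, a column exactly half gaps is retained. The retained
  -to-original column map is kept so motif coordinates survive filtering.
* **Per-column score** `1 - H / ln 20`, where `H` is the Shannon entropy of
  the residue frequencies with gaps excluded as missing observations (the
  unweighted-frequency estimator familiar from the AL2CO family of tools).
  A fully conserved column scores 1, a uniform column 0; all-gap columns
  are flagged and scored 0. Sequence weighting is deliberately omitted; the
  scorer is a small pure function and weighting can be layered on top.
* **Region test.** Whether a region (e.g. the cysteine-rich domain) is more
  conserved than the rest is tested by permuting column labels:
  statistic = mean(region) − mean(rest), one-sided, with the add-one
  estimator `p = (1 + #{perm ≥ obs}) / (1 + n_perm)` so p is never 0 and
  ties count conservatively.

Motif positions are specified in *ungapped reference coordinates* (1-based)
and mapped through the reference row's gaps; `X` and gaps never count as
the expected residue. The MSA generator plants cysteines at configurable
columns with a per-sequence conservation probability, a per-column consensus
at `background_conservation` elsewhere, and per-cell gaps that never touch
the reference row — enough structure to validate coordinate mapping,
stripping, and the permutation test, though real alignments differ (their
columns are phylogenetically correlated, while the generator draws sequences
independently, so real p-values are anti-conservative in ways a synthetic
test cannot reveal).

## Diurnal activity analysis

Counts arrive on a uniform 5-minute grid (the standard monitor export, with
status-code validation and gap rejection) and pass through:

1. the inactivity filter — any fly with a zero-count 24-h period is
   discarded. Windows are aligned to consecutive days from recording start
   by default; `rolling = TRUE` applies the stricter sliding-window reading.
   The day-aligned default was chosen because monitor data is conventionally
   summarized per calendar day; both readings agree on all-day-silent flies.
2. rebinning to 30-minute bins (sums, exactly conservative);
3. the daily profile — each fly's 48 time-of-day bins averaged over days,
   then mean ± s.e.m. per genotype;
4. per-bin comparisons from a mixed two-way repeated-measures ANOVA
   (between = genotype, within = time bin, subject = fly). Per-bin genotype
   contrasts use the pooled error `(MS_subject + 47 · MS_residual) / 48`
   appropriate for between-group differences at one within level, with
   Satterthwaite degrees of freedom. No multiplicity correction is applied
   across the 48 bins by default, matching the convention of per-bin
   asterisks at P < 0.05; a Bonferroni flag is available.

The anticipation index is defined here as activity in the 3 h preceding a
transition divided by activity in the 6 h preceding it (0.5 for a flat
profile, 1.0 when all activity crowds the transition, 0.75 for a linear
ramp). The window lengths are configurable; the 3 h / 6 h default makes the
index a self-normalized measure insensitive to overall activity level.

The generator's rate curve is baseline plus two circular Gaussian bumps at
the transitions (`peak_width` sd, default 60 min), Poisson counts per bin —
beam crossings are event counts. Knockdown scales the morning bump by
`knockdown_multiplier`. At the study design (16 flies per genotype, 7 days,
multiplier 0.2, peaks 10× baseline) every 30-min bin under the morning bump
is flagged; the effect size was calibrated for test power, since no
quantitative effect sizes are available for the real phenotype.

## Social-space analysis

From each chamber snapshot (40 flies in a 45-mm-radius arena in the default
design): per-fly nearest-neighbor distances; a histogram in half-open 5-mm
bins `[0,5), [5,10), …` — a distance of exactly 5 mm falls in bin 2, a
convention fixed here because "0–5 / 5–10 mm" labels leave the boundary
ambiguous; per-chamber averaging of the 5 capture histograms (averaging the
percentage histograms, not pooling distances — the Methods-style description
supports averaging, and pooling is available by simply concatenating
distances before `distance_histogram()`); then

$$\mathrm{SSI} = \%\,\text{bin}_1 - \%\,\text{bin}_2 .$$

Under complete spatial randomness at this density (λ = 40/(π·45²) flies per
mm²) the closed-form nearest-neighbor CDF `P(D ≤ d) = 1 − exp(−λπd²)` gives
≈ 39% in bin 1 and ≈ 47% in bin 2, i.e. an expected SSI around −8; edge
effects and the hard core push it further down. A positive SSI therefore
indicates genuine aggregation.

Genotype comparison treats the simultaneously-run chamber sets as
repeated-measures blocks (replicate = block), runs the one-way RM ANOVA and
Dunnett's many-to-one comparisons against the control. Coincident
coordinates are legal (image-derived centroids can coincide) and warn.

The arena generator is a Matérn-style cluster process: parent centers in
the inner 70% of the disc, offspring Gaussian with sd `R/(1 + 2s)` for
cluster strength `s` (s = 0 is exactly uniform), followed by hard-core
thinning at 2 mm (≈ one fly body length; the real assay specifies no
exclusion radius, but flies are not points). The mapping from `s` to
dispersion is the package's own axis of aggregation — chosen so mean SSI
rises steeply and monotonically over s ∈ {0, 0.5, 1, 2, 4} — not an
estimate of any biological parameter.

## Statistics: why implemented, not delegated

The repeated-measures ANOVA (one-way and split-plot mixed), Dunnett's test,
and the permutation framework are implemented from their sum-of-squares and
joint-distribution definitions rather than wrapped from a modeling package,
because they are the inferential core of the behavioral stages and their
error strata must be exactly the ones documented here. The test suite
cross-checks them against independent routes: `stats::aov` error strata,
`multcomp::glht` Dunnett p-values, closed-form t-test reductions, and direct
numerical integration of the equicorrelated multivariate-t tail.

Dunnett adjustment is Monte-Carlo: the max-|t| null is simulated from the
shared-control construction (`T_j = (Z_j − Z_0)/√2` over a common χ² scale,
pairwise correlation 1/2 in the balanced design) with a fixed seed, default
100 000 draws (adjusted-p Monte-Carlo error ≈ 0.001–0.002). Adjusted p is
floored at the raw p so the monotonicity guarantee holds exactly despite
Monte-Carlo noise. No sphericity correction is applied by default — the
plain RM-ANOVA is what the field reports for these designs — and unbalanced
designs are rejected rather than silently averaged.

## Numerical and degenerate-input choices

* All-constant response grids report F = 0, p = 1 (not 0/0).
* Permutation and Dunnett p-values are always in (0, 1]; permutation ties
  count as extreme (conservative).
* Zero denominators in the transition indices yield `NA`, not errors.
* Equal-width expression bins include the top edge in the last bin; a
  constant vector bins everything to bin 1 with a warning.
* Every generator takes an explicit integer seed and restores the caller's
  RNG state; identical config ⇒ byte-identical output.

## What the synthetic data does and does not show

The generators reproduce the *statistical skeleton* each analysis assumes:
Poisson counts around a smooth rhythmic curve, a shared latent expression
profile, independent sequences with planted conservation, a cluster process
with a hard core. Passing tests therefore demonstrate that the pipeline's
arithmetic, bookkeeping, calibration (type-I error, familywise error), and
power at designed effect sizes are correct. They do not demonstrate that
real fly data satisfy those assumptions: real activity counts are
overdispersed and autocorrelated, real expression noise is heavier-tailed,
real alignment columns are phylogenetically dependent, and real social
space has behavioral dynamics no static point process captures. Effect
sizes in the simulators were calibrated for test power, not fitted to any
published magnitudes.

## Problem sizes used in validation

The packaged checks run at desk scale: 1000 snapshots for the
nearest-neighbor oracle, 200 arena simulations per cluster-strength level,
2000 null grids per ANOVA calibration, 1000 Dunnett familywise-error
simulations (10⁴ Monte-Carlo draws each), and 100-seed recovery runs for
the motif and co-expression screens. These sizes give Monte-Carlo standard
errors comfortably below the tolerance of each check while keeping the full
validation run in well under a minute of compute per stage.

## A worked run

```{r example, eval = FALSE}
# plant a co-expression module and screen for it
tis <- simulate_expression(expression_sim_config(n_samples = 29, seed = 11),
                           "tissue")
dev <- simulate_expression(expression_sim_config(n_samples = 30, seed = 12),
                           "developmental")
rank_candidates(list(pairwise_correlation(tis),
                     pairwise_correlation(dev)), reference_gene = "na")

# simulate a clustering deficit and test it
ctrl <- vapply(1:8, function(i) mean(vapply(1:5, function(k)
  snapshot_ssi(simulate_arena(arena_sim_config(cluster_strength = 2,
                                               seed = 10 * i + k))),
  numeric(1))), numeric(1))
kd <- vapply(1:8, function(i) mean(vapply(1:5, function(k)
  snapshot_ssi(simulate_arena(arena_sim_config(cluster_strength = 0.5,
                                               seed = 900 + 10 * i + k))),
  numeric(1))), numeric(1))
compare_genotypes(
  data.frame(genotype = rep(c("control", "kd"), each = 8),
             replicate = rep(1:8, 2), ssi = c(ctrl, kd)),
  control = "control")
```

## Known limitations

* Balanced designs only; missing cells are an error by design.
* The conservation scorer has no sequence weighting or window smoothing.
* The activity module offers no periodogram or free-running (DD) analysis.
* The social-space module analyzes static snapshots; no tracking, no
  interaction networks.
* Image processing (fly detection) is out of scope: coordinates in mm are
  the interface, with an optional pixels-per-mm conversion in the reader.
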