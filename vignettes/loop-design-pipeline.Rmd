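---
title: "Mixed-model analysis of two-color loop-design microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model analysis of two-color loop-design microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looparray)
```

## The experimental design

A two-color microarray hybridizes two RNA samples to the same physical
array, one labeled with Cy3 (green) and one with Cy5 (red). Because the two
channels share every spot, within-array comparisons are precise, but dye
chemistry, print blocks and array-to-array variation add systematic
structure that must be removed before groups of samples can be compared. In
a *loop design* the samples are arranged so that arrays pair samples from
*different* treatment groups and each group's samples are split evenly
between the two dyes (a *dye swap*). A 12-plex slide carries 12
independently hybridizable sub-arrays, i.e. 24 sample-channels: large
enough for, say, three groups of eight individuals hybridized once each.

`make_loop_design()` builds this layout canonically: within each group,
samples alternate Cy3/Cy5 (even group sizes split exactly in half, e.g.
4/4 for eight samples or 3/3 for six); the Cy3 and Cy5 channel lists are
then dealt round-robin over groups, with the group order rotated by one for
Cy5, and paired index-by-index onto arrays. The rotation matters: it
guarantees the two channels of an array come from different groups, so
array effects are orthogonal to treatment. We learned this the hard way —
an earlier group-sorted layout placed both channels of each array in the
same group, and the normalization's array effects then silently absorbed
treatment signal, contaminating every other transcript's residuals. An odd
sample total (23 samples on 12 sub-arrays) simply leaves one channel
unused. With each sample hybridized once, the sample–array graph is a set
of disjoint edges rather than a closed cycle, so the `loop_connected` flag
of an `array_design` is reported but never enforced.

## Probe selection from a pilot array

Platforms are built by first testing several candidate probes per
transcript on a pilot array and keeping one. The ranking implemented in
`select_probe()` scores each candidate by its green-channel intensity
divided by the median intensity of all the transcript's candidates
(`compute_ratios()`); the median of an even number of candidates is the
mean of the two central order statistics. The rules by candidate count:
one candidate passes through (with a both-dyes background QC check, default
threshold 300); two candidates keep the brighter; three to six keep the
highest ratio if it is strictly below the cutoff (default 3), otherwise the
second highest; with seven candidates, a highest ratio strictly above the
cutoff marks that probe an outlier — it is removed once, ratios are
recomputed over the remaining six, and the new highest wins. The goal is
the brightest probe that is not an outlier. Ties break to the lowest input
index, a ratio exactly at the cutoff is kept in both regimes (a literal
reading of "<" for acceptance and ">" for removal), and when the top *two*
ratios both exceed the cutoff in the 3–6 case the second-highest is still
selected, with a QC flag, since no further fallback is defined. Choices are
scale-free for the ratio rules: multiplying a transcript's intensities by a
positive constant changes nothing.

## Filtering and transformation

`filter_spots()` applies two rules before the log transform: any channel
value below the array background (default 300 fluorescence units) becomes
missing, and any spot present on fewer than `min_present` (default 20)
sample-channels is dropped entirely. We count presence per channel because
a 12-plex slide's "24 arrays" are its 24 sample-channels; an alternative
reading (arrays on which *both* channels survive) is exposed as
`presence = "arrays"`. Duplicate spots of a transcript are filtered
independently, since the per-transcript model later uses the duplicate
index as a fixed effect. Surviving intensities are log2-transformed
(`log2_transform()`), the scale on which all downstream models operate.
Filtering is idempotent and monotone in the background threshold.

## The two-stage mixed model

Stage one (`fit_normalization()`) fits, jointly over all spots,

$$y = \mu + \text{dye} + \text{block} + A_{\text{array}} +
      A_{\text{array:dye}} + A_{\text{array:block}} + \varepsilon,$$

with dye and print block fixed and the array terms Gaussian random effects,
by REML. The conditional residuals (observed value minus fixed prediction
minus predicted random effects) are the normalized expression values.
Because every term in this model is constant within an
(array, dye, block) cell, the REML likelihood decomposes exactly into a
within-cell residual sum of squares and a generalized least squares problem
on the cell means; the default `"cells"` engine optimizes the three
variance ratios on that collapsed problem (typically under a hundred cells
instead of tens of thousands of spots) and is the exact REML solution — the
`"lmer"` engine fits the identical model with lme4 and agrees to numerical
precision (this equivalence is asserted in the test suite). Noise-free or
single-array inputs degenerate gracefully to ordinary least squares, with
the `method` field recording the fallback.

Stage two (`fit_gene()`) models one transcript's residuals as

$$r = \mu + \text{treatment} + \text{spot} + \text{dye} + A_{\text{array}}
      + \varepsilon,$$

with treatment (group), duplicate-spot index and dye fixed and array
random. The random array term is not decoration: a spot's two channels
share the physical spot, so a transcript's measurements on one array are
correlated even after global normalization. The fit is again exact REML,
profiled on the single variance ratio via an eigendecomposition of the
fixed-effect-projected problem; this makes a gene fit cheap enough (about a
millisecond) that the simulation studies below run tens of thousands of
them. A decomposition cache reuses the eigenstructure across transcripts
that share a missingness pattern.

### Small-sample inference

The overall treatment test is a Wald F. For its denominator degrees of
freedom we implemented both standard approaches and chose by measuring test
size. Satterthwaite df (computed analytically from the observed REML
information; numerically identical to `lmerTest`, which the tests assert)
is mildly liberal in the far left tail at these design sizes — in a
20,000-replicate null simulation of the 3x8 design, P(p < 0.01) was 0.012
and P(p < 0.05) was 0.059 — enough to push the realized false discovery
rate of the whole pipeline above its nominal level. The Kenward-Roger
adjustment, which additionally inflates the fixed-effect covariance for the
uncertainty of the REML variance estimates (including the boundary case
where the array variance is estimated at zero), restores nominal size
(P(p < 0.01) = 0.0084, P(p < 0.05) = 0.048 in the same simulation) and is
the default (`df_method = "kenward-roger"`, checked against `pbkrtest` in
the tests; `"satterthwaite"` remains available). Fixed-effects fits — used
when the random term is dropped, or on request — use classical df and
reproduce the textbook two-way ANOVA F exactly.

Transcripts with fewer than two groups of two or more observations are
skipped with a reason code rather than an error. Group summaries are
adjusted (least-squares) means; all pairwise group contrasts are t-tests
with the same small-sample treatment.

### Multiple testing

`run_de()` chains the two stages over all transcripts and applies
Benjamini–Hochberg adjustment (`bh_adjust()`, a thin validated wrapper over
`stats::p.adjust`) *within each p-value family*: the overall treatment
tests form one family and each pairwise contrast its own. The headline DE
set is the overall-test set at `q < q_threshold`; `de_set =
"union-pairwise"` switches to the union of the pairwise sets, since
published transcript counts can be defined either way. Typical thresholds
are 0.001 for a well-powered experiment and 0.1 for a low-powered one.

## Downstream statistics

* `pca_partition()` — PCA with samples as observations and genes as
  variables, covariance (not correlation) scale since log2 expression is
  already commensurable; each retained component is associated with the
  design factor maximizing the R² of its scores. Reported variance
  percentages are of the total, so a planted two-factor structure with a
  9:1 variance ratio and small noise yields PC1 near 90%.
* `kmeans_clusters()` / `ward_tree()` — k-means (default k = 2, 10
  restarts, explicit seed required) on row-standardized profiles, and
  Ward minimum-variance clustering (`hclust`, `ward.D2`). Fewer distinct
  rows than clusters collapses to a single cluster rather than erroring.
* `venn_counts()` — disjoint region counts for 2–3 sets; regions always
  sum to the union.
* `hypergeom_overlap()` — the overlap of two gene sets against a universe:
  the representation factor RF = observed / (n1·n2/N) and the upper-tail
  hypergeometric p; RF = 1 exactly at independence.
* `enrich_terms()` — per-term upper-tail hypergeometric enrichment of a
  query against an explicit background, with an optional EASE variant
  (one observed hit removed) and BH q-values. The background must be
  supplied deliberately — conclusions change with it; the natural choice
  here is all transcripts that entered the DE analysis.
* `map_to_ancestors()` — single-count collapse of terms into broad
  ancestor ("slim") categories: each input term increments each of its
  ancestors once, duplicates in the input count twice (list semantics),
  and unmapped terms land in an unassigned bucket.
* `proportion_test()` — two counts against an equal split, reporting the
  likelihood-ratio G (headline) and Pearson chi-square. For the published
  counts 404 vs 477 these give 6.056 and 6.049 on 1 df; the figure printed
  alongside those counts in the original study (6.78) matches neither form
  and is not reproducible from the printed inputs, so we report our own
  statistics and do not attempt to match it.
* `qpcr_relative()` / `kruskal_wallis()` — target expression over the
  geometric mean of housekeeping genes, rescaled so the reference group's
  mean is 1, and the ties-corrected Kruskal–Wallis rank test.

## The synthetic-data generator

`generate_experiment()` simulates the exact generative model the pipeline
fits: on the log2 scale, baseline + per-transcript offset + planted group
effects (a `fraction_de` subset of transcripts, effects drawn once per
non-reference group from N(0, `treatment_effect_sd`)) + fixed dye and block
offsets + global array, array-by-dye and array-by-block Gaussian effects +
per-(transcript, array) Gaussian effects + residual noise; intensities are
2 to that power, and missingness is injected completely at random.
Defaults describe the 3x8, 12-plex design with duplicate spots: dye offset
1.0, block offsets (0.25, −0.25, 0.1, −0.1) over four print blocks, SDs
0.5 / 0.3 / 0.2 for the global array terms, 0.1 for the
transcript-by-array term, 0.25 residual, baseline 10 (about 1000
fluorescence units, comfortably above the 300 background), transcript
offsets with SD 0.5. The transcript-by-array component deserves a note: it
is what makes the per-transcript model's random array term meaningful —
without it the true per-gene array variance is exactly zero and every gene
sits at the REML boundary, a regime real data do not occupy because the
two channels of a spot share physical hybridization. Everything is
deterministic given `seed`.

What the generator does *not* emulate: scanner saturation, spatial
gradients within blocks, intensity-dependent dye bias (the classic loess
banana), sequence-dependent probe affinity, or correlated gene modules.
Passing tests therefore demonstrate correctness of the estimation and
testing machinery under the stated model, not robustness to artifacts the
model excludes.

`generate_annotation()` plants one enriched term: genes of the planted term
are over-sampled into a designated significant set at odds
`enrichment_strength` (strength 1 is the null), giving ground truth for the
enrichment statistics.

## Simulation scales and numerical choices

The test suite exercises the pipeline at deliberate scales: 500 transcripts
by 24 channels for variance-component recovery (20 seeds) and for false
discovery rate control (100 replicates with 10% planted effects at SD 1.0,
and 100 under the global null); 20,000 single-gene fits for test size;
exhaustive orderings of 1–7 probes plus 1,000 random transcripts against a
brute-force transcription of the selection rules; every hypergeometric
configuration with a universe up to 60 against direct enumeration. These
sizes give Monte-Carlo errors small enough to detect the failure modes that
matter (a few percent on FDR, a few percent on variance components) while
keeping the whole suite to a few minutes.

Numerical details worth knowing: variance ratios are optimized on the log
scale with the boundary (zero variance) checked explicitly; a boundary
gene's inference degenerates to the classical fixed-effects ANOVA; variance
components are reported on the variance scale and are never negative;
normalization falls back to OLS when no residual variance remains (e.g.
noise-free toy data); BH q-values preserve input order and propagate NAs;
k-means requires an explicit seed so every clustering is reproducible.

## Limitations

The pipeline assumes a common residual variance per transcript across
groups, no intensity-dependence of the dye effect, and annotation given as
flat gene-to-term and term-to-ancestor tables (no ontology graph
traversal). The enrichment background is the caller's responsibility.
Published transcript counts from the original study depend on its deposited
data and annotation database and are not recomputed here; the package
reproduces the *methods*, with ground-truth recovery on synthetic data as
the evidence.
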