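---
title: "Benchmarking minimum sequencing depth for random-forest classification of amplicon tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking minimum sequencing depth for random-forest classification of amplicon tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliDepth)
```

## The problem

Amplicon surveys of microbial communities deliver an ASV-by-sample count
table whose per-sample read totals vary by an order of magnitude. When
such tables feed a supervised classifier — predicting a biotic-index
class, a pollution gradient position, a sample's origin — depth
differences are themselves a confound, so samples are rarefied to a
common depth before training. Rarefaction discards reads, which raises
the design question this package answers empirically: *down to what
per-sample depth does the classifier still perform as well as it does on
the full data?* The answer is task-dependent, and the package's second
job is to diagnose, from the community structure itself, whether a given
task will be depth-frugal or depth-hungry.

## The benchmarking procedure

The unit of analysis is an `AsvExperiment` (a `SummarizedExperiment`
carrying integer counts and one class label per sample). The pipeline is:

1. **Filtering.** ASVs with fewer than `min_total_reads = 50` reads summed
   over all samples are removed (ecologically uninformative noise after
   denoising), then samples with fewer than `min_sample_depth = 15000`
   reads are removed. The 50-read rule is read as a *dataset-total*
   threshold, the common practice for denoised tables; a per-sample
   reading would empty them. The ASV filter runs once, on the full-depth
   table; rarefied tables inherit the retained ASV set so that the
   feature space — and hence the mtry grid — is constant across depth
   levels. The two filters do not commute on contrived inputs (dropping a
   shallow sample can push an ASV below its total threshold); the
   pipeline order is fixed as ASV filter first.
2. **Relative abundance.** Counts become per-sample proportions, the
   standard compensation for residual depth differences.
3. **Depth ladder.** The first level is the shallowest retained sample's
   depth; the fixed tail is 12500, 10000, 7500, 5000, 2500, 1000, 500,
   400, 300, 200, 100, 50. When the shallowest sample is more than twice
   the `cap` (15,000), the first level is pulled back to the cap: a
   dataset sequenced twice as deep as its peers would otherwise start its
   ladder at an incomparable depth. Tail levels at or above the first
   level are dropped, which also lets much shallower (pilot or simulated)
   tables use the same machinery with a shorter ladder.
4. **Rarefaction.** Each level's table is one exact without-replacement
   subsample per sample: a multivariate hypergeometric draw implemented
   as sequential per-ASV conditional `rhyper()` draws (O(ASVs) per
   sample), distributionally identical to drawing the read subset
   uniformly — the test suite checks this equivalence against a
   brute-force subset oracle, and checks the closed-form hypergeometric
   moments. One rarefied table is drawn per level and shared by all grid
   models (`rarefy_per_model = TRUE` re-draws per model for variance
   studies; off by default so level summaries reflect model variance, not
   rarefaction variance).
5. **Model grid.** At the full depth and at every level, 21 random
   forests: mtry = ⌊√p⌋ plus offsets −3…+3 (clipped to [1, p], collisions
   deduplicated with a warning), each with three seeds. `n_trees = 6000`
   by default — the saturating value for full-scale tables. Each model is
   scored by its out-of-bag error (each sample predicted only by trees
   whose bootstrap excluded it) and by Cohen's kappa computed on the OOB
   predictions. Whether the original workflow computed kappa on OOB
   predictions or on an internal resampling is not documented anywhere we
   could check; OOB is the natural companion of the OOB error and is what
   this package does, stated here explicitly.
6. **Banding and decision.** Kappa bands: almost perfect above 0.8, poor
   below 0.6, moderate in the closed interval between (both boundary
   values are moderate, following the strict `> 0.8` and `< 0.6`
   readings). A level's band comes from its **median** grid kappa by
   default; the full model's band is the benchmark. The minimum depth is
   found by walking the ladder from deep to shallow and stopping at the
   first level whose band falls below the benchmark — a shallower level
   that recovers does not count (contiguity), since depth choices must be
   safe, not lucky. The alternative gate `gate = "best"` bands the best
   model per level (max kappa, ties to lower OOB error then lower mtry)
   instead; the median is the default because it is robust to the grid's
   worst configurations, but both are always computed and reported.
   Accuracy (1 − mean OOB error) is reported alongside and never gates:
   "accuracy of the same order of magnitude" is not an operational
   criterion.

## Saturation diagnostics

Rarefaction curves use the exact expectation
`E[S_d] = Σ_a (1 − C(N−n_a, d)/C(N, d))`, evaluated with `lchoose()` so
read totals in the millions cannot overflow; a Monte-Carlo cross-check is
part of the test suite. Richness is estimated with the bias-corrected
Chao1, `S_obs + f1(f1−1)/(2(f2+1))` — defined even with no doubletons,
never below `S_obs`; the test suite cross-checks it against an
independent community-ecology implementation. Two coverage views exist
because they answer different questions: `datasetCoverage()` divides the
pooled observed richness by the pooled table's own Chao1 (how saturated
is *this* table), while `coverageTrajectory()` fixes the full table's
Chao1 as 100% and tracks each rarefied level's observed richness against
it (how much of the attainable richness survives each ladder step). Only
the second is monotone in depth: rarefaction can *raise* own-Chao1
coverage near full depth by deleting pooled singletons faster than
observed species, which is why the trajectory is the reported quantity.
Note that coverage is meaningful on the unfiltered table; after the
50-read ASV filter the pooled table has no singletons and its own-Chao1
coverage is exactly 100%.

## Separability diagnostics

Four diagnostics address why tasks differ in their minimum depth:

- **Class-frequency Gini** `G = Σ_ij |x_i − x_j| / (2 n Σx)` (ordered
  pairs — the standard mean-absolute-difference form, so (1, 99) scores
  0.49) measures label imbalance; it is invariant to class order and to
  scaling all counts. Imbalance turns out not to drive minimum depth, and
  the statistic is provided to let users verify that on their data.
- **Per-feature CV**: the standard deviation of a feature's within-class
  mean relative abundances divided by their grand mean (n−1 denominator;
  features with zero grand mean excluded and counted). Class-specific
  features have high CV; a dataset rich in them classifies well from few
  reads.
- **Shared-feature fractions**: a feature is present in a class when its
  pooled count there reaches `presence_min_count` (default 1). "Fraction
  of sequences common to all classes" is ambiguous between ASVs and
  reads, so both weightings are always computed: `asv` counts features,
  `reads` weights them by total reads. Shared + partial + exclusive sums
  to 1 under either.
- **Ordination ellipse overlap**: Bray–Curtis dissimilarities on relative
  abundances (the community-ecology default; the distance behind the
  original ordinations is not documented), 2-D non-metric MDS via
  `vegan::metaMDS` with seeded random restarts, then one normal-theory
  confidence ellipse per class (2-D mean and covariance, chi-square(2)
  radius at `confidence = 0.95`). Pairwise overlap is the fraction of one
  ellipse's area inside the other, estimated by seeded Monte-Carlo
  sampling of 2,000 points uniform in the ellipse (unit-disk transform
  through the Cholesky factor), averaged over the two directions. A class
  with (near-)singular covariance — collinear samples — gets a small
  diagonal ridge (1e-4 on the covariance scale) and is flagged in the
  result rather than failing.

## The community simulator

`generateDataset()` draws Dirichlet-multinomial communities: a log-normal
expected relative-abundance profile shared by all classes
(`base_abundance_logmean = 0`, `base_abundance_logsd = 1.5`, a realistic
skew for bacterial amplicon tables); each class-specific ASV's expectation
multiplied by `effect_size` in its home class before renormalization; the
per-sample composition drawn from a Dirichlet with concentration
`overdispersion × profile` (smaller = noisier communities); reads a
multinomial draw at a uniform random depth in `depth_range`. `effect_size
= 1` collapses the design to an exchangeable null. The random stream is
keyed by `(seed, sample index)`, so enlarging the last class appends
samples without perturbing existing ones.

The default spec mirrors a realistic monitoring dataset: 3 classes of
25/24/27 samples, 2,800 background + 3×80 specific ASVs (~3,040 features)
and 15,000–40,000 reads per sample. Two pilot-scale presets,
`hardBoundarySpec()` and `softBoundarySpec()`, share 3×12 samples, 270
ASVs, 2,000–4,000 reads and `overdispersion = 200`, differing only in
boundary hardness (effect 10 with 40 specific ASVs per class, versus
effect 3 with 10). The soft preset is deliberately *learnable but
gradual*: its full model sits in the moderate-to-almost-perfect range and
degrades as the ladder descends, which is the regime where a minimum
depth is informative. (A community with no class signal at all is not a
"soft task" — it is the permutation null, which the tests exercise
separately.)

What the simulator does **not** emulate: taxonomic or phylogenetic
structure; the very long tail of sub-50-read ASVs of raw denoised tables
(the default spec models the *retained* table, so simulated Chao1
coverage runs higher than is typical for raw denoised tables); correlations
between ASVs beyond those a Dirichlet induces; depth–class confounding;
batch effects. Passing tests therefore demonstrate the procedure's
correctness and its qualitative behaviour under controlled class
structure, not calibrated performance on any real survey.

## Reproducibility and numerics

Every stochastic stage consumes a sub-seed derived from the master seed
through a fixed integer hash of an index path (stage, level, sample,
model), all below 2^31; stages can be rerun independently and outputs are
pure functions of (inputs, config, seed). `runPipeline()` writes a
manifest with the config, seed, package version and an MD5 checksum per
output; rerunning reproduces byte-identical files. Rarefaction refuses to
sample with replacement (depth above the sample total is an error);
kappa on two identical constant labelings is defined as 1 with a warning;
empty filter results and class-eliminating depth filters are errors, not
silent empties.

## Validation scale

The shipped tests and the acceptance script run the full procedure at
pilot scale — the 36-sample presets, 300 trees per model, ladders of
eight levels, five replicate seeds — sizes at which band decisions on the
presets are stable while a complete run stays in the minutes range on a
single core. The 6,000-tree default remains the recommendation for
full-size tables.

## Limitations

- The minimum depth is relative to the full model's *band*, not its exact
  kappa; a benchmark that sits just above a band edge can make the
  decision sensitive to grid noise. Reporting both gates (median and
  best) makes this visible.
- OOB evaluation shares all samples between model selection and
  assessment; for formal performance claims an external hold-out remains
  preferable.
- Kappa banding is a convention; the 0.6/0.8 edges are inherited from
  standard agreement-interpretation scales, not derived.
- Classification only: regression targets (continuous indices) are out of
  scope, as are feature-importance analysis and alternative classifiers.
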