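---
title: "Compositional methods in codaexplore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional methods in codaexplore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codaexplore)
```

## Why compositions

A sequencing run returns a fixed total number of reads, so the per-feature
counts in a sample tell us only the *proportions* of the underlying
molecules, not their absolute amounts. Any analysis that treats the raw
counts (or depth-rescaled counts) as absolute measurements inherits the
closure artifact: when one feature truly increases, every other feature's
proportion must decrease, so spurious anti-correlations and distances
appear. codaexplore works in the Aitchison geometry of compositions
throughout: counts are closed to proportions, zeros are handled
explicitly, and every downstream statistic operates on centered log-ratio
(CLR) values,

$$\mathrm{clr}(x)_j = \log_2 x_j - \frac{1}{D}\sum_{k=1}^{D}\log_2 x_k ,$$

which sum to zero in each sample and are invariant to rescaling the input.
All logarithms in the package are base 2, matching the fold-change
convention of differential-abundance work; the base is an argument on the
low-level functions, but every documented number assumes 2.

## Zero handling

The CLR is undefined at zero, and zeros in count data are mostly sampling
zeros: too little depth to observe a rare feature. Two strategies are
provided.

- **Count-zero multiplicative replacement** (`impute_zeros_czm()`, the
  default): in a sample of total depth $n$ with $Z$ zero features, each
  zero receives the proportion $\delta = f/(n+1)$ (default fraction
  $f = 0.65$ of the per-read detection limit), and each non-zero count
  $x_j$ becomes $(x_j/n)(1 - Z\delta)$. The multiplicative adjustment
  preserves the ratios among observed features exactly — the property the
  whole log-ratio analysis rests on. The replacement is per sample; no
  cross-sample information is used. Some implementations of this family
  add a post-hoc adjustment when an imputed value exceeds the smallest
  observed proportion; codaexplore deliberately does not, keeping the
  formula above normative and fully testable. If $Z\delta \ge 1$ the
  sample has too many zeros for its depth and the function asks for
  stronger filtering rather than fabricating a composition.
- **Pseudocount** (`impute_zeros_pseudocount()`): add 0.5 to every cell.
  Fast, familiar, slightly ratio-distorting; offered because it is common
  practice for quick looks.

## Filtering

`filter_counts()` applies its rules in a fixed order: metadata selection,
then samples below `min_sample_total`, then features below
`min_feature_total` (computed over the *retained* samples), then features
whose maximum per-sample relative abundance is below
`min_feature_max_prop`. The order is observable — removing a failed sample
changes feature totals — so it is part of the contract: failed samples are
removed first so they cannot drag features below threshold. Thresholds are
"keep if ≥". All defaults are 0: nothing is filtered silently. Every
removal is recorded with its triggering rule and exported with the run.

## Dirichlet Monte-Carlo differential abundance

Counts are modelled per sample as multinomial draws from unknown
proportions. With a Dirichlet prior of 0.5 on every feature, the posterior
is Dirichlet(counts + 0.5); `sample_mc_instances()` draws $K = 128$
posterior proportion vectors per sample (a config key) and CLR-transforms
each. Propagating these instances through every statistic carries the
count-based uncertainty with it: a feature observed at depth 100 has far
wider posterior CLR spread than the same proportion at depth 100 000.

For a two-group design the per-feature estimands, computed on the CLR
values pooled across instances within each group, are

- `diff.btw`: the median of $b - a$ over all ordered between-group pairs;
- `diff.win`: the larger of the two within-group medians of $|u - v|$
  over unordered pairs;
- `effect = diff.btw / diff.win`, a standardized, outlier-robust effect
  size — features with `|effect| ≥ 1` differ between groups by more than
  they vary within groups;
- `overlap`: the smaller of the fractions of between-group differences
  above and below zero, a tail probability of no difference.

These full-enumeration definitions are order-independent and testable
against a brute-force oracle; the default `subsample` mode draws 10 000
random pairs per estimand with an explicit seed and converges to the exact
values (the exact mode is quadratic in the pooled sizes and is used as the
test oracle). Degenerate cases are pinned down rather than left to float:
a 0/0 effect is 0, $x/0$ is signed infinity, and between-group differences
of exactly zero are split evenly between the two overlap fractions, so
constant inputs give `overlap = 0.5`.

Hypothesis testing runs per instance: a two-sided Welch unequal-variance
t-test and a two-sided Wilcoxon rank-sum test across samples for every
feature, Benjamini–Hochberg adjustment *within* each instance across
features, and the arithmetic mean across instances of each quantity — the
expected p and expected BH values (`we.ep`, `we.eBH`, `wi.ep`, `wi.eBH`).
Averaging over posterior instances makes the expected BH deliberately
conservative: a feature must be significant in most plausible realisations
of the data, not in one lucky one. Zero pooled variance in the Welch test
yields p = 1 for equal means and p = 0 otherwise (the limit behaviour,
avoiding NaNs in the averages). The Wilcoxon null distribution is
evaluated exactly for combined group sizes up to 20 without ties
(tie-broken continuous CLR values make ties measure-zero in practice) and
by the tie-corrected normal approximation with continuity correction
beyond that; the threshold is an argument.

Effect plots place `diff.win` on x and `diff.btw` on y, so the
$y = \pm x$ diagonals are the $|\mathrm{effect}| = 1$ contours; MA plots
place median CLR abundance on x. Both class features as `both`,
`effect_only`, `test_significant` or `nonsignificant` from the
`|effect| ≥ 1` and `eBH ≤ 0.05` cutoffs (Wilcoxon by default, switchable
to Welch).

## Ordination, distances, clustering

`pca_clr()` centers each feature across samples and takes the SVD of the
centered samples × features CLR matrix. The default *form* biplot puts the
singular values on the sample scores, so score distances approximate
Aitchison distances between samples; a covariance scaling is available.
Because CLR vectors sum to zero and centering removes one more degree of
freedom, at most $\min(n-1, D-1)$ singular values are non-negligible. Each
singular vector's sign is fixed by making its largest-magnitude loading
positive, so results are identical across linear-algebra backends.

The Aitchison distance is the Euclidean distance between CLR vectors —
`sample_distance_matrix()` exposes it both from zero-handled counts
(`aitchison`) and from an existing CLR matrix (`euclidean_clr`); the two
are identical by construction, and a presence/absence Jaccard distance is
included for robustness checks. Hierarchical clustering offers single,
complete, average and Ward linkage; "ward" means the squared-distance
Ward.D2 update, stated here because two Ward conventions circulate.
Dendrograms export as Newick with merge heights as branch lengths.

## Summaries

With a taxonomy column, `relative_abundance_by_taxon()` splits lineage
strings on `";"` (Greengenes/SILVA style; configurable), aggregates counts
at the requested depth and closes each sample to proportions; groups are
ordered by mean abundance, and an optional minimum-mean-proportion bin
collapses rare groups into "Other" (off by default). With MGnify-style
GO-slim annotation, `goslim_stripchart_data()` emits one record per
(category, GO id, sample) with the within-sample relative abundance,
carrying a metadata colour value when attached.

## The synthetic generator

`synth_spec()`/`generate_counts()` emulate the data the pipeline is built
for. A base composition is drawn once from a log2-normal (mean 0, sd 1 by
default — proportions spanning roughly two orders of magnitude, as in
moderately uneven functional profiles); the group-B target multiplies the
spiked features by `fold_change` in proportion space and re-closes, which
*deliberately* reproduces the closure artifact: unspiked features shift
slightly the other way, though their pairwise ratios are untouched. Each
sample draws proportions from Dirichlet(1000 × target) — total
concentration 1000 gives between-sample CLR noise of a few tenths of a
log2 unit for mid-abundance features, moderate biological variability —
and counts from a multinomial at a depth uniform on 5 000–20 000.
Everything is reproducible from one seed.

What the generator does *not* model: phylogenetic or functional
correlation between features, overdispersion beyond the single Dirichlet
level, batch structure, or structural (true biological) zeros. Passing
recovery and calibration tests on this generator therefore shows the
estimator chain is correct under its stated model, not that real data meet
that model.

The default test scale — 200 features, 10+10 samples, depths
5 000–20 000, K = 128 — is the scale at which the calibration and
recovery properties are asserted: 20 null replicates keep the mean
fraction of features with `wi.eBH ≤ 0.05` at or below 0.05, and ten
replicates with ten 8-fold spikes reach sensitivity and rank agreement
≥ 0.9 at `|effect| ≥ 1`. These sizes run in a couple of minutes on one
CPU, chosen so the whole property suite is routinely re-runnable.

## Reproducibility machinery

A run is a pure function of (inputs, flat YAML config): all seeds — the
Monte-Carlo seed and the pair-subsampling seed — are explicit config keys,
unknown config keys are errors, and every data artifact (TSV, JSON,
Newick) is written deterministically, so double runs are byte-identical.
Each rendered plot (SVG + PNG) sits next to a TSV sidecar of exactly the
plotted records, and `export_reproduction_script()` emits a commented,
parse-checked R script per plot, with every parameter named at the top,
that regenerates that sidecar byte-identically from the raw inputs. The
sidecar-plus-script pair replaces GUI interactivity: anything a hover
tooltip would show is in the sidecar.

## Known limitations

Only two-group, unpaired designs are supported; there is no
repeated-measures or multi-group machinery and no ANOSIM/PERMANOVA-style
global test. The CZM replacement implements the single documented formula,
not the Bayesian-multiplicative variants. Ordination is CLR-PCA only — no
PCoA/NMDS on other dissimilarities. Tables must fit in memory, and the
exact effect mode is quadratic in pooled group size by design (it exists
to be an oracle, not a default).
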