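---
title: "Dimensional Cophenetic Integrity: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensional Cophenetic Integrity: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcims)
```

## The problem

A mass spectrometry imaging (MSI) experiment records a full mass spectrum at
every pixel of a tissue surface, producing a datacube of tens of thousands of
pixels by hundreds to thousands of m/z channels. Non-linear dimensionality
reduction (t-SNE, UMAP) is the standard way to visualise such data and to
prepare it for clustering, but the embedding is only useful insofar as it
preserves the *relationships* between groups of spectra — and the most
commonly used hyperparameters are defaults chosen for very different data.
`dcims` implements an unsupervised score of exactly that preservation,
Dimensional Cophenetic Integrity (DCI), together with the comparator metrics
it should be judged against and an optimizer that uses it as an objective.

## The DCI score

Given a datacube $X \in \mathbb{R}^{n \times c}$ and an embedding
$Y \in \mathbb{R}^{n \times 3}$ (row-aligned), `dci()` computes:

1. **Representative sampling.** k-means with $k = \max(3,\,
   \mathrm{round}(n \cdot f))$, default $f = 0.01$, is run on $Y$; the pixel
   nearest each centroid (Euclidean, ties to the lowest index) is taken.
   Duplicate representatives are merged, so $m \le k$ pixels result. Sampling
   in the *embedding* mirrors how the score is used — each candidate
   embedding is judged on the features it itself resolves — but it also means
   different embeddings of one cube are scored on slightly different
   representative sets; `dci(..., indices = )` pins the sample when strict
   comparability is wanted.
2. **Dual-space hierarchical clustering.** Condensed pairwise distances over
   the $m$ samples: cosine on the spectra (scale-free, the same metric the
   embeddings are built with), Euclidean on the embedding coordinates. Each
   vector is clustered by average linkage (UPGMA), whose merge heights are
   provably non-decreasing; this is asserted on every tree.
3. **Cophenetic distances.** For each pair of samples, the height of the
   lowest merge that unites them — a summary of cluster relationships at
   every granularity rather than raw pointwise distances.
4. **Normalized mutual information.** The two cophenetic vectors are treated
   as categorical data — every distinct merge height is one category, by
   exact floating-point equality — and
   $\mathrm{NMI} = I(A;B) \,/\, \tfrac{1}{2}(H(A) + H(B)) \in [0, 1]$
   is the DCI score.

A score of 1 means the embedding's dendrogram carries exactly the information
of the spectral dendrogram over the sample; 0 means the cluster structure was
destroyed.

### Numerical conventions

* **No binning of cophenetic values.** Merge heights are replicated
  bit-exactly within one dendrogram, so exact-equality labelling is
  well-defined and introduces no bandwidth parameter. A strictly increasing
  transform of either cophenetic vector leaves the partition — and hence the
  score — unchanged (tested).
* **Degenerate embeddings occur in practice**, so the zero-entropy
  conventions are explicit: both vectors constant → 1.0; exactly one constant
  → 0.0 (a collapsed embedding therefore scores 0 against any structured
  cube). If the embedding has fewer distinct rows than $k$ (e.g. fully
  collapsed), k-means cannot run and a seeded uniform pixel sample is used
  instead; the outcome is the same, since the low-space cophenetic vector is
  constant either way.
* **k-means details.** The method fixes only $k = n/100$; this implementation
  uses Hartigan–Wong with 10 random restarts under a recorded seed (base R
  provides no k-means++ initialisation, and with 10 restarts at these k the
  initialisation is not a meaningful source of variance). The seed is part of
  `dci_params` and is stored in every result.
* **Linkage ties** follow the deterministic internal order of the
  agglomeration routine (`stats::hclust`). Ties can alter cophenetic
  partitions in principle, which is why the tie policy is fixed rather than
  left to chance; the brute-force oracle used in the tests traverses the tree
  actually produced, so it is insensitive to the policy.
* **Cosine distance** is clamped at zero against floating-point undershoot,
  and all-zero spectra raise an error that points at ROI filtering (they are
  off-tissue background in practice).

## The synthetic MALDI generator

The generator exists so that every claim about DCI can be tested against data
whose cluster structure is known. It emulates the statistical structure of a
MALDI-MSI section:

* a procedural tissue mask — an ellipse inscribed in the grid, partitioned
  into $k$ contiguous regions by a seeded Voronoi tessellation (a stand-in
  for an anatomical atlas section, which is external data; what the score
  exercises is *k contiguous regions with distinct templates*, not anatomy);
* a species panel with [M+H]\(^+\)/[M+Na]\(^+\)/[M+K]\(^+\) adducts at
  relative abundances (1, 0.5, 0.25) and short geometric isotope envelopes
  (decay 0.4), at random monoisotopic masses in 100–1000 Th — chemically
  schematic on purpose: the evaluation depends on region-distinct templates
  plus shared background, not on isotope fine structure;
* per-region intensity ratio templates (each region's own species drawn
  high, 5–10; all others low, 0.05–0.5) and matrix-background channels
  (CHCA-like) sharing one template row across regions;
* multiplicative intensity noise: each value is its template times
  $\max(0, 1 + \varepsilon)$, $\varepsilon \sim N(0, \mathrm{CV})$. The
  fluctuation is stated as normally distributed without a magnitude; the
  default CV of 0.1 (10%) is a typical technical CV for MALDI intensities
  and was fixed once, before any trend experiments.

Three derived constructions reproduce the harder study conditions:
`homogenize()` ($p_i - s\mu_r + s\mu_w$, blending clusters together — the
formula can produce negative intensities and they are *kept* by default,
since the printed transform has no clipping step; a `clip` flag exists),
`make_disparate()` (bootstrap-duplicating one region's spectra to emulate a
dominant tissue class), and `concatenate_cubes()` (stacking a cube above its
homogenized counterpart so that distinct and subtle structure coexist).

What the generator does **not** emulate: mass resolution and calibration
error, chemical noise and baseline, spatial autocorrelation within regions,
and intensity-dependent (heteroscedastic) noise. Passing tests therefore
demonstrate that DCI behaves correctly when cluster structure is the signal;
they do not certify behaviour under instrument artefacts.

## Embedders

t-SNE (Barnes–Hut, via Rtsne) and UMAP (via uwot) are wrapped with the fixed
configuration used throughout: 3 components, cosine metric, random (t-SNE) or
spectral (UMAP) initialisation, and the two swept hyperparameters —
(perplexity, exaggeration) and n_neighbours respectively. Two details are
this package's own documented choices:

* **"Exaggeration" is the early-exaggeration factor.** Standard t-SNE
  exposes exaggeration only for the early optimisation phase; sweeping it to
  large values (up to 1000) is interpreted as sweeping that factor.
* **Cosine metric by row normalisation.** Rows are L2-normalised and the
  embedding runs on Euclidean Barnes–Hut; on the unit sphere
  $d_E^2 = 2\,d_{\cos}$, so the Gaussian affinity calibration is equivalent
  (perplexity matching absorbs the constant). The `auto` learning-rate rule
  $\max(200, n/\text{exaggeration})$ is applied.

Embeddings are cached to disk keyed by a hash of (spectra, parameters), which
makes grids and optimizations resumable.

## Comparator metrics

Five standard embedding-quality measures are provided for side-by-side
evaluation: co-k-nearest-neighbour accuracy (local structure; k defaults to
10 — the source work does not print its k, so this is a documented choice),
random-triplet accuracy (global structure; 5 seeded triplets per anchor by
default, with an exhaustive enumeration mode used by the oracle tests),
Spearman correlation of condensed pairwise distances, and — for labelled data
only — centroid-distance correlation and the mean-based Dunn index. Tie
conventions are deterministic throughout: neighbour ties break to the lowest
index, tied triplets score 0.5, Spearman uses average ranks. All metrics can
share DCI's sampled subset (`metric_config(subsample=)`) to bound the
$O(n^2)$ distance matrices on large cubes.

## Optimization

`grid_search()` scores every (perplexity, exaggeration) cell, recording
failures per cell instead of aborting. `bayes_optimize()` maximises DCI over
the integer box (defaults 5–10000 × 1–1000, 120 calls, 60 initial points,
seed 42) with a Gaussian-process surrogate written for this package: Matérn
5/2 kernel on inputs scaled to the unit square, lengthscale selected by
marginal likelihood from a small grid, expected-improvement acquisition
maximised over a large random candidate set of unvisited integer points, and
a seeded Latin-hypercube initial design. Objective failures are pinned to
the worst observed value for the surrogate and excluded from the reported
best. The perplexity upper bound is clipped to $\lfloor (n-1)/3 \rfloor$,
the feasibility bound of Barnes–Hut t-SNE.

## Problem sizes used in the tests

The test and acceptance suites run on a "desk-scale" analogue of the study
conditions: an 8-region cube of ~2,000 pixels (52 × 50 ellipse) and 150
channels, t-SNE at 300 iterations with Barnes–Hut $\theta = 0.8$, grids of
{5, 30, 200, 600} × {1, 12, 100} aggregated as the median of 3 seeds, and a
12-call optimizer run. These sizes were chosen so the full suite completes
comfortably on a single core while preserving the qualitative behaviour of
interest (the high-perplexity / low-exaggeration trend, permutation
sensitivity, optimizer improvement); the construction-count checks use the
full-scale 152 × 307 / 30,739-pixel layout, which is cheap because only a
handful of channels are needed. Embedding quality at 300 iterations is
slightly below converged runs, which lowers absolute DCI values but not the
orderings the tests assert. The region-separation check uses a low-noise
(CV 0.05) cube rather than a zero-noise one: exact duplicate rows are a
degenerate input for Barnes–Hut trees.

## Known limitations

* DCI compares *sampled* cophenetic structures; with 1% sampling the score
  stabilises on the tested data, but pathological cubes could concentrate
  structure in rarely sampled pixels.
* Because sampling runs per embedding, scores of different embeddings are
  estimates on different subsets; pin `indices` for strict paired
  comparisons.
* Exact-equality NMI labelling assumes cophenetic values are replicated
  bit-exactly, which holds for trees built in one process but not across
  serialisation formats that round.
* The GP optimizer is a single-objective, noise-free surrogate; it assumes
  the DCI objective is deterministic given seeds (which the wrappers
  guarantee single-threaded).
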