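---
title: "Inferring regulatory module networks from RNA-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory module networks from RNA-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmodnet)
```

## The problem and the model

RNA-Seq profiles a transcriptome across experimental conditions — in the
motivating setting, soybean root-hair cells at successive stages of
nodulation after rhizobium infection, plus assorted tissues. `regmodnet`
turns such a gene × condition matrix into a *regulatory module network*: a
partition of the responsive genes into modules, each annotated with a small
binary decision tree of transcription factors (TFs) predicted to control
the module's expression.

The model rests on the working hypothesis that regulators are themselves
transcriptionally regulated, so a TF's expression profile is a proxy for
its activity. Each candidate TF profile (natural-log scale) is discretized
into three activity states by z-scoring against its own mean and standard
deviation: highly expressed (+1, z at or above `z_hi`), lowly expressed
(−1, z at or below `z_lo`), normal (0) otherwise. A tree's internal node
queries one TF: *is it highly (or lowly) expressed in this condition?* The
yes/no answers route every condition to exactly one leaf, so the leaves
partition the condition set. Within leaf $k$, every expression value of
every member gene is modeled as one Gaussian
$\mathcal N(\mu_k, \sigma_k^2)$, fitted by pooling all module genes'
values in the leaf's conditions ($\mu_k$ the mean, $\sigma_k$ the
population standard deviation). The log likelihood of a candidate split is
the sum of the leaf log densities over both sides; the log likelihood of a
gene under a tree sums its per-condition leaf densities.

Fitting alternates two coordinate-ascent steps until the gene partition
reaches a fixed point:

1. **Tree construction.** For each module, grow a tree greedily: evaluate
   every feasible query (TF × high/low), keep the one maximizing the split
   likelihood if it beats the unsplit leaf by more than `epsilon_gain`,
   and recurse into both sides with the remaining TFs.
2. **Gene reassignment.** Move every gene to the module whose tree gives
   its full profile the highest likelihood; ties go to the lowest module
   index; emptied modules are dropped.

The initial partition comes from K-means on the log expression rows, with
the number of clusters chosen from the correlation-versus-size tradeoff
(below). Candidate regulators are restricted to differentially expressed
TFs; two opt-in modes relax or tighten this — injecting a share of non-DE
TFs (for stability analysis) and restricting candidates to user-listed TF
families (prior biological knowledge).

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `z_hi`, `z_lo` | +1, −1 | z-score cutoffs for the high/low TF states |
| `max_depth` | 3 | maximum queries on a root-to-leaf path |
| `min_leaf_conditions` | 2 | smallest condition subset a leaf may hold |
| `epsilon_gain` | 1e-6 | minimum log-likelihood gain to accept a split |
| `sigma_floor` | 0.01 | lower clamp on leaf sigma, log-units |
| `max_iter` | 50 | cap on tree/reassignment iterations |
| `pseudocount` | 1 | added before the natural log |
| DEG threshold | 0.05 | inclusive adjusted-p cutoff (0.001 when importing DEGseq-style output) |
| enrichment cutoff | 0.01 | raw hypergeometric p flag |
| upstream length | 500 | bp upstream of the coding start scanned for motifs |

The z-cutoffs at one standard deviation make "high" and "low" genuinely
exceptional states while leaving most conditions "normal", matching the
three-level activity coding. The `sigma_floor` prevents infinite likelihood
on degenerate leaves (e.g. a leaf whose pooled values are identical);
`epsilon_gain` rejects splits whose improvement is numerical noise. The
natural log is used throughout: any other base rescales all log likelihoods
by the same constant and cannot change a comparison. A pseudocount of 1 is
added before the log because RNA-Seq count matrices contain zeros; it maps
zero expression to zero log expression.

## Choosing the number of clusters

Raising K increases the mean within-cluster correlation and shrinks the
clusters; the informative K sits where the correlation curve stops gaining
— the knee after the region of most drastic change. We first
operationalized the knee as the maximum discrete curvature (most negative
second difference of the correlation curve), but on data with planted
clusters that rule systematically lands one K early: for a concave rising
curve the second difference peaks mid-rise, not at the plateau onset. The
implemented rule normalizes both axes to [0, 1] and picks the K with
maximum distance *above* the chord joining the curve's endpoints (the
kneedle construction), which recovers the planted cluster number reliably.
The full curve is always returned (and exported as TSV) so the choice can
be overridden by eye, which is how it was originally done.

Degenerate cases are explicit: a candidate range narrower than three values
has no curvature — the lower midpoint is returned with a warning; a flat
correlation curve (no structure) returns the smallest K with a warning.
Pearson correlation with a zero-variance profile is undefined; such pairs
contribute 0 and singleton clusters contribute 1.

## Numerical and structural choices

* **Monotone likelihood.** Greedy tree search is not guaranteed to match
  the previous iteration's tree on a changed gene set. When rebuilding a
  module's tree, the previous tree (leaf parameters refit to the current
  members) is kept if the greedy result cannot match its likelihood, making
  the total-likelihood trace provably non-decreasing and ruling out cycles;
  together with deterministic tie-breaks this guarantees termination.
* **Tie-breaks.** Exact likelihood ties between queries go to the
  lexicographically smallest (TF id, state), with high before low;
  reassignment ties go to the lowest module index. With fixed seeds the
  whole fit is bit-reproducible.
* **Self-regulation.** A TF assigned to a module as a *target* may not
  serve as a regulator in that same module's tree (configurable off):
  letting a gene explain its own cluster is circular.
* **Query vocabulary.** Each TF contributes two candidate queries —
  state = high? and state = low? — mirroring the highly/lowly-expressed
  branches of the tree visualization; a "normal vs rest" query is excluded
  by default.
* **Identifiability.** Two different queries can induce the identical
  condition split, in which case the likelihood cannot distinguish them.
  Structural comparisons of trees therefore default to the nested
  condition-partition signature; query-labeled signatures are available.
* **Null model.** The random-reassignment null redraws the module's gene
  set and *refits* the leaf Gaussians on the fixed tree partition: the null
  asks "how well would random genes be explained by a tree of this shape",
  which requires refitting. Draws default to the DEG universe.
* **Stage discretization.** TF states are computed from the active matrix's
  full condition set by default; `states_from` lets states come from a
  larger matrix when fitting a gene subset.

## The synthetic generator

`generate_planted_network()` emulates the structure the model assumes, at
the scale of the motivating study's common-gene analysis (hundreds of
genes, tens of conditions): TF state/expression profiles drawn jointly so
that discretization recovers the planted states exactly; one planted tree
per module over disjoint TF pairs; leaf means spaced hierarchically (the
root contributes the largest offset) with pairwise separation at least
`leaf_mean_separation` (default 4 log-units); member-gene values drawn from
the leaf Gaussians with `leaf_sigma` (default 0.5, i.e. separation/noise
= 8); TF rows included in the matrix as genes so the self-regulation
exclusion is exercised; decoy TFs that regulate nothing, for injection
experiments. Background genes are *diffuse*: Gaussian at three times the
module noise level around a randomly chosen module's mean profile — the
bulk of weakly co-varying transcripts. A purely unstructured background is
deliberately avoided: under likelihood reassignment such genes all migrate
to whichever module fits worst (its wide leaf sigma makes it a catch-all),
which tells one nothing about recovery; diffuse backgrounds scatter across
modules as weakly correlated transcripts do in real data.

Recovery harnesses fit `K = n_modules + 1`, leaving one cluster for the
structureless TF rows; with `K = n_modules` exactly, two planted modules
merge to make room for them. `generate_counts()` converts the log matrix
into Poisson read counts (rates proportional to exponentiated expression,
columns scaled to the library size) with an optional between-group rate
shift planted in known genes, exercising the DEG-selection path end to end.

What passing these tests shows — and does not. The generator matches the
model's own assumptions: Gaussian leaves, exactly discretizable TF states,
noiseless tree membership. Real RNA-Seq deviates in every respect
(overdispersion, batch structure, TFs regulated post-transcriptionally,
modules sharing genes), so planted-recovery results certify the inference
machinery, not biological accuracy on real data. One empirical caveat the
tests surfaced: with very small leaf noise relative to the mean spacing,
the single best split can be to isolate one tight leaf rather than the
planted balanced root, so greedy recovery of the exact planted topology is
most reliable at moderate noise (the defaults).

## The differential-expression stand-in

The built-in `de_test()` is a replicate-free stand-in, not a reimplementation
of a count-based DE package: it pools each gene's counts per group and runs
a two-sided exact binomial test against the library-size proportion. It is
Poisson-consistent and suffices for the synthetic pipeline; real analyses
should import adjusted p-values from a dedicated tool via
`import_deg_table()`, which the comparison of 0.05-threshold edgeR-style
selections against 0.001-threshold DEGseq-style selections motivated.
Multiple testing uses Benjamini–Hochberg; thresholds compare inclusively.
At extreme sequencing depth the exact test's p-values underflow for any
gene with real condition-to-condition variation, so p-value *ranks* stop
being informative — another reason the stand-in is a stand-in.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use the generator defaults
(5 modules × 30 genes, 30 background genes, 20 regulator/decoy TF rows,
20 conditions): 10 seeds for recovery, 20 datasets for monotone
convergence, 50 random instances for the exhaustive split-search oracle
(at most 3 TFs, 8 conditions, 6 genes — small enough to enumerate every
query), 1000 random-reassignment draws for the null comparison, and 5
seeds × 4 injection fractions for stability. These sizes mirror the scale
of the study design the package targets while keeping every check cheap to
rerun.

## Known limitations

* Greedy tree search is locally optimal; no backtracking or restarts over
  tree space (the reassignment loop provides the only global coupling).
* The leaf model pools all module genes into one Gaussian per leaf; genes
  with systematically offset baselines within a module inflate leaf
  variance (no per-gene intercepts).
* The stand-in DE test ignores biological replication and overdispersion.
* Modules partition genes: a gene cannot belong to two modules.
* Motif evidence is a raw consensus-pattern count; no positional weighting
  or background correction.
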