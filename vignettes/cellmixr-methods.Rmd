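---
title: "Methods: neural cell-type deconvolution with cellmixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural cell-type deconvolution with cellmixr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bulk RNA-seq sample or a spatial-transcriptomics capture spot measures the
mixed RNA of many cells. Deconvolution estimates the proportions of the cell
types that produced the mixture. `cellmixr` implements a complete,
fixture-scale deconvolution stack: a context-free dense neural network
trained on simulated pseudobulk mixtures, a reference-guided transfer
deconvolver built on the network's internal representations, belief
propagation of predictions over a cell-type ontology, and
integrated-gradients attribution for model interpretation.

Everything is verified against synthetic single-cell corpora with planted,
recoverable cell-type structure, so the full pipeline is testable without
any external download.

## The base model

### Per-input normalization

Every vector entering the network passes four steps: depth normalization to
10,000 counts, `log2(1 + x)`, a per-vector z-score (population SD across
genes), and min-max rescaling to [0, 1]. The z-score removes any linear
rescaling, which has two useful consequences: the model is insensitive to
the log base used upstream (natural-log and log2 inputs normalize
identically, asserted to 1e-12 in the tests), and inputs from platforms with
different feature scales land in a common range. A constant vector has an
undefined z-score; it is mapped to the all-zero profile rather than an
error so that empty spots degrade gracefully.

The log transform uses a pseudocount of 1; some pseudocount is required to
handle zeros, and 1 is the field convention.

### Corruption regularization

During training only, inputs are corrupted in two steps: additive zero-mean
Gaussian noise with SD 0.05 on the unit scale applied to every entry, then
independent masking of each entry to zero with probability 0.20. A Gaussian
has no hard range; the SD = 0.05 reading (a value of 0.8 typically lands in
roughly 0.75–0.85, the ±1σ band) is recorded and configurable. Masking is
literal zeroing without the conventional 1/(1−p) survivor rescale; an
`inverted` flag enables the rescaled variant for parity experiments.
Whether noise should touch structurally-zero entries is not fixed by any
published account; here noise applies to all entries.

### Architecture and loss

The network is a stack of fully connected ELU layers with a softmax head,
so each prediction row is automatically on the simplex. The full-scale
configuration (28,867 genes; hidden 8192/4096/2048/1024; 840 outputs) has
281,395,016 dense-stack parameters by the closed form
`sum((fan_in + 1) * fan_out)`; the package treats that closed form as the
structural contract for any configuration. The tiny preset used throughout
testing is 200 genes, 256/128/64/32 hidden, 8 outputs (94,952 parameters).
No regularization is applied to the output layer.

The loss is a masked ("sparse") mean-squared error: for each sample only
the cell types truly present (truth > 0) enter the average. Mixture truth
vectors are mostly structural zeros, and an unmasked MSE would be dominated
by them, biasing training toward predicting zeros everywhere.

### Training schedule

Adam at learning rate 1e-4 with batch size 256, an 80/20 train/validation
split, up to 50 epochs. The learning rate halves when training loss fails
to improve by 1e-4 within 5 epochs; early stopping fires after 4 epochs
without a 1.25e-5 improvement. Early stopping monitors training loss by
default (the plateau rule is explicitly defined on training loss; the
early-stop metric is configurable to validation loss). Validation loss is
evaluated every 5 epochs. Weight initialization is Glorot-uniform under the
configuration seed; with single-threaded BLAS the whole run is
deterministic under one seed.

## Simulated training data

### The synthetic corpus

`make_corpus()` plants one disjoint block of marker genes per cell type:
markers have negative-binomial mean `marker_fold × base_mean` in the owning
type and `base_mean` elsewhere; counts are then rescaled to a per-cell
sequencing depth drawn uniformly, making depth independent of type by
construction. Defaults (8 types, 200 genes, 100 cells/type, 5 markers/type,
fold 8, base mean 4, dispersion 0.5, depth 1,000–5,000) were chosen once as
a realistic, clearly recoverable regime: a rank test on group means must
identify ≥ 90% of planted markers, which gates all downstream
parameter-recovery tests. Disjoint marker blocks make ground truth
unambiguous; a `leakage` parameter (default 0) lets signatures overlap.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, correlated marker programs, or realistic zero-inflation patterns.
Passing recovery tests therefore demonstrates that the machinery is
correct, not that the fixture-scale model matches the published full-scale
accuracy on real tissue.

Spatial fixtures place cells on a jittered grid and assign types from
Dirichlet-sampled compositions of Voronoi niches, emulating spatially
coherent type domains of high-resolution spatial data.

### Pseudobulk mixtures

Each mixture draws a total cell count T uniformly (full scale 1–10,000;
the recovery studies use 1–1,000), a number of distinct types N uniformly
(full scale 1–32, clipped to the catalog), the types themselves uniformly
*without replacement* — which oversamples rare classes relative to their
corpus abundance, deliberately — and fraction ratios from a flat Dirichlet,
the maximum-entropy law on the simplex.

T×F is rounded to integer per-type counts by largest-remainder
apportionment (ties by catalog order) so counts always sum to T. Cells are
sampled without replacement within type; an exhausted pool contributes
every cell it has, once. The recorded ground truth is the *realized*
fraction vector (selected counts / total selected), because the drawn F may
be unattainable and the label must describe the cells actually averaged.
Mixtures average depth-log-normalized profiles; the per-input
z-score/min-max runs later at the model boundary. Averaging in linear space
is available behind a flag.

## Transfer deconvolution

When a labeled reference is available, `run_select()` builds per-type mean
signatures, runs signatures and mixtures through the trained network, and
takes the two middle hidden layers as embedding blocks (widths 128/64 in
the tiny preset). Each block — and the signature-variance-selected gene
block — is reduced by NMF fit on the reference (deterministic NNDSVD
seeding, alternating non-negative least squares) with the mixture projected
onto the fixed dictionary by per-sample NNLS. The component count defaults
to the number of reference states, one factor per state.

Aligned components feed a bagging ensemble of 48 linear nu-SVR models
(ν = 0.5), CIBERSORT-style: for each mixture sample the component vector is
the response across observations (= components) and the per-type reference
components are the predictors, so averaged primal coefficients act as
mixture weights. Negatives are clipped and the row renormalized to the
simplex. The alternative orientation (reference rows as training samples)
is infeasible with one averaged row per state. Degenerate bootstrap draws
(constant response) fall back to a full-observation fit, then to NNLS,
keeping the ensemble size fixed.

### Batch alignment and its identifiability guard

Reference and mixture components are aligned per component as two batches:
standardize, estimate batch means (and optionally variances), adjust both
batches to the pooled location. This is the classical location/scale batch
model with per-feature estimates; empirical-Bayes pooling across features
is deliberately absent so that batch means agree *exactly* after alignment,
which is the package's testable contract. Scale adjustment is opt-in: for
batches with fewer than 3 samples or near-zero spread, variance
equalization amplifies noise instead of removing structure.

Location alignment has a failure mode worth guarding: when every mixture
sample has (near) the same composition — say a field of pure same-state
spots — the mixture batch mean is entirely biological, and shifting it to
the pooled mean moves every sample off its true signature. The two regimes
are cleanly separable in practice: the mixture-batch spread is ~13% of the
pooled spread for pure-spot fields versus ~94% for heterogeneous mixtures
on the standard fixture. Components whose mixture-batch spread falls below
25% of the pooled spread are therefore left unadjusted.

## Belief propagation over a cell-type ontology

Predictions live at mixed levels of a specificity hierarchy ("t cell" vs a
CD4 subset). Each ontology node receives the summed raw mass of itself and
all *distinct* descendants, computed with explicit reachability so a
diamond-shaped DAG counts a shared descendant once; on trees this reduces
to plain subtree sums. Internal nodes carry raw mass 0, catalog names may
map to internal nodes, and propagated values are "at-or-below" masses —
deliberately not a simplex, since ancestors double-count by design. On a
tree whose leaves cover the catalog, any root accumulates exactly 1. The
graph is user-supplied as a child→parent edge list; no ontology is shipped
and OBO parsing is out of scope.

## Integrated gradients

Attributions for a target cell type accumulate input gradients along the
linear path from the zero baseline to the sample, with trapezoidal weights,
scaled by the input itself — so unexpressed genes always receive zero. The
randomized mode additionally masks each gene at step k with probability
1 − α_k (100% → 0% as the interpolation ascends), roughly emulating low
read depth; masks are drawn independently per step and gene under a seed.
The deterministic mode (dropout off) exists to make the completeness axiom
testable: attributions must sum to F(x) − F(0), exactly for linear maps at
any step count, and within 1% relative at 200 steps for the trained tiny
model, with the gap shrinking under step refinement. Gradients are taken on
the inference graph; the training corruption layers are inactive.

## Evaluation

Agreement is scored with Lin's concordance correlation coefficient,
`2·cov(x,y) / (var(x) + var(y) + (mean(x) − mean(y))²)` with population
moments for determinism (the sample-moment variant is flag-gated and
indistinguishable at benchmark n). Unlike Pearson's r it penalizes location
and scale shifts. Degenerate columns: both sides constant with equal means
report 1 (the defined limit) with a flag; one-sided constants report 0 with
a flag.

Sensitivity sweeps hold the baseline (100 cells, 5 types, 0% gene dropout)
and vary one axis. Gene dropout defaults to the model-input stage — masking
the unit-scaled vector entering the network, the same stage where the
training corruption and the attribution dropout operate — with a
pre-normalization `expression` stage available. At fixture scale the
degradation is steeper than the published full-scale behavior in either
stage: with 5 markers per type among 200 mostly-expressed genes, 50%
masking halves the surviving marker evidence, whereas the full-scale model
draws on tens of thousands of partially redundant features. The package
asserts the strict degradation ordering; the "within 0.1 at 50%" analogue
fails at this scale and is documented as such rather than patched.

Spatial downsampling assigns every cell to exactly one square bin by
`floor(coord / bin_size)`, averages member depth-log-normalized profiles
per bin (matching the mixer's convention), and reports member type counts
over the bin total as ground truth. Empty bins are omitted; bin centers are
the spot coordinates.

## Problem sizes and determinism

The standard study conditions, fixed once: the default 8-type corpus; 5,000
training mixtures with T ∈ [1, 1000]; 500 held-out mixtures from the same
law for base-model recovery; 200 mixtures of 100 cells and 2–8 types
against a disjoint-half reference for transfer recovery; 50 replicates per
sweep point (the full-scale recipe uses 500). All randomness fans out from
one seed into named substreams (mixer, corruption, attribution masks, SVR
bagging), so every experiment is reproducible end to end and components can
be re-run in isolation.

## Known limitations

- Fixture-scale training cannot and does not reproduce published full-scale
  accuracy figures; acceptance is by parameter recovery on synthetic data.
- The corpus generator omits batch effects and doublets, so transfer
  alignment is exercised on distribution shifts induced by factorization,
  not by platform chemistry.
- The dropout-robustness analogue holds qualitatively (strict degradation)
  but not quantitatively at fixture scale (see above).
- The H5AD reader/writer covers the minimal layout used here (dense or CSR
  `X`, `obs`/`var` indices, one label column, optional spatial
  coordinates), not the full annotated-data schema.
- Checkpoints store float64 weights and are bit-exact across platforms with
  identical BLAS; training itself is deterministic only single-threaded.
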