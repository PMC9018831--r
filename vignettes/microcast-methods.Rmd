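---
title: "microcast: model, assumptions and design choices"
author: "microcast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{microcast: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Micro-C resolves chromatin contacts at nucleosome scale (200-bp bins), but
is available for only a handful of cell types, while Hi-C (>= 1-kb bins) and
epigenomic tracks (ATAC-seq, CTCF, histone marks) are widely profiled.
`microcast` learns a mapping from (lower-resolution Hi-C, epigenomic
tracks) to a nucleosome-resolution contact map, attributes any predicted
region back to the input features by integrated gradients, calls loops and
stripes at 1 kb on the result, and quantifies agreement with an observed
map through a standard evaluation suite.  A seeded synthetic generator with
planted structures provides a fully controlled test substrate for every
component.

# The model

A chromosome is processed in sliding windows (250 kb wide, 50-kb step at
the full-scale defaults).  Within a window the inputs are:

* `X`, an `m x n` matrix of epigenomic signals (`m` features, `n` 200-bp
  bins; each track is the observed value divided by its genome-wide mean);
* a contact graph whose nodes are the `n` bins and whose weighted edges are
  the input Hi-C map, bilinearly interpolated to 200 bp, O/E-normalized,
  and thresholded (default threshold 0, i.e. all support), with identity
  self-loops;
* a sinusoidal positional encoding (8 rows) appended to the node features;
  it encodes only node order and is independent of any data.

Per-bin hidden representations are the concatenation of

* a 1D convolutional stack along the genome (kernel widths 11 and 5 bins,
  32 then 64 channels) capturing local signal shape, and
* a graph convolutional stack (two layers, 64 units each) computing
  `relu(D^-1/2 A D^-1/2 H W)` over the self-looped adjacency `A`, capturing
  signal at spatially contacting loci.

Two output heads are summed:

* a **contact-profile head**: an affine map from each bin's hidden vector to
  its contact profile over offsets `-w..w` (`w` = band / 200); the resulting
  matrix is symmetrized by averaging the two predictions for each pixel;
* a **loop head**: an affine map to a 64-dimensional embedding per bin; the
  output is `relu(E E^T)`, a non-negative low-rank term capturing focal
  contacts.

The output is exactly symmetric, exactly zero outside the prediction band
(200 kb at full-scale defaults, from the model's stated prediction range),
and additive in the two heads.  Targets and predictions live in `log1p`
count space — the standard variance-stabilizing choice for contact counts;
`expContacts()` maps a predicted map back to count scale.

## Sequential training

Training is MSE under Adam (lr `1e-3`, betas 0.9/0.999), in two phases:

1. **Loop phase** — the loss is restricted to the union of 10 kb x 10 kb
   squares (50 x 50 bins) centered at the training loop calls; the trunk and
   the loop head are updated (the profile head never is).
2. **Profile phase** — the residual map (observed target minus the loop-head
   output of the phase-1 model, computed once and then fixed) is fit by the
   profile head under a band-masked MSE.

The loop-head parameters are never touched in phase 2.  We also freeze the
shared trunk in phase 2 by default: the residual target is defined by the
phase-1 loop output, and fine-tuning the trunk would silently move that
loop output (the inner product is quadratic in the hidden state) — in our
experiments this diverged within a few epochs.  `freezeTrunk = FALSE`
restores trunk fine-tuning for users who want it.

Phase order is enforced (`trainProfileBranch()` refuses to run without a
phase-1 `TrainState`), and parameter snapshots in the test suite prove the
freeze contract.

# Attribution

For a scalar target `y` — the sum of predicted values over a chosen output
region, counted on the upper triangle only — the attribution of signal `s`
at bin `i` is the straight-line path integral of the gradient from the
all-zeros epigenomic background to the real input.  We discretize with a
midpoint Riemann sum (300 steps by default) and report the completeness gap
`|sum(A) - (y(X) - y(0))|` with every result as a self-diagnostic; at the
default step count it is expected within 1% of `|y(X) - y(0)|`.  The
positional-encoding rows and the contact graph are held fixed along the
path: they are not epigenomic inputs and receive no attribution.
Attributions are signed — a feature can peak at an anchor and still
contribute negatively to a particular structure.

# Loop and stripe calling

Calling operates at 1 kb (200-bp maps are pooled 5 x 5: block sums for
counts, full-block means for normalized states).

**Loops.** A pixel is a candidate when its count exceeds 1.75x each of six
local background estimates — a donut (radius 5, excluding a 2-pixel core),
a lower-left quadrant, and four directional single-width rays (left, right,
up, down along the row/column) — and its Poisson upper-tail probability
against the most conservative background passes Benjamini-Hochberg at
FDR 0.1.  Each background is estimated as (local observed / local expected)
x stratum expectation, which corrects for distance decay across the
neighborhood.  Candidates within 2 pixels merge by single linkage; the
cluster's maximal pixel is the call.  The in-line backgrounds are
directional single-width rays rather than pooled 3-wide strips because a
pixel on (or at the end of) a stripe ridge then has at least one background
riding on the ridge itself and is rejected; pooled strips dilute the ridge
with its flanks and systematically admit stripe pixels as spurious loops.
All thresholds (fold 1.75, radius 5, core 2, FDR 0.1, 10 kb-200 kb distance
limits) are exposed as arguments/config keys.

**Stripes.** For each anchor bin the caller scans the O/E values along its
row (vertical stripes, anchor at the smaller coordinate) and column
(horizontal); contiguous runs of >= 10 pixels exceeding twice the per-pixel
median of the +/-3 flanking rows/columns are reported, and overlapping runs
from adjacent anchors merge into the strongest call.

**Matching** between call sets (for Venn counts) is greedy one-to-one on
anchor midpoints within 5 kb (stripes additionally require equal
orientation), ties broken by smallest distance then genomic order, so the
counts are deterministic.

# Evaluation suite

* **SCC** — both maps are smoothed with a (2h+1)^2 uniform kernel (h = 5),
  Pearson r is computed per distance stratum, and the aggregate is the
  variance-weighted mean with weights `N_k sqrt(var_a var_b)`.  The
  implementation works on diagonal strips in O(n x band); an independent
  dense implementation in the test suite agrees to 1e-12.  Smoothing uses
  zero padding with a constant divisor; both maps receive the identical
  treatment so the convention does not bias the comparison.
* **Distance-stratified Pearson** — per-diagonal r on unsmoothed values.
* **Fragment Spearman** — the chromosome is cut into mutually exclusive
  250-kb fragments; each fragment's two O/E maps are smoothed with a 5 x 5
  uniform kernel (renormalized at the map edges so constant maps stay
  constant) and Spearman's rho is computed over band pixels; constant
  fragments carry an undefined flag.  Comparisons between fragment groups
  use a one-sided Welch t test (the unequal-variance form of the one-sided
  t test).
* **A/B compartments** — sign split of the leading eigenvector of the O/E
  matrix after removing its rank-one overall-intensity component (by
  Perron-Frobenius the leading eigenvector of a strictly positive matrix is
  single-signed and carries no plaid information; centering removes it).  A
  config switch uses the correlation matrix instead.  The sign group with
  the higher mean H3K27ac is labeled "A", which makes the labeling invariant
  to the arbitrary eigenvector sign.
* **Replication timing** — early iff the two-stage repli-seq value is
  strictly positive; the boundary value 0 is late (documented, configurable
  through the caller).
* **Conservation tiers** — fragments ranked by phastCons; top 10%,
  top 10-50%, rest (`ceiling` cutoffs so tiers are non-empty for small n).
* **eQTL pairs** — variant and TSS binned at 200 bp; pairs separated by
  >= 180 kb (the 200-kb prediction range minus the 20-kb window margin) or
  reported in more than one tissue are dropped; pile-ups are 101 x 101 by
  default with the central 5 x 5 mean as the score, and regions clipped at
  map edges are dropped rather than zero-padded (padding would bias the
  mean).

Correlation comparisons between an imputed map and a target are made in
`log1p` count space by default (the imputed map's native space; per-stratum
Pearson is scale-invariant, so the choice mainly affects the weighting of
large counts).

# The synthetic generator

`syntheticSpec()` defines a synthetic chromosome with:

* distance decay — expected count `c0 (1+d)^-alpha` (`alpha = 1`,
  `c0 = 100` at distance 0);
* an alternating A/B compartment plaid (260-kb blocks, same-block contacts
  x1.25, cross-block /1.25);
* 20 planted loops: 2D Gaussian foci (sigma 1.5 fine pixels) at 8x the
  local decay, anchor separations 10-18 kb, anchors mutually >= 25 kb apart;
* 10 planted stripes: ridges (sigma 1 pixel across) at 10x the local decay
  extending 15-25 kb from the anchor.  The fine-scale fold is chosen so the
  1-kb fold after 5 x 5 pooling (~35% of the fine fold at the worst anchor
  alignment) lands at ~3-4x, and the extents so the 1-kb run length clears
  the stripe caller's 10-pixel minimum with margin — the planted truth is
  detectable by construction, which is the point of a planted-truth
  benchmark;
* Poisson count noise; the "Micro-C" truth keeps full depth (~4M contacts
  over 1.3 Mb), the Hi-C surrogate is binomially thinned to 1% and pooled
  to 1 kb — emulating the deep-target / shallow-input regime (a 100x depth
  gap, the low end of the downsampling regime studied for real inputs);
* six matched tracks: ATAC-seq and CTCF peak at every anchor, H3K4me1
  flanks anchors (+/-1 kb), H3K4me3 marks loop anchors, H3K27ac marks stripe
  anchors and A blocks, H3K27me3 is elevated over B blocks; gamma
  background noise; all normalized by their genome-wide means.

The track-structure coupling is deliberately strong so that a small model
can learn the epigenome-to-structure mapping: this is a test harness, not a
biological simulator.  Passing the benchmark demonstrates that the
pipeline's machinery (preprocessing, two-phase optimization, stitching,
calling, statistics) is correct and that the model can exploit exactly the
signals the architecture was designed for; it does not demonstrate
biological transferability, realistic noise spectra, TAD hierarchies, or
assay-specific artifacts of real data.

## Desk-scale problem sizes

The bundled benchmark runs on one CPU in a couple of minutes, with sizes
chosen as the package's own benchmark configuration: a 1.3-Mb chromosome
(6,500 fine bins), 50-kb windows with 12.5-kb steps (101 windows, the same
4x diagonal overlap as the full-scale geometry), a 20-kb prediction band,
and the default small model (~80k parameters).  Training runs 40 loop-phase
and 25 profile-phase epochs of per-window Adam steps.  Function defaults
keep the full-scale geometry (250-kb windows, 50-kb steps, 200-kb band);
the desk-scale values are simply what `makeDataset()` uses.

# Numerical choices and degenerate inputs

* Interpolation is bilinear on bin centers (nearest-neighbor available),
  clamped at 0; values at coarse-bin centers are preserved exactly.
* O/E stratum means are computed per chromosome over the map's extent,
  structural zeros included; zero-mean strata stay 0.
* The terminal window of a chromosome is right-aligned at the end so band
  coverage is complete; overlapping window predictions are stitched by the
  arithmetic mean (median available).
* Poisson tails use the continuous-gamma form
  `P(Pois(lambda) >= x) = pgamma(lambda, x)`, which is smooth in `x` and
  therefore applies to non-integer (model-predicted) counts.
* Adam state is re-initialized at each phase boundary; window order is
  reshuffled per epoch under the phase seed, and every stochastic entry
  point takes a mandatory seed, so runs are bit-reproducible.
* Constant matrices are rejected by the compartment caller (degenerate
  eigenproblem); constant fragments are flagged undefined rather than
  given a correlation; empty maps cannot be O/E-normalized.
* Backpropagation uses the subgradient-0 convention at ReLU kinks; all
  gradients are verified against central differences in the test suite.

# Known limitations

* The loop head's low-rank inner product can predict contacts between any
  pair of anchor-like bins within the band; on real data this over-calls
  and would need the Hi-C graph to be informative, exactly as in the
  original design.
* Training is plain per-window SGD in R; it is deliberately small-scale and
  makes no attempt at the multi-cell-type, genome-wide training runs of the
  original work.
* The contact-map container materializes dense per-window matrices;
  chromosome-scale operations are band-limited, so memory scales with
  n x band, not n^2, but very deep bands on full chromosomes are untested.
* Cross-assembly coordinate mapping, ICE/KR balancing and .hic binary I/O
  are out of scope; contact maps are exchanged as cooler-style plain-text
  pixel tables (bins at a stated resolution + upper-triangle counts).
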