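---
title: "Cell-community networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-community networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellgraphs)
```

This vignette is the package's own account of the methods it implements:
the graph constructions, the metric definitions and their conventions, the
null models, the community-effect statistics, and the places where a
design choice had to be made and why it was made that way.

## The model: cells as nodes, proximity or co-activity as edges

A segmented image is a *label mask*: a 2D integer matrix in which 0 is
background and each positive label marks one object. Per-object geometry
(area, centroid as the unweighted mean of 0-based pixel coordinates,
equivalent diameter $2\sqrt{A/\pi}$, boundary pixels, border contact) is
the currency every graph construction consumes.

**Type II (centroid) graphs** connect objects $i,j$ when
$\lVert c_i - c_j\rVert < S\,(d_i + d_j)/2$, with equivalent diameters
$d$ and scaling factor $S$ (default 3, the conventional value for nucleus
images). The comparison is strict (`<`); coincident centroids therefore
always connect. The rule depends only on pairwise distances, so the edge
set is invariant under rigid motion of the layout and monotone
non-decreasing in $S$ — both are tested properties.

**Type I (shared border) graphs** dilate each object's mask by an
`expansion` radius (default 2 px) with a *Euclidean disk* structuring
element — an isotropic choice whose footprint
$\{(dx,dy): dx^2+dy^2 \le r^2\}$ is exactly reproducible — and connect
objects whose dilated supports overlap, with the shared pixel count kept
as the edge weight $S_b$.

*Border cells.* Cells touching the image border have truncated
neighborhoods, which biases their local metrics. The adjacency including
border cells is always constructed and stored; border cells are flagged
(`border_excluded` in the local metric table) so that reports can omit
their own rows while still letting them contribute as neighbors of
interior cells. Global metrics use all cells. This is the only reading we
found that keeps border cells available as neighbors while protecting
per-cell statistics, and it is a package convention rather than a claim
about any upstream implementation.

**Perimeter-distance graphs** threshold a table of minimum
boundary-to-boundary distances (`<=` semantics, so a pair exactly at the
threshold connects). In a label mask two distinct objects always occupy
distinct pixels, so objects in 8-neighbor pixel contact have a raw
minimum pixel distance of 1 or $\sqrt 2$; contact is reported as distance
0. No default threshold is sensible across magnifications, so the
threshold is a required user parameter.

## Calcium traces and functional graphs

Traces are ROI-mean intensities per frame. Normalization runs in a fixed
order:

1. **Linear detrending**, per trace, in closed form about the trace mean
   (subtracting $\hat\beta (t-\bar t)$ keeps the mean, so intensities stay
   on the raw positive scale and a constant trace passes through
   bit-exactly).
2. **Moving baseline** $F_0[t]$: the 8th percentile
   (linear-interpolation definition, pinned so tests are exact) over
   frames $[t-w, t+w]$ with $w = \mathrm{round}(0.01\,T)$, truncated at
   the ends — no padding, to avoid fabricating data.
3. $\Delta F/F = (F - F_0)/F_0$. A non-positive baseline raises an error
   naming the ROI; the caller may offset raw intensities.
4. **Smoothing**: a centered moving average of width 5 frames. The choice
   of smoother is genuinely open; the moving average is the simplest
   deterministic option and both the width and (by setting width 1) the
   smoother itself are user-controllable. Smoothing precedes spike
   detection; the reverse order is also defensible but one had to be
   fixed.
5. **Spike detection**: local maxima ($f_{t-1} < f_t \ge f_{t+1}$, so a
   plateau counts once at its leftmost frame) at least
   $\max(0.25 \max f,\ 0.05)$ high.
6. **Activity filter**: traces with fewer than 3 spikes are dropped
   before any cross-covariance, to control false positives.

**Functional edges** use the lag-0 cross-covariance in its
mean-subtracted, unit-normalized (Pearson) form: normalization makes one
pooled threshold meaningful across ROIs of different brightness. The
threshold is the 99th percentile of a shuffle null in which each trace is
circularly rotated at an independent uniform breakpoint — preserving each
trace's autocorrelation while destroying cross-trace alignment. One
shuffled dataset is the default (`n_shuffles` pools more). A pooled
global threshold, not per-pair thresholds, matches the single-null-dataset
design. Under this null, about 1% of noise pairs exceed the threshold by
construction; the acceptance suite verifies the realized false-positive
rate stays below 3%.

**Ramp classification** characterizes single-transient recordings by
ramp-up (time from 20% of the peak to the peak) and ramp-down (time back
to 20%), frame-quantized without interpolation. The crossing convention
is *at-or-below* on both sides: ramp-up runs from the last frame before
the peak with $f \le 0.2\,f_{peak}$, ramp-down to the first such frame
after it. This convention reproduces the canonical worked cases exactly
(a 10-frame linear rise crossing 0.2 eight frames before its peak gives
ramp-up 8 s at 1 s frames; an instantaneous one-frame spike gives one
frame up and one frame down). Ramp-class edges additionally require
centroid distance at most 10 times the mean of the two cell diameters.

## Metric conventions

All definitions are pinned so that independent brute-force implementations
(Floyd–Warshall distances, exhaustive subgraph enumeration, direct
shortest-path counting) reproduce them to 1e-10; the test suite runs that
comparison over every non-isomorphic graph on up to 6 nodes and 200
random graphs on up to 12.

- **Population variance/SD** everywhere a variance is named: the metrics
  describe the observed graph, not an estimator of a larger one.
- **Efficiency** $E$ is the mean over unordered pairs of reciprocal
  shortest-path length with $1/\infty = 0$; the **diameter** is the
  largest *finite* shortest path (0 for an edgeless graph).
- **Closeness** $c_n$ is harmonic centrality normalized by $n-1$, i.e.
  $\frac{1}{n-1}\sum_{j\ne i} 1/d(i,j)$. The raw-sum variant grows with
  component size; the normalized form stays in $[0,1]$, which is what
  makes fixed bucket boundaries (e.g. 0.025/0.05) meaningful across
  images of different cell counts.
- **Local efficiency** $E_l$ is the standard Latora–Marchiori form: the
  pair efficiency of the subgraph induced by a node's neighbors (0 for
  degree < 2). A looser reading as "average path length in the
  neighborhood" is unbounded and unusable as a clustering feature, so the
  standard bounded form is used.
- **Betweenness** $w_n$ is the raw (unnormalized) count of shortest paths
  through a node with fractional attribution among equally short paths.
- **Star motifs** are non-induced: a node of degree $k$ hosts
  $\binom{k}{s-1}$ $s$-stars; triangles are counted separately as
  $\mathrm{tr}(A^3)/6$.
- **Rich club** $\phi(k) = 2E_{>k}/(N_{>k}(N_{>k}-1))$ over threshold
  degrees $1..n-1$, defined only where at least two nodes exceed the
  threshold; undefined thresholds are omitted from the curve and from its
  mean/variance.
- **Pair nodes** are connected components of exactly two nodes.
- Internally, shortest paths and centralities are computed with igraph
  (always with weights disabled — path lengths are in links); everything
  degree- and motif-based is computed directly from the adjacency matrix.

Community detection/modularity is deliberately out of scope: no specific
algorithm is part of the method, and clustering is accepted as an input
column instead.

## Null models

The **degree-preserving null** applies double-edge swaps (default
$10m$ accepted swaps; proposals creating loops or multi-edges are
rejected, with a retry cap of $100 \times$ the swap target so termination
is guaranteed). Graphs admitting no valid swap (triangles, stars) are
returned unchanged with a warning. The **random spatial null** re-places
$N$ disks with the *common* mean equivalent diameter uniformly at
continuous coordinates in the field (no pixel snapping, matching the
continuous centroid geometry; overlaps permitted — resampling them would
bias density) and re-applies the type II rule. Ensembles default to 100
iterations; iteration $i$ runs under a seed derived deterministically
from (master seed, $i$), so any iteration can be replayed in isolation.

## Community-effect statistics

The **neighborhood similarity score** for cell $i$ with phase $p$ is the
fraction of $i$'s neighbors in phase $p$ divided by the population
fraction of $p$; $N_S$ is the mean over eligible cells. Isolated cells
are excluded (their neighbor fraction is 0/0). The population fraction by
default counts *all* labeled cells, including phases excluded from
scoring (e.g. quiescent cells); `population = "eligible"` gives the
restricted variant, since either reading is defensible. $N_S$ is computed
per frame only; no smoothing across time-lapse frames is applied.

**Quantile multidimensional binning** assigns each cell a tuple of
quantile bins (default 5 per metric, edges at the 20/40/60/80% points,
linear-interpolation quantiles; a value exactly on an edge goes to the
lower bin; tied edges collapse, so a constant metric contributes a single
bin) and subtracts the bin mean of each target feature. Bins with one
member yield corrected value 0 — forced by the subtraction rule — and
within-bin centering can only reduce variance, so
$1 - V_{corr}/V_{uncorr} \ge 0$ always. Requesting fewer than 2 bins is
an input error rather than silently degenerating to global centering.

## Segmentation recipes

The **activity mask** computes the per-pixel max − min range across
frames (order-free, hence invariant to frame permutation), normalizes it,
thresholds by Otsu, re-thresholds by Otsu *within* the initial
foreground (skipped when the foreground is constant, where no refinement
is possible), closes with a disk of radius 3, and removes objects under
10 px. The **nucleus watershed** binarizes by adaptive local-mean
threshold (window 51 px, offset 0), takes the Euclidean distance
transform, and floods from its regional maxima with shallow-extrema
suppression depth $h = 1$ px. The **cell watershed** for
cytoskeleton-stained images equalizes and Gaussian-smooths (sigma 2) the
actin+tubulin composite, binarizes by Otsu, dilates, removes objects
under 1% of the image, derives markers from a high threshold of the
nucleus and tubulin channels (components under 10 px are discarded as
bright-texture specks), and grows marker-seeded regions inside the cell
area over the smoothed intensity landscape. An outer loop adjusts the
marker threshold until the segmented-area to marker-area ratio falls in
the configured band, capped at 20 iterations with the best iterate
returned on non-convergence. The band defaults to [5, 50] — accepted
markers cover roughly 2–20% of the cell area, i.e. they are
nucleus-sized seeds well inside cells. A band near 1 would force markers
to fill the cells and make nucleus-seeded splitting of touching cells
impossible, which is why this package centers the band where
marker-controlled splitting is achievable. None of the three recipes uses
randomness.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and a seed.

- `make_label_image` packs non-overlapping disks with a minimum gap —
  idealized round cells with known centers and diameters.
- `make_calcium_stack` gives cells of a block a shared latent train
  (Poisson events through an instantaneous-rise, exponential-decay kernel
  with $\tau = 2$ s — the simplest kernel that exercises the spike and
  ramp logic; a trapezoid flag generates single-transient traces with
  chosen ramp times instead) plus independent Gaussian noise at a chosen
  signal-to-noise ratio; pixel values are constant within a ROI.
- `make_phase_labels` interpolates between i.i.d. phases ($p=0$) and
  component-constant phases ($p=1$) by a per-node copy-from-neighbor
  step.
- `make_feature_table` draws the 7 local-metric columns from a Gaussian
  copula with exchangeable correlation 0.99 — a single latent crowding
  factor with small metric-specific variation, reflecting that local
  network metrics in real images all track local cell density. The
  strength matters: with 5 bins over 7 metrics the bin space has $5^7$
  cells, and only strong inter-metric dependence keeps the number of
  *occupied* bins far below the cell count (about 400 at $n = 10{,}000$
  here), which is what makes the planted variance fraction $a/(a+b)$
  recoverable — with weakly dependent metrics most cells would sit alone
  in their bin and bin-mean subtraction would absorb noise variance
  wholesale. The planted morphology column is an exact function of the
  bin tuple scaled to variance $a$, plus noise of variance $b$.

What passing tests on these fixtures shows is that the *algorithms*
implement their definitions and recover planted structure under the
stated conditions. What they do not show: robustness to irregular cell
shapes, uneven illumination, motion, neuropil contamination, or
segmentation error — the generators model none of these, and the package
deliberately excludes motion correction and deconvolution.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are informative yet complete in minutes: metric-oracle
comparison over all 207 non-isomorphic graphs on up to 6 nodes plus 200
random graphs on up to 12; functional false-positive and planted-block
checks with 20–30 ROIs, 600 frames, 20 seeds; permutation nulls with 200
shuffles on a 100-node fixture; binning recovery at $n = 10{,}000$ cells;
null ensembles of 100 iterations. Quantiles are type-7
(linear-interpolation) throughout; label masks are written as 16-bit
TIFF (lossless for labels up to 65535); integer image stacks round-trip
bit-exactly, float stacks are stored normalized as 32-bit.

## Known limitations

- Graph metrics are unweighted; weighted generalizations (e.g. using
  $S_b$ or covariance weights in paths) are not provided.
- Functional connectivity is lag-0 and undirected; no lagged, directed or
  causal inference.
- The cell watershed's area-ratio loop is a heuristic; heavily textured
  markers can fail to converge, in which case the best iterate is
  returned with a warning.
- 3D segmentation is out of scope; volumetric data should be reduced to
  maximum-intensity projections first.
- Multi-channel correction of undersegmented nuclei is not implemented;
  supply corrected masks if channel fusion is needed.
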