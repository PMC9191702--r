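# cellgraphs

Quantitative analysis of cell communities in microscopy images. The
package turns a segmented image (a label mask) or a calcium image sequence
into a graph over cells, and then asks structural questions of that graph:
how heterogeneous is the community, how efficiently could information flow
through it, do functionally similar cells sit next to each other, and how
much of a cell's morphology is explained by its local neighborhood rather
than by an experimental treatment.

It is written for quantitative cell biologists working with cultured or in
vivo imaging data — neural progenitor cultures, endothelial monolayers,
sensory tissue recordings — who want network-level statistics with
explicit, reproducible definitions and matching null models.

## What it computes

**Graphs over cells.** Three spatial constructions and two functional ones:

- *Type I* (shared border): each object's mask is dilated by a small radius
  (default 2 px, Euclidean disk); an edge joins objects whose dilated
  supports overlap, weighted by the shared pixel count S_b.
- *Type II* (centroid distance): an edge joins objects whose centroid
  distance is below S · (d_i + d_j)/2, where d is the equivalent diameter
  2·sqrt(area/pi) and S is a scaling factor (default 3).
- *Perimeter distance*: edges from a table of minimum boundary-to-boundary
  distances under a user threshold.
- *Functional*: traces are normalized to dF/F = (F − F0)/F0 against a
  moving 8th-percentile baseline, low-activity ROIs (< 3 spikes) are
  dropped, and an edge joins ROIs whose lag-0 cross-covariance (Pearson
  form) exceeds the 99th percentile of a circular-shuffle null.
- *Ramp class*: for single-transient recordings, cells are classified by
  ramp-up/ramp-down times (time from 20% of peak to peak and back); edges
  join same-class cells within 10 cell diameters.

**Metrics.** A global record per graph (degree mean/variance, network
heterogeneity = SD(k)/mean(k), efficiency E = mean reciprocal shortest
path, clustering C, component structure, diameter, motif counts including
triangles and k-stars, rich-club average/variance, degree assortativity)
and a per-cell table (degree, mean neighbor degree, local clustering,
local efficiency, harmonic closeness, betweenness, shared border). All
variances are population variances; disconnected pairs contribute 0 to
efficiency.

**Null models.** Degree-preserving double-edge-swap rewiring, and random
spatial graphs that re-place equal-diameter disks uniformly in the field
and re-apply the type II rule; both as seeded 100-iteration ensembles.

**Community statistics.** The neighborhood similarity score N_S (mean over
cells of the fraction of same-phase neighbors divided by that phase's
population fraction; ≈ 1 under random mixing), quantile multidimensional
binning correction (5 bins per local network metric; bin means subtracted
from morphology features), variance explained 1 − V_corr/V_uncorr, and
Cohen's d.

**Segmentation.** Three recipes: activity masks from calcium stacks
(max − min delta image, two-pass Otsu, closing, size filter), nucleus
watershed (adaptive threshold, distance transform, h-suppressed seeds),
and marker-controlled watershed for cytoskeleton-stained cells.

## Worked example

```r
library(cellgraphs)

# a synthetic culture: 30 disk-shaped cells in a 300 x 300 px field
li      <- make_label_image(30, c(300, 300), radius_range = c(5, 8), seed = 11)
regions <- extract_regions(li$mask)
g       <- build_type2_graph(regions, scaling_factor = 3)
g
#> <cell_graph:spatial_type2> 30 nodes, 21 edges

round(global_metrics(g, li$mask)[, c("n","m","A","avgeK","NetworkHeterogeneity","E","C")], 3)
#>    n  m     A avgeK NetworkHeterogeneity    E     C
#> 1 30 21 0.041   1.4                 1.02 0.07 0.194

# is the observed clustering more than its degree sequence implies?
null <- null_distribution(g, "degree_preserving", n_iterations = 100, seed = 1)
subset(null$summary, metric == "C")
#>      mean     sd
#> 10 0.0271 0.0269

# do same-phase cells sit together?
neighborhood_similarity(g, make_phase_labels(g, p = 1, seed = 2))$N_S  # 1.954
neighborhood_similarity(g, make_phase_labels(g, p = 0, seed = 3))$N_S  # 0.935
```

Reading the numbers: 4.1% of the field is covered by cells; the graph has
mean degree 1.4 with heterogeneity 1.02 (hub-prone), efficiency 0.07
(fragmented), and clustering 0.194 — roughly seven times the mean
clustering of its degree-preserving null (0.0271 ± 0.0269), i.e. the
spatial layout carries real triangle structure. With phases constant per
connected component the neighborhood similarity score is 1.95 (phase
clustering); with random phases it sits near 1.

A command-line front end is installed with the package
(`exec/cellgraphs`), with subcommands `run`, `spatial`, `functional`,
`metrics`, `null`, `community`, `segment` and `synth` driven by a JSON
config; see `run_pipeline()` for the schema.

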