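Package: cellgraphs
Title: Spatial and Functional Cell-Community Graphs from Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Turns segmented microscopy images and calcium image sequences
    into cell-community graphs and quantifies their structure. Builds spatial
    proximity graphs from label masks (shared expanded-boundary pixels, scaled
    centroid distance, or perimeter distance), functional graphs from
    lag-zero cross-covariance of baseline-normalized calcium traces with a
    circular-shuffle null threshold, and ramp-class similarity graphs for
    single-transient recordings. Computes a full suite of global and per-cell
    network metrics (degree heterogeneity, efficiency, clustering, rich-club,
    assortativity, centralities, motif counts), degree-preserving and random
    spatial null ensembles, and community-effect statistics (neighborhood
    similarity score, quantile multidimensional binning correction with
    variance explained, Cohen's d). Includes watershed-based segmentation
    recipes for nuclei, cytoskeleton-stained cells and activity-based masks,
    plus synthetic-fixture generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
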