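#' Build a type II (scaled centroid-distance) spatial graph
#'
#' Two cells are connected when the Euclidean distance between their
#' centroids is strictly lower than a threshold equal to the average of the
#' two equivalent diameters multiplied by the scaling factor S. S = 3 is the
#' conventional choice for images of cell nuclei.
#'
#' @param regions region table from [extract_regions()] (needs `label`,
#'   `centroid_row`, `centroid_col`, `equiv_diameter`)
#' @param scaling_factor positive scaling factor S applied to the mean
#'   equivalent diameter of each pair
#' @return a `cell_graph` of kind `spatial_type2`
#' @export
build_type2_graph <- function(regions, scaling_factor = 3) {
  stopifnot(scaling_factor > 0)
  if (anyDuplicated(regions$label)) stop("duplicate region labels")
  n <- nrow(regions)
  A <- matrix(0, n, n)
  if (n >= 2) {
    cen <- cbind(regions$centroid_row, regions$centroid_col)
    D <- as.matrix(stats::dist(cen))
    d <- regions$equiv_diameter
    thr <- scaling_factor * outer(d, d, "+") / 2
    A[D < thr] <- 1
    diag(A) <- 0
  }
  cell_graph(regions$label, A, kind = "spatial_type2",
             params = list(scaling_factor = scaling_factor))
}

#' Build a type I (shared expanded-pixel) spatial graph
#'
#' Each object's mask is morphologically dilated by `expansion` pixels with
#' a Euclidean disk structuring element; two cells are connected when their
#' dilated supports share at least one pixel, and the edge weight is the
#' number of shared pixels (the shared cell border S_b). Cells touching the
#' image border are flagged in `params$border_labels` so local-metric
#' reporting can exclude them while keeping them available as neighbors;
#' see [local_metrics()].
#'
#' @param mask integer label matrix
#' @param expansion dilation radius in pixels (0 = no expansion)
#' @return a `cell_graph` of kind `spatial_type1` with shared-pixel weights
#' @export
build_type1_graph <- function(mask, expansion = 2) {
  stopifnot(is.matrix(mask))
  if (expansion < 0) stop("expansion must be non-negative")
  labs <- sort(unique(mask[mask > 0L]))
  n <- length(labs)
  A <- matrix(0, n, n)
  Wt <- matrix(0, n, n)
  kern <- if (expansion > 0) disk_kernel(expansion) else NULL
  supports <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- mask == labs[i]
    if (!is.null(kern)) obj <- EBImage::dilate(EBImage::Image(obj), kern) > 0
    supports[[i]] <- which(obj)
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(supports[[i]], supports[[j]]))
        if (shared > 0) {
          A[i, j] <- A[j, i] <- 1
          Wt[i, j] <- Wt[j, i] <- shared
        }
      }
    }
  }
  border <- border_labels(mask)
  cell_graph(labs, A, weights = Wt, kind = "spatial_type1",
             params = list(expansion = expansion, border_labels = border))
}

# labels of objects with a pixel on the image border
border_labels <- function(mask) {
  edge_vals <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
  sort(unique(edge_vals[edge_vals > 0L]))
}

#' Minimum perimeter-to-perimeter distances between all cell pairs
#'
#' For each unordered pair of regions, the minimum Euclidean distance
#' between their boundary pixels. Touching or overlapping objects get 0.
#'
#' @param regions region table from [extract_regions()] including the
#'   `boundary_pixels` list-column
#' @return data.frame (`label_i`, `label_j`, `distance`) with label_i <
#'   label_j, distances in pixels; carries `pixel_size` over as an attribute
#'   when the region table has one
#' @export
perimeter_distances <- function(regions) {
  if (nrow(regions) < 2) stop("need at least 2 regions")
  if (is.null(regions$boundary_pixels)) stop("regions lack boundary pixels")
  n <- nrow(regions)
  bp <- regions$boundary_pixels
  if (any(vapply(bp, nrow, 1L) == 0L)) stop("region without boundary pixels")
  pairs <- utils::combn(n, 2)
  dist_one <- function(a, b) {
    dr <- outer(a[, 1], b[, 1], "-")
    dc <- outer(a[, 2], b[, 2], "-")
    sqrt(min(dr * dr + dc * dc))
  }
  d <- apply(pairs, 2, function(p) dist_one(bp[[p[1]]], bp[[p[2]]]))
  # in a label mask distinct objects occupy distinct pixels, so objects in
  # pixel contact (8-adjacent boundary pixels) have raw distance 1 or
  # sqrt(2); contact is reported as distance 0
  d[d <= sqrt(2) + 1e-12] <- 0
  out <- data.frame(label_i = regions$label[pairs[1, ]],
                    label_j = regions$label[pairs[2, ]],
                    distance = d)
  attr(out, "pixel_size") <- attr(regions, "pixel_size")
  out
}

#' Threshold a perimeter-distance table into a graph
#'
#' An edge joins every pair whose minimum perimeter distance is less than or
#' equal to the threshold (at-or-below semantics, so a pair exactly at the
#' threshold is connected).
#'
#' @param table data.frame from [perimeter_distances()]
#' @param threshold distance threshold (> 0), in the table's units
#' @return a `cell_graph` of kind `perimeter` with distances as weights
#' @export
graph_from_distances <- function(table, threshold) {
  stopifnot(threshold > 0)
  labs <- sort(unique(c(table$label_i, table$label_j)))
  n <- length(labs)
  A <- matrix(0, n, n)
  Wt <- matrix(0, n, n)
  i <- match(table$label_i, labs)
  j <- match(table$label_j, labs)
  on <- table$distance <= threshold
  A[cbind(i[on], j[on])] <- 1
  A[cbind(j[on], i[on])] <- 1
  Wt[cbind(i[on], j[on])] <- table$distance[on]
  Wt[cbind(j[on], i[on])] <- table$distance[on]
  cell_graph(labs, A, weights = Wt, kind = "perimeter",
             params = list(threshold = threshold))
}
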