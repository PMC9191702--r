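# shared small fixtures built in code

adjacency_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  A
}

triangle_graph <- function()
  cell_graph(1:3, adjacency_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3))),
             kind = "spatial_type2")

star_graph <- function()  # K1,3, hub = node 1
  cell_graph(1:4, adjacency_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))),
             kind = "spatial_type2")

path_graph <- function()
  cell_graph(c("a", "b", "c"),
             adjacency_from_edges(3, list(c(1, 2), c(2, 3))),
             kind = "spatial_type2")

complete_graph <- function(n)
  cell_graph(seq_len(n), matrix(1, n, n) - diag(n), kind = "spatial_type2")

empty_graph <- function(n)
  cell_graph(seq_len(n), matrix(0, n, n), kind = "spatial_type2")

cycle_graph <- function(n)
  cell_graph(seq_len(n),
             adjacency_from_edges(n, c(lapply(seq_len(n - 1), function(i)
               c(i, i + 1)), list(c(n, 1)))),
             kind = "spatial_type2")

# minimal normalized_traces object for functions that consume dF/F directly
fake_norm <- function(dff, frame_interval = 1, labels = NULL) {
  dff <- as.matrix(dff)
  labels <- labels %||% seq_len(nrow(dff))
  rownames(dff) <- labels
  structure(list(dff = dff, F0 = dff * 0 + 1,
                 spikes = rep(list(integer()), nrow(dff)),
                 active = rep(TRUE, nrow(dff)),
                 roi_labels = labels, frame_interval = frame_interval),
            class = "normalized_traces")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random region layout on a field, for brute-force comparisons
random_layout <- function(n, field = 100, dmin = 2, dmax = 12) {
  data.frame(label = seq_len(n),
             centroid_row = runif(n, 0, field),
             centroid_col = runif(n, 0, field),
             equiv_diameter = runif(n, dmin, dmax))
}
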