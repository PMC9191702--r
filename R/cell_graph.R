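#' Cell graph container
#'
#' An undirected simple graph over region labels. The adjacency matrix is
#' symmetric and binary with a zero diagonal; optional edge weights (shared
#' boundary pixel counts for type I graphs, cross-covariance values for
#' functional graphs) are stored in a parallel symmetric matrix that is
#' non-zero only where an edge exists. `kind` records the construction
#' provenance, `params` the construction parameters.
#'
#' @param node_labels integer or character vector of region labels
#' @param adjacency symmetric 0/1 matrix with zero diagonal
#' @param weights optional symmetric numeric matrix, entries only on edges
#' @param kind one of "spatial_type1", "spatial_type2", "perimeter",
#'   "functional", "ramp"
#' @param params list of construction parameters
#' @return object of class `cell_graph`
#' @export
cell_graph <- function(node_labels, adjacency,
                       weights = NULL,
                       kind = c("spatial_type1", "spatial_type2", "perimeter",
                                "functional", "ramp"),
                       params = list()) {
  kind <- match.arg(kind)
  n <- length(node_labels)
  if (anyDuplicated(node_labels)) stop("duplicate node labels")
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (n > 0) {
    if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
    if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  }
  storage.mode(A) <- "double"
  dimnames(A) <- list(node_labels, node_labels)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    stopifnot(all(dim(weights) == n))
    weights[A == 0] <- 0
    dimnames(weights) <- dimnames(A)
  }
  structure(list(node_labels = node_labels, adjacency = A,
                 weights = weights, kind = kind, params = params),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph:%s> %d nodes, %d edges\n",
              x$kind, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Number of nodes of a cell graph
#' @param graph a `cell_graph`
#' @return integer
#' @export
n_nodes <- function(graph) length(graph$node_labels)

#' Number of edges of a cell graph
#' @param graph a `cell_graph`
#' @return integer
#' @export
n_edges <- function(graph) as.integer(round(sum(graph$adjacency) / 2))

#' Convert a cell graph to an igraph object
#'
#' Node labels are kept in the `name` vertex attribute; type I shared-pixel
#' or functional weights (where present) in the `weight` edge attribute.
#'
#' @param graph a `cell_graph`
#' @return an [igraph::igraph] undirected graph
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  if (!is.null(graph$weights) && igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- graph$weights[el]
  }
  g
}

#' Edge list of a cell graph
#'
#' @param graph a `cell_graph`
#' @return data.frame with `source_label`, `target_label` and (if weights are
#'   stored) `weight`; one row per unordered edge with source < target in
#'   node order
#' @export
edge_list <- function(graph) {
  A <- graph$adjacency
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  out <- data.frame(source_label = graph$node_labels[idx[, 1]],
                    target_label = graph$node_labels[idx[, 2]])
  if (!is.null(graph$weights)) out$weight <- graph$weights[idx]
  out[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Write a cell graph as an edge-list CSV
#' @param graph a `cell_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(graph, path) {
  write.csv(edge_list(graph), path, row.names = FALSE)
  invisible(path)
}

#' Write a cell graph in GraphML format
#' @param graph a `cell_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write the dense adjacency matrix as CSV
#' @param graph a `cell_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_adjacency_csv <- function(graph, path) {
  write.csv(as.data.frame(graph$adjacency), path, row.names = TRUE)
  invisible(path)
}
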