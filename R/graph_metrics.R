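#' Global graph metrics
#'
#' Computes the full global metric record of a cell graph. Conventions:
#' every variance or standard deviation is the population form (the metrics
#' describe the observed graph, not an estimator); disconnected node pairs
#' contribute 0 to the efficiency (reciprocal of an infinite path length);
#' the diameter is the largest finite shortest-path length (0 for an
#' edgeless graph); star motifs are non-induced (a node of degree k hosts
#' choose(k, s-1) s-stars); the rich-club coefficient phi(k) is the edge
#' density among nodes of degree > k, defined where at least two such nodes
#' exist, averaged over threshold degrees 1..n-1.
#'
#' @param graph a `cell_graph`
#' @param mask optional label mask; when supplied, `A` is the fraction of
#'   the field of view covered by cells
#' @return one-row data.frame with columns `n`, `m`, `A`, `avgeK`, `varK`,
#'   `NetworkHeterogeneity`, `avgeNeighborK`, `varNeighborK`, `E`, `C`,
#'   `nConnectedComponents`, `avgeComponentSize`, `varComponentSize`,
#'   `networkDiameter`, `nIsolatedNodes`, `nPairNodes`, `nLoops3`,
#'   `nStar4`, `nStar5`, `nStar6`, `avgeRichClubMetric`,
#'   `varRichClubMetric`, `Assortativity`
#' @export
global_metrics <- function(graph, mask = NULL) {
  stopifnot(inherits(graph, "cell_graph"))
  A <- graph$adjacency
  n <- nrow(A)
  m <- n_edges(graph)
  A_frac <- if (!is.null(mask)) mean(mask > 0) else NA_real_
  rec <- data.frame(n = n, m = m, A = A_frac, avgeK = NA_real_,
                    varK = NA_real_, NetworkHeterogeneity = NA_real_,
                    avgeNeighborK = NA_real_, varNeighborK = NA_real_,
                    E = NA_real_, C = NA_real_,
                    nConnectedComponents = NA_real_,
                    avgeComponentSize = NA_real_,
                    varComponentSize = NA_real_, networkDiameter = NA_real_,
                    nIsolatedNodes = NA_real_, nPairNodes = NA_real_,
                    nLoops3 = NA_real_, nStar4 = NA_real_,
                    nStar5 = NA_real_, nStar6 = NA_real_,
                    avgeRichClubMetric = NA_real_,
                    varRichClubMetric = NA_real_,
                    Assortativity = NA_real_)
  if (n == 0) return(rec)

  k <- rowSums(A)
  rec$avgeK <- mean(k)
  rec$varK <- pop_var(k)
  rec$NetworkHeterogeneity <- if (mean(k) > 0) pop_sd(k) / mean(k) else NA_real_

  kn <- neighbor_degrees(A, k)
  rec$avgeNeighborK <- if (any(k > 0)) mean(kn[k > 0]) else NA_real_
  rec$varNeighborK <- if (any(k > 0)) pop_var(kn[k > 0]) else NA_real_

  g <- as_igraph(graph)
  D <- igraph::distances(g, weights = NA)  # path lengths in links, never weights
  rec$E <- pair_efficiency(D)
  rec$C <- mean(local_clustering(A, k))

  comp <- igraph::components(g)
  rec$nConnectedComponents <- comp$no
  rec$avgeComponentSize <- mean(comp$csize)
  rec$varComponentSize <- pop_var(comp$csize)
  finite_off <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  rec$networkDiameter <- if (length(finite_off)) max(finite_off) else 0
  rec$nIsolatedNodes <- sum(k == 0)
  rec$nPairNodes <- sum(comp$csize == 2)
  rec$nLoops3 <- round(sum(diag(A %*% A %*% A)) / 6)
  rec$nStar4 <- sum(choose(k, 3))
  rec$nStar5 <- sum(choose(k, 4))
  rec$nStar6 <- sum(choose(k, 5))

  rc <- rich_club_curve(graph)
  if (nrow(rc) > 0) {
    rec$avgeRichClubMetric <- mean(rc$phi)
    rec$varRichClubMetric <- pop_var(rc$phi)
  }
  rec$Assortativity <- degree_assortativity(A, k)
  rec
}

# mean neighbor degree per node (NA where degree 0)
neighbor_degrees <- function(A, k) {
  kn <- as.vector(A %*% k)
  kn[k > 0] <- kn[k > 0] / k[k > 0]
  kn[k == 0] <- NA_real_
  kn
}

# local clustering coefficient per node, 0 where degree < 2
local_clustering <- function(A, k) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k[i] * (k[i] - 1))
  }, 1)
}

# mean over unordered node pairs of 1/shortest-path length (1/Inf = 0)
pair_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  up <- D[upper.tri(D)]
  mean(ifelse(is.finite(up), 1 / up, 0))
}

# Pearson correlation of degrees over the 2m ordered edge endpoint pairs
degree_assortativity <- function(A, k) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  x <- c(k[idx[, 1]], k[idx[, 2]])
  y <- c(k[idx[, 2]], k[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Rich-club curve
#'
#' phi(k) = 2 E_k / (N_k (N_k - 1)) where N_k is the number of nodes of
#' degree greater than k and E_k the number of edges among them; evaluated
#' for threshold degrees 1..n-1 and reported only where N_k >= 2.
#'
#' @param graph a `cell_graph` with at least 2 nodes
#' @return data.frame with columns `k` and `phi` (undefined thresholds
#'   omitted)
#' @export
rich_club_curve <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  A <- graph$adjacency
  n <- nrow(A)
  if (n < 2) stop("rich-club curve needs at least 2 nodes")
  deg <- rowSums(A)
  out <- lapply(seq_len(n - 1), function(thr) {
    sel <- which(deg > thr)
    N <- length(sel)
    if (N < 2) return(NULL)
    E_sub <- sum(A[sel, sel]) / 2
    data.frame(k = thr, phi = 2 * E_sub / (N * (N - 1)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(k = integer(), phi = numeric()) else out
}

#' Per-node (local) graph metrics
#'
#' Computes, for every node: degree `k`; mean neighbor degree `k_n` (NA for
#' isolated nodes); local clustering coefficient `C` (0 where k < 2); local
#' efficiency `E_l`, the pair efficiency of the subgraph induced by the
#' node's neighbors (0 where k < 2); harmonic closeness centrality `c_n`,
#' the sum of reciprocal graph distances to all other nodes divided by
#' n - 1 (unreachable nodes contribute 0); betweenness centrality `w_n`,
#' the raw count of shortest paths through the node with fractional
#' attribution among equally short paths; and, for type I graphs, the
#' shared cell border `S_b` (total shared pixels with all neighbors) and a
#' `border_excluded` flag marking cells that touch the image border, whose
#' local metrics are conventionally not reported (they still contribute as
#' neighbors of interior cells).
#'
#' @param graph a `cell_graph`
#' @return data.frame with one row per node: `label`, `k`, `k_n`, `C`,
#'   `E_l`, `c_n`, `w_n`, `S_b`, `border_excluded`
#' @export
local_metrics <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  A <- graph$adjacency
  n <- nrow(A)
  labs <- graph$node_labels
  if (n == 0)
    return(data.frame(label = labs, k = numeric(), k_n = numeric(),
                      C = numeric(), E_l = numeric(), c_n = numeric(),
                      w_n = numeric(), S_b = numeric(),
                      border_excluded = logical()))
  k <- rowSums(A)
  g <- as_igraph(graph)
  c_n <- if (n >= 2)
    igraph::harmonic_centrality(g, normalized = TRUE, weights = NA)
  else rep(0, n)
  w_n <- igraph::betweenness(g, directed = FALSE, weights = NA)
  E_l <- vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    Dn <- igraph::distances(igraph::graph_from_adjacency_matrix(
      A[nb, nb, drop = FALSE], mode = "undirected"))
    pair_efficiency(Dn)
  }, 1)
  S_b <- if (graph$kind == "spatial_type1" && !is.null(graph$weights))
    rowSums(graph$weights)
  else rep(NA_real_, n)
  border <- if (graph$kind == "spatial_type1")
    labs %in% (graph$params$border_labels %||% integer())
  else rep(FALSE, n)
  data.frame(label = labs, k = k, k_n = neighbor_degrees(A, k),
             C = local_clustering(A, k), E_l = E_l, c_n = as.numeric(c_n),
             w_n = as.numeric(w_n), S_b = S_b, border_excluded = border)
}

#' Write global metrics (one row per graph) as CSV
#' @param record data.frame from [global_metrics()] (rows may be stacked)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_global_metrics_csv <- function(record, path) {
  write.csv(record, path, row.names = FALSE)
  invisible(path)
}

#' Write local metrics (one row per node) as CSV
#' @param table data.frame from [local_metrics()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_local_metrics_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
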