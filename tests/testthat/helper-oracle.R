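# Brute-force reference implementations of every graph metric, written
# directly from the definitions (Floyd-Warshall paths, exhaustive subgraph
# enumeration, direct shortest-path counting). Deliberately independent of
# the package internals and of igraph.

oracle_pop_var <- function(x) mean((x - mean(x))^2)

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_components <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[is.finite(D[i, ])] <- cur
    }
  }
  comp
}

oracle_triangles <- function(A) {
  n <- nrow(A)
  if (n < 3) return(0)
  cnt <- 0
  trip <- utils::combn(n, 3)
  for (c in seq_len(ncol(trip))) {
    v <- trip[, c]
    if (A[v[1], v[2]] == 1 && A[v[1], v[3]] == 1 && A[v[2], v[3]] == 1)
      cnt <- cnt + 1
  }
  cnt
}

# number of s-stars: enumerate, for every hub, all (s-1)-subsets of its
# neighbourhood
oracle_stars <- function(A, s) {
  n <- nrow(A)
  total <- 0
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    if (length(nb) >= s - 1)
      total <- total + ncol(utils::combn(length(nb), s - 1))
  }
  total
}

oracle_rich_club <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  out <- NULL
  for (thr in seq_len(max(n - 1, 0))) {
    sel <- which(deg > thr)
    if (length(sel) < 2) next
    e <- 0
    for (i in sel) for (j in sel) if (i < j && A[i, j] == 1) e <- e + 1
    out <- rbind(out, c(thr, 2 * e / (length(sel) * (length(sel) - 1))))
  }
  out
}

oracle_assortativity <- function(A) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  k <- rowSums(A)
  x <- c(k[idx[, 1]], k[idx[, 2]])
  y <- c(k[idx[, 2]], k[idx[, 1]])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
# layers, from Floyd-Warshall distances
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_path_counts(A, D)
  bw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bw
}

oracle_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  vals <- c()
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      vals <- c(vals, if (is.finite(D[i, j])) 1 / D[i, j] else 0)
  mean(vals)
}

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    e <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) e <- e + 1
    2 * e / (k[i] * (k[i] - 1))
  }, 1)
}

oracle_global_metrics <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(A) / 2
  D <- oracle_distances(A)
  comp <- oracle_components(A)
  csize <- as.numeric(table(comp))
  kn <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (!length(nb)) NA_real_ else mean(k[nb])
  }, 1)
  finite_off <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  rc <- oracle_rich_club(A)
  list(
    n = n, m = m,
    avgeK = mean(k), varK = oracle_pop_var(k),
    NetworkHeterogeneity = if (mean(k) > 0)
      sqrt(oracle_pop_var(k)) / mean(k) else NA_real_,
    avgeNeighborK = if (any(k > 0)) mean(kn[k > 0]) else NA_real_,
    varNeighborK = if (any(k > 0)) oracle_pop_var(kn[k > 0]) else NA_real_,
    E = oracle_efficiency(D),
    C = mean(oracle_local_clustering(A)),
    nConnectedComponents = length(csize),
    avgeComponentSize = mean(csize),
    varComponentSize = oracle_pop_var(csize),
    networkDiameter = if (length(finite_off)) max(finite_off) else 0,
    nIsolatedNodes = sum(k == 0),
    nPairNodes = sum(csize == 2),
    nLoops3 = oracle_triangles(A),
    nStar4 = oracle_stars(A, 4),
    nStar5 = oracle_stars(A, 5),
    nStar6 = oracle_stars(A, 6),
    avgeRichClubMetric = if (!is.null(rc)) mean(rc[, 2]) else NA_real_,
    varRichClubMetric = if (!is.null(rc)) oracle_pop_var(rc[, 2]) else NA_real_,
    Assortativity = oracle_assortativity(A)
  )
}

oracle_local_metrics <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  D <- oracle_distances(A)
  kn <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (!length(nb)) NA_real_ else mean(k[nb])
  }, 1)
  E_l <- vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    oracle_efficiency(oracle_distances(A[nb, nb, drop = FALSE]))
  }, 1)
  c_n <- vapply(seq_len(n), function(i) {
    if (n < 2) return(0)
    sum(ifelse(is.finite(D[i, -i]) & D[i, -i] > 0, 1 / D[i, -i], 0)) / (n - 1)
  }, 1)
  list(k = k, k_n = kn, C = oracle_local_clustering(A), E_l = E_l,
       c_n = c_n, w_n = oracle_betweenness(A))
}

# compare a package metric record to an oracle list at the stated tolerances
expect_metrics_match <- function(A, label = "") {
  g <- cellgraphs::cell_graph(seq_len(nrow(A)), A, kind = "spatial_type2")
  got <- cellgraphs::global_metrics(g)
  want <- oracle_global_metrics(A)
  int_fields <- c("n", "m", "nConnectedComponents", "networkDiameter",
                  "nIsolatedNodes", "nPairNodes", "nLoops3", "nStar4",
                  "nStar5", "nStar6")
  for (f in names(want)) {
    w <- want[[f]]; v <- got[[f]]
    if (is.na(w)) {
      expect_true(is.na(v), label = paste0(label, " ", f, " should be NA"))
    } else if (f %in% int_fields) {
      expect_identical(as.numeric(v), as.numeric(w),
                       label = paste0(label, " ", f))
    } else {
      expect_true(abs(v - w) < 1e-10,
                  label = paste0(label, " ", f, ": got ", v, " want ", w))
    }
  }
  gl <- cellgraphs::local_metrics(g)
  wl <- oracle_local_metrics(A)
  for (f in c("k", "C", "E_l", "c_n", "w_n")) {
    expect_true(all(abs(gl[[f]] - wl[[f]]) < 1e-10),
                label = paste0(label, " local ", f))
  }
  kn_ok <- ifelse(is.na(wl$k_n), is.na(gl$k_n), abs(gl$k_n - wl$k_n) < 1e-10)
  expect_true(all(kn_ok), label = paste0(label, " local k_n"))
}

# seeded Erdos-Renyi-style random adjacency matrix
random_adjacency <- function(n, p = 0.35) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}
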