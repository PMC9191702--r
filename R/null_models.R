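#' Random spatial (geometric) null graph
#'
#' Places as many synthetic disks as there are regions, each with diameter
#' equal to the average equivalent diameter of all regions, at uniformly
#' random continuous locations in the field of view, and re-applies the
#' type II connection rule with the same scaling factor. Overlapping disks
#' are permitted.
#'
#' @param regions region table from [extract_regions()]
#' @param field_shape c(H, W) of the field of view in pixels
#' @param scaling_factor type II scaling factor S (default 3)
#' @param seed optional RNG seed
#' @return a `cell_graph` of kind `spatial_type2` (params record the null)
#' @export
random_spatial_graph <- function(regions, field_shape, scaling_factor = 3,
                                 seed = NULL) {
  n <- nrow(regions)
  stopifnot(n >= 1, length(field_shape) == 2, all(field_shape > 0))
  dbar <- mean(regions$equiv_diameter)
  with_seed(seed, {
    cen <- cbind(runif(n, 0, field_shape[1]), runif(n, 0, field_shape[2]))
    fake <- data.frame(label = seq_len(n), centroid_row = cen[, 1],
                       centroid_col = cen[, 2], equiv_diameter = dbar)
    g <- build_type2_graph(fake, scaling_factor)
    g$params <- c(g$params, list(null = "random_spatial", seed = seed,
                                 mean_diameter = dbar,
                                 field_shape = field_shape))
    g
  })
}

#' Degree-preserving rewiring null
#'
#' Randomizes a graph by repeated double-edge swaps: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b). Swaps that would create a
#' self-loop or a multi-edge are rejected and retried, so the degree
#' sequence of the output is exactly that of the input. If no valid swap is
#' found within the retry cap (e.g. for a star or triangle, which admit no
#' swap), the input is returned unchanged with a warning.
#'
#' @param graph a `cell_graph` with at least 2 edges
#' @param n_swaps number of accepted swaps to perform (default 10 * m)
#' @param seed optional RNG seed
#' @return a `cell_graph` of the same kind with identical degree sequence
#' @export
rewire_preserving_degrees <- function(graph, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(graph, "cell_graph"))
  m <- n_edges(graph)
  if (m < 2) stop("degree-preserving rewiring needs at least 2 edges")
  n_swaps <- n_swaps %||% (10 * m)
  A <- graph$adjacency
  n <- nrow(A)
  edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  with_seed(seed, {
    accepted <- 0L
    attempts <- 0L
    cap <- 100 * n_swaps
    while (accepted < n_swaps && attempts < cap) {
      attempts <- attempts + 1L
      ij <- sample.int(m, 2)
      e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
      a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
      if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed new edges: (a,d) and (c,b)
      if (a == d || c == b) next
      if (A[a, d] == 1 || A[c, b] == 1) next
      A[a, b] <- A[b, a] <- 0
      A[c, d] <- A[d, c] <- 0
      A[a, d] <- A[d, a] <- 1
      A[c, b] <- A[b, c] <- 1
      edges[ij[1], ] <- sort(c(a, d))
      edges[ij[2], ] <- sort(c(c, b))
      accepted <- accepted + 1L
    }
    if (accepted == 0L) {
      warning("no valid degree-preserving swap found; returning input unchanged")
      return(graph)
    }
    cell_graph(graph$node_labels, A, kind = graph$kind,
               params = c(graph$params,
                          list(null = "degree_preserving", n_swaps = accepted,
                               seed = seed)))
  })
}

#' Null ensemble of global metrics
#'
#' Generates `n_iterations` null graphs (degree-preserving rewirings of an
#' observed graph, or random spatial re-drawings of a region layout),
#' computes [global_metrics()] for each, and summarizes each metric by mean
#' and standard deviation across iterations. Iteration i uses a seed
#' deterministically derived from (`seed`, i), so ensembles are fully
#' reproducible.
#'
#' @param source a `cell_graph` (for `"degree_preserving"`) or a region
#'   table (for `"random_spatial"`)
#' @param kind `"degree_preserving"` or `"random_spatial"`
#' @param n_iterations number of null graphs (default 100)
#' @param seed master RNG seed
#' @param field_shape,scaling_factor passed to [random_spatial_graph()]
#'   when `kind = "random_spatial"`
#' @param n_swaps passed to [rewire_preserving_degrees()]
#' @return a `null_ensemble`: list with `kind`, `n_iterations`, `seed`,
#'   `records` (one global-metric row per iteration) and `summary`
#'   (metric, mean, sd)
#' @export
null_distribution <- function(source,
                              kind = c("degree_preserving", "random_spatial"),
                              n_iterations = 100, seed = NULL,
                              field_shape = NULL, scaling_factor = 3,
                              n_swaps = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_iterations >= 1)
  seed <- seed %||% 0L
  records <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    si <- derive_seed(seed, i)
    gi <- if (kind == "degree_preserving") {
      rewire_preserving_degrees(source, n_swaps = n_swaps, seed = si)
    } else {
      if (is.null(field_shape)) stop("field_shape required for random_spatial")
      random_spatial_graph(source, field_shape, scaling_factor, seed = si)
    }
    records[[i]] <- global_metrics(gi)
  }
  records <- do.call(rbind, records)
  num <- vapply(records, is.numeric, TRUE)
  summary <- data.frame(metric = names(records)[num],
                        mean = vapply(records[num], function(x)
                          mean(x, na.rm = TRUE), 1),
                        sd = vapply(records[num], function(x)
                          stats::sd(x, na.rm = TRUE), 1),
                        row.names = NULL)
  structure(list(kind = kind, n_iterations = n_iterations, seed = seed,
                 records = records, summary = summary),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble:%s> %d iterations (seed %s)\n",
              x$kind, x$n_iterations, format(x$seed)))
  invisible(x)
}

#' Write a null-ensemble summary as CSV
#' @param ensemble a `null_ensemble`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_null_summary_csv <- function(ensemble, path) {
  df <- ensemble$summary
  df$n_iterations <- ensemble$n_iterations
  df$kind <- ensemble$kind
  df$seed <- ensemble$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
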