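#' Neighborhood similarity score
#'
#' For each cell i with phase p, the score s_i is the fraction of i's graph
#' neighbors in phase p divided by the fraction of all cells in the
#' population with phase p. The neighborhood similarity score N_S is the
#' mean of s_i over eligible cells (those with at least one neighbor and a
#' phase in `include_phases`). Under random mixing N_S is approximately 1;
#' values above 1 indicate phase clustering. Isolated cells are excluded
#' (the fraction of neighbors is undefined for them); by default the
#' population fraction in the denominator counts all labeled cells,
#' including cells whose phase is excluded from scoring.
#'
#' @param graph a `cell_graph`
#' @param phases named vector mapping node label to categorical phase
#'   (names must be node labels of `graph`)
#' @param include_phases phases whose cells are scored (default: all
#'   observed phases)
#' @param population `"all"` (default) to compute population fractions over
#'   all labeled cells, or `"eligible"` to restrict to included phases
#' @return list with `N_S` (scalar, NA with a warning if no cell is
#'   eligible) and `scores` (data.frame: label, phase, n_neighbors, score)
#' @export
neighborhood_similarity <- function(graph, phases, include_phases = NULL,
                                    population = c("all", "eligible")) {
  stopifnot(inherits(graph, "cell_graph"))
  population <- match.arg(population)
  labs <- as.character(graph$node_labels)
  if (!all(names(phases) %in% labs))
    stop("phase labels refer to nodes absent from the graph")
  ph <- as.character(phases[labs])
  names(ph) <- labs
  observed <- unique(ph[!is.na(ph)])
  include_phases <- include_phases %||% observed
  if (!all(include_phases %in% observed))
    stop("include_phases contains phases not observed in the labels")
  pop <- if (population == "all") ph[!is.na(ph)]
         else ph[!is.na(ph) & ph %in% include_phases]
  pop_frac <- table(pop) / length(pop)
  A <- graph$adjacency
  k <- rowSums(A)
  eligible <- !is.na(ph) & ph %in% include_phases & k > 0
  scores <- data.frame(label = graph$node_labels, phase = ph,
                       n_neighbors = k, score = NA_real_, row.names = NULL)
  for (i in which(eligible)) {
    nb <- which(A[i, ] == 1)
    frac_same <- mean(ph[nb] == ph[i], na.rm = FALSE)
    scores$score[i] <- frac_same / as.numeric(pop_frac[[ph[i]]])
  }
  if (!any(eligible)) {
    warning("no eligible cell for neighborhood similarity")
    return(list(N_S = NA_real_, scores = scores))
  }
  list(N_S = mean(scores$score[eligible]), scores = scores)
}

# quantile bin assignment for one numeric column: interior edges at the
# i/n_bins quantiles (linear interpolation); a value exactly on an edge
# goes to the lower bin; tied edges are collapsed so a constant column
# yields a single bin
quantile_bins <- function(x, n_bins) {
  probs <- seq_len(n_bins - 1) / n_bins
  edges <- unique(as.numeric(stats::quantile(x, probs, type = 7)))
  bin <- rowSums(outer(x, edges, ">")) + 1L
  list(bin = as.integer(bin), edges = edges)
}

#' Quantile multidimensional binning correction
#'
#' Partitions cells into quantile bins of several covariate columns
#' simultaneously (by default 5 bins per metric), then subtracts from each
#' target column the mean of its values within each occupied
#' multidimensional bin. This removes the variance in the targets that is
#' attributable to the binned covariates (e.g. local network metrics
#' capturing cell crowding). When `treatment_column` is given, a
#' treatment-corrected variant is also produced by subtracting per-treatment
#' means.
#'
#' @param table data.frame of per-cell features
#' @param bin_metrics character vector of covariate column names to bin on
#'   (conventionally the 7 local network metrics)
#' @param n_bins bins per metric (default 5; must be >= 2)
#' @param target_columns character vector of columns to correct
#' @param treatment_column optional categorical column name
#' @return a `correction_result`: list with `bin_edges` (per metric),
#'   `bin_id` (per-cell bin tuple as a string), `corrected` (data.frame of
#'   bin-mean-corrected targets), `treatment_corrected` (or NULL) and
#'   `variance_explained` (data.frame: feature, factor, fraction)
#' @export
quantile_bin_correct <- function(table, bin_metrics, n_bins = 5,
                                 target_columns, treatment_column = NULL) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  stopifnot(all(bin_metrics %in% names(table)),
            all(target_columns %in% names(table)))
  for (cn in c(bin_metrics, target_columns))
    if (any(is.na(table[[cn]]))) stop("missing values in column ", cn)
  n <- nrow(table)
  if (n < 1) stop("empty feature table")
  bins <- lapply(bin_metrics, function(cn) quantile_bins(table[[cn]], n_bins))
  names(bins) <- bin_metrics
  bin_id <- do.call(paste, c(lapply(bins, `[[`, "bin"), sep = "."))
  corrected <- table[, target_columns, drop = FALSE]
  for (cn in target_columns) {
    bm <- stats::ave(table[[cn]], bin_id, FUN = mean)
    corrected[[cn]] <- table[[cn]] - bm
  }
  treatment_corrected <- NULL
  # a zero-variance target (e.g. a single cell) has no variance to explain
  ve_safe <- function(raw, corr)
    if (pop_var(raw) == 0) NA_real_ else variance_explained(raw, corr)
  ve <- list()
  for (cn in target_columns) {
    ve[[length(ve) + 1L]] <-
      data.frame(feature = cn, factor = "network_bins",
                 fraction = ve_safe(table[[cn]], corrected[[cn]]))
  }
  if (!is.null(treatment_column)) {
    stopifnot(treatment_column %in% names(table))
    treatment_corrected <- table[, target_columns, drop = FALSE]
    for (cn in target_columns) {
      tm <- stats::ave(table[[cn]], table[[treatment_column]], FUN = mean)
      treatment_corrected[[cn]] <- table[[cn]] - tm
      ve[[length(ve) + 1L]] <-
        data.frame(feature = cn, factor = "treatment",
                   fraction = ve_safe(table[[cn]], treatment_corrected[[cn]]))
    }
  }
  structure(list(bin_edges = lapply(bins, `[[`, "edges"), bin_id = bin_id,
                 corrected = corrected,
                 treatment_corrected = treatment_corrected,
                 variance_explained = do.call(rbind, ve)),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %d cells, %d bin metrics\n",
              length(x$bin_id), length(x$bin_edges)))
  print(x$variance_explained)
  invisible(x)
}

#' Fraction of variance explained by a correction
#'
#' 1 - Var(corrected) / Var(raw), with population variances. Since
#' within-bin centering can only reduce variance, the result lies in
#' \[0, 1\] for any bin-mean correction.
#'
#' @param raw raw measurement vector (must have positive variance)
#' @param corrected corrected vector of the same length
#' @return scalar fraction
#' @export
variance_explained <- function(raw, corrected) {
  stopifnot(length(raw) == length(corrected))
  v_raw <- pop_var(raw)
  if (is.na(v_raw) || v_raw == 0) stop("raw measurements have zero variance")
  1 - pop_var(corrected) / v_raw
}

#' Cohen's d effect size
#'
#' (mean_a - mean_b) / pooled SD, with the pooled SD computed from sample
#' variances: sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)).
#'
#' @param group_a,group_b numeric vectors with at least 2 values each
#' @return signed effect size
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean(group_a) - mean(group_b)) / sp
}

#' Representative cell of a cluster
#'
#' The member with the smallest sum of squared distances to the
#' column-wise median of the cluster's feature rows. A convenience helper
#' for labeling clusters produced by any external clustering routine.
#'
#' @param features numeric matrix or data.frame (rows = cells)
#' @return row index of the representative cell
#' @export
representative_cell <- function(features) {
  X <- as.matrix(features)
  med <- apply(X, 2, stats::median)
  which.min(rowSums(sweep(X, 2, med)^2))
}
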