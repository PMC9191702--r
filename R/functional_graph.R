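#' Lag-0 normalized cross-covariance matrix of dF/F traces
#'
#' The mean-subtracted, unit-normalized cross-covariance at lag 0 — i.e. the
#' Pearson correlation coefficient of each pair of dF/F traces.
#' Normalization makes the pooled shuffle-null threshold scale-free across
#' ROIs of different brightness.
#'
#' @param norm a `normalized_traces` object with at least 2 ROIs
#' @return symmetric matrix in \[-1, 1\] with unit diagonal, dimnames =
#'   ROI labels
#' @export
crosscov_matrix <- function(norm) {
  stopifnot(inherits(norm, "normalized_traces"))
  X <- t(norm$dff)
  if (ncol(X) < 2) stop("need at least 2 ROIs")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance dF/F trace for ROI ",
         paste(norm$roi_labels[sds == 0], collapse = ", "))
  M <- stats::cor(X)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(norm$roi_labels, norm$roi_labels)
  M
}

#' Shuffle-null threshold for functional connectivity
#'
#' Each dF/F trace is circularly rotated at an independently drawn uniform
#' random breakpoint — preserving its autocorrelation while destroying
#' cross-trace alignment — and all pairwise lag-0 cross-covariance values of
#' the shuffled set are pooled. The returned threshold is the given
#' percentile of the pooled null values; with `n_shuffles > 1`, values are
#' pooled across repetitions.
#'
#' @param norm a `normalized_traces` object with at least 2 ROIs
#' @param percentile percentile of the null distribution (default 99)
#' @param n_shuffles number of full shuffled datasets to pool (default 1)
#' @param seed optional RNG seed for reproducibility
#' @return scalar threshold in \[-1, 1\]
#' @export
shuffle_null_threshold <- function(norm, percentile = 99, n_shuffles = 1,
                                   seed = NULL) {
  stopifnot(inherits(norm, "normalized_traces"), n_shuffles >= 1)
  dff <- norm$dff
  n <- nrow(dff); Tn <- ncol(dff)
  if (n < 2) stop("need at least 2 ROIs")
  with_seed(seed, {
    pooled <- unlist(lapply(seq_len(n_shuffles), function(s) {
      shifts <- sample.int(Tn, n, replace = TRUE) - 1L
      sh <- dff
      for (i in seq_len(n)) {
        k <- shifts[i]
        if (k > 0) sh[i, ] <- c(dff[i, (Tn - k + 1):Tn], dff[i, 1:(Tn - k)])
      }
      M <- stats::cor(t(sh))
      M[upper.tri(M)]
    }))
    as.numeric(stats::quantile(pooled, percentile / 100, type = 7))
  })
}

#' Threshold a connectivity matrix into a functional graph
#'
#' An edge joins every pair whose matrix entry strictly exceeds the
#' threshold; matrix values are stored as edge weights.
#'
#' @param matrix symmetric connectivity matrix (e.g. from
#'   [crosscov_matrix()]); dimnames are used as node labels if present
#' @param threshold edge threshold (e.g. from [shuffle_null_threshold()])
#' @return a `cell_graph` of kind `functional`
#' @export
build_functional_graph <- function(matrix, threshold) {
  M <- as.matrix(matrix)
  stopifnot(nrow(M) == ncol(M))
  if (!isTRUE(all.equal(M, t(M)))) stop("connectivity matrix must be symmetric")
  labs <- rownames(M) %||% seq_len(nrow(M))
  A <- matrix(0, nrow(M), ncol(M))
  A[M > threshold] <- 1
  diag(A) <- 0
  Wt <- M * A
  cell_graph(labs, A, weights = Wt, kind = "functional",
             params = list(threshold = threshold))
}

#' Classify single-transient traces by ramp-up and ramp-down time
#'
#' For recordings in which each cell shows one major transient, each trace
#' is characterized not by its magnitude but by the time it took to reach
#' its peak from `fraction` (default 20%) of the peak value (ramp-up) and
#' the time needed to return to that fraction (ramp-down). Crossings are
#' frame-quantized with no interpolation: ramp-up runs from the last frame
#' before the peak at which dF/F is at or below `fraction * peak`, and
#' ramp-down to the first such frame after the peak. A trace that never
#' dips to the band on one side gets NA there (with a warning).
#'
#' @param norm a `normalized_traces` object; each trace needs a unique
#'   positive global maximum
#' @param fraction band fraction of the peak (default 0.2)
#' @return data.frame with `label`, `peak_time_s`, `ramp_up_s`,
#'   `ramp_down_s` (times in seconds; frame times start at 0)
#' @export
classify_ramps <- function(norm, fraction = 0.2) {
  stopifnot(inherits(norm, "normalized_traces"))
  dt <- norm$frame_interval
  if (is.na(dt)) stop("frame_interval required for ramp classification")
  n <- nrow(norm$dff)
  out <- data.frame(label = norm$roi_labels,
                    peak_time_s = NA_real_, ramp_up_s = NA_real_,
                    ramp_down_s = NA_real_)
  for (i in seq_len(n)) {
    f <- norm$dff[i, ]
    pk <- max(f)
    if (pk <= 0) stop("trace for ROI ", norm$roi_labels[i],
                      " has non-positive maximum")
    at <- which(f == pk)
    if (length(at) > 1)
      warning("ROI ", norm$roi_labels[i],
              ": tied global maximum; using the first peak frame")
    at <- at[1]
    band <- fraction * pk
    out$peak_time_s[i] <- (at - 1) * dt
    before <- which(f[seq_len(at - 1)] <= band)
    after <- if (at < length(f)) which(f[(at + 1):length(f)] <= band) else integer()
    if (length(before)) out$ramp_up_s[i] <- (at - max(before)) * dt
    else warning("ROI ", norm$roi_labels[i], ": ramp-up undefined ",
                 "(trace never at or below the band before the peak)")
    if (length(after)) out$ramp_down_s[i] <- min(after) * dt
    else warning("ROI ", norm$roi_labels[i], ": ramp-down undefined ",
                 "(trace never returns to the band after the peak)")
  }
  out
}

#' Build a ramp-class similarity graph with a spatial proximity gate
#'
#' An edge joins two cells exactly when (a) they have the same ramp-up and
#' ramp-down times and (b) the Euclidean distance between their centroids
#' is at most `distance_factor` times the mean of their two equivalent
#' diameters. Cells with a missing ramp class stay isolated (a warning is
#' issued).
#'
#' @param ramps data.frame from [classify_ramps()]
#' @param regions region table from [extract_regions()] (matched by label)
#' @param distance_factor proximity gate multiplier (default 10)
#' @return a `cell_graph` of kind `ramp`
#' @export
build_ramp_graph <- function(ramps, regions, distance_factor = 10) {
  labs <- ramps$label
  ri <- match(labs, regions$label)
  if (any(is.na(ri))) stop("ramp table contains labels absent from regions")
  n <- length(labs)
  A <- matrix(0, n, n)
  missing_class <- is.na(ramps$ramp_up_s) | is.na(ramps$ramp_down_s)
  if (any(missing_class))
    warning("cells with missing ramp class left isolated: ",
            paste(labs[missing_class], collapse = ", "))
  if (n >= 2) {
    cen <- cbind(regions$centroid_row[ri], regions$centroid_col[ri])
    D <- as.matrix(stats::dist(cen))
    d <- regions$equiv_diameter[ri]
    gate <- D <= distance_factor * outer(d, d, "+") / 2
    same <- outer(ramps$ramp_up_s, ramps$ramp_up_s, "==") &
      outer(ramps$ramp_down_s, ramps$ramp_down_s, "==")
    same[is.na(same)] <- FALSE
    A[same & gate] <- 1
    diag(A) <- 0
  }
  cell_graph(labs, A, kind = "ramp",
             params = list(distance_factor = distance_factor))
}

#' Write a ramp-class table as CSV
#' @param ramps data.frame from [classify_ramps()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ramps_csv <- function(ramps, path) {
  write.csv(ramps, path, row.names = FALSE)
  invisible(path)
}
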