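#' Extract mean-intensity traces per ROI from an image stack
#'
#' The raw fluorescence trace F of each ROI is the average of the pixel
#' intensities inside that ROI, per frame.
#'
#' @param stack an `image_stack` (H x W x T)
#' @param mask integer label matrix of the same H x W; each positive label
#'   is one ROI
#' @return a `trace_matrix`: list with `F` (n_rois x T), `roi_labels` and
#'   `frame_interval`
#' @export
extract_traces <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), is.matrix(mask))
  d <- dim(stack$frames)
  if (d[1] != nrow(mask) || d[2] != ncol(mask))
    stop("stack frames and mask have different shapes")
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) stop("mask contains no ROIs")
  idx <- which(mask > 0L)
  grp <- match(mask[idx], labs)
  Tn <- d[3]
  flat <- matrix(stack$frames, nrow = d[1] * d[2], ncol = Tn)
  sums <- rowsum(flat[idx, , drop = FALSE], grp)
  counts <- tabulate(grp, nbins = length(labs))
  F <- sums / counts
  rownames(F) <- labs
  structure(list(F = F, roi_labels = labs,
                 frame_interval = stack$frame_interval),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROIs x %d frames\n", nrow(x$F), ncol(x$F)))
  invisible(x)
}

#' Construct a trace matrix directly from a numeric matrix
#'
#' @param F n_rois x T matrix of raw intensities
#' @param roi_labels optional labels (default 1..n)
#' @param frame_interval seconds per frame
#' @return a `trace_matrix`
#' @export
trace_matrix <- function(F, roi_labels = NULL, frame_interval = NA_real_) {
  F <- as.matrix(F)
  labs <- roi_labels %||% seq_len(nrow(F))
  stopifnot(length(labs) == nrow(F))
  rownames(F) <- labs
  structure(list(F = F, roi_labels = labs, frame_interval = frame_interval),
            class = "trace_matrix")
}

# least-squares removal of a linear trend about the trace mean, in closed
# form: subtracting slope * (t - mean(t)) keeps the mean, so the detrended
# intensity stays on the raw scale (and positive for modest trends), and a
# constant trace passes through bit-exactly
detrend_linear <- function(f) {
  t <- seq_along(f)
  tc <- t - mean(t)
  slope <- sum(tc * (f - mean(f))) / sum(tc^2)
  f - slope * tc
}

# moving low-percentile baseline: F0[t] = percentile of f over frames
# [t - w, t + w], truncated at the trace ends (no padding)
moving_percentile <- function(f, w, p) {
  Tn <- length(f)
  vapply(seq_len(Tn), function(t) {
    lo <- max(1L, t - w); hi <- min(Tn, t + w)
    as.numeric(stats::quantile(f[lo:hi], p / 100, type = 7))
  }, 1)
}

# centered moving average of odd width, truncated at the ends
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  h <- (width - 1) %/% 2
  Tn <- length(x)
  vapply(seq_len(Tn), function(t) mean(x[max(1L, t - h):min(Tn, t + h)]), 1)
}

#' Normalize raw traces to dF/F with spike detection and activity flags
#'
#' The pipeline, in order: (1) per-trace least-squares linear detrending
#' with the trace mean re-added; (2) moving baseline F0, the
#' `baseline_percentile`-th percentile (linear-interpolation definition)
#' over a window of `round(window_fraction * T)` frames before and after
#' each frame, truncated at the trace ends; (3) dF/F = (F - F0)/F0;
#' (4) centered moving-average smoothing of width `smooth_window`;
#' (5) spike detection with [detect_spikes()]; (6) the `active` flag, true
#' when a trace has at least `min_spikes` spikes.
#'
#' @param traces a `trace_matrix`
#' @param baseline_percentile percentile of the moving baseline (default 8)
#' @param window_fraction half-window as a fraction of the trace length
#'   (default 0.01, i.e. one-hundredth of the total number of frames)
#' @param smooth_window odd width of the smoothing window in frames
#' @param rel_threshold,abs_floor spike thresholds, see [detect_spikes()]
#' @param min_spikes minimum spike count for a trace to count as active
#' @return a `normalized_traces` object: `dff` and `F0` matrices, `spikes`
#'   (list of frame-index vectors), `active` (logical), `roi_labels`,
#'   `frame_interval`
#' @export
normalize_traces <- function(traces, baseline_percentile = 8,
                             window_fraction = 0.01, smooth_window = 5,
                             rel_threshold = 0.25, abs_floor = 0.05,
                             min_spikes = 3) {
  stopifnot(inherits(traces, "trace_matrix"))
  F <- traces$F
  Tn <- ncol(F)
  if (Tn < 10) stop("need at least 10 frames for baseline normalization")
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
  w <- max(1L, as.integer(round(window_fraction * Tn)))
  n <- nrow(F)
  dff <- F0 <- matrix(0, n, Tn, dimnames = dimnames(F))
  for (i in seq_len(n)) {
    fd <- detrend_linear(F[i, ])
    f0 <- moving_percentile(fd, w, baseline_percentile)
    if (any(f0 <= 0))
      stop("non-positive baseline for ROI ", traces$roi_labels[i],
           "; offset the raw intensities before normalizing")
    F0[i, ] <- f0
    dff[i, ] <- moving_average((fd - f0) / f0, smooth_window)
  }
  spikes <- lapply(seq_len(n), function(i)
    detect_spikes(dff[i, ], rel_threshold, abs_floor))
  names(spikes) <- traces$roi_labels
  active <- vapply(spikes, length, 1L) >= min_spikes
  structure(list(dff = dff, F0 = F0, spikes = spikes, active = active,
                 roi_labels = traces$roi_labels,
                 frame_interval = traces$frame_interval,
                 params = list(baseline_percentile = baseline_percentile,
                               window_fraction = window_fraction,
                               smooth_window = smooth_window,
                               rel_threshold = rel_threshold,
                               abs_floor = abs_floor,
                               min_spikes = min_spikes)),
            class = "normalized_traces")
}

#' @export
print.normalized_traces <- function(x, ...) {
  cat(sprintf("<normalized_traces> %d ROIs x %d frames, %d active\n",
              nrow(x$dff), ncol(x$dff), sum(x$active)))
  invisible(x)
}

#' Detect calcium spikes in a dF/F trace
#'
#' A spike is a local maximum whose dF/F value is at least
#' `rel_threshold` times the trace maximum or `abs_floor`, whichever is
#' higher. Local maxima satisfy dff[t-1] < dff[t] >= dff[t+1], so a plateau
#' maximum is counted once, at its leftmost frame; trace endpoints are never
#' spikes.
#'
#' @param dff_trace numeric dF/F vector (length >= 3)
#' @param rel_threshold fraction of the trace maximum (default 0.25)
#' @param abs_floor absolute dF/F floor (default 0.05)
#' @return integer vector of spike frame indices (1-based), strictly
#'   increasing
#' @export
detect_spikes <- function(dff_trace, rel_threshold = 0.25, abs_floor = 0.05) {
  if (length(dff_trace) < 3) stop("trace too short for spike detection")
  if (any(!is.finite(dff_trace))) stop("non-finite values in dF/F trace")
  Tn <- length(dff_trace)
  t <- 2:(Tn - 1)
  is_max <- dff_trace[t - 1] < dff_trace[t] & dff_trace[t] >= dff_trace[t + 1]
  thr <- max(rel_threshold * max(dff_trace), abs_floor)
  t[is_max & dff_trace[t] >= thr]
}

#' Keep only active ROIs
#'
#' Traces with fewer than `min_spikes` spikes are filtered out to avoid
#' false positives in the cross-covariance analysis; label association is
#' preserved.
#'
#' @param norm a `normalized_traces` object
#' @param min_spikes minimum spike count (default 3)
#' @return a `normalized_traces` object restricted to active ROIs
#' @export
select_active <- function(norm, min_spikes = 3) {
  stopifnot(inherits(norm, "normalized_traces"))
  keep <- vapply(norm$spikes, length, 1L) >= min_spikes
  out <- norm
  out$dff <- norm$dff[keep, , drop = FALSE]
  out$F0 <- norm$F0[keep, , drop = FALSE]
  out$spikes <- norm$spikes[keep]
  out$active <- norm$active[keep]
  out$roi_labels <- norm$roi_labels[keep]
  out
}

#' Write traces as CSV (rows = ROIs, columns = frames)
#' @param traces a `trace_matrix` or `normalized_traces` (writes `dff`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(traces, path) {
  M <- if (inherits(traces, "normalized_traces")) traces$dff else traces$F
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  colnames(df) <- c("label", paste0("frame_", seq_len(ncol(M))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a spike table as CSV (label, frame, time_s)
#' @param norm a `normalized_traces` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spikes_csv <- function(norm, path) {
  rows <- do.call(rbind, lapply(seq_along(norm$spikes), function(i) {
    fr <- norm$spikes[[i]]
    if (length(fr) == 0) return(NULL)
    data.frame(label = norm$roi_labels[i], frame = fr,
               time_s = (fr - 1) * norm$frame_interval)
  }))
  if (is.null(rows)) rows <- data.frame(label = integer(), frame = integer(),
                                        time_s = numeric())
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
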