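#' Synthetic label mask of non-overlapping disk-shaped cells
#'
#' Places `n_cells` disks with radii drawn uniformly from `radius_range`
#' into a field, rejecting candidate centers closer than the sum of radii
#' plus `min_gap` to an accepted disk, until the packing succeeds or the
#' attempt cap is hit. Labels are assigned in placement order, and the
#' ground-truth centers and diameters are returned alongside the mask.
#'
#' @param n_cells number of disks
#' @param field_shape c(H, W) in pixels
#' @param radius_range c(min, max) disk radius in pixels
#' @param min_gap minimum edge-to-edge spacing in pixels (default 2)
#' @param seed optional RNG seed
#' @param keep_off_border if TRUE (default) disks are kept at least one
#'   pixel away from the image border
#' @param max_tries rejection-sampling cap per disk (default 2000)
#' @return list with `mask` (integer label matrix) and `truth`
#'   (data.frame: label, centroid_row, centroid_col, radius, diameter)
#' @export
make_label_image <- function(n_cells, field_shape = c(128, 128),
                             radius_range = c(4, 7), min_gap = 2,
                             seed = NULL, keep_off_border = TRUE,
                             max_tries = 2000) {
  stopifnot(n_cells >= 1, length(field_shape) == 2)
  H <- field_shape[1]; W <- field_shape[2]
  with_seed(seed, {
    centers <- matrix(NA_real_, n_cells, 2)
    radii <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- runif(1, radius_range[1], radius_range[2])
        margin <- if (keep_off_border) r + 1 else 0
        if (H - 2 * margin <= 0 || W - 2 * margin <= 0)
          stop("field too small for the requested radii")
        cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                   2, cand)^2))
          ok <- all(dd >= radii[seq_len(i - 1)] + r + min_gap)
        }
        if (ok) { centers[i, ] <- cand; radii[i] <- r; placed <- TRUE; break }
      }
      if (!placed) stop("disk packing infeasible after ", max_tries,
                        " tries (cell ", i, " of ", n_cells, ")")
    }
    mask <- matrix(0L, H, W)
    rows0 <- matrix(rep(0:(H - 1), W), H, W)
    cols0 <- matrix(rep(0:(W - 1), each = H), H, W)
    for (i in seq_len(n_cells)) {
      inside <- (rows0 - centers[i, 1])^2 + (cols0 - centers[i, 2])^2 <=
        radii[i]^2
      mask[inside] <- i
    }
    list(mask = mask,
         truth = data.frame(label = seq_len(n_cells),
                            centroid_row = centers[, 1],
                            centroid_col = centers[, 2],
                            radius = radii, diameter = 2 * radii))
  })
}

# one latent calcium trace: Poisson-like spike train convolved with an
# instantaneous-rise, exponential-decay kernel
latent_calcium_trace <- function(Tn, dt, spike_rate, tau) {
  events <- rbinom(Tn, 1, min(1, spike_rate * dt))
  as.numeric(stats::filter(events, exp(-dt / tau), method = "recursive"))
}

# one trapezoidal single-transient trace (frame-quantized linear ramps)
trapezoid_trace <- function(Tn, peak_frame, ramp_up_frames, ramp_down_frames) {
  f <- numeric(Tn)
  up <- seq(0, 1, length.out = ramp_up_frames + 1)
  for (j in seq_along(up)) {
    t <- peak_frame - (ramp_up_frames + 1) + j
    if (t >= 1 && t <= Tn) f[t] <- up[j]
  }
  down <- seq(1, 0, length.out = ramp_down_frames + 1)
  for (j in seq_along(down)) {
    t <- peak_frame + (j - 1)
    if (t >= 1 && t <= Tn) f[t] <- down[j]
  }
  f
}

#' Synthetic calcium image stack with planted functional blocks
#'
#' Cells in the same block share a latent signal — a Poisson spike train
#' convolved with an exponential-decay calcium kernel (`waveform =
#' "spikes"`), or a single trapezoidal transient with block-specific
#' ramp-up/ramp-down times (`waveform = "trapezoid"`) — plus independent
#' Gaussian noise scaled so that sd(signal)/sd(noise) = `snr`. Pixel
#' intensities inside each ROI equal the cell's trace; the true functional
#' adjacency is the union of within-block complete graphs.
#'
#' @param mask integer label mask defining the ROIs
#' @param block_structure list of label vectors partitioning the labels
#' @param snr signal-to-noise ratio (sd of shared signal / sd of noise);
#'   `Inf` for noiseless traces
#' @param spike_rate latent spike rate in events per second (default 0.1)
#' @param T number of frames (default 600)
#' @param frame_interval seconds per frame (default 0.5)
#' @param seed optional RNG seed
#' @param baseline,amplitude intensity offset and scale (defaults 100, 50)
#' @param tau calcium decay time constant in seconds (default 2)
#' @param waveform `"spikes"` (default) or `"trapezoid"`
#' @param ramp_params for `waveform = "trapezoid"`: data.frame with one row
#'   per block (`peak_frame`, `ramp_up_frames`, `ramp_down_frames`)
#' @return list with `stack` (an `image_stack`), `true_adjacency`
#'   (binary matrix over sorted labels), `block_of` (named block index) and
#'   `cell_traces` (n x T matrix of the noiseless-pixel cell traces)
#' @export
make_calcium_stack <- function(mask, block_structure, snr = 5,
                               spike_rate = 0.1, T = 600,
                               frame_interval = 0.5, seed = NULL,
                               baseline = 100, amplitude = 50, tau = 2,
                               waveform = c("spikes", "trapezoid"),
                               ramp_params = NULL) {
  waveform <- match.arg(waveform)
  labs <- sort(unique(mask[mask > 0L]))
  stopifnot(setequal(unlist(block_structure), labs))
  Tn <- as.integer(T)
  with_seed(seed, {
    n_blocks <- length(block_structure)
    latents <- matrix(0, n_blocks, Tn)
    for (b in seq_len(n_blocks)) {
      latents[b, ] <- if (waveform == "spikes") {
        latent_calcium_trace(Tn, frame_interval, spike_rate, tau)
      } else {
        stopifnot(!is.null(ramp_params), nrow(ramp_params) >= b)
        trapezoid_trace(Tn, ramp_params$peak_frame[b],
                        ramp_params$ramp_up_frames[b],
                        ramp_params$ramp_down_frames[b])
      }
    }
    block_of <- setNames(rep(seq_len(n_blocks),
                             vapply(block_structure, length, 1L)),
                         unlist(block_structure))
    block_of <- block_of[as.character(labs)]
    traces <- matrix(0, length(labs), Tn, dimnames = list(labs, NULL))
    for (i in seq_along(labs)) {
      sig <- amplitude * latents[block_of[i], ]
      noise_sd <- if (is.infinite(snr)) 0 else {
        s <- stats::sd(sig)
        if (s == 0) amplitude * 0.02 else s / snr
      }
      traces[i, ] <- baseline + sig + rnorm(Tn, 0, noise_sd)
    }
    H <- nrow(mask); W <- ncol(mask)
    frames <- array(baseline, dim = c(H, W, Tn))
    flat <- matrix(frames, H * W, Tn)
    for (i in seq_along(labs)) {
      flat[mask == labs[i], ] <- rep(traces[i, ], each = sum(mask == labs[i]))
    }
    frames <- array(flat, dim = c(H, W, Tn))
    A <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
    for (b in seq_len(n_blocks)) {
      members <- which(block_of == b)
      A[members, members] <- 1
    }
    diag(A) <- 0
    list(stack = image_stack(frames, frame_interval), true_adjacency = A,
         block_of = block_of, cell_traces = traces)
  })
}

#' Synthetic per-cell phase labels with tunable spatial assortment
#'
#' With mixing parameter p = 0 every cell draws its phase independently and
#' uniformly; with p = 1 each connected component of the graph is assigned
#' a single phase; for intermediate p each cell first draws independently
#' and then, with probability p, copies the phase of a uniformly chosen
#' neighbor (one pass in node order).
#'
#' @param graph a `cell_graph`
#' @param p assortment knob in \[0, 1\]
#' @param phases character vector of phase names (default G1 / SG2M)
#' @param seed optional RNG seed
#' @return named character vector (names = node labels)
#' @export
make_phase_labels <- function(graph, p = 0.5, phases = c("G1", "SG2M"),
                              seed = NULL) {
  stopifnot(inherits(graph, "cell_graph"), p >= 0, p <= 1)
  n <- n_nodes(graph)
  labs <- as.character(graph$node_labels)
  with_seed(seed, {
    if (p == 1) {
      comp <- igraph::components(as_igraph(graph))
      ph <- sample(phases, comp$no, replace = TRUE)[comp$membership]
    } else {
      ph <- sample(phases, n, replace = TRUE)
      if (p > 0) {
        A <- graph$adjacency
        copy <- runif(n) < p
        for (i in which(copy)) {
          nb <- which(A[i, ] == 1)
          if (length(nb)) ph[i] <- ph[sample(nb, 1)]
        }
      }
    }
    setNames(ph, labs)
  })
}

#' Synthetic feature table with a known variance decomposition
#'
#' Draws 7 correlated local-network-metric columns from a Gaussian copula
#' (exchangeable correlation 0.99, i.e. a single latent crowding factor
#' with small metric-specific variation — local network metrics in real
#' images are strongly inter-correlated because they all reflect local cell
#' density — with heterogeneous marginals), computes the
#' quantile bin tuple of every cell, and builds one morphology column as
#' f(bin tuple) * sqrt(a) + noise * sqrt(b) + treatment offset, where f is
#' the standardized sum of bin indices, `a = bin_signal_strength` and
#' `b = noise`. The realized bin-signal variance fraction a/(a+b) is
#' recorded as ground truth.
#'
#' @param n_cells number of rows
#' @param bin_signal_strength variance of the bin-determined component (a)
#' @param noise variance of the independent noise component (b)
#' @param treatment_effects optional named numeric vector of per-condition
#'   offsets; conditions are assigned round-robin
#' @param seed optional RNG seed
#' @param n_bins bins per metric used to define the generating bin tuple
#'   (default 5)
#' @return list with `table` (data.frame: 7 metric columns `k`, `k_n`, `C`,
#'   `E_l`, `c_n`, `w_n`, `S_b`, plus `morphology` and `treatment`) and
#'   `truth` (list: `variance_fraction_bins` = a/(a+b), per-cell `f`)
#' @export
make_feature_table <- function(n_cells, bin_signal_strength = 1, noise = 1,
                               treatment_effects = NULL, seed = NULL,
                               n_bins = 5) {
  stopifnot(n_cells >= 2, bin_signal_strength >= 0, noise >= 0)
  metric_names <- c("k", "k_n", "C", "E_l", "c_n", "w_n", "S_b")
  p <- length(metric_names)
  with_seed(seed, {
    R <- matrix(0.99, p, p); diag(R) <- 1
    Z <- matrix(rnorm(n_cells * p), n_cells, p) %*% chol(R)
    U <- stats::pnorm(Z)
    tab <- data.frame(
      k = stats::qpois(U[, 1], 4),
      k_n = stats::qgamma(U[, 2], shape = 4, rate = 1),
      C = U[, 3],
      E_l = U[, 4],
      c_n = stats::qbeta(U[, 5], 2, 8),
      w_n = stats::qexp(U[, 6], 0.2),
      S_b = stats::qpois(U[, 7], 30)
    )
    bins <- lapply(metric_names, function(cn) quantile_bins(tab[[cn]], n_bins))
    tuple <- do.call(cbind, lapply(bins, `[[`, "bin"))
    f <- rowSums(tuple)
    f <- (f - mean(f)) / max(pop_sd(f), 1e-12)
    morph <- f * sqrt(bin_signal_strength) + rnorm(n_cells) * sqrt(noise)
    treatment <- rep("control", n_cells)
    if (!is.null(treatment_effects)) {
      conds <- names(treatment_effects)
      treatment <- conds[(seq_len(n_cells) - 1) %% length(conds) + 1]
      morph <- morph + treatment_effects[treatment]
    }
    tab$morphology <- as.numeric(morph)
    tab$treatment <- treatment
    a <- bin_signal_strength; b <- noise
    list(table = tab,
         truth = list(variance_fraction_bins = if (a + b > 0) a / (a + b) else 0,
                      f = f))
  })
}
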