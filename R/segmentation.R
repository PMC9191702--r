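#' Activity-based mask from a calcium image sequence
#'
#' Segments only the active cells of a recording: for each pixel the
#' difference between its maximum and minimum intensity across all frames
#' is computed and normalized to \[0, 1\]; a first Otsu threshold gives an
#' initial foreground, a second Otsu threshold computed on the delta values
#' within that foreground refines it; the refined binary image undergoes
#' morphological closing with a Euclidean disk, objects smaller than
#' `min_size` pixels are removed, and the survivors are
#' connected-component labeled (8-connectivity). Since the max/min range
#' is order-free, the result is invariant to any permutation of the
#' frames. A temporally constant stack yields an empty mask with a warning.
#'
#' @param stack an `image_stack` with at least 2 frames
#' @param closing_radius disk radius for morphological closing (default 3)
#' @param min_size minimum object size in pixels (default 10)
#' @return integer label matrix
#' @export
activity_mask <- function(stack, closing_radius = 3, min_size = 10) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  if (dim(fr)[3] < 2) stop("activity mask needs at least 2 frames")
  delta <- apply(fr, c(1, 2), max) - apply(fr, c(1, 2), min)
  rng <- range(delta)
  if (rng[2] - rng[1] <= 0) {
    warning("temporally constant stack; returning empty mask")
    return(matrix(0L, dim(fr)[1], dim(fr)[2]))
  }
  delta <- (delta - rng[1]) / (rng[2] - rng[1])
  th1 <- EBImage::otsu(EBImage::Image(delta), range = c(0, 1))
  fg1 <- delta > th1
  # second pass: re-threshold using only the delta values already called
  # foreground; on a two-level delta image the foreground is constant and
  # no refinement is possible
  th2 <- if (length(unique(delta[fg1])) < 2) th1 else otsu_vec(delta[fg1])
  fg <- delta > th2
  if (closing_radius > 0)
    fg <- EBImage::closing(EBImage::Image(fg), disk_kernel(closing_radius)) > 0
  fg <- matrix(as.logical(fg), nrow(delta), ncol(delta))
  lab <- label_components(fg, connectivity = 8)
  filter_small_objects(lab, min_size)
}

#' Watershed segmentation of nucleus images
#'
#' Binarizes a single-channel nucleus image with locally adaptive (moving
#' average) thresholding, computes the Euclidean distance transform of the
#' foreground, and splits touching nuclei by a watershed on the distance
#' transform whose seeds are its regional maxima (equivalently, regional
#' minima of the negated transform) with shallow extrema suppressed by the
#' depth parameter `h`.
#'
#' @param image 2D intensity matrix
#' @param window adaptive-threshold window size in pixels (odd, default 51)
#' @param offset adaptive-threshold offset subtracted from the local mean
#'   (on the normalized 0-1 intensity scale, default 0)
#' @param h suppression depth for shallow watershed extrema, in pixels of
#'   distance-transform height (default 1)
#' @param min_size minimum object size in pixels (default 0 = keep all)
#' @return integer label matrix
#' @export
segment_nuclei_watershed <- function(image, window = 51, offset = 0,
                                     h = 1, min_size = 0) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) return(matrix(0L, nrow(image), ncol(image)))
  img <- (image - rng[1]) / (rng[2] - rng[1])
  w <- min((window - 1) %/% 2, nrow(img) - 2, ncol(img) - 2)
  bin <- EBImage::thresh(EBImage::Image(img), w = w, h = w, offset = offset)
  bin <- matrix(as.logical(bin > 0), nrow(img), ncol(img))
  if (!any(bin)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(bin))
  ws <- EBImage::watershed(dm, tolerance = h, ext = 1)
  lab <- matrix(as.integer(ws), nrow(img), ncol(img))
  if (min_size > 0) lab <- filter_small_objects(lab, min_size)
  lab
}

#' Marker-controlled watershed segmentation of cytoskeleton-stained cells
#'
#' Implements the composite-channel recipe for immunofluorescence images of
#' cells stained for actin, tubulin and nuclei: (1) contrast enhancement by
#' histogram equalization of the cytoskeletal composite; (2) Gaussian
#' smoothing; (3) Otsu binarization; (4) dilation to fill cell areas;
#' (5) removal of objects smaller than `min_area_frac` of the image (the
#' final binary image); (6) a marker image from the nucleus and tubulin
#' channels thresholded at a high value; (7-9) marker-controlled watershed
#' of the smoothed intensity landscape, seeded at the markers and
#' constrained to the final binary image; (10) refinement with a composite
#' actin+tubulin marker. An outer loop adjusts the high threshold until the
#' ratio of segmented area to marker area falls inside `area_ratio_band`,
#' up to `max_iter` iterations; on non-convergence the best iterate is
#' returned with a warning.
#'
#' @param actin,tubulin,nuclei co-registered 2D intensity matrices
#' @param high_threshold initial marker threshold on the 0-1 scale
#'   (default 0.5)
#' @param area_ratio_band acceptable segmented-area / marker-area band
#'   (default c(5, 50): accepted markers are nucleus-sized regions covering
#'   roughly 2-20 percent of the cell area, well inside cells)
#' @param max_iter outer-loop cap (default 20)
#' @param sigma Gaussian smoothing sigma in pixels (default 2)
#' @param dilate_radius radius of the fill dilation (default 2)
#' @param min_area_frac object-size cutoff as a fraction of image area
#'   (default 0.01)
#' @param marker_min_size smallest marker component (in pixels) allowed to
#'   seed a cell; smaller specks of bright texture are discarded
#' @return integer label matrix
#' @export
segment_cells_watershed <- function(actin, tubulin, nuclei,
                                    high_threshold = 0.5,
                                    area_ratio_band = c(5, 50),
                                    max_iter = 20, sigma = 2,
                                    dilate_radius = 2,
                                    min_area_frac = 0.01,
                                    marker_min_size = 10) {
  stopifnot(is.matrix(actin), all(dim(actin) == dim(tubulin)),
            all(dim(actin) == dim(nuclei)))
  norm01 <- function(x) {
    r <- range(x)
    if (r[2] - r[1] <= 0) matrix(0, nrow(x), ncol(x))
    else (x - r[1]) / (r[2] - r[1])
  }
  composite <- norm01(norm01(actin) + norm01(tubulin))
  if (max(composite) <= 0) return(matrix(0L, nrow(actin), ncol(actin)))
  eq <- EBImage::equalize(EBImage::Image(composite), range = c(0, 1))
  sm <- EBImage::gblur(eq, sigma = sigma)
  bin <- sm > EBImage::otsu(sm, range = c(0, 1))
  if (dilate_radius > 0)
    bin <- EBImage::dilate(bin, disk_kernel(dilate_radius)) > 0
  bin <- matrix(as.logical(bin), nrow(actin), ncol(actin))
  lab0 <- label_components(bin, connectivity = 8)
  final_bin <- filter_small_objects(lab0,
                                    ceiling(min_area_frac * length(bin))) > 0
  if (!any(final_bin)) return(matrix(0L, nrow(actin), ncol(actin)))
  nuc <- norm01(nuclei); tub <- norm01(tubulin)
  seg_area <- sum(final_bin)

  run_once <- function(thr, marker_src) {
    marker <- (marker_src > thr) & final_bin
    if (!any(marker)) return(NULL)
    seeds <- filter_small_objects(label_components(marker, connectivity = 8),
                                  marker_min_size)
    if (max(seeds) == 0) return(NULL)
    ws <- EBImage::propagate(EBImage::Image(as.matrix(sm)),
                             EBImage::Image(seeds),
                             mask = EBImage::Image(final_bin))
    list(lab = matrix(as.integer(ws), nrow(actin), ncol(actin)),
         marker_area = sum(seeds > 0))
  }

  thr <- high_threshold
  best <- NULL
  best_gap <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- run_once(thr, pmax(nuc, tub))
    if (is.null(res)) { thr <- thr * 0.8; next }
    ratio <- seg_area / res$marker_area
    gap <- if (ratio < area_ratio_band[1]) area_ratio_band[1] - ratio
           else if (ratio > area_ratio_band[2]) ratio - area_ratio_band[2]
           else 0
    if (gap < best_gap) { best <- res; best_gap <- gap }
    if (gap == 0) { converged <- TRUE; break }
    # markers too large (ratio low) -> raise threshold; too small -> lower
    thr <- if (ratio < area_ratio_band[1]) min(0.99, thr * 1.25)
           else max(0.01, thr * 0.8)
  }
  if (!converged)
    warning("marker-area ratio did not reach the acceptance band; ",
            "returning the best iterate")
  if (is.null(best)) return(matrix(0L, nrow(actin), ncol(actin)))
  # refinement pass: composite actin+tubulin marker at the accepted threshold
  ref <- run_once(attr(best, "thr") %||% thr, pmax(norm01(actin), tub))
  lab <- if (!is.null(ref) && max(ref$lab) >= max(best$lab)) ref$lab else best$lab
  lab
}
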