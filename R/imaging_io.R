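#' Read a label mask from a TIFF or PNG file
#'
#' A label mask is a 2D integer image in which 0 is background and each
#' positive integer marks one object (labels need not be contiguous).
#' Binary inputs (values 0/1 or 0/255) are connected-component labeled with
#' 8-connectivity, numbering components in raster-scan order of their first
#' pixel so the labeling is deterministic.
#'
#' @param path path to a single-page TIFF or PNG file of integer type
#' @param pixel_size optional physical pixel size (micrometres per pixel);
#'   attached as the `pixel_size` attribute
#' @return integer matrix with attribute `pixel_size` (may be NULL)
#' @export
read_label_mask <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read label mask: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    # png values come back in [0,1]; rescale to the native integer range
    p <- png::readPNG(path)
    round(p * 255)
  } else {
    stop("unsupported mask format: .", ext)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L && !all(img[, , 1] == img[, , -1]))
      stop("multichannel image is not a valid label mask: ", path)
    img <- img[, , 1]
  }
  if (any(!is.finite(img))) stop("non-finite pixel values in ", path)
  if (any(abs(img - round(img)) > 1e-9))
    stop("floating-point image with non-integral values cannot be a label mask: ", path)
  m <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  vals <- sort(unique(as.vector(m)))
  binary <- identical(vals, c(0L, 1L)) || identical(vals, c(0L, 255L)) ||
    identical(vals, 1L) || identical(vals, 255L)
  if (binary && any(m > 1L)) m[m > 0L] <- 1L
  if (binary) m <- label_components(m, connectivity = 8)
  attr(m, "pixel_size") <- pixel_size
  m
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels are stored losslessly for values up to 65535; reading the file
#' back with [read_label_mask()] reproduces the labels exactly.
#'
#' @param mask integer matrix (0 = background)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0) || any(mask > 65535))
    stop("labels must lie in 0..65535 for 16-bit TIFF output")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Extract per-object geometry from a label mask
#'
#' One row per distinct positive label, in ascending label order. Centroids
#' are intensity-unweighted means of 0-based (row, col) pixel coordinates.
#' The equivalent diameter is the diameter of the circle with the same area,
#' 2*sqrt(area/pi). Boundary pixels are object pixels 4-adjacent to a pixel
#' of another value or to the image edge. `touches_border` flags objects
#' with a pixel on the first/last row or column.
#'
#' @param mask integer label matrix (optionally carrying a `pixel_size`
#'   attribute in micrometres per pixel)
#' @return data.frame with columns `label`, `area`, `centroid_row`,
#'   `centroid_col`, `equiv_diameter`, `touches_border` and a list-column
#'   `boundary_pixels` (n x 2 matrices of 0-based (row, col)); if a pixel
#'   size is attached, `equiv_diameter_um` is added
#' @export
extract_regions <- function(mask) {
  stopifnot(is.matrix(mask))
  px <- attr(mask, "pixel_size")
  labs <- sort(unique(mask[mask > 0L]))
  n <- length(labs)
  empty <- data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      equiv_diameter = numeric(), touches_border = logical())
  if (n == 0L) {
    empty$boundary_pixels <- list()
    return(empty)
  }
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask > 0L)
  lab_of <- mask[idx]
  rows0 <- (idx - 1L) %% H          # 0-based row
  cols0 <- (idx - 1L) %/% H         # 0-based col

  # boundary test, vectorized: a pixel is boundary if any 4-neighbour has a
  # different value or falls outside the image
  is_boundary <- rep(FALSE, length(idx))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- rows0 + d[1L]; nc <- cols0 + d[2L]
    outside <- nr < 0L | nr >= H | nc < 0L | nc >= W
    nb_val <- rep(-1L, length(idx))
    ok <- !outside
    nb_val[ok] <- mask[cbind(nr[ok] + 1L, nc[ok] + 1L)]
    is_boundary <- is_boundary | outside | nb_val != lab_of
  }

  grp <- match(lab_of, labs)
  area <- tabulate(grp, nbins = n)
  centroid_row <- as.vector(tapply(rows0, grp, mean))
  centroid_col <- as.vector(tapply(cols0, grp, mean))
  touches <- as.vector(tapply(rows0 == 0L | rows0 == H - 1L |
                              cols0 == 0L | cols0 == W - 1L, grp, any))
  bp <- vector("list", n)
  for (g in seq_len(n)) {
    sel <- grp == g & is_boundary
    bp[[g]] <- cbind(row = rows0[sel], col = cols0[sel])
  }
  out <- data.frame(label = as.integer(labs), area = as.integer(area),
                    centroid_row = centroid_row, centroid_col = centroid_col,
                    equiv_diameter = 2 * sqrt(area / pi),
                    touches_border = touches)
  out$boundary_pixels <- bp
  if (!is.null(px)) {
    out$equiv_diameter_um <- out$equiv_diameter * px
    attr(out, "pixel_size") <- px
  }
  out
}

#' Write a region table as CSV
#'
#' @param regions data.frame from [extract_regions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions_csv <- function(regions, path) {
  df <- data.frame(label = regions$label, area_px = regions$area,
                   centroid_row = regions$centroid_row,
                   centroid_col = regions$centroid_col,
                   equiv_diameter_px = regions$equiv_diameter,
                   touches_border = regions$touches_border)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Frames are returned in page order. The frame interval is an acquisition
#' parameter supplied by the caller, never read from file metadata.
#'
#' @param path multi-page TIFF, all pages of equal shape
#' @param frame_interval seconds per frame (required for temporal analysis)
#' @return an `image_stack`: list with `frames` (H x W x T array) and
#'   `frame_interval`
#' @export
read_image_stack <- function(path, frame_interval = NA_real_) {
  if (!file.exists(path)) stop("cannot read image stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent page shapes in ", path, ": ", paste(unique(shapes), collapse = ", "))
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frames <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  image_stack(frames, frame_interval)
}

#' Construct an image stack from an array
#'
#' @param frames H x W x T numeric array (a matrix is treated as T = 1)
#' @param frame_interval seconds per frame
#' @return an `image_stack` object
#' @export
image_stack <- function(frames, frame_interval = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 1L)
  if (!is.na(frame_interval) && frame_interval <= 0)
    stop("frame_interval must be positive")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px, frame interval %s s\n",
              d[3], d[1], d[2],
              ifelse(is.na(x$frame_interval), "?", format(x$frame_interval))))
  invisible(x)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer-valued stacks in 0..65535 are written as 16-bit pages and
#' round-trip bit-exactly through [read_image_stack()]; other values are
#' written as 32-bit float.
#'
#' @param stack an `image_stack`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  Tn <- dim(fr)[3]
  pages <- lapply(seq_len(Tn), function(t) fr[, , t])
  integral <- all(abs(fr - round(fr)) < 1e-9) && min(fr) >= 0 && max(fr) <= 65535
  if (integral) {
    tiff::writeTIFF(lapply(pages, function(p) round(p) / 65535), path,
                    bits.per.sample = 16L)
  } else {
    rng <- range(fr)
    scaled <- lapply(pages, function(p) (p - rng[1]) / max(rng[2] - rng[1], 1e-12))
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  }
  invisible(path)
}
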