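`%||%` <- function(x, y) if (is.null(x)) y else x

#' Euclidean disk structuring element
#'
#' Binary kernel containing offsets (dx, dy) with dx^2 + dy^2 <= radius^2.
#' Used for type I mask expansion and morphological closing so that the
#' element is isotropic and its footprint is exactly reproducible.
#'
#' @param radius non-negative integer radius in pixels
#' @return (2*radius+1) x (2*radius+1) 0/1 matrix
#' @export
disk_kernel <- function(radius) {
  stopifnot(length(radius) == 1, radius >= 0)
  radius <- as.integer(radius)
  if (radius == 0L) return(matrix(1, 1, 1))
  off <- -radius:radius
  k <- outer(off^2, off^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

# Population (not sample) variance / sd: metrics describe the observed
# graph, not an estimator of a larger population.
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

# Stable 32-bit seed derivation for iteration i of an ensemble seeded with
# `seed`: a small multiplicative hash kept below 2^31.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 2654435761 + as.double(i) * 40503) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (if not
# NULL), restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash (32-bit, carried in doubles) of a character scalar, reported
# as 8 hex digits. Used to stamp pipeline outputs with a config fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Otsu threshold of a numeric vector in [0, 1] via EBImage on a 1 x N image.
otsu_vec <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2)
  img <- EBImage::Image(values, dim = c(length(values), 1L))
  EBImage::otsu(img, range = c(0, 1), levels = levels)
}

#' Label connected components of a binary image
#'
#' Deterministic flood-fill labeling: components are numbered 1, 2, ... in
#' raster-scan order (row-major) of their first pixel.
#'
#' @param binary logical or 0/1 matrix
#' @param connectivity 8 (default) or 4
#' @return integer matrix of labels (0 = background)
#' @export
label_components <- function(binary, connectivity = 8) {
  stopifnot(is.matrix(binary), connectivity %in% c(4, 8))
  fg <- binary > 0
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  current <- 0L
  # raster scan is row-major: rows outer, columns inner
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      if (!fg[r, cc] || lab[r, cc] != 0L) next
      current <- current + 1L
      queue <- matrix(c(r, cc), ncol = 2)
      lab[r, cc] <- current
      while (nrow(queue) > 0L) {
        p <- queue[1L, , drop = TRUE]
        queue <- queue[-1L, , drop = FALSE]
        nr <- p[1L] + dr; nc <- p[2L] + dc
        ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
        nr <- nr[ok]; nc <- nc[ok]
        idx <- cbind(nr, nc)
        hit <- fg[idx] & lab[idx] == 0L
        if (any(hit)) {
          idx <- idx[hit, , drop = FALSE]
          lab[idx] <- current
          queue <- rbind(queue, idx)
        }
      }
    }
  }
  lab
}

# Remove labeled objects smaller than min_size pixels and relabel the
# survivors 1..K in raster order of first pixel.
filter_small_objects <- function(lab, min_size) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab %in% keep] <- lab[lab %in% keep]
  if (max(out) > 0L) out <- label_components(out > 0L, connectivity = 8)
  out
}
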