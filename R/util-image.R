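# Low-level raster primitives used by the detection/tracking/posture pipeline.
#
# Conventions (used everywhere in the package):
#   * a frame is a numeric matrix [nrow = height, ncol = width], values 0..255;
#   * positions are 0-based pixel-center coordinates, x rightward (column - 1),
#     y downward (row - 1);
#   * a box is an integer vector c(x0, y0, x1, y1), inclusive, 0-based;
#   * connectivity is 8-connected throughout.

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian convolution with replicate (edge-clamp) boundary
#' handling. The kernel is truncated at `ceiling(3 * sigma)` taps on each side
#' and renormalized, so a constant image is exactly preserved and `sigma = 0`
#' is the identity.
#'
#' @param pixels numeric matrix (gray values).
#' @param sigma kernel standard deviation in pixels; `0` returns the input.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(pixels, sigma) {
  stopifnot(is.matrix(pixels), sigma >= 0)
  if (sigma == 0) return(pixels)
  k <- gaussian_kernel_1d(sigma)
  convolve_separable(pixels, k)
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding; compiled hot path.
convolve_separable <- function(m, k) {
  convolve_separable_cpp(m, k)
}

#' Smooth only a rectangular region of a frame
#'
#' Crops `box` expanded by the kernel radius, smooths the crop, and returns
#' the values over `box`. Away from the frame border the result is identical
#' to smoothing the whole frame and cropping, at a fraction of the cost; at
#' the frame border the replicate padding coincides with whole-frame
#' smoothing because the expansion is clipped to the frame.
#'
#' @param pixels frame matrix.
#' @param box inclusive 0-based `c(x0, y0, x1, y1)`.
#' @param sigma Gaussian sigma in pixels.
#' @return matrix of size `(y1 - y0 + 1) x (x1 - x0 + 1)`.
#' @export
gaussian_smooth_box <- function(pixels, box, sigma) {
  if (sigma == 0) return(crop_box(pixels, box))
  r <- ceiling(3 * sigma)
  big <- clip_box(box + c(-r, -r, r, r), dim(pixels))
  sm <- gaussian_smooth(crop_box(pixels, big), sigma)
  # offset of requested box inside the expanded crop
  ox <- box[1] - big[1]; oy <- box[2] - big[2]
  sm[(oy + 1):(oy + box[4] - box[2] + 1), (ox + 1):(ox + box[3] - box[1] + 1),
     drop = FALSE]
}

## box helpers ---------------------------------------------------------------

clip_box <- function(box, dims) {
  c(max(box[1], 0L), max(box[2], 0L),
    min(box[3], dims[2] - 1L), min(box[4], dims[1] - 1L))
}

crop_box <- function(m, box) {
  m[(box[2] + 1):(box[4] + 1), (box[1] + 1):(box[3] + 1), drop = FALSE]
}

expand_box <- function(box, pad, dims) {
  clip_box(c(box[1] - pad, box[2] - pad, box[3] + pad, box[4] + pad), dims)
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  c(min(w[, 2]) - 1L, min(w[, 1]) - 1L, max(w[, 2]) - 1L, max(w[, 1]) - 1L)
}

## connected components ------------------------------------------------------

#' Label 8-connected components of a binary mask
#'
#' Flood-fill labeling over foreground pixels only, so cost scales with the
#' number of foreground pixels rather than the frame area.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  nxt <- 0L
  # neighbor offsets in column-major linear indexing
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (s in fg) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (p in cur) {
        pr <- ((p - 1L) %% nr) + 1L
        for (o in offs) {
          q <- p + o
          if (q < 1L || q > nr * nc) next
          qr <- ((q - 1L) %% nr) + 1L
          if (abs(qr - pr) > 1L) next  # wrapped across a column edge
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Per-component area, centroid (0-based frame coords given an origin offset)
# and bounding box. Returns a list of lists.
component_stats <- function(lab, origin = c(0L, 0L)) {
  n <- max(lab)
  if (n == 0) return(list())
  nr <- nrow(lab)
  w <- which(lab > 0)
  ids <- lab[w]
  rows <- ((w - 1L) %% nr)        # 0-based y within crop
  cols <- ((w - 1L) %/% nr)       # 0-based x within crop
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- ids == i
    xs <- cols[sel]; ys <- rows[sel]
    out[[i]] <- list(
      id = i,
      area = sum(sel),
      centroid = c(mean(xs) + origin[1], mean(ys) + origin[2]),
      bbox = c(min(xs), min(ys), max(xs), max(ys)) +
        c(origin[1], origin[2], origin[1], origin[2])
    )
  }
  out
}

## binary morphology ---------------------------------------------------------

#' Dilate a binary mask with a 3x3 structuring element
#'
#' @param mask logical matrix.
#' @param iterations number of dilation passes (radius in pixels).
#' @return dilated logical matrix.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(iterations)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nr, , drop = FALSE])
    v <- m | up | dn
    lf <- cbind(v[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, v[, -nc, drop = FALSE])
    m <- v | lf | rt
  }
  m
}

# count of 8-neighbors that are TRUE, per pixel
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  s <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + m[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  s
}
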