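# Automatic animal detection and background reconstruction.
#
# The detector has no prior on where the animal is. It accumulates a running
# mean of the Gaussian-filtered frames; once the difference between the
# current frame and that mean contains exactly one blob with animal-like
# area, the blob's neighborhood becomes the region of interest. A local
# binarization threshold is then calibrated inside that ROI on the first
# frame, and once the animal has vacated its initial footprint, the occupied
# region of the first frame is patched with pixels from a later frame to
# yield an animal-free background image.

#' Gaussian pre-filtering of a frame
#'
#' Every image entering the pipeline is smoothed with a Gaussian kernel whose
#' sigma scales with the animal's size, to suppress camera noise.
#' `sigma = 0` is the identity.
#'
#' @param frame a frame list (from [get_frame()]) or a bare pixel matrix.
#' @param sigma kernel sigma in pixels.
#' @return same type as the input, with smoothed pixels.
#' @export
preprocess <- function(frame, sigma) {
  if (is.matrix(frame)) return(gaussian_smooth(frame, sigma))
  frame$pixels <- gaussian_smooth(frame$pixels, sigma)
  frame
}

#' Motion detection against the running mean image
#'
#' Computes `D = current - mean_image`; the animal's new position carries
#' values below the threshold `mean(D) - 4` (it is darker than the
#' background it moved onto). If binarization yields exactly one 8-connected
#' component whose area lies within the configured bounds, that component's
#' bounding box expanded by `roi_padding_px` (clipped to the frame) is
#' returned; otherwise `NULL`, and the caller accumulates the next frame
#' into the mean.
#'
#' @param mean_image running mean of the (filtered) frames so far.
#' @param current current filtered frame matrix.
#' @param params [animal_parameters()].
#' @return ROI box `c(x0, y0, x1, y1)` or `NULL` when no unique motion blob
#'   is present.
#' @export
detect_motion <- function(mean_image, current, params) {
  d <- current - mean_image
  thr <- mean(d) - 4
  mask <- d < thr
  if (!any(mask)) return(NULL)
  st <- component_stats(label_components(mask))
  areas <- vapply(st, function(s) s$area, numeric(1))
  ok <- which(areas >= params$min_area_px & areas <= params$max_area_px)
  if (length(ok) != 1) return(NULL)
  expand_box(st[[ok]]$bbox, params$roi_padding_px, dim(current))
}

#' Calibrate the local binarization threshold inside the first-frame ROI
#'
#' Starting from `mean(roi) - 4`, the gray-value cutoff is adjusted one gray
#' level at a time until binarization (`pixels < threshold`) yields exactly
#' one component whose area satisfies the bounds: the threshold is lowered
#' while more than one candidate blob passes, and raised while none does.
#' The sweep fails once the 0..255 range is exhausted.
#'
#' @param roi_pixels matrix of (filtered) first-frame gray values inside the
#'   ROI.
#' @param params [animal_parameters()].
#' @return list with `threshold` and `mask` (logical matrix over the ROI,
#'   the animal's silhouette in the first frame).
#' @export
calibrate_local_threshold <- function(roi_pixels, params) {
  count_valid <- function(thr) {
    mask <- roi_pixels < thr
    if (!any(mask)) return(list(n = 0L, mask = NULL))
    st <- component_stats(lab <- label_components(mask))
    areas <- vapply(st, function(s) s$area, numeric(1))
    ok <- which(areas >= params$min_area_px & areas <= params$max_area_px)
    list(n = length(ok),
         mask = if (length(ok) == 1) lab == st[[ok]]$id else NULL)
  }
  thr <- mean(roi_pixels) - 4
  seen_lo <- -Inf; seen_hi <- Inf
  repeat {
    res <- count_valid(thr)
    if (res$n == 1) return(list(threshold = thr, mask = res$mask))
    if (res$n > 1) thr <- thr - 1 else thr <- thr + 1
    if (thr < 0 || thr > 255 || thr <= seen_lo || thr >= seen_hi)
      stop("no unique animal blob: threshold calibration failed")
    # guard against oscillation between the two regimes
    if (res$n > 1) seen_hi <- min(seen_hi, thr + 1) else
      seen_lo <- max(seen_lo, thr - 1)
  }
}

#' Reconstruct an animal-free background image
#'
#' Waits until the animal has vacated its initial footprint: each new
#' (filtered) frame is binarized with the calibrated local threshold inside
#' the initial ROI, and the pixels the animal has left
#' (`initial_mask & !current_mask`) are searched for a blob identical to the
#' initial silhouette (centroid within 2 px, area within 20%). Once found,
#' the first frame's pixels under the initial mask, dilated by 2 px plus the
#' Gaussian kernel radius to cover the soft halo the pre-filter spreads
#' around the body, are replaced by the corresponding pixels of that later
#' frame — except where the animal's current silhouette (dilated by the
#' same margin) still grazes the patch: that sliver is filled with the
#' median of the cleanly pasted background pixels instead of animal pixels,
#' and is re-pasted from a pristine frame once the animal has moved a full
#' kernel radius away (see [run_closed_loop()]).
#'
#' @param first_pixels filtered first frame (full matrix).
#' @param source frame source to scan forward.
#' @param roi_box initial ROI (from [detect_motion()]).
#' @param local_threshold,initial_mask from [calibrate_local_threshold()];
#'   `initial_mask` is ROI-local.
#' @param params [animal_parameters()].
#' @param start_index 0-based index of the first frame to scan.
#' @param budget_frames give up after this many frames.
#' @return list with `background` (full-frame matrix, filtered scale),
#'   `source_frame_index` (frame whose pixels were patched in) and
#'   `patched_mask` (full-frame logical mask of replaced pixels).
#' @export
reconstruct_background <- function(first_pixels, source, roi_box,
                                   local_threshold, initial_mask, params,
                                   start_index = 1L,
                                   budget_frames = n_frames(source)) {
  st0 <- component_stats(label_components(initial_mask),
                         origin = roi_box[1:2])
  stopifnot(length(st0) == 1)
  c0 <- st0[[1]]$centroid; a0 <- st0[[1]]$area
  # margin covering the halo the Gaussian pre-filter spreads around the body
  halo <- 2L + as.integer(ceiling(3 * params$gaussian_sigma_px))
  nr <- nrow(first_pixels); nc <- ncol(first_pixels)
  # the animal may straddle the ROI border by vacate time: binarize over an
  # expanded box so its silhouette is fully masked out of the patch
  ext_box <- expand_box(roi_box, halo + 6L, c(nr, nc))
  ox <- roi_box[1] - ext_box[1]; oy <- roi_box[2] - ext_box[2]
  roi_rows <- (oy + 1):(oy + roi_box[4] - roi_box[2] + 1)
  roi_cols <- (ox + 1):(ox + roi_box[3] - roi_box[1] + 1)
  last <- min(n_frames(source) - 1L, start_index + budget_frames - 1L)
  i <- start_index
  while (i <= last) {
    fr <- get_frame(source, i)
    cur_ext <- gaussian_smooth_box(fr$pixels, ext_box,
                                   params$gaussian_sigma_px)
    cur_bin_ext <- cur_ext < local_threshold
    cur_bin <- cur_bin_ext[roi_rows, roi_cols, drop = FALSE]
    left <- initial_mask & !cur_bin
    st <- component_stats(label_components(left), origin = roi_box[1:2])
    for (s in st) {
      if (sqrt(sum((s$centroid - c0)^2)) <= 2 &&
          abs(s$area - a0) <= 0.2 * a0) {
        # vacated: patch the initial footprint from this frame
        later <- gaussian_smooth(fr$pixels, params$gaussian_sigma_px)
        full_mask <- matrix(FALSE, nr, nc)
        full_mask[(roi_box[2] + 1):(roi_box[4] + 1),
                  (roi_box[1] + 1):(roi_box[3] + 1)] <- initial_mask
        full_mask <- dilate_mask(full_mask, halo)
        # sliver still grazed by the animal's (dilated) silhouette
        sliver <- matrix(FALSE, nr, nc)
        sliver[(ext_box[2] + 1):(ext_box[4] + 1),
               (ext_box[1] + 1):(ext_box[3] + 1)] <-
          dilate_mask(cur_bin_ext, halo + 3L)
        clean <- full_mask & !sliver
        bg <- first_pixels
        bg[clean] <- later[clean]
        if (any(full_mask & sliver)) {
          fill <- if (any(clean)) stats::median(later[clean])
                  else stats::median(later[!full_mask])
          bg[full_mask & sliver] <- fill
        }
        return(list(background = bg, source_frame_index = fr$index,
                    patched_mask = full_mask))
      }
    }
    i <- i + 1L
  }
  stop("animal never moved: background reconstruction failed after ",
       last - start_index + 1L, " frames")
}

#' Full animal auto-detection pass
#'
#' Runs the motion detector over the leading frames, calibrates the local
#' threshold inside the first-frame ROI, and reconstructs the animal-free
#' background. This is the startup phase of every closed-loop run.
#'
#' @param source a `vrt_frame_source`.
#' @param params [animal_parameters()].
#' @param max_detect_frames abort if no unique motion blob is found within
#'   this many frames.
#' @return a `vrt_detection` list: `roi_box`, `local_threshold`,
#'   `initial_mask` (ROI-local logical), `initial_centroid`, `background`
#'   (full-frame matrix), `background_frame_index`, `ready_frame` (0-based
#'   index of the first frame available for tracking), `motion_frame`.
#' @export
detect_animal <- function(source, params,
                          max_detect_frames = n_frames(source)) {
  nf <- n_frames(source)
  if (nf < 3) stop("detection never succeeded: source too short")
  sigma <- params$gaussian_sigma_px
  f0 <- gaussian_smooth(get_frame(source, 0L)$pixels, sigma)
  mean_img <- f0
  n_acc <- 1L
  roi <- NULL
  i <- 1L
  last <- min(nf - 1L, max_detect_frames - 1L)
  while (i <= last) {
    cur <- gaussian_smooth(get_frame(source, i)$pixels, sigma)
    mean_img <- mean_img + (cur - mean_img) / (n_acc + 1L)  # mean incl. current
    n_acc <- n_acc + 1L
    roi <- detect_motion(mean_img, cur, params)
    if (!is.null(roi)) break
    i <- i + 1L
  }
  if (is.null(roi))
    stop("detection never succeeded: no unique motion blob in ",
         n_acc, " frames")
  cal <- calibrate_local_threshold(crop_box(f0, roi), params)
  st0 <- component_stats(label_components(cal$mask), origin = roi[1:2])
  bg <- reconstruct_background(f0, source, roi, cal$threshold, cal$mask,
                               params, start_index = i + 1L)
  structure(list(
    roi_box = roi,
    local_threshold = cal$threshold,
    initial_mask = cal$mask,
    initial_centroid = st0[[1]]$centroid,
    background = bg$background,
    background_frame_index = bg$source_frame_index,
    patched_mask = bg$patched_mask,
    motion_frame = i,
    ready_frame = bg$source_frame_index + 1L), class = "vrt_detection")
}

#' @export
print.vrt_detection <- function(x, ...) {
  cat(sprintf(paste0("<vrt_detection> motion at frame %d, threshold %.1f, ",
                     "background from frame %d\n"),
              x$motion_frame, x$local_threshold, x$background_frame_index))
  invisible(x)
}

#' Save a background image as PNG
#' @param background background matrix (gray 0..255).
#' @param path output file.
#' @export
write_background_png <- function(background, path) {
  png::writePNG(pmin(pmax(background, 0), 255) / 255, path)
  invisible(path)
}
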