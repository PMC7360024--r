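# Per-frame animal localization by local background subtraction inside a
# moving region of interest, and the closed-loop experiment orchestrator
# that binds tracking to the virtual landscape.

#' Track the animal in one frame
#'
#' Inside `roi_box`, computes the difference `D = frame - background` on the
#' Gaussian-filtered frame; the animal stands out as values below the
#' threshold `mean(D) - 3 * sd(D)`. Among 8-connected components whose area
#' lies within the configured bounds, the largest is the animal (ties are
#' broken toward the component nearest the previous centroid). The next
#' search box is the blob's bounding box expanded by `roi_padding_px`.
#'
#' @param pixels raw frame matrix (filtering is applied internally, ROI-only
#'   for speed, identically to whole-frame filtering).
#' @param background animal-free background (filtered scale), full frame.
#' @param roi_box search box `c(x0, y0, x1, y1)`.
#' @param params [animal_parameters()].
#' @param prev_centroid optional previous centroid for tie-breaking.
#' @return a `vrt_blob` list (`centroid`, `area`, `mask`, `mask_origin`,
#'   `roi_box`, `next_roi`) or `NULL` when no valid blob is present (the
#'   "lost" outcome).
#' @export
track_frame <- function(pixels, background, roi_box, params,
                        prev_centroid = NULL) {
  cur <- gaussian_smooth_box(pixels, roi_box, params$gaussian_sigma_px)
  bg <- crop_box(background, roi_box)
  d <- cur - bg
  thr <- mean(d) - 3 * stats::sd(as.vector(d))
  mask <- d < thr
  if (!any(mask)) return(NULL)
  lab <- label_components(mask)
  st <- component_stats(lab, origin = roi_box[1:2])
  areas <- vapply(st, function(s) s$area, numeric(1))
  ok <- which(areas >= params$min_area_px & areas <= params$max_area_px)
  if (length(ok) == 0) return(NULL)
  amax <- max(areas[ok])
  cand <- ok[areas[ok] == amax]
  pick <- cand[1]
  if (length(cand) > 1 && !is.null(prev_centroid)) {
    dd <- vapply(cand, function(i)
      sum((st[[i]]$centroid - prev_centroid)^2), numeric(1))
    pick <- cand[which.min(dd)]
  }
  s <- st[[pick]]
  structure(list(
    centroid = s$centroid,
    area = s$area,
    mask = lab == s$id,
    mask_origin = roi_box[1:2],
    roi_box = roi_box,
    next_roi = expand_box(s$bbox, params$roi_padding_px, dim(pixels))),
    class = "vrt_blob")
}

#' Run a closed-loop virtual-reality experiment on a frame source
#'
#' The orchestrator reproduces the device's life cycle on recorded or
#' synthetic frames: (1) auto-detection and background reconstruction on the
#' leading frames ([detect_animal()]); (2) per-frame ROI tracking
#' ([track_frame()]) with skeleton-endpoint head/tail classification; (3)
#' stimulus command generation: for every frame `t` with a valid fix, the
#' commanded intensity at frame `t + lag_frames` is the landscape value at
#' the tracked point's position at `t`. Frames before the first command
#' carry intensity 0; during lost frames the last command holds. Commands
#' are strictly causal: `I(t)` is a function of frames at or before
#' `t - lag_frames` only.
#'
#' Lost-animal recovery: on a lost frame, the search box is kept but grown
#' by one more padding step; after 3 consecutive losses the whole frame is
#' searched. Lost frames are marked invalid, never interpolated.
#'
#' Head/tail bootstrap: on the first tracked frame, the head is the endpoint
#' leading the net motion since first detection (the animal has necessarily
#' moved about a body length for the background to exist); thereafter the
#' previous-tail nearest-distance rule applies. A one-time orientation audit
#' swaps the labels of the recorded trajectory if the head systematically
#' trails the direction of motion (the stimulus log is never rewritten).
#'
#' @param source a `vrt_frame_source`.
#' @param params [animal_parameters()].
#' @param landscape a `vrt_landscape`, or `NULL` to track without stimulus.
#' @param lag_frames whole-frame stimulus lag (>= 1); the closed-loop update
#'   lands within the following frame interval by default.
#' @param tracked_point which body point drives the stimulus: `"head"`
#'   (larva experiments), `"centroid"` (fly, fish) or `"tail"`. Falls back
#'   to the centroid on frames with degenerate posture.
#' @param ht_mode head/tail assignment mode, see [assign_head_tail()].
#' @return a `vrt_run` list with `trajectory` ([trajectory()]), `stimulus`
#'   ([stimulus_log()]) and `detection` (the [detect_animal()] result).
#' @export
run_closed_loop <- function(source, params, landscape = NULL,
                            lag_frames = 1L,
                            tracked_point = c("head", "centroid", "tail"),
                            ht_mode = "nearest") {
  tracked_point <- match.arg(tracked_point)
  stopifnot(lag_frames >= 1)
  nf <- n_frames(source)
  rate <- source$frame_rate_hz
  det <- detect_animal(source, params)
  dims <- dim(det$background)

  traj <- data.frame(
    frame = 0:(nf - 1), time_s = (0:(nf - 1)) / rate,
    x = NA_real_, y = NA_real_, head_x = NA_real_, head_y = NA_real_,
    tail_x = NA_real_, tail_y = NA_real_, area_px = NA_real_,
    roi_x0 = NA_integer_, roi_y0 = NA_integer_, roi_x1 = NA_integer_,
    roi_y1 = NA_integer_, valid = FALSE)
  cmd <- rep(NA_real_, nf)

  roi <- expand_box(det$roi_box, params$roi_padding_px, dims)
  prev_centroid <- det$initial_centroid
  prev_tail <- NULL; prev_head <- NULL
  lost_streak <- 0L
  # one-time background refinement: the initial patch is pasted while the
  # animal's Gaussian skirt may still graze it; once the animal has cleared
  # the patch by a full kernel radius, re-paste it from a pristine frame
  refine_pending <- TRUE
  refine_margin <- ceiling(3 * params$gaussian_sigma_px) + 4
  patch_bbox <- mask_bbox(det$patched_mask)
  # orientation audit state
  audit_done <- FALSE; audit_proj <- 0; audit_path <- 0
  body_len <- NULL
  first_fix <- TRUE

  for (i in det$ready_frame:(nf - 1)) {
    fr <- get_frame(source, i)
    obs <- track_frame(fr$pixels, det$background, roi, params,
                       prev_centroid = prev_centroid)
    if (is.null(obs)) {
      lost_streak <- lost_streak + 1L
      roi <- if (lost_streak >= 3L) c(0L, 0L, dims[2] - 1L, dims[1] - 1L)
             else expand_box(roi, params$roi_padding_px, dims)
      next
    }
    lost_streak <- 0L
    if (refine_pending) {
      blob_box <- mask_bbox(obs$mask) + rep(obs$mask_origin, 2)
      gap_x <- max(0, max(blob_box[1], patch_bbox[1]) -
                     min(blob_box[3], patch_bbox[3]))
      gap_y <- max(0, max(blob_box[2], patch_bbox[2]) -
                     min(blob_box[4], patch_bbox[4]))
      if (sqrt(gap_x^2 + gap_y^2) >= refine_margin) {
        fresh <- gaussian_smooth_box(fr$pixels, patch_bbox,
                                     params$gaussian_sigma_px)
        sub <- crop_box(det$background, patch_bbox)
        msk <- crop_box(det$patched_mask, patch_bbox)
        sub[msk] <- fresh[msk]
        det$background[(patch_bbox[2] + 1):(patch_bbox[4] + 1),
                       (patch_bbox[1] + 1):(patch_bbox[3] + 1)] <- sub
        refine_pending <- FALSE
      }
    }
    row <- i + 1L
    # posture on the blob's bounding-box crop
    bb <- mask_bbox(obs$mask)
    crop <- obs$mask[(bb[2] + 1):(bb[4] + 1), (bb[1] + 1):(bb[3] + 1),
                     drop = FALSE]
    origin <- c(obs$mask_origin[1] + bb[1], obs$mask_origin[2] + bb[2])
    if (first_fix) {
      motion_dir <- obs$centroid - det$initial_centroid
      se <- skeleton_endpoints(crop)
      if (!se$degenerate) {
        ep <- se$endpoints
        ep[, 1] <- ep[, 1] + origin[1]; ep[, 2] <- ep[, 2] + origin[2]
        proj <- (ep[, 1] - obs$centroid[1]) * motion_dir[1] +
          (ep[, 2] - obs$centroid[2]) * motion_dir[2]
        hi <- which.max(proj)
        post <- list(head = as.numeric(ep[hi, ]),
                     tail = as.numeric(ep[-hi, ]), degenerate = FALSE)
      } else {
        post <- list(head = NULL, tail = NULL, degenerate = TRUE)
      }
      first_fix <- FALSE
    } else {
      ref <- if (!is.null(prev_tail)) prev_tail else obs$centroid
      post <- blob_posture(crop, origin, ref, prev_head = prev_head,
                           mode = ht_mode)
    }
    traj$x[row] <- obs$centroid[1]; traj$y[row] <- obs$centroid[2]
    traj$area_px[row] <- obs$area
    traj$roi_x0[row] <- obs$roi_box[1]; traj$roi_y0[row] <- obs$roi_box[2]
    traj$roi_x1[row] <- obs$roi_box[3]; traj$roi_y1[row] <- obs$roi_box[4]
    traj$valid[row] <- TRUE
    if (!post$degenerate) {
      traj$head_x[row] <- post$head[1]; traj$head_y[row] <- post$head[2]
      traj$tail_x[row] <- post$tail[1]; traj$tail_y[row] <- post$tail[2]
      if (is.null(body_len))
        body_len <- sqrt(sum((post$head - post$tail)^2))
      # audit: does the head lead the motion?
      if (!audit_done && !is.null(prev_centroid)) {
        step <- obs$centroid - prev_centroid
        hvec <- post$head - obs$centroid
        hn <- sqrt(sum(hvec^2))
        if (hn > 0) {
          audit_proj <- audit_proj + sum(hvec / hn * step)
          audit_path <- audit_path + sqrt(sum(step^2))
        }
        if (audit_path >= 1.5 * body_len && sum(traj$valid) >= 10L) {
          if (audit_proj < 0) {
            hx <- traj$head_x; hy <- traj$head_y
            traj$head_x <- traj$tail_x; traj$head_y <- traj$tail_y
            traj$tail_x <- hx; traj$tail_y <- hy
            tmp <- post$head; post$head <- post$tail; post$tail <- tmp
          }
          audit_done <- TRUE
        }
      }
      prev_head <- post$head; prev_tail <- post$tail
    }
    # stimulus command from the tracked point at this frame
    if (!is.null(landscape) && i + lag_frames <= nf - 1) {
      pos <- switch(tracked_point,
        head = if (post$degenerate) obs$centroid else post$head,
        tail = if (post$degenerate) obs$centroid else post$tail,
        centroid = obs$centroid)
      cmd[i + lag_frames + 1L] <- intensity_at(landscape, pos)
    }
    prev_centroid <- obs$centroid
    roi <- obs$next_roi
  }

  # materialize the command series: 0 before the first command, hold-last
  # across lost gaps
  intensity <- numeric(nf)
  lastv <- 0
  for (t in seq_len(nf)) {
    if (!is.na(cmd[t])) lastv <- cmd[t]
    intensity[t] <- lastv
  }

  out <- list(
    trajectory = trajectory(traj, px_per_mm = params$px_per_mm,
                            frame_rate_hz = params$frame_rate_hz),
    stimulus = stimulus_log(
      data.frame(frame = 0:(nf - 1), time_s = (0:(nf - 1)) / rate,
                 intensity = intensity),
      lag_frames = lag_frames, tracked_point = tracked_point),
    detection = det)
  class(out) <- "vrt_run"
  out
}

#' @export
print.vrt_run <- function(x, ...) {
  cat("<vrt_run>\n")
  print(x$detection)
  print(x$trajectory)
  invisible(x)
}
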