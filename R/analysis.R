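# Trajectory analysis: smoothing filters, locomotion speed, sensory
# experience, distance to source, checkerboard preference index, swim-bout
# segmentation, turn-angle statistics, turn index and trial-inclusion
# filters.

## smoothing filters ---------------------------------------------------------

triang_weights <- function(window) {
  # symmetric triangular taper of length `window` (peak at the middle)
  k <- seq_len(window)
  pmin(k, window + 1 - k)
}

rolling_weighted <- function(x, w, center) {
  # centered weighted moving average; truncated windows are renormalized;
  # NA inputs stay NA and are excluded (with renormalization) from their
  # neighbors' windows
  n <- length(x)
  wl <- length(w)
  out <- rep(NA_real_, n)
  offs <- seq_len(wl) - center
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    idx <- i + offs
    ok <- idx >= 1 & idx <= n
    xi <- x[idx[ok]]
    wi <- w[ok]
    keep <- !is.na(xi)
    out[i] <- sum(xi[keep] * wi[keep]) / sum(wi[keep])
  }
  out
}

#' Triangular rolling filter
#'
#' Centered weighted moving average with triangular weights peaking at the
#' current sample. `window_frames = 1` is the identity; a constant series is
#' unchanged; at the edges the truncated window is renormalized.
#'
#' @param series numeric vector (NAs preserved).
#' @param window_frames window length in frames (>= 1).
#' @return filtered series.
#' @export
smooth_triangular <- function(series, window_frames) {
  stopifnot(window_frames >= 1)
  w <- triang_weights(window_frames)
  rolling_weighted(series, w, center = (window_frames + 1) %/% 2)
}

#' Half-triangular (causal ramp) rolling filter
#'
#' Linearly increasing weights over the trailing window, ending at the
#' current frame: no future samples leak into the estimate. Used for fish
#' coordinate smoothing.
#'
#' @inheritParams smooth_triangular
#' @export
smooth_half_triangular <- function(series, window_frames) {
  stopifnot(window_frames >= 1)
  w <- seq_len(window_frames)
  rolling_weighted(series, w, center = window_frames)
}

#' Boxcar rolling filter
#'
#' Centered moving average with uniform weights; used on the stimulus
#' intensity time course before differentiation.
#'
#' @inheritParams smooth_triangular
#' @export
smooth_boxcar <- function(series, window_frames) {
  stopifnot(window_frames >= 1)
  rolling_weighted(series, rep(1, window_frames),
                   center = (window_frames + 1) %/% 2)
}

#' Coordinate-smoothing window from the animal's speed bound
#'
#' The window spans the time the animal needs to traverse one pixel at its
#' high-bound speed: `round(frame_rate / (speed_bound * px_per_mm))` frames,
#' at least 1. At 30 Hz this is typically ~0.3 s for a larva (1 mm/s bound)
#' and 0.06-0.09 s for a walking fly (~5 mm/s).
#'
#' @param frame_rate_hz frames per second.
#' @param speed_bound_mm_s organism high-bound speed.
#' @param px_per_mm spatial calibration.
#' @return integer window length in frames.
#' @export
position_smoothing_window <- function(frame_rate_hz, speed_bound_mm_s,
                                      px_per_mm) {
  stopifnot(frame_rate_hz > 0, speed_bound_mm_s > 0, px_per_mm > 0)
  max(1L, as.integer(round(frame_rate_hz / (speed_bound_mm_s * px_per_mm))))
}

## speed ---------------------------------------------------------------------

#' Locomotion speed from a trajectory
#'
#' Per-organism pipeline: coordinates are smoothed (triangular window sized
#' by [position_smoothing_window()] for larva and fly; causal 1 s
#' half-triangular for fish), the per-frame Euclidean displacement is
#' converted to mm/s, and the speed series is smoothed again (1 s triangular
#' for larva and fly; 0.3 s triangular for fish). Missing frames propagate
#' as missing speed.
#'
#' @param traj a [trajectory()].
#' @param organism `"larva"`, `"fly"` or `"fish"`.
#' @param point which coordinates to use: `"centroid"`, `"head"` or
#'   `"tail"`.
#' @param speed_bound_mm_s override for the organism's high-bound speed
#'   (defaults: 1 larva, 5 fly).
#' @return numeric vector of speeds in mm/s, one per frame (first frame NA).
#' @export
compute_speed <- function(traj, organism = c("larva", "fly", "fish"),
                          point = "centroid", speed_bound_mm_s = NULL) {
  organism <- match.arg(organism)
  rate <- attr(traj, "frame_rate_hz")
  ppm <- attr(traj, "px_per_mm")
  xy <- traj_point(traj, point)
  if (organism == "fish") {
    w <- max(1L, as.integer(round(rate)))
    xs <- smooth_half_triangular(xy[, 1], w)
    ys <- smooth_half_triangular(xy[, 2], w)
  } else {
    sb <- speed_bound_mm_s %||% if (organism == "larva") 1 else 5
    w <- position_smoothing_window(rate, sb, ppm)
    xs <- smooth_triangular(xy[, 1], w)
    ys <- smooth_triangular(xy[, 2], w)
  }
  disp <- c(NA_real_, sqrt(diff(xs)^2 + diff(ys)^2))
  speed <- disp * rate / ppm
  w2 <- max(1L, as.integer(round(if (organism == "fish") 0.3 * rate
                                 else rate)))
  smooth_triangular(speed, w2)
}

traj_point <- function(traj, point) {
  switch(match.arg(point, c("centroid", "head", "tail")),
         centroid = cbind(traj$x, traj$y),
         head = cbind(traj$head_x, traj$head_y),
         tail = cbind(traj$tail_x, traj$tail_y))
}

## sensory experience --------------------------------------------------------

#' Relative sensory experience (1/I) dI/dt
#'
#' Boxcar-smooths the stimulus intensity over 1 s, then returns the
#' normalized temporal derivative by central differences. Frames where the
#' smoothed intensity is 0 yield missing values (the relative change is
#' undefined without stimulus).
#'
#' @param I_series commanded or experienced intensity per frame (>= 0).
#' @param frame_rate_hz frames per second.
#' @return numeric vector, per-second relative change; NA at the ends and
#'   where I = 0.
#' @export
sensory_experience <- function(I_series, frame_rate_hz) {
  stopifnot(all(I_series >= 0, na.rm = TRUE))
  w <- max(1L, as.integer(round(frame_rate_hz)))
  s <- smooth_boxcar(I_series, w)
  n <- length(s)
  didt <- rep(NA_real_, n)
  if (n >= 3) {
    didt[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2 * frame_rate_hz
  }
  out <- didt / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

## distance to source --------------------------------------------------------

#' Distance to the (virtual) source
#'
#' Per-frame Euclidean distance in mm from the tracked point to the source,
#' defined per experiment: a user-marked position for a real odor source
#' (`"real_source"`), the landscape intensity maximum (`"landscape_max"`),
#' the nearest point of the volcano rim circle (`"volcano_rim"`, distance
#' `| |p - c| - R |`), or the landscape reference translated relative to the
#' animal's starting position for unstimulated controls
#' (`"relative_control"`, with `control_offset` the start-to-source vector
#' in px). Fish coordinates are pre-smoothed with the causal 1 s
#' half-triangular filter, like the speed pipeline.
#'
#' @param traj a [trajectory()].
#' @param landscape the `vrt_landscape` (required except for
#'   `"real_source"`).
#' @param mode one of `"landscape_max"`, `"volcano_rim"`, `"real_source"`,
#'   `"relative_control"`.
#' @param source_xy marked source position (px), for `"real_source"`.
#' @param control_offset start-to-source vector (px), for
#'   `"relative_control"`.
#' @param tracked_point `"head"` (larva experiments) or `"centroid"`.
#' @param organism set `"fish"` to enable the causal coordinate filter.
#' @return numeric vector of distances (mm) per frame.
#' @export
distance_to_source <- function(traj, landscape = NULL,
                               mode = c("landscape_max", "volcano_rim",
                                        "real_source", "relative_control"),
                               source_xy = NULL, control_offset = NULL,
                               tracked_point = "centroid",
                               organism = NULL) {
  mode <- match.arg(mode)
  ppm <- attr(traj, "px_per_mm")
  rate <- attr(traj, "frame_rate_hz")
  xy <- traj_point(traj, tracked_point)
  if (identical(organism, "fish")) {
    w <- max(1L, as.integer(round(rate)))
    xy <- cbind(smooth_half_triangular(xy[, 1], w),
                smooth_half_triangular(xy[, 2], w))
  }
  dist_px <- switch(mode,
    real_source = {
      stopifnot(!is.null(source_xy))
      sqrt((xy[, 1] - source_xy[1])^2 + (xy[, 2] - source_xy[2])^2)
    },
    landscape_max = {
      stopifnot(!is.null(landscape))
      s <- landscape_source(landscape)
      sqrt((xy[, 1] - s[1])^2 + (xy[, 2] - s[2])^2)
    },
    volcano_rim = {
      if (is.null(landscape) || landscape$kind != "volcano")
        stop("volcano_rim mode requires a volcano landscape")
      r <- sqrt((xy[, 1] - landscape$center[1])^2 +
                  (xy[, 2] - landscape$center[2])^2)
      abs(r - landscape$rim_radius)
    },
    relative_control = {
      stopifnot(!is.null(control_offset))
      start <- xy[which(!is.na(xy[, 1]))[1], ]
      s <- start + control_offset
      if (!is.null(landscape) && landscape$kind == "volcano") {
        r <- sqrt((xy[, 1] - s[1])^2 + (xy[, 2] - s[2])^2)
        abs(r - landscape$rim_radius)
      } else {
        sqrt((xy[, 1] - s[1])^2 + (xy[, 2] - s[2])^2)
      }
    })
  dist_px / ppm
}

## preference index ----------------------------------------------------------

#' Checkerboard occupancy and preference index
#'
#' Classifies every valid frame's centroid as ON (landscape intensity > 0)
#' or OFF and computes `PI = (T_on - T_off) / (T_on + T_off)`, where the T
#' are occupancy times.
#'
#' @param traj a [trajectory()].
#' @param landscape a checkerboard (or any) `vrt_landscape`.
#' @return list with `T_on_s`, `T_off_s` and `PI`.
#' @export
preference_index <- function(traj, landscape) {
  rate <- attr(traj, "frame_rate_hz")
  ok <- traj$valid & !is.na(traj$x)
  if (!any(ok)) stop("preference index undefined: zero valid frames")
  I <- intensity_at(landscape, cbind(traj$x[ok], traj$y[ok]))
  n_on <- sum(I > 0)
  n_off <- sum(I <= 0)
  list(T_on_s = n_on / rate, T_off_s = n_off / rate,
       PI = (n_on - n_off) / (n_on + n_off))
}

## bouts ---------------------------------------------------------------------

#' Bout detection and turn-statistics parameters
#'
#' Defaults follow the zebrafish analysis: speed peaks of at least
#' 2.5 mm/s separated by at least 5 frames define bouts; positions
#' 0.66 s before and after each peak delimit a bout's displacement; bouts
#' with reorientation angle of 135 degrees or more are discarded (reflection
#' artifacts near the dish wall); 90 degrees is the boundary between
#' swimming toward and away from the source.
#'
#' @param min_peak_speed_mm_s minimum peak height.
#' @param min_separation_frames minimum frames between consecutive peaks.
#' @param turn_window_s half-window around the peak for pre/post positions.
#' @param max_turn_angle_deg discard bouts with theta at or above this.
#' @param toward_boundary_deg toward/away boundary for the turn index.
#' @return a `vrt_bout_params` list.
#' @export
bout_params <- function(min_peak_speed_mm_s = 2.5,
                        min_separation_frames = 5L,
                        turn_window_s = 0.66,
                        max_turn_angle_deg = 135,
                        toward_boundary_deg = 90) {
  stopifnot(min_peak_speed_mm_s > 0, min_separation_frames > 0,
            turn_window_s > 0, max_turn_angle_deg > 0,
            max_turn_angle_deg <= 180, toward_boundary_deg > 0)
  structure(list(min_peak_speed_mm_s = min_peak_speed_mm_s,
                 min_separation_frames = as.integer(min_separation_frames),
                 turn_window_s = turn_window_s,
                 max_turn_angle_deg = max_turn_angle_deg,
                 toward_boundary_deg = toward_boundary_deg),
            class = "vrt_bout_params")
}

#' Detect swim-bout peaks in a speed series
#'
#' Local maxima of at least `min_peak_speed_mm_s`, with any two retained
#' peaks at least `min_separation_frames` apart; when candidates conflict,
#' the higher peak wins (greedy by descending height, ties broken toward the
#' earlier frame). Plateau maxima are assigned to the plateau's middle
#' sample.
#'
#' @param speed_series speeds in mm/s (NAs treated as non-peaks).
#' @param params a [bout_params()].
#' @return integer vector of 0-based peak frame indices, ascending.
#' @export
detect_bouts <- function(speed_series, params = bout_params()) {
  x <- speed_series
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (is.na(x[i])) { i <- i + 1L; next }
    if (!is.na(x[i - 1]) && x[i] > x[i - 1]) {
      # scan forward over a possible plateau
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && !is.na(x[j + 1]) && x[j + 1] < x[i]) {
        cand <- c(cand, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  cand <- cand[x[cand] >= params$min_peak_speed_mm_s]
  if (length(cand) <= 1) return(cand - 1L)
  # greedy separation: highest first, earlier frame on ties
  o <- order(-x[cand], cand)
  keep <- logical(length(cand))
  taken <- integer(0)
  for (k in o) {
    if (all(abs(cand[k] - taken) >= params$min_separation_frames)) {
      keep[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  sort(cand[keep]) - 1L
}

angle_between_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosv <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Per-bout kinematics: turn angle, intensity change, bearing error
#'
#' For each pair of consecutive bout peaks, the displacement vector of a
#' bout connects the animal's coordinates `turn_window_s` before and after
#' the peak; the reorientation angle theta is the unsigned angle between
#' consecutive displacement vectors. The intensity change `delta_I` is the
#' change experienced during the previous bout — intensity at the previous
#' bout's post-window frame minus at its pre-window frame — so its sign
#' (up- versus down-gradient) reflects only motion completed before the
#' turn; `I_prev`, the intensity at the previous bout's peak, is used for
#' binning. The
#' bearing error alpha is the angle between the current bout's heading and
#' the bearing to the source at the bout's start. Bouts whose theta reaches
#' `max_turn_angle_deg`, or whose windows fall outside the record or on
#' invalid frames, are discarded.
#'
#' @param traj a [trajectory()].
#' @param peaks 0-based peak frames from [detect_bouts()].
#' @param params a [bout_params()].
#' @param intensity per-frame intensity series (e.g. the stimulus log); if
#'   `NULL` and `landscape` is given, sampled at the tracked point.
#' @param landscape optional `vrt_landscape` for intensity and source.
#' @param source_xy source position (px) for alpha; default
#'   [landscape_source()] of `landscape`.
#' @param tracked_point coordinates used, default `"centroid"`.
#' @return a `vrt_bouts` data frame: `peak_frame`, `prev_peak_frame`,
#'   `pre_x`, `pre_y`, `post_x`, `post_y`, `theta_deg`, `delta_I`, `I_prev`,
#'   `alpha_deg`.
#' @export
bout_kinematics <- function(traj, peaks, params = bout_params(),
                            intensity = NULL, landscape = NULL,
                            source_xy = NULL, tracked_point = "centroid") {
  rate <- attr(traj, "frame_rate_hz")
  w <- as.integer(round(params$turn_window_s * rate))
  xy <- traj_point(traj, tracked_point)
  n <- nrow(xy)
  if (is.null(intensity) && !is.null(landscape))
    intensity <- intensity_at(landscape, xy)
  if (is.null(source_xy) && !is.null(landscape) &&
      landscape$kind %in% c("gaussian", "exponential", "raster"))
    source_xy <- landscape_source(landscape)

  res <- list()
  prev_vec <- NULL; prev_peak <- NA_integer_
  for (p in peaks) {
    i0 <- p - w + 1L; i1 <- p + w + 1L  # 1-based rows
    if (i0 < 1 || i1 > n) { prev_vec <- NULL; prev_peak <- NA; next }
    pre <- xy[i0, ]; post <- xy[i1, ]
    if (any(is.na(pre)) || any(is.na(post))) {
      prev_vec <- NULL; prev_peak <- NA; next
    }
    v <- post - pre
    if (!is.null(prev_vec)) {
      theta <- angle_between_deg(prev_vec, v)
      dI <- if (is.null(intensity)) NA_real_ else
        intensity[prev_peak + w + 1L] - intensity[prev_peak - w + 1L]
      Iprev <- if (is.null(intensity)) NA_real_ else intensity[prev_peak + 1L]
      alpha <- if (is.null(source_xy)) NA_real_ else
        angle_between_deg(v, source_xy - pre)
      if (!is.na(theta) && theta < params$max_turn_angle_deg) {
        res[[length(res) + 1L]] <- data.frame(
          peak_frame = p, prev_peak_frame = prev_peak,
          pre_x = pre[1], pre_y = pre[2], post_x = post[1], post_y = post[2],
          theta_deg = theta, delta_I = dI, I_prev = Iprev, alpha_deg = alpha)
      }
    }
    prev_vec <- v; prev_peak <- p
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(peak_frame = integer(0), prev_peak_frame = integer(0),
               pre_x = numeric(0), pre_y = numeric(0), post_x = numeric(0),
               post_y = numeric(0), theta_deg = numeric(0),
               delta_I = numeric(0), I_prev = numeric(0),
               alpha_deg = numeric(0))
  structure(out, class = c("vrt_bouts", "data.frame"))
}

#' Turn index
#'
#' `beta = (#toward - #away) / N` over bouts carrying a bearing error alpha:
#' toward means alpha below the 90-degree boundary, away means above. Bouts
#' exactly on the boundary count toward neither direction but stay in the
#' denominator.
#'
#' @param bouts a [bout_kinematics()] table.
#' @param boundary_deg toward/away boundary, default 90.
#' @return beta in `[-1, 1]`, or NA when no bout carries alpha.
#' @export
turn_index <- function(bouts, boundary_deg = 90) {
  a <- bouts$alpha_deg
  a <- a[!is.na(a)]
  if (length(a) == 0) return(NA_real_)
  (sum(a < boundary_deg) - sum(a > boundary_deg)) / length(a)
}

## inclusion filters ---------------------------------------------------------

#' Trial-inclusion criteria
#'
#' A trial enters the final data set only if the animal moved at least
#' `min_total_path_mm` over the experiment, with per-frame movements at or
#' below `min_step_mm` treated as detection noise (the centroid of a resting
#' animal jitters), and the animal tracked for at least
#' `min_tracked_fraction` of the trial.
#'
#' @param min_total_path_mm default 20.
#' @param min_step_mm default 1.
#' @param min_tracked_fraction default 3/5.
#' @return a `vrt_inclusion` list.
#' @export
inclusion_criteria <- function(min_total_path_mm = 20, min_step_mm = 1,
                               min_tracked_fraction = 3 / 5) {
  stopifnot(min_total_path_mm > 0, min_step_mm > 0,
            min_tracked_fraction > 0, min_tracked_fraction <= 1)
  structure(list(min_total_path_mm = min_total_path_mm,
                 min_step_mm = min_step_mm,
                 min_tracked_fraction = min_tracked_fraction),
            class = "vrt_inclusion")
}

#' Apply trial-inclusion filters
#'
#' Sub-threshold movements are removed by anchoring: the position only
#' advances once the animal is more than `min_step_mm` from the last
#' recorded position. The cleaned trajectory carries the anchored
#' coordinates; the total path is the sum of anchor jumps.
#'
#' @param traj a [trajectory()].
#' @param criteria an [inclusion_criteria()].
#' @return list with `included` (flag), `total_path_mm`, `tracked_fraction`
#'   and `cleaned` (the anchored trajectory).
#' @export
apply_inclusion <- function(traj, criteria = inclusion_criteria()) {
  ppm <- attr(traj, "px_per_mm")
  x <- traj$x; y <- traj$y
  ok <- which(traj$valid & !is.na(x))
  total <- 0
  if (length(ok) >= 2) {
    ax <- x[ok[1]]; ay <- y[ok[1]]
    for (i in ok[-1]) {
      d <- sqrt((x[i] - ax)^2 + (y[i] - ay)^2) / ppm
      if (d > criteria$min_step_mm) {
        total <- total + d
        ax <- x[i]; ay <- y[i]
      } else {
        x[i] <- ax; y[i] <- ay
      }
    }
  }
  frac <- mean(traj$valid)
  cleaned <- traj
  cleaned$x <- x; cleaned$y <- y
  list(included = total >= criteria$min_total_path_mm &&
         frac >= criteria$min_tracked_fraction,
       total_path_mm = total, tracked_fraction = frac, cleaned = cleaned)
}

## binned turn statistics ----------------------------------------------------

#' Bin turn angles by experienced intensity
#'
#' Groups each bout's theta by the intensity experienced during the previous
#' bout (`I_prev`), optionally splitting every bin by the sign of
#' `delta_I` (up- vs down-gradient). Returns per-group count, mean and
#' standard deviation; empty bins are reported with zero count.
#'
#' @param bouts a [bout_kinematics()] table.
#' @param bin_edges monotone increasing intensity bin edges (length k + 1
#'   for k bins).
#' @param split_by_delta also split by `sign(delta_I)`.
#' @return data frame with `bin`, `lo`, `hi`, (`gradient`,) `n`,
#'   `mean_theta`, `sd_theta`.
#' @export
bin_by_intensity <- function(bouts, bin_edges, split_by_delta = FALSE) {
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  k <- length(bin_edges) - 1L
  bin_of <- function(I) findInterval(I, bin_edges, rightmost.closed = TRUE,
                                     all.inside = FALSE)
  grp_stats <- function(th) {
    data.frame(n = length(th),
               mean_theta = if (length(th)) mean(th) else NA_real_,
               sd_theta = if (length(th) > 1) stats::sd(th) else NA_real_)
  }
  b <- bin_of(bouts$I_prev)
  rows <- list()
  for (i in seq_len(k)) {
    sel <- !is.na(b) & b == i
    if (split_by_delta) {
      for (g in c("down", "up")) {
        s2 <- sel & !is.na(bouts$delta_I) &
          (if (g == "down") bouts$delta_I < 0 else bouts$delta_I > 0)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(bin = i, lo = bin_edges[i], hi = bin_edges[i + 1],
                     gradient = g), grp_stats(bouts$theta_deg[s2]))
      }
    } else {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(bin = i, lo = bin_edges[i], hi = bin_edges[i + 1]),
        grp_stats(bouts$theta_deg[sel]))
    }
  }
  do.call(rbind, rows)
}

#' Compare turn angles between groups with a standard test
#'
#' Thin wrapper over [stats::t.test()] / [stats::wilcox.test()] with
#' Bonferroni correction across the supplied comparisons; the hypothesis
#' tests themselves are delegated to the standard library, not
#' re-implemented.
#'
#' @param groups named list of numeric theta vectors.
#' @param pairs list of length-2 character vectors naming the group pairs to
#'   compare.
#' @param test `"t"` or `"wilcox"`.
#' @param alternative passed to the test (first group vs second).
#' @return data frame with one row per comparison: `group1`, `group2`, `n1`,
#'   `n2`, `p_value`, `p_adjusted` (Bonferroni).
#' @export
compare_theta_groups <- function(groups, pairs, test = c("t", "wilcox"),
                                 alternative = "two.sided") {
  test <- match.arg(test)
  p <- vapply(pairs, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (test == "t")
      stats::t.test(x, y, alternative = alternative)$p.value
    else
      stats::wilcox.test(x, y, alternative = alternative, exact = FALSE)$p.value
  }, numeric(1))
  data.frame(
    group1 = vapply(pairs, `[`, character(1), 1),
    group2 = vapply(pairs, `[`, character(1), 2),
    n1 = vapply(pairs, function(pr) length(groups[[pr[1]]]), numeric(1)),
    n2 = vapply(pairs, function(pr) length(groups[[pr[2]]]), numeric(1)),
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = "bonferroni"))
}
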