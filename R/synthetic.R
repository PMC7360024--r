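# Ground-truthed synthetic experiments: seeded agent simulations with
# organism-like kinematics (crawling larva, walking fly, bout-swimming
# fish) and a renderer that turns a ground-truth trajectory into the
# imaging model the detector expects — a static bright infrared backlight,
# a darker animal silhouette, Gaussian camera noise, 8-bit quantization.
#
# The generators are emulation devices: their kinematic constants are
# config-exposed with defaults chosen to match reported magnitudes (peak
# speeds of ~1.6 mm/s for larvae and ~12 mm/s for flies, ~1.5 s inter-bout
# intervals for fish), not claims about any particular data set.

# run body with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Default synthetic arena
#'
#' A 100 mm circular dish rendered in a 640 x 480 frame: the dish's 480 px
#' vertical extent fixes the scale at 4.8 px/mm.
#'
#' @return an [arena()] (circle, center of the frame, radius 240 px).
#' @export
synthetic_arena <- function() {
  arena(640, 480, shape = "circle", center = c(319.5, 239.5), radius = 240)
}

synth_const <- list(px_per_mm = 4.8, frame_rate_hz = 30,
                    wall_margin_mm = 4)

gt_trajectory <- function(n, rate, ppm) {
  data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / rate,
             x = NA_real_, y = NA_real_, head_x = NA_real_,
             head_y = NA_real_, tail_x = NA_real_, tail_y = NA_real_,
             area_px = NA_real_, roi_x0 = NA_integer_, roi_y0 = NA_integer_,
             roi_x1 = NA_integer_, roi_y1 = NA_integer_, valid = TRUE,
             intensity = NA_real_, mid_x = NA_real_, mid_y = NA_real_)
}

# reflect the heading off the dish wall (specular, with a little noise)
# when the next step would leave the walkable area; specular reflection
# preserves the tangential component, so wall encounters do not bias
# motion toward the dish center
wall_steer <- function(pos, heading, step_px, arena, margin_px) {
  nxt <- pos + step_px * c(cos(heading), sin(heading))
  r <- sqrt(sum((nxt - arena$center)^2))
  if (r > arena$radius - margin_px) {
    n <- (pos - arena$center)
    nn <- sqrt(sum(n^2))
    if (nn == 0) return(heading + pi)
    n <- n / nn
    h <- c(cos(heading), sin(heading))
    h <- h - 2 * sum(h * n) * n
    heading <- atan2(h[2], h[1]) + stats::rnorm(1, 0, 0.15)
    # still outward (grazing case): fall back to the inward normal
    if (sum(c(cos(heading), sin(heading)) * n) > 0.5)
      heading <- atan2(-n[2], -n[1]) + stats::rnorm(1, 0, 0.3)
  }
  heading
}

#' Simulate a crawling larva
#'
#' Runs with sinusoidally modulated crawling speed (forward peristalsis;
#' mean ~0.7 mm/s, peaks below 1.6 mm/s) alternate with stochastic
#' stop-and-cast events during which forward motion ceases and the head
#' sweeps laterally, after which a new heading is adopted. With
#' `gain > 0` the agent chemotaxes: stops are triggered preferentially when
#' its relative sensory experience (1/I) dI/dt turns negative, and the cast
#' accepts the side on which the sampled intensity is higher.
#'
#' @param landscape a `vrt_landscape` (the virtual gradient the agent
#'   senses); use a flat raster for unstimulated controls.
#' @param seed RNG seed; identical seeds reproduce the output bit-exactly.
#' @param n_frames trial length in frames (30 Hz).
#' @param gain chemotaxis gain; 0 gives an isotropic run-and-turn walk.
#' @param start_xy optional start position (px); default drawn in the dish.
#' @param sim further kinematic constants, see [larva_sim_params()].
#' @return a `vrt_ground_truth` list: `trajectory` (a [trajectory()] with an
#'   extra `intensity` column), `seed`, `organism`, `sim`.
#' @export
simulate_larva <- function(landscape, seed, n_frames = 1800, gain = 0,
                           start_xy = NULL, sim = larva_sim_params()) {
  a <- synthetic_arena()
  ppm <- synth_const$px_per_mm; rate <- synth_const$frame_rate_hz
  margin <- synth_const$wall_margin_mm * ppm
  L <- sim$body_length_mm * ppm
  with_seed(seed, {
    tr <- gt_trajectory(n_frames, rate, ppm)
    pos <- start_xy %||% (a$center +
      stats::runif(1, 0, a$radius - 3 * margin) *
        c(cos(th0 <- stats::runif(1, 0, 2 * pi)), sin(th0)))
    heading <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    Ihist <- rep(NA_real_, n_frames)
    state <- "run"; cast_left <- 0L; cast_side <- 1
    for (t in seq_len(n_frames)) {
      I <- intensity_at(landscape, pos)
      Ihist[t] <- I
      head_dir <- heading
      if (state == "run") {
        sp <- sim$speed_mean_mm_s *
          (1 + sim$peristalsis_depth * sin(2 * pi * sim$peristalsis_hz *
                                             (t / rate) + phase))
        heading <- heading + stats::rnorm(1, 0, sim$heading_jitter_rad)
        heading <- wall_steer(pos, heading, sp / rate * ppm, a, margin)
        pos <- pos + sp / rate * ppm * c(cos(heading), sin(heading))
        # stop decision driven by the sensed relative intensity change
        w <- as.integer(rate / 2)
        E <- if (t > w && !is.na(Ihist[t - w]) && Ihist[t] > 0)
          (Ihist[t] - Ihist[t - w]) / (w / rate) / Ihist[t] else 0
        p_stop <- sim$stop_prob * (1 + gain * (E < 0))
        if (stats::runif(1) < p_stop) {
          state <- "cast"
          cast_left <- as.integer(sim$cast_duration_s * rate)
          cast_side <- sample(c(-1, 1), 1)
          if (gain > 0) {
            # sample the gradient on both sides with the head
            probe <- function(s) intensity_at(landscape, pos + 0.45 * L *
              c(cos(heading + s * sim$cast_amplitude_rad),
                sin(heading + s * sim$cast_amplitude_rad)))
            dI <- probe(1) - probe(-1)
            p_pos <- 1 / (1 + exp(-gain * dI / max(Ihist[t],
                                                   .Machine$double.eps)))
            cast_side <- if (stats::runif(1) < p_pos) 1 else -1
          }
        }
      } else {
        k <- sim$cast_duration_s * rate - cast_left
        head_dir <- heading + cast_side * sim$cast_amplitude_rad *
          sin(pi * k / (sim$cast_duration_s * rate))
        cast_left <- cast_left - 1L
        if (cast_left <= 0L) {
          heading <- heading + cast_side *
            abs(stats::rnorm(1, sim$turn_mean_rad, sim$turn_sd_rad))
          state <- "run"
        }
      }
      u_body <- c(cos(heading), sin(heading))
      u_head <- c(cos(head_dir), sin(head_dir))
      hd <- pos + 0.5 * L * u_head
      tl <- pos - 0.5 * L * u_body
      # the recorded centroid is the rendered body's shape centroid, which
      # moves off the midline point when the body bends during casts
      ctr <- capsule_centroid(hd, pos, tl)
      tr$x[t] <- ctr[1]; tr$y[t] <- ctr[2]
      tr$mid_x[t] <- pos[1]; tr$mid_y[t] <- pos[2]
      tr$head_x[t] <- hd[1]; tr$head_y[t] <- hd[2]
      tr$tail_x[t] <- tl[1]; tr$tail_y[t] <- tl[2]
      tr$intensity[t] <- I
    }
    ground_truth(tr, seed, "larva", sim)
  })
}

#' Larva simulation constants
#' @param speed_mean_mm_s mean crawling speed during runs.
#' @param peristalsis_hz,peristalsis_depth frequency and relative depth of
#'   the speed oscillation (peak speed = mean * (1 + depth)).
#' @param heading_jitter_rad per-frame heading diffusion during runs.
#' @param stop_prob baseline per-frame probability of a stop-and-cast.
#' @param cast_duration_s duration of the lateral head sweep.
#' @param cast_amplitude_rad maximal head deflection during a cast.
#' @param turn_mean_rad,turn_sd_rad magnitude of the post-cast heading
#'   change.
#' @param body_length_mm body length.
#' @export
larva_sim_params <- function(speed_mean_mm_s = 0.7, peristalsis_hz = 1,
                             peristalsis_depth = 0.9,
                             heading_jitter_rad = 0.03,
                             stop_prob = 1 / 240,
                             cast_duration_s = 1,
                             cast_amplitude_rad = 1.0,
                             turn_mean_rad = 0.8, turn_sd_rad = 0.3,
                             body_length_mm = 4) {
  as.list(environment())
}

#' Simulate a walking adult fly on a checkerboard
#'
#' A continuous heading-persistent walker (peak speed ~12 mm/s). With
#' `gain > 0` the agent expresses the bitter-avoidance phenotype: its speed
#' distribution shifts up while it stands on a lit (ON) square, and on an
#' ON-to-OFF transition it frequently stops — so time accumulates in the
#' dark squares and the occupancy preference index turns negative.
#'
#' @inheritParams simulate_larva
#' @param sim see [fly_sim_params()].
#' @export
simulate_fly <- function(landscape, seed, n_frames = 1800, gain = 0,
                         start_xy = NULL, sim = fly_sim_params()) {
  a <- synthetic_arena()
  ppm <- synth_const$px_per_mm; rate <- synth_const$frame_rate_hz
  margin <- synth_const$wall_margin_mm * ppm
  L <- sim$body_length_mm * ppm
  with_seed(seed, {
    tr <- gt_trajectory(n_frames, rate, ppm)
    pos <- start_xy %||% (a$center +
      stats::runif(1, 0, a$radius - 3 * margin) *
        c(cos(th0 <- stats::runif(1, 0, 2 * pi)), sin(th0)))
    heading <- stats::runif(1, 0, 2 * pi)
    speed <- sim$speed_base_mm_s
    stop_left <- 0L
    prev_on <- NA
    for (t in seq_len(n_frames)) {
      I <- intensity_at(landscape, pos)
      on <- I > 0
      if (!is.na(prev_on) && prev_on && !on && gain > 0 &&
          stats::runif(1) < sim$stop_prob_on_relief * gain) {
        stop_left <- as.integer(stats::rexp(1, 1 / sim$stop_mean_s) * rate)
      }
      if (stop_left > 0L) {
        stop_left <- stop_left - 1L
        speed <- 0
      } else {
        mu <- sim$speed_base_mm_s * (1 + gain * sim$speed_on_boost * on)
        speed <- speed + sim$speed_relax * (mu - speed) +
          stats::rnorm(1, 0, sim$speed_noise_mm_s)
        speed <- min(max(speed, 0), sim$speed_max_mm_s)
        heading <- heading + stats::rnorm(1, 0, sim$heading_jitter_rad)
        heading <- wall_steer(pos, heading, speed / rate * ppm, a, margin)
        pos <- pos + speed / rate * ppm * c(cos(heading), sin(heading))
      }
      u <- c(cos(heading), sin(heading))
      tr$x[t] <- pos[1]; tr$y[t] <- pos[2]
      tr$mid_x[t] <- pos[1]; tr$mid_y[t] <- pos[2]
      tr$head_x[t] <- pos[1] + 0.5 * L * u[1]
      tr$head_y[t] <- pos[2] + 0.5 * L * u[2]
      tr$tail_x[t] <- pos[1] - 0.5 * L * u[1]
      tr$tail_y[t] <- pos[2] - 0.5 * L * u[2]
      tr$intensity[t] <- I
      prev_on <- on
    }
    ground_truth(tr, seed, "fly", sim)
  })
}

#' Fly simulation constants
#' @param speed_base_mm_s mean walking speed off stimulus.
#' @param speed_on_boost relative speed increase on lit squares (at
#'   gain 1).
#' @param speed_max_mm_s peak walking speed.
#' @param speed_relax,speed_noise_mm_s speed process dynamics.
#' @param heading_jitter_rad per-frame heading diffusion.
#' @param stop_prob_on_relief probability of stopping when entering a dark
#'   square (at gain 1).
#' @param stop_mean_s mean stop duration.
#' @param body_length_mm body length.
#' @export
fly_sim_params <- function(speed_base_mm_s = 4, speed_on_boost = 1,
                           speed_max_mm_s = 14, speed_relax = 0.2,
                           speed_noise_mm_s = 0.6,
                           heading_jitter_rad = 0.15,
                           stop_prob_on_relief = 0.6, stop_mean_s = 1,
                           body_length_mm = 2.5) {
  as.list(environment())
}

#' Simulate a bout-swimming zebrafish larva
#'
#' A discrete bout generator: approximately straight displacements at ~1.5 s
#' intervals, each bout preceded by a reorientation drawn from a base turn
#' distribution. With `gain > 0` the turn dispersion is amplified when the
#' previous bout went down-gradient (`delta I < 0`) AND the current
#' intensity is low — the phototaxis strategy of modulated turn amplitude.
#' Turn direction is symmetric, so the agent carries no bias toward the
#' source (recovered turn index ~0) at any gain.
#'
#' @inheritParams simulate_larva
#' @param sim see [fish_sim_params()].
#' @export
simulate_fish <- function(landscape, seed, n_frames = 1800, gain = 0,
                          start_xy = NULL, sim = fish_sim_params()) {
  a <- synthetic_arena()
  ppm <- synth_const$px_per_mm; rate <- synth_const$frame_rate_hz
  margin <- synth_const$wall_margin_mm * ppm
  L <- sim$body_length_mm * ppm
  with_seed(seed, {
    tr <- gt_trajectory(n_frames, rate, ppm)
    if (is.null(start_xy)) {
      # starts spread over the mid-to-outer dish so trials sample the whole
      # intensity range of the gradient, as the published trajectories do
      th0 <- stats::runif(1, 0, 2 * pi)
      pos <- a$center + stats::runif(1, 0.35, 0.8) * (a$radius - 2 * margin) *
        c(cos(th0), sin(th0))
    } else pos <- start_xy
    # trials start with the animal facing the source (when one exists)
    heading <- tryCatch({
      s <- landscape_source(landscape)
      atan2(s[2] - pos[2], s[1] - pos[1])
    }, error = function(e) stats::runif(1, 0, 2 * pi))
    I_prev_bout <- intensity_at(landscape, pos)
    next_bout <- 1L + as.integer(stats::runif(1, 0.2, 0.8) * rate)
    bout_step <- numeric(0)  # remaining per-frame displacements (px)
    for (t in seq_len(n_frames)) {
      if (t >= next_bout && length(bout_step) == 0) {
        I_now <- intensity_at(landscape, pos)
        dI <- I_now - I_prev_bout
        amp <- gain * (dI < 0 && I_now < sim$low_I_frac * landscape$i_max)
        # base reorientation: mixture of forward scoots and routine turns
        # (heavy-tailed, as larval swims are); the down-gradient/low-light
        # amplification scales the drawn magnitude
        mag <- if (stats::runif(1) < sim$routine_turn_prob)
          abs(stats::rnorm(1, sim$routine_turn_mean_deg,
                           sim$routine_turn_sd_deg))
        else abs(stats::rnorm(1, 0, sim$turn_sd_deg))
        mag <- min(mag * (1 + amp), 170)
        dturn <- sample(c(-1, 1), 1) * mag
        heading <- heading + dturn * pi / 180
        len <- max(sim$bout_length_min_mm,
                   stats::rnorm(1, sim$bout_length_mm, sim$bout_length_sd_mm))
        heading <- wall_steer(pos, heading, len * ppm, a, margin)
        d <- max(2L, as.integer(sim$bout_duration_s * rate))
        w <- triang_weights(d)
        bout_step <- len * ppm * w / sum(w)
        I_prev_bout <- I_now
        gap <- max(sim$bout_interval_min_s,
                   stats::rnorm(1, sim$bout_interval_s, sim$bout_interval_sd_s))
        next_bout <- t + as.integer(round(gap * rate))
      }
      if (length(bout_step)) {
        pos <- pos + bout_step[1] * c(cos(heading), sin(heading))
        bout_step <- bout_step[-1]
      }
      u <- c(cos(heading), sin(heading))
      tr$x[t] <- pos[1]; tr$y[t] <- pos[2]
      tr$mid_x[t] <- pos[1]; tr$mid_y[t] <- pos[2]
      tr$head_x[t] <- pos[1] + 0.35 * L * u[1]
      tr$head_y[t] <- pos[2] + 0.35 * L * u[2]
      tr$tail_x[t] <- pos[1] - 0.65 * L * u[1]
      tr$tail_y[t] <- pos[2] - 0.65 * L * u[2]
      tr$intensity[t] <- intensity_at(landscape, pos)
    }
    ground_truth(tr, seed, "fish", sim)
  })
}

#' Fish simulation constants
#' @param bout_interval_s,bout_interval_sd_s,bout_interval_min_s inter-bout
#'   interval distribution (seconds).
#' @param bout_length_mm,bout_length_sd_mm,bout_length_min_mm per-bout
#'   displacement distribution.
#' @param bout_duration_s duration of the displacement burst.
#' @param turn_sd_deg dispersion of forward-scoot reorientations.
#' @param routine_turn_prob,routine_turn_mean_deg,routine_turn_sd_deg the
#'   routine-turn component of the reorientation mixture.
#' @param low_I_frac intensity fraction of I_max below which the
#'   down-gradient turn amplification acts.
#' @param body_length_mm body length.
#' @export
fish_sim_params <- function(bout_interval_s = 1.5, bout_interval_sd_s = 0.3,
                            bout_interval_min_s = 0.8,
                            bout_length_mm = 2, bout_length_sd_mm = 0.5,
                            bout_length_min_mm = 0.6,
                            bout_duration_s = 0.2,
                            turn_sd_deg = 15, routine_turn_prob = 0.35,
                            routine_turn_mean_deg = 45,
                            routine_turn_sd_deg = 18,
                            low_I_frac = 0.35,
                            body_length_mm = 4) {
  as.list(environment())
}

ground_truth <- function(tr, seed, organism, sim) {
  structure(list(
    trajectory = trajectory(tr, px_per_mm = synth_const$px_per_mm,
                            frame_rate_hz = synth_const$frame_rate_hz),
    seed = seed, organism = organism, sim = sim),
    class = "vrt_ground_truth")
}

#' @export
print.vrt_ground_truth <- function(x, ...) {
  cat(sprintf("<vrt_ground_truth> %s, seed %d, %d frames\n", x$organism,
              x$seed, nrow(x$trajectory)))
  invisible(x)
}

## rendering -----------------------------------------------------------------

#' Rendering parameters
#'
#' @param background_gray gray value of the static bright backlight.
#' @param contrast how many gray levels the animal silhouette lies below
#'   the background.
#' @param noise_sd Gaussian camera noise sd in gray levels (added before
#'   8-bit quantization).
#' @param width_px,height_px frame size.
#' @param body_width_mm silhouette width (organism-specific defaults are
#'   applied by [render_video()] when `NULL`).
#' @export
render_params <- function(background_gray = 200, contrast = 80,
                          noise_sd = 0, width_px = 640, height_px = 480,
                          body_width_mm = NULL) {
  stopifnot(background_gray > 0, contrast > 0,
            background_gray - contrast >= 0, noise_sd >= 0)
  as.list(environment())
}

#' Render a ground-truth trajectory into a synthetic video
#'
#' Produces a lazily rendered frame source implementing the pipeline's
#' imaging model: a uniform bright background, the animal stamped
#' `contrast` gray levels darker (an ellipse for fly and fish, a curved
#' capsule with an enlarged head lobe for the larva, aligned to the
#' ground-truth head), optional additive Gaussian pixel noise, and 8-bit
#' quantization. Frames are deterministic functions of `(seed, index)`, so
#' any access order — and any truncation — reproduces identical pixels.
#'
#' @param gt a `vrt_ground_truth` from one of the simulators.
#' @param rp [render_params()].
#' @param seed seed for the per-frame noise streams.
#' @return list with `source` (a `vrt_frame_source`) and `ground_truth`
#'   (`gt`, unchanged).
#' @export
render_video <- function(gt, rp = render_params(), seed = gt$seed) {
  tr <- gt$trajectory
  n <- nrow(tr)
  ppm <- attr(tr, "px_per_mm")
  width_mm <- rp$body_width_mm %||%
    switch(gt$organism, larva = 1.2, fly = 1.2, fish = 1.1)
  if (n > 0) {
    inx <- tr$x >= 0 & tr$x <= rp$width_px - 1 &
      tr$y >= 0 & tr$y <= rp$height_px - 1
    if (!all(inx, na.rm = TRUE)) stop("animal outside frame")
  }
  src <- structure(
    list(gt = gt, rp = rp, seed = seed, organism = gt$organism,
         width_mm = width_mm,
         frame_rate_hz = attr(tr, "frame_rate_hz"),
         dims = c(rp$height_px, rp$width_px), n = n,
         template = matrix(round(rp$background_gray), rp$height_px,
                           rp$width_px),
         value = round(rp$background_gray - rp$contrast)),
    class = c("vrt_render_source", "vrt_frame_source"))
  list(source = src, ground_truth = gt)
}

#' @export
n_frames.vrt_render_source <- function(source) source$n

#' @export
get_frame.vrt_render_source <- function(source, index) {
  i <- as.integer(index)
  if (i < 0 || i >= source$n) stop("frame index out of range: ", index)
  tr <- source$gt$trajectory
  rp <- source$rp
  ppm <- attr(tr, "px_per_mm")
  px <- source$template
  row <- i + 1L
  value <- source$value
  wpx <- source$width_mm * ppm
  if (source$organism %in% c("fly", "fish")) {
    px <- stamp_ellipse(px, c(tr$x[row], tr$y[row]),
                        c(tr$head_x[row], tr$head_y[row]),
                        c(tr$tail_x[row], tr$tail_y[row]), wpx / 2, value)
  } else {
    # the capsule centerline passes through the spine midpoint (mid_x/y),
    # recorded by the simulator; the `x`/`y` columns hold the resulting
    # shape centroid, which shifts into the bend during casts
    mid <- if (!is.null(tr$mid_x) && !is.na(tr$mid_x[row]))
      c(tr$mid_x[row], tr$mid_y[row]) else c(tr$x[row], tr$y[row])
    px <- stamp_capsule(px, c(tr$head_x[row], tr$head_y[row]), mid,
                        c(tr$tail_x[row], tr$tail_y[row]), wpx / 2, value)
  }
  if (rp$noise_sd > 0) {
    px <- px + with_seed((source$seed * 7919L + i) %% 2147483647,
                         stats::rnorm(length(px), 0, rp$noise_sd))
    px <- round(px)
    px[px < 0] <- 0; px[px > 255] <- 255
  }
  frame_obj(i, source$frame_rate_hz, px)
}

# axis-aligned-in-body-frame ellipse through head and tail
stamp_ellipse <- function(px, centroid, head, tail, semi_minor, value) {
  axis <- head - tail
  a <- sqrt(sum(axis^2)) / 2
  if (a == 0) a <- semi_minor
  u <- if (sqrt(sum(axis^2)) > 0) axis / sqrt(sum(axis^2)) else c(1, 0)
  b <- semi_minor
  r <- ceiling(max(a, b)) + 1L
  xs <- max(0, floor(centroid[1] - r)):min(ncol(px) - 1, ceiling(centroid[1] + r))
  ys <- max(0, floor(centroid[2] - r)):min(nrow(px) - 1, ceiling(centroid[2] + r))
  gx <- outer(rep(1, length(ys)), xs) - centroid[1]
  gy <- outer(ys, rep(1, length(xs))) - centroid[2]
  lon <- gx * u[1] + gy * u[2]
  lat <- -gx * u[2] + gy * u[1]
  inside <- (lon / a)^2 + (lat / b)^2 <= 1
  sub <- px[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- value
  px[ys + 1, xs + 1] <- sub
  px
}

# arc-length-weighted centroid of the bezier centerline, a close proxy for
# the area centroid of the constant-width capsule stamped by the renderer
capsule_centroid <- function(head, mid, tail) {
  p1 <- 2 * mid - (head + tail) / 2
  ts <- seq(0, 1, length.out = 25)
  bx <- (1 - ts)^2 * tail[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * head[1]
  by <- (1 - ts)^2 * tail[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * head[2]
  dx <- 2 * (1 - ts) * (p1[1] - tail[1]) + 2 * ts * (head[1] - p1[1])
  dy <- 2 * (1 - ts) * (p1[2] - tail[2]) + 2 * ts * (head[2] - p1[2])
  w <- sqrt(dx^2 + dy^2)
  c(sum(bx * w) / sum(w), sum(by * w) / sum(w))
}

# curved capsule: disks along a quadratic bezier tail -> centroid -> head;
# constant width so the silhouette centroid stays on the ground-truth
# centroid (the bezier passes through it exactly at t = 0.5)
stamp_capsule <- function(px, head, centroid, tail, radius, value) {
  p1 <- 2 * centroid - (head + tail) / 2  # control point: curve near centroid
  ts <- seq(0, 1, length.out = 25)
  bx <- (1 - ts)^2 * tail[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * head[1]
  by <- (1 - ts)^2 * tail[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * head[2]
  rr <- rep(radius, length(ts))
  xs <- max(0, floor(min(bx) - max(rr))):min(ncol(px) - 1,
                                             ceiling(max(bx) + max(rr)))
  ys <- max(0, floor(min(by) - max(rr))):min(nrow(px) - 1,
                                             ceiling(max(by) + max(rr)))
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  inside <- matrix(FALSE, length(ys), length(xs))
  for (k in seq_along(ts)) {
    inside <- inside | ((gx - bx[k])^2 + (gy - by[k])^2 <= rr[k]^2)
  }
  sub <- px[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- value
  px[ys + 1, xs + 1] <- sub
  px
}
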