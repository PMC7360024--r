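# Animal-parameter and experiment configuration handling (YAML), and the
# trajectory / stimulus table readers and writers (plain CSV, one-line
# header, empty fields for missing values).

#' Animal tracking parameters
#'
#' Bundles the per-organism constants the detector and tracker need. Presets
#' for `"larva"`, `"fly"` and `"fish"` reflect typical geometry in a 100 mm
#' dish imaged at ~4.8 px/mm and the organisms' speed bounds (1 mm/s larva,
#' ~5 mm/s walking fly, burst swimming fish).
#'
#' @param organism optional preset: `"larva"`, `"fly"` or `"fish"`.
#' @param min_area_px,max_area_px accepted blob area bounds (pixels).
#' @param gaussian_sigma_px sigma of the Gaussian pre-filter applied to every
#'   frame, scaled to the animal's size.
#' @param roi_padding_px half-width added around the detected blob to form
#'   the next search box; must exceed the expected per-frame displacement.
#' @param px_per_mm spatial calibration.
#' @param frame_rate_hz acquisition rate.
#' @param speed_bound_mm_s high bound on the organism's speed, used to size
#'   coordinate-smoothing windows.
#' @return an object of class `vrt_params`.
#' @export
animal_parameters <- function(organism = NULL,
                              min_area_px = NULL, max_area_px = NULL,
                              gaussian_sigma_px = NULL, roi_padding_px = NULL,
                              px_per_mm = 4.8, frame_rate_hz = 30,
                              speed_bound_mm_s = NULL) {
  preset <- list(
    larva = list(min_area_px = 25, max_area_px = 500, gaussian_sigma_px = 3,
                 roi_padding_px = 25, speed_bound_mm_s = 1),
    fly   = list(min_area_px = 15, max_area_px = 400, gaussian_sigma_px = 2,
                 roi_padding_px = 25, speed_bound_mm_s = 5),
    fish  = list(min_area_px = 20, max_area_px = 500, gaussian_sigma_px = 2,
                 roi_padding_px = 25, speed_bound_mm_s = 25))
  base <- if (!is.null(organism)) {
    organism <- match.arg(organism, names(preset))
    preset[[organism]]
  } else {
    list(min_area_px = 25, max_area_px = 500, gaussian_sigma_px = 2,
         roi_padding_px = 25, speed_bound_mm_s = 1)
  }
  p <- list(
    organism = if (is.null(organism)) NA_character_ else organism,
    min_area_px = min_area_px %||% base$min_area_px,
    max_area_px = max_area_px %||% base$max_area_px,
    gaussian_sigma_px = gaussian_sigma_px %||% base$gaussian_sigma_px,
    roi_padding_px = roi_padding_px %||% base$roi_padding_px,
    px_per_mm = px_per_mm,
    frame_rate_hz = frame_rate_hz,
    speed_bound_mm_s = speed_bound_mm_s %||% base$speed_bound_mm_s)
  stopifnot(p$min_area_px > 0, p$min_area_px < p$max_area_px,
            p$gaussian_sigma_px >= 0, p$roi_padding_px >= 1,
            p$px_per_mm > 0, p$frame_rate_hz > 0, p$speed_bound_mm_s > 0)
  structure(p, class = "vrt_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vrt_params <- function(x, ...) {
  cat("<vrt_params>", if (!is.na(x$organism)) x$organism else "custom", "\n")
  cat(sprintf("  area [%g, %g] px, sigma %g px, roi padding %g px\n",
              x$min_area_px, x$max_area_px, x$gaussian_sigma_px,
              x$roi_padding_px))
  cat(sprintf("  %g px/mm, %g Hz, speed bound %g mm/s\n",
              x$px_per_mm, x$frame_rate_hz, x$speed_bound_mm_s))
  invisible(x)
}

#' Read / write an experiment configuration (YAML)
#'
#' A config file holds the animal parameters plus experiment settings
#' (landscape spec, stimulus lag in frames, tracked point, output directory).
#'
#' @param path YAML file path.
#' @return `read_experiment_config()` returns a list with elements
#'   `params` (a [animal_parameters()] object), `landscape` (spec list or
#'   NULL), `lag_frames`, `tracked_point` and any further fields verbatim.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("unreadable path: ", path)
  cfg <- yaml::read_yaml(path)
  ap <- cfg$animal_parameters %||% list()
  params <- do.call(animal_parameters, ap)
  list(params = params,
       landscape = cfg$landscape,
       lag_frames = cfg$lag_frames %||% 1L,
       tracked_point = cfg$tracked_point %||% "centroid",
       extra = cfg[setdiff(names(cfg), c("animal_parameters", "landscape",
                                         "lag_frames", "tracked_point"))])
}

#' @rdname read_experiment_config
#' @param config list as returned by `read_experiment_config()`, or a list
#'   with the same fields.
#' @export
write_experiment_config <- function(config, path) {
  out <- list(
    animal_parameters = unclass(config$params)[
      setdiff(names(config$params), "organism")],
    landscape = config$landscape,
    lag_frames = config$lag_frames,
    tracked_point = config$tracked_point)
  out <- c(out, config$extra)
  yaml::write_yaml(out, path)
  invisible(path)
}

## trajectory tables ---------------------------------------------------------

traj_columns <- c("frame", "time_s", "x", "y", "head_x", "head_y",
                  "tail_x", "tail_y", "area_px",
                  "roi_x0", "roi_y0", "roi_x1", "roi_y1", "valid")

#' Construct a trajectory table
#'
#' The trajectory is the tracker's output and the analysis input: one row per
#' processed frame with centroid, head, tail (0-based pixel coordinates),
#' blob area, the ROI searched, and a validity flag. Invalid frames carry NA
#' positions. Optional extra columns (e.g. `intensity` for ground truth) are
#' preserved by the CSV round trip.
#'
#' @param df data frame holding at least the canonical columns (see Details).
#' @param px_per_mm,frame_rate_hz calibration metadata carried as attributes
#'   and serialized as columns.
#' @return a `vrt_trajectory` (a data frame).
#' @export
trajectory <- function(df, px_per_mm, frame_rate_hz) {
  missing_cols <- setdiff(traj_columns, names(df))
  if (length(missing_cols))
    stop("trajectory schema error: missing column ", missing_cols[1])
  stopifnot(px_per_mm > 0, frame_rate_hz > 0)
  structure(as.data.frame(df),
            px_per_mm = px_per_mm, frame_rate_hz = frame_rate_hz,
            class = c("vrt_trajectory", "data.frame"))
}

#' @export
print.vrt_trajectory <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<vrt_trajectory> %d frames (%d valid), %g px/mm, %g Hz\n",
              nrow(x), nv, attr(x, "px_per_mm"), attr(x, "frame_rate_hz")))
  if (nv > 0) {
    v <- x[x$valid, ]
    cat(sprintf("  frames %d..%d tracked\n", min(v$frame), max(v$frame)))
  }
  invisible(x)
}

#' Write / read a trajectory CSV
#'
#' Plain CSV with a one-line header; missing values are written as empty
#' fields. Calibration metadata travels as the constant columns `px_per_mm`
#' and `frame_rate_hz`, so the file is self-contained and the round trip is
#' lossless.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$px_per_mm <- attr(traj, "px_per_mm")
  df$frame_rate_hz <- attr(traj, "frame_rate_hz")
  utils::write.table(df, path, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns the reconstructed `vrt_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("unreadable path: ", path)
  df <- utils::read.csv(path, na.strings = "")
  missing_cols <- setdiff(c(traj_columns, "px_per_mm", "frame_rate_hz"),
                          names(df))
  if (length(missing_cols))
    stop("trajectory schema error: missing column ", missing_cols[1])
  ppm <- df$px_per_mm[1]; fr <- df$frame_rate_hz[1]
  df$px_per_mm <- NULL; df$frame_rate_hz <- NULL
  df$valid <- as.logical(df$valid)
  trajectory(df, px_per_mm = ppm, frame_rate_hz = fr)
}

## stimulus log --------------------------------------------------------------

#' Construct a stimulus log
#'
#' Per-frame commanded intensity `I(t)` in landscape units, together with the
#' lag (in frames) and the tracked body point that produced the commands.
#'
#' @param df data frame with columns `frame`, `time_s`, `intensity`.
#' @param lag_frames whole-frame stimulus lag used.
#' @param tracked_point `"head"`, `"centroid"` or `"tail"`.
#' @return a `vrt_stimulus` data frame.
#' @export
stimulus_log <- function(df, lag_frames, tracked_point) {
  missing_cols <- setdiff(c("frame", "time_s", "intensity"), names(df))
  if (length(missing_cols))
    stop("stimulus schema error: missing column ", missing_cols[1])
  structure(as.data.frame(df), lag_frames = as.integer(lag_frames),
            tracked_point = tracked_point,
            class = c("vrt_stimulus", "data.frame"))
}

#' Write / read a stimulus log CSV
#' @param stim a [stimulus_log()].
#' @param path file path.
#' @export
write_stimulus <- function(stim, path) {
  df <- as.data.frame(stim)
  df$lag_frames <- attr(stim, "lag_frames")
  df$tracked_point <- attr(stim, "tracked_point")
  utils::write.table(df, path, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  if (!file.exists(path)) stop("unreadable path: ", path)
  df <- utils::read.csv(path, na.strings = "")
  missing_cols <- setdiff(c("frame", "time_s", "intensity", "lag_frames",
                            "tracked_point"), names(df))
  if (length(missing_cols))
    stop("stimulus schema error: missing column ", missing_cols[1])
  lag <- df$lag_frames[1]; tp <- df$tracked_point[1]
  df$lag_frames <- NULL; df$tracked_point <- NULL
  stimulus_log(df, lag_frames = lag, tracked_point = tp)
}
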