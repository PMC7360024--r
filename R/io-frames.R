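# Frame acquisition. A frame source yields grayscale frames (matrices in
# 0..255) in index order at a fixed frame rate. Three concrete sources exist:
# a directory of numbered PNG/TIFF images, an in-memory list of matrices, and
# the lazily rendered synthetic source produced by render_video().

#' Open a source of grayscale frames
#'
#' @param path directory containing numbered grayscale images
#'   (`*.png`, `*.tif`, `*.tiff`), sorted by zero-padded index in the name.
#' @param frame_rate_hz acquisition rate, frames per second.
#' @return a `vrt_frame_source` object; query it with [n_frames()] and
#'   [get_frame()].
#' @details Color images are converted to gray as the unweighted mean of the
#'   channels. All images in a directory must share the same dimensions.
#' @export
open_frame_source <- function(path, frame_rate_hz) {
  stopifnot(is.character(path), length(path) == 1, frame_rate_hz > 0)
  if (!dir.exists(path)) stop("unreadable path: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no frames found in ", path)
  files <- files[order(basename(files))]
  src <- structure(
    list(files = files, frame_rate_hz = frame_rate_hz, dims = NULL),
    class = c("vrt_image_dir_source", "vrt_frame_source"))
  f0 <- get_frame(src, 0L)
  src$dims <- dim(f0$pixels)
  src
}

#' In-memory frame source
#'
#' Wraps a list of gray matrices (values 0..255) as a frame source; mainly
#' used for tests and small synthetic scenes.
#'
#' @param frames list of numeric matrices, identical dimensions.
#' @param frame_rate_hz frames per second.
#' @return a `vrt_frame_source`.
#' @export
memory_frame_source <- function(frames, frame_rate_hz) {
  stopifnot(is.list(frames), frame_rate_hz > 0)
  if (length(frames) == 0) stop("no frames")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("inconsistent image shapes in source")
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz, dims = d),
            class = c("vrt_memory_source", "vrt_frame_source"))
}

#' Number of frames in a source
#' @param source a `vrt_frame_source`.
#' @return integer frame count.
#' @export
n_frames <- function(source) UseMethod("n_frames")

#' @export
n_frames.vrt_image_dir_source <- function(source) length(source$files)

#' @export
n_frames.vrt_memory_source <- function(source) length(source$frames)

#' Fetch one frame from a source
#'
#' @param source a `vrt_frame_source`.
#' @param index 0-based frame index.
#' @return a list with `index`, `time_s` (= index / frame rate) and `pixels`
#'   (gray matrix, 0..255).
#' @export
get_frame <- function(source, index) UseMethod("get_frame")

frame_obj <- function(index, rate, pixels) {
  list(index = as.integer(index), time_s = index / rate, pixels = pixels)
}

#' @export
get_frame.vrt_image_dir_source <- function(source, index) {
  i <- as.integer(index)
  if (i < 0 || i >= length(source$files)) stop("frame index out of range: ", index)
  px <- read_gray_image(source$files[i + 1L])
  if (!is.null(source$dims) && !identical(dim(px), source$dims))
    stop("inconsistent image shapes in source")
  frame_obj(i, source$frame_rate_hz, px)
}

#' @export
get_frame.vrt_memory_source <- function(source, index) {
  i <- as.integer(index)
  if (i < 0 || i >= length(source$frames)) stop("frame index out of range: ", index)
  frame_obj(i, source$frame_rate_hz, source$frames[[i + 1L]])
}

#' @export
print.vrt_frame_source <- function(x, ...) {
  cat(sprintf("<%s> %d frames, %g Hz, %d x %d px\n", class(x)[1], n_frames(x),
              x$frame_rate_hz, x$dims[2], x$dims[1]))
  invisible(x)
}

# Read a PNG/TIFF as a gray matrix in 0..255. Multi-channel input is averaged
# across channels (unweighted); an alpha channel, if present, is dropped.
read_gray_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  a <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    if (nch == 4 || nch == 2) a <- a[, , -nch, drop = FALSE]  # drop alpha
    a <- apply(a, c(1, 2), mean)
  }
  a * 255
}

#' Write frames of a source to numbered PNG files
#'
#' @param source a `vrt_frame_source`.
#' @param dir output directory (created if needed).
#' @param indices 0-based frame indices; default all.
#' @return invisibly, the written file paths.
#' @export
write_frames_png <- function(source, dir, indices = seq_len(n_frames(source)) - 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(indices))
  for (k in seq_along(indices)) {
    f <- get_frame(source, indices[k])
    paths[k] <- file.path(dir, sprintf("frame_%06d.png", f$index))
    png::writePNG(pmin(pmax(f$pixels, 0), 255) / 255, paths[k])
  }
  invisible(paths)
}
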