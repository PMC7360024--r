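# Virtual sensory landscapes: a mapping from arena position (pixel
# coordinates) to stimulus intensity, evaluated in closed form for the
# parametric kinds and by nearest-neighbor lookup for rasters. Intensities
# are abstract landscape units normalized to I_max = 1 by default; a config
# scale can map them to physical units for reporting.

#' Define an arena
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param shape `"rect"` (whole frame) or `"circle"` (e.g. a petri dish).
#' @param center,radius circle geometry (pixel coords); default inscribed
#'   circle.
#' @return a `vrt_arena` list.
#' @export
arena <- function(width_px, height_px, shape = c("rect", "circle"),
                  center = NULL, radius = NULL) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(center)) center <- c((width_px - 1) / 2, (height_px - 1) / 2)
    if (is.null(radius)) radius <- min(width_px, height_px) / 2
  }
  structure(list(width_px = width_px, height_px = height_px, shape = shape,
                 center = center, radius = radius), class = "vrt_arena")
}

in_arena <- function(a, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  inside <- x >= 0 & x <= a$width_px - 1 & y >= 0 & y <= a$height_px - 1
  if (a$shape == "circle") {
    inside <- inside &
      (x - a$center[1])^2 + (y - a$center[2])^2 <= a$radius^2
  }
  inside
}

new_landscape <- function(kind, arena, i_max, fields) {
  stopifnot(inherits(arena, "vrt_arena"), i_max > 0)
  structure(c(list(kind = kind, arena = arena, i_max = i_max), fields),
            class = c(paste0("vrt_landscape_", kind), "vrt_landscape"))
}

check_center <- function(center, a) {
  if (!any(in_arena(a, matrix(center, ncol = 2))))
    stop("landscape center outside arena")
}

#' Gaussian intensity landscape
#'
#' `I(p) = I_max * exp(-|p - center|^2 / (2 sigma^2))`: peak `I_max` exactly
#' at the center, radially monotone decreasing.
#'
#' @param center peak position, pixel coords.
#' @param sigma gradient width in pixels (> 0).
#' @param i_max intensity ceiling (landscape units).
#' @param arena an [arena()].
#' @return a `vrt_landscape`.
#' @export
make_gaussian <- function(center, sigma, i_max = 1, arena) {
  stopifnot(sigma > 0)
  check_center(center, arena)
  new_landscape("gaussian", arena, i_max, list(center = center, sigma = sigma))
}

#' Exponential intensity landscape
#'
#' `I(p) = I_max * exp(-|p - center| / lambda)`, the alternative point-source
#' profile; same interface as [make_gaussian()].
#'
#' @param center peak position, pixel coords.
#' @param lambda decay length in pixels (> 0).
#' @inheritParams make_gaussian
#' @export
make_exponential <- function(center, lambda, i_max = 1, arena) {
  stopifnot(lambda > 0)
  check_center(center, arena)
  new_landscape("exponential", arena, i_max,
                list(center = center, lambda = lambda))
}

#' Volcano intensity landscape
#'
#' A radially symmetric field peaking on a ring:
#' `I(p) = I_max * exp(-(|p - center| - rim_radius)^2 / (2 rim_width^2))`.
#' The maximum `I_max` is attained exactly on the rim circle and the center
#' is depressed.
#'
#' @param center ring center, pixel coords.
#' @param rim_radius ring radius in pixels.
#' @param rim_width Gaussian width of the ring profile (0 < width < radius).
#' @inheritParams make_gaussian
#' @export
make_volcano <- function(center, rim_radius, rim_width, i_max = 1, arena) {
  stopifnot(rim_width > 0, rim_width < rim_radius)
  check_center(center, arena)
  new_landscape("volcano", arena, i_max,
                list(center = center, rim_radius = rim_radius,
                     rim_width = rim_width))
}

#' Checkerboard intensity landscape
#'
#' `I(p) = I_on` where `floor(x / s) + floor(y / s) + phase` is odd, else 0.
#'
#' @param square_size side of one square in pixels (> 0).
#' @param i_on intensity of lit squares.
#' @param phase 0 or 1; flipping inverts every square.
#' @param arena an [arena()].
#' @export
make_checkerboard <- function(square_size, i_on = 1, phase = 0, arena) {
  stopifnot(square_size > 0, phase %in% c(0, 1))
  new_landscape("checkerboard", arena, i_on,
                list(square_size = square_size, phase = phase))
}

#' Raster intensity landscape
#'
#' Wraps a 2D intensity grid; positions are sampled nearest-neighbor. The
#' grid is indexed in the same convention as frames (rows = y, cols = x).
#'
#' @param grid numeric matrix of intensities (>= 0).
#' @param arena an [arena()]; defaults to the grid's rectangle.
#' @export
make_raster <- function(grid, arena = NULL) {
  stopifnot(is.matrix(grid), all(grid >= 0))
  if (is.null(arena)) arena <- arena(ncol(grid), nrow(grid))
  new_landscape("raster", arena, max(max(grid), .Machine$double.eps),
                list(grid = grid))
}

#' Load a landscape from a specification list or YAML file
#'
#' The spec block is what the experiment config holds: a list with `kind`
#' plus the kind's geometry parameters; raster landscapes may point at a
#' grayscale PNG/TIFF or CSV grid via `file`.
#'
#' @param spec list (or path to a YAML file holding one).
#' @param arena default [arena()] used when the spec lacks `width_px` /
#'   `height_px`.
#' @return a `vrt_landscape`.
#' @export
landscape_from_spec <- function(spec, arena = NULL) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  if (is.null(arena)) {
    stopifnot(!is.null(spec$width_px), !is.null(spec$height_px))
    arena <- arena(spec$width_px, spec$height_px,
                   shape = spec$arena_shape %||% "rect")
  }
  kind <- match.arg(spec$kind, c("gaussian", "exponential", "volcano",
                                 "checkerboard", "raster"))
  switch(kind,
    gaussian = make_gaussian(unlist(spec$center), spec$sigma,
                             spec$i_max %||% 1, arena),
    exponential = make_exponential(unlist(spec$center), spec$lambda,
                                   spec$i_max %||% 1, arena),
    volcano = make_volcano(unlist(spec$center), spec$rim_radius,
                           spec$rim_width, spec$i_max %||% 1, arena),
    checkerboard = make_checkerboard(spec$square_size, spec$i_on %||% 1,
                                     spec$phase %||% 0, arena),
    raster = {
      g <- if (!is.null(spec$file)) {
        ext <- tolower(tools::file_ext(spec$file))
        if (ext == "csv") as.matrix(utils::read.csv(spec$file, header = FALSE))
        else read_gray_image(spec$file)
      } else {
        matrix(unlist(spec$grid), nrow = spec$grid_rows, byrow = TRUE)
      }
      make_raster(g, arena)
    })
}

#' Evaluate a landscape at positions
#'
#' Pure function: parametric kinds are evaluated in closed form at the exact
#' (sub-pixel) position; rasters are sampled nearest-neighbor. Positions
#' outside the arena return 0.
#'
#' @param landscape a `vrt_landscape`.
#' @param position_px numeric length-2 x,y or an n x 2 matrix.
#' @return numeric vector of intensities.
#' @export
intensity_at <- function(landscape, position_px) {
  p <- if (is.matrix(position_px)) position_px else
    matrix(position_px, ncol = 2)
  v <- intensity_eval(landscape, p)
  v[!in_arena(landscape$arena, p)] <- 0
  v[is.na(p[, 1]) | is.na(p[, 2])] <- NA_real_
  v
}

intensity_eval <- function(ls, p) UseMethod("intensity_eval")

#' @export
intensity_eval.vrt_landscape_gaussian <- function(ls, p) {
  r2 <- (p[, 1] - ls$center[1])^2 + (p[, 2] - ls$center[2])^2
  ls$i_max * exp(-r2 / (2 * ls$sigma^2))
}

#' @export
intensity_eval.vrt_landscape_exponential <- function(ls, p) {
  r <- sqrt((p[, 1] - ls$center[1])^2 + (p[, 2] - ls$center[2])^2)
  ls$i_max * exp(-r / ls$lambda)
}

#' @export
intensity_eval.vrt_landscape_volcano <- function(ls, p) {
  r <- sqrt((p[, 1] - ls$center[1])^2 + (p[, 2] - ls$center[2])^2)
  ls$i_max * exp(-(r - ls$rim_radius)^2 / (2 * ls$rim_width^2))
}

#' @export
intensity_eval.vrt_landscape_checkerboard <- function(ls, p) {
  odd <- (floor(p[, 1] / ls$square_size) + floor(p[, 2] / ls$square_size) +
            ls$phase) %% 2 == 1
  ifelse(odd, ls$i_max, 0)
}

#' @export
intensity_eval.vrt_landscape_raster <- function(ls, p) {
  r <- round(p[, 2]) + 1L
  cc <- round(p[, 1]) + 1L
  out <- numeric(nrow(p))
  ok <- !is.na(r) & !is.na(cc) & r >= 1 & r <= nrow(ls$grid) & cc >= 1 &
    cc <= ncol(ls$grid)
  out[ok] <- ls$grid[cbind(r[ok], cc[ok])]
  out
}

#' @export
print.vrt_landscape <- function(x, ...) {
  cat(sprintf("<vrt_landscape> kind=%s, I_max=%g, arena %gx%g (%s)\n",
              x$kind, x$i_max, x$arena$width_px, x$arena$height_px,
              x$arena$shape))
  invisible(x)
}

#' Render a landscape over the arena grid
#'
#' Samples the landscape at every pixel center; useful for inspection
#' (`landscape render` CLI subcommand) and for locating the raster argmax.
#'
#' @param landscape a `vrt_landscape`.
#' @return matrix `[height x width]` of intensities.
#' @export
landscape_render <- function(landscape) {
  w <- landscape$arena$width_px; h <- landscape$arena$height_px
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  matrix(intensity_at(landscape, cbind(xs, ys)), nrow = h, ncol = w)
}

#' Reference source point of a landscape
#'
#' The position a navigating animal is heading for: the intensity maximum
#' for point-source kinds (the center), the argmax pixel for rasters. For a
#' volcano the source is the rim circle, not a point; see
#' [distance_to_source()].
#'
#' @param landscape a `vrt_landscape`.
#' @return length-2 x,y in pixels.
#' @export
landscape_source <- function(landscape) {
  if (landscape$kind %in% c("gaussian", "exponential", "volcano"))
    return(landscape$center)
  if (landscape$kind == "raster") {
    g <- landscape$grid
    i <- which.max(g)
    return(c((i - 1) %/% nrow(g), (i - 1) %% nrow(g)))
  }
  stop("landscape kind '", landscape$kind, "' has no point source")
}
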