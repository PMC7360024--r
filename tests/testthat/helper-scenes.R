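# Shared fixtures: all scenes are built in code at test time.

# Minimal moving-blob scene on a uniform background: a dark square of side
# `side` starts at (x0, y0) and moves `step` px per frame along +x.
# Returns a memory frame source.
square_scene <- function(n_frames, dims = c(100, 120), bg = 200, dark = 80,
                         side = 11, x0 = 20, y0 = 40, step = 2,
                         frame_rate = 30) {
  frames <- lapply(seq_len(n_frames) - 1L, function(i) {
    m <- matrix(bg, dims[1], dims[2])
    x <- x0 + i * step
    m[(y0 + 1):(y0 + side), (x + 1):(x + side)] <- dark
    m
  })
  memory_frame_source(frames, frame_rate)
}

square_params <- function(side = 11) {
  animal_parameters(min_area_px = round(0.3 * side^2),
                    max_area_px = round(3 * side^2),
                    gaussian_sigma_px = 0, roi_padding_px = 12,
                    px_per_mm = 4.8, frame_rate_hz = 30)
}

# small raster landscape that is flat (constant intensity)
flat_landscape <- function(value = 0.5, w = 640, h = 480) {
  make_raster(matrix(value, h, w), arena(w, h))
}

# reference 8-connected labeling: slow double-loop flood fill
label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        r2 <- p[1] + dy; c2 <- p[2] + dx
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# canonicalize a labeling so two labelings can be compared exactly
canon_labels <- function(lab) {
  ord <- unique(lab[lab > 0])
  out <- lab
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

# exhaustive local-maxima oracle with greedy separation by descending height
bout_oracle <- function(x, min_h, min_sep) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (!is.na(x[i]) && !is.na(x[i - 1]) && x[i] > x[i - 1]) {
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && !is.na(x[j + 1]) && x[j + 1] < x[i]) {
        cand <- c(cand, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  cand <- cand[x[cand] >= min_h]
  keep <- integer(0)
  for (k in cand[order(-x[cand], cand)]) {
    if (all(abs(k - keep) >= min_sep)) keep <- c(keep, k)
  }
  sort(keep) - 1L
}

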