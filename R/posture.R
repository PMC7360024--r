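# Head/tail assignment from the blob silhouette. The binary mask is thinned
# to a 1-px morphological skeleton; skeleton pixels with exactly one
# neighbor are the body endpoints, one of which must be the head and the
# other the tail. The tail is the endpoint closer to the previous tail
# (or to the centroid when no history exists).

#' Topological thinning (skeletonization) of a binary mask
#'
#' Two-subiteration parallel thinning (Guo-Hall conditions): iteratively
#' peels boundary pixels that neither break 8-connectivity nor shorten the
#' medial line, until a 1-px-wide, 8-connected skeleton remains. Preserves
#' the full length of elongated blobs better than the classic two-pass
#' scheme, which retracts the skeleton inside wide rounded ends.
#'
#' @param mask logical matrix (one 8-connected component).
#' @return logical matrix of the same shape: the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(m)
  shift <- function(x, dy, dx) {
    out <- matrix(FALSE, nr, nc)
    ys <- max(1, 1 - dy):min(nr, nr - dy)
    xs <- max(1, 1 - dx):min(nc, nc - dx)
    out[ys, xs] <- x[ys + dy, xs + dx]
    out
  }
  repeat {
    changed <- FALSE
    for (odd in c(TRUE, FALSE)) {
      # neighbors x1..x8 = E, NE, N, NW, W, SW, S, SE
      x1 <- shift(m, 0, 1);  x2 <- shift(m, -1, 1)
      x3 <- shift(m, -1, 0); x4 <- shift(m, -1, -1)
      x5 <- shift(m, 0, -1); x6 <- shift(m, 1, -1)
      x7 <- shift(m, 1, 0);  x8 <- shift(m, 1, 1)
      # crossing number
      xh <- (!x1 & (x2 | x3)) + (!x3 & (x4 | x5)) +
        (!x5 & (x6 | x7)) + (!x7 & (x8 | x1))
      n1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
      n2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
      mn <- pmin(n1, n2)
      g2 <- mn >= 2 & mn <= 3
      g3 <- if (odd) !((x2 | x3 | !x8) & x1) else !((x6 | x7 | !x4) & x5)
      cond <- m & xh == 1 & g2 & g3
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeleton endpoints of a blob
#'
#' Thins the mask and returns the skeleton pixels having exactly one
#' skeleton neighbor (8-connectivity). When thinning artifacts leave more
#' than two endpoints, the pair farthest apart along the skeleton (geodesic
#' distance) is returned. The result is degenerate — no usable endpoints —
#' when the skeleton is a single pixel or a closed loop, and also when the
#' endpoints lie less than 4 px apart along the skeleton: a compact
#' (disk-like) blob thins to a residual stub that carries no body
#' orientation.
#'
#' @param mask logical matrix, one 8-connected component.
#' @return list with `endpoints` (n x 2 matrix of 0-based x,y; `NULL` when
#'   degenerate), `skeleton` (logical matrix) and `degenerate` flag.
#' @export
skeleton_endpoints <- function(mask) {
  sk <- skeletonize(mask)
  cnt <- neighbor_count(sk)
  ep <- which(sk & cnt == 1L, arr.ind = TRUE)
  if (nrow(ep) < 2)
    return(list(endpoints = NULL, skeleton = sk, degenerate = TRUE))
  pts <- cbind(x = ep[, 2] - 1L, y = ep[, 1] - 1L)
  if (nrow(pts) > 2) {
    # geodesic BFS from each endpoint along the skeleton
    best <- c(1L, 2L); bestd <- -1
    for (i in seq_len(nrow(ep))) {
      d <- skeleton_bfs(sk, ep[i, 1], ep[i, 2])
      for (j in seq_len(nrow(ep))) {
        if (j == i) next
        dij <- d[ep[j, 1], ep[j, 2]]
        if (is.finite(dij) && dij > bestd) {
          bestd <- dij; best <- c(i, j)
        }
      }
    }
    ep <- ep[best, , drop = FALSE]
    pts <- pts[best, , drop = FALSE]
  } else {
    bestd <- skeleton_bfs(sk, ep[1, 1], ep[1, 2])[ep[2, 1], ep[2, 2]]
  }
  if (!is.finite(bestd) || bestd < 4)
    return(list(endpoints = NULL, skeleton = sk, degenerate = TRUE))
  # deterministic order: smaller (y, x) first
  o <- order(pts[, "y"], pts[, "x"])
  list(endpoints = pts[o, , drop = FALSE], skeleton = sk, degenerate = FALSE)
}

# BFS geodesic distance over skeleton pixels from (r0, c0); unit steps.
skeleton_bfs <- function(sk, r0, c0) {
  nr <- nrow(sk); nc <- ncol(sk)
  d <- matrix(Inf, nr, nc)
  d[r0, c0] <- 0
  frontier <- matrix(c(r0, c0), ncol = 2)
  while (nrow(frontier)) {
    nxt <- NULL
    for (k in seq_len(nrow(frontier))) {
      r <- frontier[k, 1]; cc <- frontier[k, 2]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        r2 <- r + dy; c2 <- cc + dx
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (sk[r2, c2] && d[r2, c2] > d[r, cc] + 1) {
          d[r2, c2] <- d[r, cc] + 1
          nxt <- rbind(nxt, c(r2, c2))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
  }
  d
}

#' Assign head and tail among two skeleton endpoints
#'
#' Default rule: the endpoint with the smaller Euclidean distance to the
#' reference point (the previous frame's tail, or the centroid on the first
#' frame) is the tail; the other is the head. The optional `"assignment"`
#' mode solves the 2x2 correspondence between `(previous head, previous
#' tail)` and the two endpoints by minimizing summed distance, the form the
#' general matching algorithm reduces to with two candidates.
#'
#' Exact ties are broken toward preserving the previous head-tail axis
#' orientation when one is supplied, and otherwise toward the endpoint with
#' smaller `(y, x)` as tail.
#'
#' @param endpoints 2 x 2 matrix of 0-based x,y rows.
#' @param reference previous tail, or centroid fallback (length-2 x,y).
#' @param prev_head optional previous head position (enables the axis
#'   tie-break and the `"assignment"` mode).
#' @param mode `"nearest"` (default) or `"assignment"`.
#' @return list with `head` and `tail`, each length-2 x,y.
#' @export
assign_head_tail <- function(endpoints, reference, prev_head = NULL,
                             mode = c("nearest", "assignment")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(endpoints), nrow(endpoints) == 2)
  e1 <- as.numeric(endpoints[1, ]); e2 <- as.numeric(endpoints[2, ])
  d1 <- sqrt(sum((e1 - reference)^2)); d2 <- sqrt(sum((e2 - reference)^2))
  if (mode == "assignment" && !is.null(prev_head)) {
    # permutation 1: tail = e1, head = e2; permutation 2: the swap
    c1 <- d1 + sqrt(sum((e2 - prev_head)^2))
    c2 <- d2 + sqrt(sum((e1 - prev_head)^2))
    if (c1 < c2) return(list(head = e2, tail = e1))
    if (c2 < c1) return(list(head = e1, tail = e2))
    # fall through to tie handling
  } else if (d1 < d2) {
    return(list(head = e2, tail = e1))
  } else if (d2 < d1) {
    return(list(head = e1, tail = e2))
  }
  # exact tie
  if (!is.null(prev_head)) {
    axis <- prev_head - reference
    if (sum((e2 - e1) * axis) >= 0) return(list(head = e2, tail = e1))
    return(list(head = e1, tail = e2))
  }
  # endpoints are (y, x)-sorted, so endpoint 1 is the tail
  list(head = e2, tail = e1)
}

#' Posture (head/tail) from a blob mask
#'
#' Convenience wrapper: skeletonize, extract endpoints, and assign head and
#' tail relative to a reference point. Degenerate skeletons (disk-like blobs,
#' loops) yield missing head/tail rather than fabricated points.
#'
#' @param mask ROI-local logical blob mask.
#' @param origin 0-based x,y of the mask's top-left pixel in the frame.
#' @param reference previous tail (frame coords), or centroid fallback.
#' @param prev_head optional previous head (frame coords).
#' @param mode see [assign_head_tail()].
#' @return list with `head`, `tail` (frame coords or `NULL`), `endpoints`,
#'   `degenerate`.
#' @export
blob_posture <- function(mask, origin, reference, prev_head = NULL,
                         mode = "nearest") {
  se <- skeleton_endpoints(mask)
  if (se$degenerate)
    return(list(head = NULL, tail = NULL, endpoints = NULL,
                degenerate = TRUE))
  ep <- se$endpoints
  ep[, 1] <- ep[, 1] + origin[1]
  ep[, 2] <- ep[, 2] + origin[2]
  ht <- assign_head_tail(ep, reference, prev_head = prev_head, mode = mode)
  list(head = ht$head, tail = ht$tail, endpoints = ep, degenerate = FALSE)
}
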