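test_that("tracking threshold sits three standard deviations below the mean", {
  p <- animal_parameters(min_area_px = 30, max_area_px = 200,
                         gaussian_sigma_px = 0, roi_padding_px = 10)
  # background minus frame difference with mean 0 and sd 2 -> threshold -6:
  # a 49-px blob at -6.5 is found, at -5.5 it is not
  set.seed(21)
  bg <- matrix(150, 60, 60)
  for (depth in c(6.5, 5.5)) {
    d <- matrix(2 * rep(c(-1, 1), length.out = 3600), 60, 60)
    d[20:26, 20:26] <- -depth
    d <- d - mean(d)
    d <- d * (2 / stats::sd(as.vector(d)))  # pin sd exactly at 2
    obs <- track_frame(bg + d, bg, c(0L, 0L, 59L, 59L), p)
    thr <- mean(d) - 3 * stats::sd(as.vector(d))
    if (-depth < thr) expect_s3_class(obs, "vrt_blob") else expect_null(obs)
  }
})

test_that("a uniform region of interest is a lost outcome", {
  p <- square_params()
  bg <- matrix(150, 40, 40)
  expect_null(track_frame(bg, bg, c(0L, 0L, 39L, 39L), p))
})

test_that("the largest valid blob wins over speckles", {
  p <- animal_parameters(min_area_px = 50, max_area_px = 300,
                         gaussian_sigma_px = 0, roi_padding_px = 8)
  bg <- matrix(200, 60, 60)
  fr <- bg
  fr[20:29, 20:31] <- 80  # 120-px animal
  fr[45:47, 45:47] <- 80  # 9-px speckle (below min area)
  obs <- track_frame(fr, bg, c(0L, 0L, 59L, 59L), p)
  expect_equal(obs$area, 120)
  # brute-force component enumeration oracle
  lab <- label_components((fr - bg) < -10)
  st <- vrtracker:::component_stats(lab)
  areas <- vapply(st, function(s) s$area, numeric(1))
  big <- st[[which.max(areas)]]
  expect_equal(obs$centroid, big$centroid, tolerance = 1e-9)
  # next search box is the blob box expanded by the padding, clipped
  expect_equal(obs$next_roi, c(19 - 8, 19 - 8, 30 + 8, 28 + 8))
})

test_that("the closed-loop run logs a causal, truncation-stable stimulus", {
  ls <- make_gaussian(center = c(319.5, 239.5), sigma = 72,
                      arena = synthetic_arena())
  gt <- simulate_fish(ls, seed = 11, n_frames = 260, gain = 0)
  rv <- render_video(gt, render_params(noise_sd = 0), seed = 11)
  p <- animal_parameters("fish")
  run <- run_closed_loop(rv$source, p, ls, lag_frames = 1,
                         tracked_point = "centroid")
  nf <- 260
  expect_equal(nrow(run$stimulus), nf)
  # truncating the source at frame T leaves I(0..T) unchanged
  gt_t <- gt
  gt_t$trajectory <- gt$trajectory[1:200, ]
  rv_t <- render_video(gt_t, render_params(noise_sd = 0), seed = 11)
  run_t <- run_closed_loop(rv_t$source, p, ls, lag_frames = 1,
                           tracked_point = "centroid")
  expect_identical(run_t$stimulus$intensity, run$stimulus$intensity[1:200])
  # I(t) equals the landscape at the logged tracked point at t - lag, exactly
  tr <- run$trajectory
  for (t in which(tr$valid)) {
    tt <- t + 1  # command lands one frame later
    if (tt <= nf) {
      expect_equal(run$stimulus$intensity[tt],
                   intensity_at(ls, c(tr$x[t], tr$y[t])), tolerance = 1e-12)
    }
  }
  # frames before the first command carry intensity zero
  first_valid <- which(tr$valid)[1]
  expect_true(all(run$stimulus$intensity[seq_len(first_valid)] == 0))
})

test_that("a static scene aborts with a diagnostic", {
  frames <- lapply(1:20, function(i) {
    m <- matrix(200, 100, 120); m[41:51, 21:31] <- 80; m
  })
  src <- memory_frame_source(frames, 30)
  expect_error(run_closed_loop(src, square_params(), NULL),
               "no unique motion blob|never moved")
})

test_that("repeated closed-loop runs are bit-identical", {
  ls <- make_gaussian(center = c(319.5, 239.5), sigma = 72,
                      arena = synthetic_arena())
  gt <- simulate_fish(ls, seed = 5, n_frames = 200, gain = 1)
  p <- animal_parameters("fish")
  r1 <- run_closed_loop(render_video(gt, render_params(noise_sd = 2),
                                     seed = 5)$source, p, ls)
  r2 <- run_closed_loop(render_video(gt, render_params(noise_sd = 2),
                                     seed = 5)$source, p, ls)
  expect_identical(r1$stimulus$intensity, r2$stimulus$intensity)
  expect_identical(as.data.frame(r1$trajectory), as.data.frame(r2$trajectory))
})

test_that("the next search box always contains the next true position", {
  ls <- flat_landscape()
  gt <- simulate_fish(ls, seed = 9, n_frames = 250, gain = 0)
  rv <- render_video(gt, render_params(noise_sd = 0), seed = 9)
  p <- animal_parameters("fish")
  run <- run_closed_loop(rv$source, p, ls, tracked_point = "centroid")
  tr <- run$trajectory
  gtr <- gt$trajectory
  rows <- which(tr$valid)
  rows <- rows[rows + 1 <= nrow(tr) & tr$valid[pmin(rows + 1, nrow(tr))]]
  for (i in rows) {
    # displacement bounded by the padding -> containment guaranteed
    nxt <- c(gtr$x[i + 1], gtr$y[i + 1])
    disp <- sqrt(sum((nxt - c(gtr$x[i], gtr$y[i]))^2))
    if (disp <= p$roi_padding_px) {
      roi <- unlist(tr[i + 1, c("roi_x0", "roi_y0", "roi_x1", "roi_y1")])
      expect_true(nxt[1] >= roi[1] && nxt[1] <= roi[3] &&
                    nxt[2] >= roi[2] && nxt[2] <= roi[4])
    }
  }
})
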