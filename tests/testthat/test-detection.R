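test_that("preprocess with sigma 0 is the identity and constants pass through", {
  src <- square_scene(2)
  f <- get_frame(src, 0)
  expect_identical(preprocess(f, 0), f)
  cf <- list(index = 0L, time_s = 0, pixels = matrix(128, 20, 20))
  expect_lt(max(abs(preprocess(cf, 2)$pixels - 128)), 1e-12)
})

test_that("no motion means no detection, however long the scene", {
  p <- square_params()
  m <- get_frame(square_scene(1), 0)$pixels
  for (i in 1:20) expect_null(detect_motion(m, m, p))
})

test_that("motion threshold sits 4 gray levels below the difference mean", {
  p <- square_params(side = 7)
  # craft mean/current whose difference D = current - mean has mean 9.7;
  # a blob of pixels at 5.5 (below the 5.7 threshold) must be detected,
  # the same blob at 5.9 must not
  base <- matrix(100, 60, 60)
  for (blobval in c(5.5, 5.9)) {
    d <- matrix(9.7 + 0.2 * rep(c(-1, 1), length.out = 3600), 60, 60)
    d[20:26, 20:26] <- blobval
    d <- d - (mean(d) - 9.7)  # pin the mean exactly
    roi <- detect_motion(base, base + d, p)
    if (blobval < 5.7) expect_false(is.null(roi)) else expect_null(roi)
  }
})

test_that("a moved blob yields its padded bounding box", {
  p <- square_params()
  src <- square_scene(12, step = 3)
  f0 <- get_frame(src, 0)$pixels
  f6 <- get_frame(src, 6)$pixels
  mean_img <- (f0 + f6) / 2
  roi <- detect_motion(mean_img, f6, p)
  expect_false(is.null(roi))
  # brute-force oracle: the box must contain the blob's current position
  w <- which(f6 < 150, arr.ind = TRUE)
  expect_true(all(w[, 2] - 1 >= roi[1] & w[, 2] - 1 <= roi[3]))
  expect_true(all(w[, 1] - 1 >= roi[2] & w[, 1] - 1 <= roi[4]))
})

test_that("local threshold calibration accepts exactly one animal-sized blob", {
  p <- animal_parameters(min_area_px = 50, max_area_px = 300,
                         gaussian_sigma_px = 0, roi_padding_px = 10)
  roi <- matrix(200, 40, 40)
  roi[10:19, 10:21] <- 60  # 120-px blob
  cal <- calibrate_local_threshold(roi, p)
  expect_gt(cal$threshold, 60)
  expect_lt(cal$threshold, 200)
  expect_equal(sum(cal$mask), 120)
  expect_identical(unname(which(cal$mask)), unname(which(roi == 60)))
})

test_that("calibration fails on uniform and on twin-blob regions", {
  p <- animal_parameters(min_area_px = 50, max_area_px = 300,
                         gaussian_sigma_px = 0, roi_padding_px = 10)
  expect_error(calibrate_local_threshold(matrix(200, 30, 30), p),
               "no unique animal blob")
  two <- matrix(200, 40, 40)
  two[5:14, 5:14] <- 60
  two[25:34, 25:34] <- 60
  expect_error(calibrate_local_threshold(two, p), "no unique animal blob")
})

test_that("background reconstruction is exact on a zero-noise scene", {
  src <- square_scene(40, step = 2)  # 11-px square moving 2 px/frame
  p <- square_params()
  det <- detect_animal(src, p)
  expect_lt(max(abs(det$background - 200)), 1e-9)
  # the reconstructed background, binarized with the calibrated threshold,
  # contains no valid-area component
  mask <- det$background < det$local_threshold
  st <- vrtracker:::component_stats(label_components(mask))
  areas <- vapply(st, function(s) s$area, numeric(1))
  expect_false(any(areas >= p$min_area_px & areas <= p$max_area_px))
})

test_that("an animal that never moves exhausts the reconstruction budget", {
  # blob jitters by 1 px but never vacates its footprint
  frames <- lapply(1:30, function(i) {
    m <- matrix(200, 100, 120)
    x <- 20 + (i %% 2)
    m[41:51, (x + 1):(x + 11)] <- 80
    m
  })
  src <- memory_frame_source(frames, 30)
  expect_error(detect_animal(src, square_params()),
               "never moved|no unique motion blob")
})

test_that("detection fires only after real displacement on a static lead-in", {
  frames <- c(
    lapply(1:15, function(i) {
      m <- matrix(200, 100, 120); m[41:51, 21:31] <- 80; m
    }),
    lapply(1:25, function(i) {
      m <- matrix(200, 100, 120)
      x <- 20 + 2 * i
      m[41:51, (x + 1):(x + 11)] <- 80
      m
    }))
  src <- memory_frame_source(frames, 30)
  det <- detect_animal(src, square_params())
  expect_gte(det$motion_frame, 15)
})

test_that("calibration result is independent of the starting offset", {
  p <- animal_parameters(min_area_px = 50, max_area_px = 300,
                         gaussian_sigma_px = 0, roi_padding_px = 10)
  roi <- matrix(200, 40, 40)
  roi[10:19, 10:21] <- 60
  cal1 <- calibrate_local_threshold(roi, p)
  # well-separated bimodal input: any accepted threshold marks the same blob
  roi2 <- roi + 10
  cal2 <- calibrate_local_threshold(roi2, p)
  expect_identical(cal1$mask, cal2$mask)
})
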