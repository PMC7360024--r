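make_traj <- function(x, y, rate = 30, ppm = 4.8, valid = TRUE) {
  n <- length(x)
  trajectory(data.frame(
    frame = 0:(n - 1), time_s = (0:(n - 1)) / rate, x = x, y = y,
    head_x = x, head_y = y, tail_x = x, tail_y = y, area_px = 100,
    roi_x0 = 0L, roi_y0 = 0L, roi_x1 = 10L, roi_y1 = 10L,
    valid = rep_len(valid, n)), px_per_mm = ppm, frame_rate_hz = rate)
}

test_that("triangular filter: identity window, constants, impulse weights", {
  x <- runif(30)
  expect_equal(smooth_triangular(x, 1), x)
  expect_equal(smooth_triangular(rep(3, 20), 7), rep(3, 20))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- smooth_triangular(imp, 5)
  # direct weighted-sum oracle: kernel (1,2,3,2,1)/9 centered on the impulse
  expect_equal(out[9:13], c(1, 2, 3, 2, 1) / 9, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("half-triangular filter is causal", {
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- smooth_half_triangular(imp, 6)
  expect_true(all(out[1:10] == 0))      # nothing before the impulse
  expect_equal(out[11], 6 / 21)          # current sample has maximal weight
  expect_true(all(out[17:21] == 0))      # support ends after window frames
})

test_that("position smoothing window follows the speed-bound rule", {
  # 30 fps, 1 mm/s bound, ~3.33 px/mm -> 9 frames (0.3 s)
  expect_equal(position_smoothing_window(30, 1, 10 / 3), 9)
  # fly: 5 mm/s bound -> 2 frames (~0.07 s)
  expect_equal(position_smoothing_window(30, 5, 3), 2)
  expect_equal(position_smoothing_window(30, 100, 10), 1)  # clamped
})

test_that("speed of uniform motion matches the closed form", {
  n <- 120
  traj <- make_traj(x = (0:(n - 1)) * 1.0, y = rep(50, n), ppm = 10)
  sp <- compute_speed(traj, "larva")
  # 1 px/frame at 30 fps and 10 px/mm -> 3 mm/s away from the edges
  expect_equal(sp[40:80], rep(3, 41), tolerance = 1e-9)
  stat <- compute_speed(make_traj(rep(5, 60), rep(5, 60)), "larva")
  expect_true(all(abs(stat[-1]) < 1e-12))
})

test_that("doubling px_per_mm halves reported speeds", {
  # fish smoothing windows are time-based, so the calibration is a pure
  # scale factor and the halving is exact
  set.seed(3)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  s1 <- compute_speed(make_traj(x, y, ppm = 4), "fish")
  s2 <- compute_speed(make_traj(x, y, ppm = 8), "fish")
  expect_equal(s1, 2 * s2, tolerance = 1e-12)
})

test_that("speed pipeline matches a brute-force recomputation", {
  set.seed(9)
  x <- cumsum(rnorm(200, 0, 2)); y <- cumsum(rnorm(200, 0, 2))
  traj <- make_traj(x, y, ppm = 4.8)
  got <- compute_speed(traj, "larva")
  w <- position_smoothing_window(30, 1, 4.8)
  xs <- smooth_triangular(x, w); ys <- smooth_triangular(y, w)
  sp <- c(NA, sqrt(diff(xs)^2 + diff(ys)^2)) * 30 / 4.8
  expect_equal(got, smooth_triangular(sp, 30), tolerance = 1e-9)
})

test_that("sensory experience recovers exponential growth rates", {
  rate <- 30
  t <- (0:299) / rate
  I <- 2 * exp(0.4 * t)
  e <- sensory_experience(I, rate)
  mid <- 100:200
  expect_equal(mean(e[mid]), 0.4, tolerance = 0.01)
  expect_true(all(abs(sensory_experience(rep(5, 100), rate)[16:85]) < 1e-12))
  withz <- sensory_experience(c(rep(0, 50), rep(2, 50)), rate)
  expect_true(all(is.na(withz[1:20])))
})

test_that("distance to a volcano rim equals | |p-c| - R | (brute force)", {
  ar <- arena(640, 480)
  ls <- make_volcano(center = c(320, 240), rim_radius = 96, rim_width = 24,
                     arena = ar)
  set.seed(4)
  x <- runif(50, 0, 639); y <- runif(50, 0, 479)
  traj <- make_traj(x, y, ppm = 4.8)
  got <- distance_to_source(traj, ls, mode = "volcano_rim")
  # brute force: min distance to 10,000 points on the rim circle
  th <- seq(0, 2 * pi, length.out = 10000)
  rim <- cbind(320 + 96 * cos(th), 240 + 96 * sin(th))
  brute <- vapply(seq_along(x), function(i) {
    min(sqrt((rim[, 1] - x[i])^2 + (rim[, 2] - y[i])^2))
  }, numeric(1)) / 4.8
  expect_equal(got, brute, tolerance = 1e-4)
  # animal at the center is rim_radius away
  expect_equal(distance_to_source(make_traj(320, 240), ls,
                                  mode = "volcano_rim"),
               96 / 4.8, tolerance = 1e-9)
  expect_error(distance_to_source(traj, make_gaussian(c(320, 240), 50,
                                                      arena = ar),
                                  mode = "volcano_rim"), "volcano")
})

test_that("distance to source: landscape max, marked source, control", {
  ar <- arena(640, 480)
  ls <- make_gaussian(center = c(100, 100), sigma = 50, arena = ar)
  traj <- make_traj(c(100, 130), c(100, 140))
  d <- distance_to_source(traj, ls, mode = "landscape_max")
  expect_equal(d, c(0, 50 / 4.8), tolerance = 1e-9)
  d2 <- distance_to_source(traj, mode = "real_source", source_xy = c(70, 60))
  expect_equal(d2[1], 50 / 4.8, tolerance = 1e-9)
  # control: source sits at the stated offset from the start position
  d3 <- distance_to_source(traj, mode = "relative_control",
                           control_offset = c(30, 40))
  expect_equal(d3, c(50 / 4.8, 0), tolerance = 1e-9)
})

test_that("preference index matches direct occupancy arithmetic", {
  ar <- arena(640, 480)
  cb <- make_checkerboard(square_size = 320, i_on = 1, arena = ar)
  # 100 s in an ON square, 200 s in an OFF square at 30 fps
  n_on <- 100 * 30; n_off <- 200 * 30
  x <- c(rep(350, n_on), rep(100, n_off))
  y <- rep(100, n_on + n_off)
  expect_equal(intensity_at(cb, c(350, 100)), 1)
  expect_equal(intensity_at(cb, c(100, 100)), 0)
  res <- preference_index(make_traj(x, y), cb)
  expect_equal(res$PI, -1 / 3, tolerance = 1e-12)
  expect_equal(res$T_on_s, 100)
  all_on <- preference_index(make_traj(rep(350, 10), rep(100, 10)), cb)
  expect_equal(all_on$PI, 1)
  expect_error(preference_index(make_traj(1, 1, valid = FALSE), cb),
               "zero valid")
})

test_that("bout detection equals the exhaustive oracle on random traces", {
  set.seed(11)
  bp <- bout_params()
  for (i in 1:100) {
    x <- pmax(0, stats::filter(rnorm(200, 1.5, 1.5), rep(1 / 3, 3),
                               circular = TRUE))
    x <- as.numeric(x)
    expect_identical(detect_bouts(x, bp),
                     bout_oracle(x, bp$min_peak_speed_mm_s,
                                 bp$min_separation_frames))
  }
})

test_that("bout detection spec examples hold", {
  x <- rep(0, 40); x[11] <- 3; x[21] <- 3
  expect_equal(detect_bouts(x), c(10, 20))
  expect_length(detect_bouts(replace(rep(0, 30), 16, 2.0)), 0)
  x2 <- rep(0, 40); x2[11] <- 3; x2[14] <- 2.8
  expect_equal(detect_bouts(x2), 10)
})

test_that("turn angles: collinear, right angle, reversal filtering", {
  rate <- 30
  bp <- bout_params()
  w <- round(bp$turn_window_s * rate)  # 20 frames
  seg <- function(from, to, n) cbind(seq(from[1], to[1], length.out = n),
                                     seq(from[2], to[2], length.out = n))
  # piecewise path: straight, then a right-angle turn at the second peak
  p <- rbind(seg(c(0, 0), c(60, 0), 61), seg(c(61, 1), c(60, 60), 60))
  traj <- make_traj(p[, 1], p[, 2])
  peaks <- c(30, 90)
  bouts <- bout_kinematics(traj, peaks, bp)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$theta_deg, 90, tolerance = 2)
  # collinear motion: zero turn
  straight <- make_traj(seq(0, 200, length.out = 150), rep(0, 150))
  b2 <- bout_kinematics(straight, c(40, 100), bp)
  expect_equal(b2$theta_deg, 0, tolerance = 1e-9)
  # full reversal: discarded by the 135-degree rule
  rev <- rbind(seg(c(0, 0), c(60, 0), 61), seg(c(59, 0), c(0, 0), 60))
  b3 <- bout_kinematics(make_traj(rev[, 1], rev[, 2]), c(30, 90), bp)
  expect_equal(nrow(b3), 0)
})

test_that("theta is invariant under rotation and translation", {
  set.seed(12)
  n <- 400
  x <- cumsum(rnorm(n, 1, 2)); y <- cumsum(rnorm(n, 0, 2))
  peaks <- seq(30, 370, by = 45)
  b0 <- bout_kinematics(make_traj(x, y), peaks, bout_params())
  phi <- 0.7
  xr <- 100 + cos(phi) * x - sin(phi) * y
  yr <- -40 + sin(phi) * x + cos(phi) * y
  b1 <- bout_kinematics(make_traj(xr, yr), peaks, bout_params())
  expect_equal(b1$theta_deg, b0$theta_deg, tolerance = 1e-9)
})

test_that("delta_I flips sign when the landscape is inverted", {
  ar <- arena(640, 480)
  set.seed(13)
  n <- 300
  x <- 100 + cumsum(rnorm(n, 1, 1)); y <- 100 + cumsum(rnorm(n, 0.5, 1))
  traj <- make_traj(x, y)
  ls <- make_gaussian(center = c(320, 240), sigma = 150, arena = ar)
  inv <- make_raster(1 - landscape_render(ls), ar)
  peaks <- seq(30, 270, by = 40)
  b <- bout_kinematics(traj, peaks, intensity = intensity_at(ls, cbind(x, y)))
  bi <- bout_kinematics(traj, peaks,
                        intensity = intensity_at(inv, cbind(x, y)))
  # the raster inversion is sampled at pixel centers; signs must flip
  expect_true(all(sign(b$delta_I) == -sign(bi$delta_I)))
})

test_that("turn index counts toward and away bouts per the 90-degree rule", {
  mk <- function(alpha) data.frame(alpha_deg = alpha)
  expect_equal(turn_index(mk(c(10, 20, 80))), 1)
  expect_equal(turn_index(mk(c(10, 170))), 0)
  expect_equal(turn_index(mk(c(rep(45, 6), rep(135, 4)))), 0.2)
  # alpha exactly 90 stays in the denominator only
  expect_equal(turn_index(mk(c(45, 90, 135, 45))), 1 / 4)
  expect_true(is.na(turn_index(mk(numeric(0)))))
})

test_that("inclusion criteria gate on path length and tracked fraction", {
  crit <- inclusion_criteria()
  # stationary animal: excluded
  still <- apply_inclusion(make_traj(rep(100, 9000), rep(100, 9000)), crit)
  expect_false(still$included)
  expect_equal(still$total_path_mm, 0)
  # 25 mm path, fully tracked: included (steps of 1.25 mm > 1 mm noise gate)
  n <- 20
  moving <- make_traj(seq(0, 25 * 4.8, length.out = n + 1), rep(0, n + 1))
  res <- apply_inclusion(moving, crit)
  expect_true(res$included)
  expect_equal(res$total_path_mm, 25, tolerance = 1e-9)
  # same path but tracked 2 of 5 minutes: excluded
  nn <- 9000
  x <- c(seq(0, 25 * 4.8, length.out = 3600), rep(25 * 4.8, nn - 3600))
  part <- make_traj(x, rep(0, nn), valid = c(rep(TRUE, 3600),
                                             rep(FALSE, nn - 3600)))
  expect_false(apply_inclusion(part, crit)$included)
  # sub-threshold jitter is treated as noise
  jit <- make_traj(100 + cumsum(rep(c(1, -1), 400)), rep(0, 800))
  expect_equal(apply_inclusion(jit, crit)$total_path_mm, 0)
})

test_that("intensity binning groups thetas and splits by gradient sign", {
  b <- data.frame(theta_deg = c(10, 20, 30, 40, 50, 60),
                  delta_I = c(-1, 1, -1, 1, -1, 1),
                  I_prev = c(0.1, 0.1, 0.4, 0.4, 0.8, 0.8))
  g <- bin_by_intensity(b, c(0, 0.25, 0.5, 1))
  expect_equal(g$n, c(2, 2, 2))
  expect_equal(g$mean_theta, c(15, 35, 55))
  gs <- bin_by_intensity(b, c(0, 0.25, 0.5, 1), split_by_delta = TRUE)
  expect_equal(sum(gs$n), 6)  # the split partitions each bin exactly
  expect_equal(gs$mean_theta[gs$bin == 1 & gs$gradient == "down"], 10)
  # all bouts in one bin leaves the others empty
  g1 <- bin_by_intensity(b, c(0, 1, 2, 3))
  expect_equal(g1$n, c(6, 0, 0))
})

test_that("group comparisons delegate to standard tests with Bonferroni", {
  set.seed(14)
  gr <- list(a = rnorm(40, 10), b = rnorm(40, 30), c = rnorm(40, 10.2))
  res <- compare_theta_groups(gr, list(c("a", "b"), c("a", "c")))
  expect_lt(res$p_value[1], 0.001)
  expect_gt(res$p_value[2], 0.05)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 2), tolerance = 1e-12)
})
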