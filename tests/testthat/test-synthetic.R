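test_that("generators are bit-exact for a fixed seed and leave the RNG alone", {
  ls <- flat_landscape()
  set.seed(123)
  before <- .Random.seed
  g1 <- simulate_larva(ls, seed = 42, n_frames = 120)
  expect_identical(.Random.seed, before)  # private RNG stream
  g2 <- simulate_larva(ls, seed = 42, n_frames = 120)
  expect_identical(g1$trajectory, g2$trajectory)
  f1 <- simulate_fish(ls, seed = 7, n_frames = 120, gain = 2)
  f2 <- simulate_fish(ls, seed = 7, n_frames = 120, gain = 2)
  expect_identical(f1$trajectory, f2$trajectory)
  y1 <- simulate_fly(ls, seed = 9, n_frames = 120, gain = 1)
  y2 <- simulate_fly(ls, seed = 9, n_frames = 120, gain = 1)
  expect_identical(y1$trajectory, y2$trajectory)
})

test_that("gain-0 walks on a flat landscape have no net drift", {
  ls <- flat_landscape()
  net <- vapply(1:40, function(s) {
    tr <- simulate_larva(ls, seed = s, n_frames = 400, gain = 0)$trajectory
    n <- nrow(tr)
    c((tr$x[n] - tr$x[1]), (tr$y[n] - tr$y[1]))
  }, numeric(2))
  # mean net displacement compatible with zero at Monte-Carlo precision
  se <- apply(net, 1, stats::sd) / sqrt(ncol(net))
  expect_lt(abs(mean(net[1, ])), 3.5 * se[1] + 1e-9)
  expect_lt(abs(mean(net[2, ])), 3.5 * se[2] + 1e-9)
})

test_that("rendered frames honor the stated imaging model", {
  ls <- flat_landscape()
  gt <- simulate_fish(ls, seed = 3, n_frames = 5)
  rv <- render_video(gt, render_params(background_gray = 200, contrast = 80,
                                       noise_sd = 0), seed = 3)
  f <- get_frame(rv$source, 2)
  vals <- sort(unique(as.vector(f$pixels)))
  expect_identical(vals, c(120, 200))  # animal exactly background - contrast
  # the animal's silhouette covers the ground-truth centroid
  row <- 3
  expect_equal(f$pixels[round(gt$trajectory$y[row]) + 1,
                        round(gt$trajectory$x[row]) + 1], 120)
  # noise + quantization: integer gray values in range
  rvn <- render_video(gt, render_params(noise_sd = 3), seed = 3)
  fn <- get_frame(rvn$source, 2)
  expect_true(all(fn$pixels == round(fn$pixels)))
  expect_true(all(fn$pixels >= 0 & fn$pixels <= 255))
  # per-frame noise streams are index-keyed: same frame, same pixels
  expect_identical(get_frame(rvn$source, 2)$pixels, fn$pixels)
})

test_that("rendering rejects ground truth outside the frame", {
  ls <- flat_landscape()
  gt <- simulate_fish(ls, seed = 3, n_frames = 5)
  gt$trajectory$x[3] <- 900
  expect_error(render_video(gt, render_params()), "outside frame")
})

test_that("ground truth round-trips through the trajectory CSV schema", {
  ls <- flat_landscape()
  gt <- simulate_larva(ls, seed = 6, n_frames = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(gt$trajectory, path)
  back <- read_trajectory(path)
  expect_equal(back$x, gt$trajectory$x, tolerance = 1e-12)
  expect_equal(back$intensity, gt$trajectory$intensity, tolerance = 1e-12)
  expect_equal(back$mid_x, gt$trajectory$mid_x, tolerance = 1e-12)
})

test_that("chemotaxing larvae approach the gaussian peak, controls do not", {
  ar <- synthetic_arena()
  ls <- make_gaussian(center = c(319.5, 239.5), sigma = 72, arena = ar)
  final_dist <- function(seed, gain) {
    tr <- simulate_larva(ls, seed, n_frames = 900, gain = gain)$trajectory
    d <- distance_to_source(tr, ls, mode = "landscape_max",
                            tracked_point = "head")
    d[length(d)]
  }
  d_gain <- vapply(1:15, final_dist, numeric(1), gain = 4)
  d_ctrl <- vapply(1:15, final_dist, numeric(1), gain = 0)
  expect_lt(median(d_gain), median(d_ctrl))
})

test_that("speed-modulating flies avoid lit squares", {
  ar <- synthetic_arena()
  cb <- make_checkerboard(square_size = 120, i_on = 1, arena = ar)
  pi_of <- function(seed, gain) {
    tr <- simulate_fly(cb, seed, n_frames = 900, gain = gain)$trajectory
    preference_index(tr, cb)$PI
  }
  p_mod <- vapply(1:15, pi_of, numeric(1), gain = 1)
  expect_lt(median(p_mod), 0)
})

test_that("rendered and tracked fish recover their own bout structure", {
  ar <- synthetic_arena()
  ls <- make_gaussian(center = c(319.5, 239.5), sigma = 72, arena = ar)
  gt <- simulate_fish(ls, seed = 21, n_frames = 400, gain = 0)
  rv <- render_video(gt, render_params(noise_sd = 0), seed = 21)
  run <- run_closed_loop(rv$source, animal_parameters("fish"), ls,
                         tracked_point = "centroid")
  tr <- run$trajectory
  v <- tr$valid
  err <- sqrt((tr$x - gt$trajectory$x)^2 + (tr$y - gt$trajectory$y)^2)
  expect_lte(sqrt(mean(err[v]^2)), 1)  # end-to-end render->track oracle
  # bouts seen by the tracker match the ground-truth bout count closely
  sp_t <- compute_speed(tr, "fish")
  sp_g <- compute_speed(gt$trajectory, "fish")
  expect_lte(abs(length(detect_bouts(sp_t)) - length(detect_bouts(sp_g))), 2)
})
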