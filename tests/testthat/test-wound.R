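# Collective wound-front statistics.

small_wound <- function(...) {
  simulate_wound(width_px = 100, height_px = 50, initial_gap = 120,
                 front_speed = 10, pixel_size = 2, n_frames = 20, ...)
}

test_that("gap area counts background pixels times pixel area", {
  expect_equal(gap_area(matrix(1, 5, 5), 2), 0)
  expect_equal(gap_area(matrix(0, 10, 10), 2), 400)
  expect_error(gap_area(matrix(2, 3, 3), 1), "binary")
})

test_that("closure rate follows (A0 - An)/A0 x 100", {
  expect_equal(closure_rate(80, 80), 0)
  expect_equal(closure_rate(80, 0), 100)
  expect_equal(closure_rate(80, 20), 75)
  for (A0 in c(1, 50, 1e4)) {
    expect_equal(closure_rate(A0, A0), 0)
    expect_equal(closure_rate(A0, 0), 100)
  }
  expect_error(closure_rate(0, 0), "A0")
  expect_warning(r <- closure_rate(10, 12), "retraction")
  expect_lt(r, 0)
})

test_that("time to fractional closure interpolates linearly", {
  lin <- data.frame(t_h = 0:10, closed_pct = 10 * (0:10))
  expect_equal(time_to_fraction(lin, 50), 5)
  brk <- data.frame(t_h = c(0, 4, 6), closed_pct = c(0, 40, 60))
  expect_equal(time_to_fraction(brk, 50), 5)
  plateau <- data.frame(t_h = 0:5, closed_pct = c(0, 10, 20, 30, 30, 30))
  expect_warning(t50 <- time_to_fraction(plateau, 50), "never")
  expect_true(is.na(t50))
  expect_error(time_to_fraction(lin, 0), "fraction")
  expect_error(time_to_fraction(lin, 101), "fraction")
})

test_that("closure series of a monotone wound is monotone with 0% at t0", {
  sim <- small_wound(roughness_variance = 2, seed = 21)
  cs <- closure_series(sim$stack)
  expect_equal(cs$closed_pct[1], 0)
  expect_true(all(diff(cs$closed_pct) >= 0))
  expect_true(all(cs$closed_pct >= 0 & cs$closed_pct <= 100))
})

test_that("front velocity matches the configured closure speed and integrates", {
  v <- 10
  sim <- small_wound(roughness_variance = 0, seed = 2)
  cs <- closure_series(sim$stack)
  wound_len <- 50 * 2  # height_px x pixel_size
  fv <- front_velocity(cs, wound_length = wound_len, window = 2)
  mid <- 5:15
  expect_equal(mean(fv$edge_speed_um_per_h[mid]), v, tolerance = 0.05)
  expect_equal(mean(fv$area_rate_um2_per_h[mid]), 2 * v * wound_len,
               tolerance = 0.05)
  # trailing differences telescope exactly to the total closed area
  tr <- front_velocity(cs, wound_length = wound_len, align = "trailing")
  expect_equal(sum(tr$area_rate_um2_per_h[-1] * diff(cs$t_h)),
               cs$area_um2[1] - cs$area_um2[nrow(cs)])
  expect_error(front_velocity(cs, wound_len, window = 50), "window")
  # a fully closed segment has zero rate
  closed <- data.frame(t_h = 0:3, area_um2 = rep(0, 4) + 0,
                       closed_pct = rep(100, 4))
  closed$area_um2 <- 0
  expect_equal(front_velocity(closed, wound_len)$area_rate_um2_per_h,
               rep(0, 4))
})

test_that("front extraction reads flat and notched fronts exactly", {
  p <- 1.5
  frame <- matrix(0L, 20, 100)
  frame[, 1:40] <- 1L   # left monolayer up to column 40
  frame[, 81:100] <- 1L # right monolayer from column 81
  fp <- extract_front(frame, pixel_size = p)
  expect_equal(fp$left_um, rep(40 * p, 20))
  expect_equal(fp$right_um, rep(80 * p, 20))
  expect_false(any(fp$closed))
  notched <- frame
  notched[7, 36:40] <- 0L  # 5 px notch in one row
  fn <- extract_front(notched, pixel_size = p)
  expect_equal(fn$left_um[7], 35 * p)
  expect_equal(fn$left_um[-7], rep(40 * p, 19))
  # fully closed frame: every row flagged
  fc <- extract_front(matrix(1L, 5, 8), pixel_size = p)
  expect_true(all(fc$closed))
})

test_that("extracted fronts recover simulator truth within one pixel", {
  sim <- small_wound(roughness_variance = 16, seed = 33)
  for (fr in c(2L, 10L)) {
    fp <- extract_front(sim$stack$frames[, , fr] * 1L, pixel_size = 2)
    open <- !fp$closed
    expect_true(all(abs(fp$left_um[open] - sim$truth$left_um[open, fr]) <= 2))
    expect_true(all(abs(fp$right_um[open] - sim$truth$right_um[open, fr]) <= 2))
  }
})

test_that("edge regularity is the sample variance of edge travel", {
  f0 <- data.frame(line = 1:4, left_um = rep(0, 4), right_um = rep(100, 4),
                   closed = FALSE)
  ft <- data.frame(line = 1:4, left_um = c(10, 10, 20, 20),
                   right_um = 100 - c(10, 10, 20, 20), closed = FALSE)
  r <- edge_regularity(ft, f0)
  expect_equal(as.numeric(r), var(c(10, 10, 20, 20)))
  expect_equal(as.numeric(r), 100 / 3, tolerance = 1e-9)
  # uniform advance gives zero dispersion
  fu <- data.frame(line = 1:4, left_um = rep(15, 4), right_um = rep(85, 4),
                   closed = FALSE)
  expect_equal(as.numeric(edge_regularity(fu, f0)), 0)
  # shifting every distance by a constant leaves the variance unchanged
  ft2 <- ft
  ft2$left_um <- ft$left_um + 7
  ft2$right_um <- ft$right_um - 7
  expect_equal(as.numeric(edge_regularity(ft2, f0)), as.numeric(r))
  # fewer than two open rows is an error
  fc <- ft
  fc$closed <- c(FALSE, TRUE, TRUE, TRUE)
  expect_error(edge_regularity(fc, f0), "fewer than 2")
})

test_that("mirrored stacks give identical statistics", {
  sim <- small_wound(roughness_variance = 9, seed = 44)
  flipped <- sim$stack$frames[, rev(seq_len(dim(sim$stack$frames)[2])), ]
  mirror <- mask_stack(flipped * 1L, pixel_size = 2, frame_interval = 1 / 6)
  expect_equal(closure_series(mirror)$area_um2,
               closure_series(sim$stack)$area_um2)
  expect_equal(as.numeric(wound_regularity(mirror, at_time = 2)),
               as.numeric(wound_regularity(sim$stack, at_time = 2)))
})

test_that("pixel-size scaling: areas and regularity scale by k^2", {
  sim <- small_wound(roughness_variance = 9, seed = 55)
  k <- 3
  rescaled <- mask_stack(sim$stack$frames * 1L, pixel_size = 2 * k,
                         frame_interval = 1 / 6)
  expect_equal(closure_series(rescaled)$area_um2,
               k^2 * closure_series(sim$stack)$area_um2)
  expect_equal(as.numeric(wound_regularity(rescaled, at_time = 2)),
               k^2 * as.numeric(wound_regularity(sim$stack, at_time = 2)))
})

test_that("regularity recovers a planted roughness variance", {
  sigma2 <- 100
  sim <- simulate_wound(width_px = 300, height_px = 2000, initial_gap = 300,
                        front_speed = 25, roughness_variance = sigma2,
                        pixel_size = 2, n_frames = 2, frame_interval = 2,
                        seed = 66)
  r <- wound_regularity(sim$stack, at_time = 2)
  expect_equal(as.numeric(r), sigma2, tolerance = 0.07)
})

test_that("mask stacks round-trip through TIFF with their sidecar", {
  sim <- simulate_wound(width_px = 40, height_px = 20, initial_gap = 30,
                        pixel_size = 1, n_frames = 3, seed = 77)
  path <- tempfile(fileext = ".tif")
  write_mask_stack(sim$stack, path)
  back <- read_mask_stack(path)
  expect_equal(back$frames, sim$stack$frames)
  expect_equal(back$pixel_size, 1)
  expect_equal(back$frame_interval, 1 / 6)
  unlink(c(path, paste0(path, ".json")))
})
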