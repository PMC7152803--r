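test_that("scene generation is deterministic in spec + seed", {
  sp <- scene_spec(n_segments = 40, align_fraction = 0.3,
                   lesion_radius_px = 15, seed = 11)
  g1 <- generate_scene(sp)
  g2 <- generate_scene(sp)
  expect_identical(g1, g2)
  g3 <- generate_scene(scene_spec(n_segments = 40, align_fraction = 0.3,
                                  lesion_radius_px = 15, seed = 12))
  expect_false(identical(g1$scene$vessel_mask, g3$scene$vessel_mask))
})

test_that("aligned segments are laid exactly toward the lesion center", {
  g <- make_scene(seed = 2, align = 1, lesion = 15, n = 100)
  expect_true(all(abs(g$truth$segment_theta) <= pi / 12))
  expect_true(all(g$truth$segment_theta == 0))
  # absolute orientation equals the center direction (mod pi) at midpoints
  for (i in c(1, 50, 100)) {
    cl <- g$truth$segment_centerlines[[i]]
    mid <- colMeans(cl)
    b <- wrap_orientation(atan2(g$spec$lesion_center_xy[2] - mid[2],
                                g$spec$lesion_center_xy[1] - mid[1]))
    expect_lt(abs(wrap_orientation(g$truth$segment_alpha[i] - b)), 0.2)
  }
})

test_that("unaligned orientations are uniform: ~1/6 within +/- pi/12", {
  g <- make_scene(seed = 5, align = 0, lesion = 0, n = 2000)
  frac <- mean(abs(g$truth$segment_theta) <= pi / 12)
  # binomial sd at n = 2000 is 0.0083; allow 3.5 sd
  expect_lt(abs(frac - 1 / 6), 0.03)
})

test_that("no vessel pixels inside the lesion disk; bad lesions error", {
  g <- make_scene(seed = 3, align = 0.5, lesion = 25)
  expect_false(any(g$scene$vessel_mask & g$scene$lesion_mask))
  expect_equal(g$truth$lesion_area_px, sum(g$scene$lesion_mask))
  expect_error(scene_spec(grid_nx = 64, grid_ny = 64, lesion_radius_px = 40),
               "inside the grid")
  expect_error(scene_spec(grid_nx = 20, grid_ny = 20, grid_nz = 8,
                          lesion_center_xy = c(10, 10),
                          lesion_radius_px = 12),
               "grid|vascularized")
})

test_that("repeat B-frames are identical for static tissue without noise", {
  # a scene whose vessels miss some slow-axis position entirely
  sp <- scene_spec(n_segments = 1, noise_sigma = 0, seed = 4)
  g <- generate_scene(sp)
  empty_y <- which(colSums(g$scene$vessel_mask) == 0)[1]
  pair <- render_bframe_pair(g$scene, empty_y, bulk_phase = 0, seed = 9)
  expect_identical(pair$frame_a, pair$frame_b)

  pair2 <- render_bframe_pair(g$scene, empty_y, bulk_phase = 0.7, seed = 9)
  ratio <- pair2$frame_b / pair2$frame_a
  expect_lt(max(abs(Mod(ratio) - 1)), 1e-12)
  expect_lt(max(abs(Arg(ratio) - 0.7)), 1e-12)
})

test_that("vessel pixels decorrelate between repeats", {
  sp <- scene_spec(n_segments = 60, noise_sigma = 0, seed = 2)
  g <- generate_scene(sp)
  y <- which.max(colSums(g$scene$vessel_mask))
  vx <- which(g$scene$vessel_mask[, y])[1]
  zc <- sp$grid_nz %/% 2
  # Monte-Carlo over many renders: inter-repeat complex difference of a
  # vessel pixel has a substantial mean magnitude
  d <- vapply(1:1000, function(s) {
    p <- render_bframe_pair(g$scene, y, bulk_phase = 0, seed = s)
    Mod(p$frame_a[zc, vx] - p$frame_b[zc, vx])
  }, numeric(1))
  expect_gt(mean(d), 0.5)
})

test_that("stall-free series is constant and stall log empty", {
  g <- make_separated_scene(seed = 7, n = 20)
  r <- render_angiogram_series(g$scene, g$truth,
                               stall_process_spec(10, 0, seed = 1), g$spec)
  expect_true(all(lengths(r$truth$stall_log) == 0))
  expect_identical(r$series$frames[[1]], r$series$frames[[10]])
})

test_that("stall_prob = 1 with all segments eligible stalls everything", {
  g <- make_separated_scene(seed = 7, n = 20)
  r <- render_angiogram_series(g$scene, g$truth,
                               stall_process_spec(6, 1, 1, seed = 1), g$spec)
  expect_equal(sum(lengths(r$truth$stall_log)), 20 * 6)
  # with every segment stalled every frame, frames are pure background
  expect_true(all(r$series$frames[[3]][g$scene$vessel_mask] ==
                    g$spec$background_intensity))
})

test_that("stall events match binomial expectation and painted dropouts", {
  g <- make_separated_scene(seed = 8, n = 35)
  st <- stall_process_spec(60, 0.05, 1, seed = 21)
  r <- render_angiogram_series(g$scene, g$truth, st, g$spec)
  total <- sum(lengths(r$truth$stall_log))
  # n p = 35 * 60 * 0.05 = 105, sd = 10; allow 4 sd
  expect_lt(abs(total - 105), 40)
  # conservation: each logged (segment, frame) is painted at background
  for (s in seq_len(35)) {
    for (f in r$truth$stall_log[[s]]) {
      expect_true(all(r$series$frames[[f]][g$scene$segment_pixels[[s]]] ==
                        g$spec$background_intensity))
    }
  }
})

test_that("render_angiogram_series is reproducible", {
  g <- make_separated_scene(seed = 9, n = 15, noise = 0.02)
  st <- stall_process_spec(8, 0.1, 0.5, seed = 3)
  r1 <- render_angiogram_series(g$scene, g$truth, st, g$spec)
  r2 <- render_angiogram_series(g$scene, g$truth, st, g$spec)
  expect_identical(r1$series$frames, r2$series$frames)
  expect_identical(r1$truth$stall_log, r2$truth$stall_log)
})
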