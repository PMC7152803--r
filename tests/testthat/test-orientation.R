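test_that("structure tensor recovers orientation of gratings", {
  n <- 64
  xg <- matrix(seq_len(n), n, n)
  yg <- matrix(rep(seq_len(n), each = n), n, n)
  interior <- as.matrix(expand.grid(20:44, 20:44))

  # stripes parallel to x (varying only along y): alpha = 0, coherence ~ 1
  st <- structure_tensor_orientation(sin(2 * pi * yg / 8))
  expect_lt(max(abs(st$alpha[interior])), 1e-6)
  expect_gt(min(st$coherence[interior]), 0.99)

  # same grating rotated 45 degrees: structure along (1, -1), alpha = -pi/4
  st2 <- structure_tensor_orientation(sin(2 * pi * (xg + yg) / 8))
  expect_lt(max(abs(st2$alpha[interior] + pi / 4)), 0.02)
  # and along (1, 1): alpha = +pi/4
  st3 <- structure_tensor_orientation(sin(2 * pi * (xg - yg) / 8))
  expect_lt(max(abs(st3$alpha[interior] - pi / 4)), 0.02)

  # constant image: coherence identically 0 by the epsilon rule
  st4 <- structure_tensor_orientation(matrix(1, 32, 32))
  expect_true(all(st4$coherence == 0))
})

test_that("beta map encodes the undirected direction to the center", {
  b <- synthesize_beta_map(c(64, 64), c(50, 32))
  expect_equal(b[20, 32], 0)          # due left: horizontal line
  expect_equal(b[50, 10], -pi / 2)    # directly above: vertical line
  expect_equal(b[50, 60], -pi / 2)    # directly below: same undirected line
  # point reflection through the center leaves the map unchanged
  for (d in list(c(5, 9), c(-12, 3), c(7, -7))) {
    expect_equal(b[50 + d[1], 32 + d[2]], b[50 - d[1], 32 - d[2]])
  }
  # pixel at the center is flagged and set to 0
  expect_equal(b[50, 32], 0)
  expect_true(((32 - 1) * 64 + 50) %in% attr(b, "center_pixels"))
})

test_that("theta wrap matches naive mod-pi enumeration on a 1-degree grid", {
  naive_wrap <- function(x) {
    while (x < -pi / 2) x <- x + pi
    while (x >= pi / 2) x <- x - pi
    x
  }
  deg <- pi / 180
  angles <- seq(-90, 89, by = 1) * deg
  grid <- expand.grid(a = angles, b = angles)
  got <- as.vector(theta_map(matrix(grid$a), matrix(grid$b)))
  want <- mapply(function(a, b) naive_wrap(a - b), grid$a, grid$b)
  # compare as orientations: -pi/2 and +pi/2 are the same undirected angle
  expect_lt(max(abs(wrap_orientation(got - want))), 1e-9)
})

test_that("theta identities hold", {
  a <- matrix(runif(100, -pi / 2, pi / 2), 10, 10)
  expect_true(all(theta_map(a, a) == 0))
  expect_equal(theta_map(matrix(80 * pi / 180), matrix(-80 * pi / 180))[1],
               -20 * pi / 180, tolerance = 1e-12)
  b <- matrix(runif(100, -pi / 2, pi / 2), 10, 10)
  expect_equal(theta_map(wrap_orientation(a + pi), b), theta_map(a, b),
               tolerance = 1e-12)
})

test_that("angular distribution counts masked pixels and aligned fraction", {
  th <- matrix(seq(-pi / 2, pi / 2 - 1e-9, length.out = 100), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  d <- angular_distribution(th, mask, n_bins = 18)
  expect_equal(sum(d$counts), 100)
  expect_equal(d$aligned_fraction, mean(abs(th) <= pi / 12))

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  th0 <- matrix(1, 10, 10); th0[5, 5] <- 0
  expect_equal(angular_distribution(th0, single)$aligned_fraction, 1)
  expect_error(angular_distribution(th, matrix(FALSE, 10, 10)),
               "no vessel pixels")
})

test_that("HSV rendering follows the documented encoding", {
  th <- matrix(0.3, 8, 8)
  coh <- matrix(0, 8, 8)
  img <- matrix(runif(64), 8, 8)
  rgb <- render_hsv(th, coh, img)
  # zero coherence = zero saturation = grayscale
  expect_equal(rgb[, , 1], rgb[, , 2], tolerance = 1e-7)
  expect_equal(rgb[, , 2], rgb[, , 3], tolerance = 1e-7)

  rgb2 <- render_hsv(th, matrix(1, 8, 8), matrix(1, 8, 8))
  expect_equal(max(abs(sweep(rgb2, 3, rgb2[1, 1, ]))), 0)  # single hue
  # theta = -pi/2 and theta -> +pi/2 wrap to the same hue
  lo <- render_hsv(matrix(-pi / 2), matrix(1), matrix(1))
  hi <- render_hsv(matrix(pi / 2 - 1e-9), matrix(1), matrix(1))
  expect_equal(lo, hi, tolerance = 1e-4)
})

test_that("theta histogram is covariant under joint 90-degree rotation", {
  gen <- make_scene(seed = 6, align = 0.5, lesion = 15)
  avg <- scene_enface(gen)
  rot <- function(m) t(m)[ncol(m):1, ]
  center <- gen$spec$lesion_center_xy
  n <- nrow(avg)
  center_rot <- c(n + 1 - center[2], center[1])

  run <- function(img, ctr) {
    enh <- enhance_vessels(img)
    st <- structure_tensor_orientation(enh)
    th <- theta_map(st$alpha, synthesize_beta_map(dim(img), ctr))
    m <- make_mask(enh)
    sort(round(th[m$mask], 8))
  }
  expect_equal(run(avg, center), run(rot(avg), center_rot),
               tolerance = 1e-6)
})

test_that("aligned fraction tracks the generator's alignment level", {
  levels <- c(0, 0.5, 1)
  means <- vapply(levels, function(af) {
    mean(vapply(1:2, function(s) measure_aligned_fraction(af, s),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[3], 0.85)
  expect_lt(abs(means[1] - 1 / 6), 0.07)
})

test_that("orientation_analysis is internally consistent", {
  gen <- make_scene(seed = 4, align = 0.75, lesion = 15)
  avg <- scene_enface(gen)
  oa <- orientation_analysis(avg, center_xy = gen$spec$lesion_center_xy)
  expect_equal(oa$maps$theta,
               theta_map(oa$maps$alpha, oa$maps$beta))
  expect_true(all(oa$maps$coherence >= 0 & oa$maps$coherence <= 1))
  expect_true(all(oa$maps$alpha >= -pi / 2 & oa$maps$alpha < pi / 2))
  expect_true(all(oa$maps$theta >= -pi / 2 & oa$maps$theta < pi / 2))
  standalone <- angular_distribution(oa$maps$theta, oa$mask,
                                     coherence = oa$maps$coherence)
  expect_equal(oa$distribution$aligned_fraction,
               standalone$aligned_fraction)
})
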