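test_that("LBP handles the tie convention and a hand-enumerated 3x3 case", {
  # constant plane: every neighbour ties (>= centre), code 11111111 = 255
  h <- lbp_histogram(matrix(3, 6, 6), "basic")
  expect_equal(h[256], 1)
  expect_equal(sum(h), 1)
  hr <- lbp_histogram(matrix(3, 6, 6), "riu2")
  expect_equal(hr[9], 1)   # bin index 8 (0-based): eight ones

  # centre 5, ring clockwise from top-left: 6 4 4 4 4 4 4 6
  # -> bits 0 and 7 set: code 2^0 + 2^7 = 129, circularly contiguous ones
  p <- matrix(c(6, 4, 4,
                6, 5, 4,
                4, 4, 4), 3, 3, byrow = TRUE)
  codes <- lbp_codes(p)
  expect_identical(dim(codes), c(1L, 1L))
  expect_identical(codes[1, 1], 129L)
  expect_equal(lbp_histogram(p, "riu2")[3], 1)   # uniform, 2 ones -> bin 2

  # same two bits but opposite corners: not circularly contiguous
  p2 <- matrix(c(6, 4, 4,
                 4, 5, 4,
                 6, 4, 4), 3, 3, byrow = TRUE)
  expect_equal(lbp_histogram(p2, "riu2")[10], 1) # non-uniform bin
  expect_error(lbp_codes(matrix(1, 2, 5)), "3 x 3")
})

test_that("riu2-LBP histogram is exactly invariant under 90-degree rotations", {
  set.seed(401)
  p <- matrix(runif(20 * 20), 20, 20)
  h0 <- lbp_histogram(p, "riu2")
  p90 <- rotate90(p)
  expect_equal(lbp_histogram(p90, "riu2"), h0)
  expect_equal(lbp_histogram(rotate90(p90), "riu2"), h0)   # 180
  expect_equal(lbp_histogram(rotate90(rotate90(p90)), "riu2"), h0)  # 270
})

test_that("LPQ is exactly invariant to affine intensity changes", {
  set.seed(402)
  p <- matrix(runif(24 * 24), 24, 24)
  for (w in c(3L, 7L)) {
    h <- lpq_histogram(p, w)
    expect_identical(lpq_histogram(p + 17.3, w), h)        # offset
    expect_identical(lpq_histogram(3.7 * p, w), h)         # gain
    expect_identical(lpq_histogram(2.1 * p - 0.4, w), h)   # both
    expect_equal(sum(h), 1)
    expect_true(all(h >= 0))
  }
  expect_error(lpq_histogram(p, 4), "odd")
  expect_error(lpq_histogram(matrix(1, 4, 4), 9), "too small")
})

test_that("LPQ codes match the direct windowed-DFT oracle at random pixels", {
  set.seed(403)
  p <- matrix(runif(30 * 30), 30, 30)
  for (w in c(5L, 7L)) {
    r <- (w - 1L) / 2L
    codes <- lpq_codes(p, w, decorrelate = FALSE)
    for (i in 1:10) {
      rr <- sample((r + 1):(30 - r), 1)
      cc <- sample((r + 1):(30 - r), 1)
      expect_identical(codes[rr - r, cc - r],
                       as.integer(oracle_lpq_code(p, rr, cc, w)))
    }
  }
})

test_that("whitened LPQ spreads codes but keeps the histogram contract", {
  set.seed(404)
  p <- matrix(runif(28 * 28), 28, 28)
  h_plain <- lpq_histogram(p, 5, decorrelate = FALSE)
  h_white <- lpq_histogram(p, 5, decorrelate = TRUE)
  expect_equal(sum(h_white), 1)
  expect_false(identical(h_plain, h_white))
  # whitening preserves affine invariance
  expect_identical(lpq_histogram(2 * p + 1, 5, decorrelate = TRUE), h_white)
})

test_that("rLPQ: constant plane collapses to one code; forced 0 equals LPQ", {
  h <- rlpq_histogram(matrix(1.5, 16, 16), 5)
  expect_equal(max(h), 1)   # single code for all pixels
  set.seed(405)
  p <- matrix(runif(26 * 26), 26, 26)
  for (w in c(3L, 5L)) {
    expect_identical(rlpq_histogram(p, w, orientation = 0),
                     lpq_histogram(p, w))
  }
})

test_that("rLPQ is robust to rotation where plain LPQ texture pairs differ", {
  set.seed(406)
  tex_a <- sinusoid_plane(48, 30, 0.15, noise_sd = 0.05)
  tex_a90 <- rotate90(tex_a)
  tex_b <- sinusoid_plane(48, 30, 0.35, noise_sd = 0.05)   # other class
  h_a <- rlpq_histogram(tex_a, 7)
  h_a90 <- rlpq_histogram(tex_a90, 7)
  h_b <- rlpq_histogram(tex_b, 7)
  d_rot <- chi_square_dist(h_a, h_a90)
  d_class <- chi_square_dist(h_a, h_b)
  expect_lt(d_rot, d_class)
})

test_that("cube_features fuses per-band histograms with slice locality", {
  set.seed(407)
  cube <- spectral_cube(array(runif(24 * 24 * 5), c(24, 24, 5)))
  cfg <- texture_config("rlpq", window = 5)
  full <- cube_features(cube, cfg)
  expect_length(full$values, 5 * 256)
  # per-band normalization within the concatenation
  for (b in 0:4) expect_equal(sum(full$values[b * 256 + 1:256]), 1)
  sub <- cube_features(cube, cfg, retained = c(1L, 3L))
  expect_length(sub$values, 512)
  expect_identical(sub$values,
                   c(full$values[256 + 1:256], full$values[3 * 256 + 1:256]))
  m <- cube_features(cube, texture_config("rlpq", 5, fusion = "mean"))
  expect_length(m$values, 256)
  expect_equal(sum(m$values), 1)
  riu <- cube_features(cube, texture_config("riu2_lbp"))
  expect_length(riu$values, 5 * 10)
  rgbish <- spectral_cube(array(runif(24 * 24 * 3), c(24, 24, 3)))
  expect_length(cube_features(rgbish, cfg)$values, 768)
  expect_error(cube_features(cube, cfg, retained = integer(0)),
               "at least one band")
})

test_that("feature extraction is deterministic and feature sets slice/save", {
  set.seed(408)
  cubes <- lapply(1:4, function(i)
    spectral_cube(array(runif(20 * 20 * 3), c(20, 20, 3)),
                  label = c("a", "a", "b", "b")[i],
                  source_id = paste0("s", i)))
  cfg <- texture_config("lpq", window = 3)
  fx1 <- feature_matrix(cubes, cfg)
  fx2 <- feature_matrix(cubes, cfg)
  expect_identical(fx1$x, fx2$x)
  expect_identical(dim(fx1$x), c(4L, 768L))
  sl <- slice_feature_bands(fx1, c(0L, 2L), 3L)
  expect_identical(sl$x, fx1$x[, c(1:256, 513:768)])
  f <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fx1, f)
  back <- read_features_csv(f)
  expect_equal(back$x, fx1$x, ignore_attr = TRUE)
  expect_identical(back$labels, fx1$labels)
})
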