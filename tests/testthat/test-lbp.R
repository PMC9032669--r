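test_that("grayscale conversion is luma-weighted and idempotent on gray", {
  white <- array(255, c(2, 2, 3))
  black <- array(0, c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  expect_true(all(to_grayscale(black) == 0))
  gray <- array(rep(77, 12), c(2, 2, 3))
  expect_true(all(to_grayscale(gray) == 77))
})

test_that("circular neighbourhood sampling follows the (P,R) conventions", {
  g <- matrix(1:25, 5, 5)
  # (8,1): the classic 3x3 lattice, p=0 east, counter-clockwise
  nb <- circular_neighbors(g, c(3, 3), 8, 1)
  expect_equal(nb, c(g[3, 4], g[2, 4], g[2, 3], g[2, 2],
                     g[3, 2], g[4, 2], g[4, 3], g[4, 4]))
  # constant image: P identical values for every resolution
  const <- matrix(42, 9, 9)
  expect_equal(circular_neighbors(const, c(5, 5), 16, 2), rep(42, 16))
  expect_equal(circular_neighbors(const, c(5, 5), 24, 3), rep(42, 24))
  # linear ramp: bilinear interpolation of a plane is exact
  ramp <- outer(1:11, 1:11, function(i, j) 2 * i + 3 * j)
  ctr <- c(6, 6)
  nb <- circular_neighbors(ramp, ctr, 16, 2)
  theta <- 2 * pi * (0:15) / 16
  expect_equal(nb, 2 * (6 - 2 * sin(theta)) + 3 * (6 + 2 * cos(theta)),
               tolerance = 1e-10)
  expect_error(circular_neighbors(g, c(1, 3), 8, 1), "border")
})

test_that("bit pattern, code, uniformity and riu2 reproduce the worked example", {
  # the printed 3x3 walkthrough: center 77, pattern 11110010, code 79
  pat <- c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 0L)
  expect_equal(lbp_code(pat), 79)
  expect_equal(uniformity(pat), 4)
  expect_equal(riu2_code(pat), 9)          # non-uniform -> P + 1
  # ties count as 1: s(0) = 1
  expect_equal(binary_pattern(100, rep(100, 8)), rep(1L, 8))
  expect_equal(binary_pattern(100, c(99, 101, 100, 50, 150, 100, 0, 255)),
               c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L))
  expect_equal(lbp_code(rep(0L, 8)), 0)
  expect_equal(lbp_code(rep(1L, 8)), 255)
  # uniformity examples
  expect_equal(uniformity(rep(0L, 8)), 0)
  expect_equal(uniformity(rep(1L, 8)), 0)
  expect_equal(uniformity(c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L)), 2)
  expect_equal(uniformity(rep(c(1L, 0L), 4)), 8)
  # riu2 of the two-transition pattern 11001111 is its count of ones
  expect_equal(riu2_code(c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L)), 6)
  expect_equal(riu2_code(rep(0L, 8)), 0)
})

test_that("exhaustive 8-bit enumeration: 58 uniform patterns, shift invariance", {
  codes <- integer(256)
  n_uniform <- 0
  for (v in 0:255) {
    bits <- as.integer(intToBits(v)[1:8])
    expect_equal(uniformity(bits), oracle_uniformity(bits))
    if (oracle_uniformity(bits) <= 2) n_uniform <- n_uniform + 1
    codes[v + 1] <- riu2_code(bits)
    # invariance under every circular shift
    for (s in 1:7) {
      shifted <- c(bits[(s + 1):8], bits[1:s])
      expect_equal(riu2_code(shifted), codes[v + 1])
    }
  }
  expect_equal(n_uniform, 58)
  expect_true(all(codes >= 0 & codes <= 9))
  expect_equal(sort(unique(codes)), 0:9)
})

test_that("riu2 histograms match the naive double loop and normalize to 1", {
  # constant image: every pattern is all-ones -> all mass in bin P
  h <- riu2_histogram(matrix(7, 12, 12), 8, 1)
  expect_length(h, 10)
  expect_equal(h[9], 1)
  expect_length(riu2_histogram(matrix(7, 12, 12), 16, 2), 18)
  expect_length(riu2_histogram(matrix(7, 12, 12), 24, 3), 26)
  set.seed(51)
  for (i in 1:5) {
    g <- matrix(sample(0:255, 12 * 16, TRUE), 12, 16)
    h <- riu2_histogram(g, 8, 1)
    expect_equal(sum(h), 1, tolerance = 1e-9)
    expect_equal(h, oracle_riu2_hist_81(g), tolerance = 1e-12)
  }
  expect_error(riu2_histogram(matrix(1, 2, 2), 8, 1), "too small")
})

test_that("codes are invariant to monotone gray-level shifts", {
  set.seed(61)
  g <- matrix(sample(50:150, 20 * 20, TRUE), 20, 20)
  for (pr in list(c(8, 1), c(16, 2), c(24, 3))) {
    h1 <- riu2_histogram(g, pr[1], pr[2])
    h2 <- riu2_histogram(g + 37, pr[1], pr[2])   # shift, no clipping occurs
    expect_equal(h1, h2)
  }
})

test_that("cell-grid features have the configured length and raster layout", {
  # arithmetic across the full configuration grid
  grid <- list(c(256, c(8, 16, 32, 64, 128)),
               c(128, c(8, 16, 32, 64)),
               c(64, c(8, 16, 32)))
  for (p_r in list(c(8, 1), c(16, 2), c(24, 3))) {
    n_cfg <- 0
    for (g in grid) {
      img_size <- g[1]
      for (cell in g[-1]) {
        cfg <- lbp_config(p_r[1], p_r[2], img_size, cell)
        expect_equal(feature_length(cfg),
                     (img_size / cell)^2 * (p_r[1] + 2))
        n_cfg <- n_cfg + 1
      }
    }
    expect_equal(n_cfg, 12)
  }
  # concrete small case: verify concatenation order is cell-row-major
  cfg <- lbp_config(8, 1, image_size = 64, cell_size = 32)
  set.seed(71)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  fv <- cell_grid_features(img, cfg)
  expect_length(fv, 40)
  expect_equal(fv[1:10], riu2_histogram(img[1:32, 1:32], 8, 1))
  expect_equal(fv[11:20], riu2_histogram(img[1:32, 33:64], 8, 1))
  expect_equal(fv[31:40], riu2_histogram(img[33:64, 33:64], 8, 1))
  # invalid configurations are rejected
  expect_error(lbp_config(8, 1, 64, 64), "smaller")
  expect_error(lbp_config(8, 1, 256, 48), "divide")
  expect_error(lbp_config(12, 1), "must be one of")
  expect_error(lbp_config(24, 3, 64, 4), "exceed")
})

test_that("per-cell histograms are rotation invariant under 90-degree rotation", {
  set.seed(81)
  cell <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  rot90 <- t(cell)[, 32:1]   # 90-degree rotation
  h1 <- riu2_histogram(cell, 8, 1)
  h2 <- riu2_histogram(rot90, 8, 1)
  expect_equal(h1, h2)
})

test_that("patch featurization is deterministic and flags degenerate input", {
  set.seed(91)
  patch <- array(sample(0:255, 50 * 40 * 3, TRUE), c(50, 40, 3))
  cfg <- lbp_config(8, 1, image_size = 64, cell_size = 32)
  f1 <- featurize_patch(patch, cfg)
  f2 <- featurize_patch(patch, cfg)
  expect_identical(f1, f2)
  expect_length(f1, feature_length(cfg))
  expect_true(all(f1 >= 0))
  # constant patch: every cell concentrates in bin P
  const <- array(120, c(30, 30, 3))
  fc <- featurize_patch(const, cfg)
  expect_equal(sum(fc[seq(9, 40, by = 10)]), 4)  # bin index P within each cell
  # a 180-degree image rotation shifts every neighbourhood by P/2 positions,
  # so the riu2 histogram is unchanged exactly
  g <- resize_gray(to_grayscale(patch), 64)
  expect_equal(riu2_histogram(g, 8, 1), riu2_histogram(g[64:1, 64:1], 8, 1))
  expect_error(resize_gray(matrix(numeric(0), 0, 5), 64), "degenerate")
})

test_that("featurize_patches returns a labeled feature frame", {
  set.seed(101)
  patches <- lapply(1:3, function(i) array(sample(0:255, 40 * 40 * 3, TRUE),
                                           c(40, 40, 3)))
  cfg <- lbp_config(8, 1, image_size = 64, cell_size = 32)
  df <- featurize_patches(patches, cfg, labels = c("Crop", "NLW", "BLW"))
  expect_equal(dim(df), c(3, 2 + 40))
  expect_equal(df$label, c("Crop", "NLW", "BLW"))
  expect_equal(names(df)[3], "f_0")
})
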