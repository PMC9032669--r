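test_that("RGB to HSV uses the byte-range hue convention", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(0, 255, 0)     # pure green
  img[1, 2, ] <- c(128, 128, 128) # gray
  img[2, 1, ] <- c(255, 0, 0)     # pure red
  img[2, 2, ] <- c(10, 20, 30)
  hsv <- rgb_to_hsv(img)
  expect_equal(hsv[1, 1, ], c(60, 255, 255))
  expect_equal(hsv[1, 2, 2:3], c(0, 128))
  expect_equal(hsv[2, 1, ], c(0, 255, 255))
  # pointwise map: a constant image maps to a constant HSV image
  flat <- array(rep(c(30, 90, 50), each = 12), c(3, 4, 3))
  hflat <- rgb_to_hsv(flat)
  for (k in 1:3) expect_true(all(hflat[, , k] == hflat[1, 1, k]))
  expect_true(all(hsv[, , 1] >= 0 & hsv[, , 1] < 180))
})

test_that("vegetation thresholding is inclusive and binary", {
  mk <- function(h, s, v) {
    x <- array(0, c(1, 1, 3)); x[1, 1, ] <- c(h, s, v); x
  }
  th <- hsv_thresholds()
  expect_equal(threshold_vegetation(mk(33, 34, 60), th)[1, 1], 255)   # at lower bounds
  expect_equal(threshold_vegetation(mk(95, 255, 250), th)[1, 1], 255) # at upper bounds
  expect_equal(threshold_vegetation(mk(32, 200, 200), th)[1, 1], 0)   # hue below band
  expect_equal(threshold_vegetation(mk(60, 33, 200), th)[1, 1], 0)    # saturation below
  black <- rgb_to_hsv(array(0, c(4, 4, 3)))
  expect_true(all(threshold_vegetation(black, th) == 0))
  # output alphabet
  set.seed(1)
  img <- array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3))
  out <- threshold_vegetation(rgb_to_hsv(img), th)
  expect_true(all(out %in% c(0, 255)))
})

test_that("widening any threshold bound never removes foreground", {
  set.seed(7)
  img <- array(sample(0:255, 20 * 20 * 3, TRUE), c(20, 20, 3))
  hsv <- rgb_to_hsv(img)
  base <- threshold_vegetation(hsv, hsv_thresholds())
  wider <- list(
    hsv_thresholds(hl = 20), hsv_thresholds(hh = 120),
    hsv_thresholds(sl = 0), hsv_thresholds(vl = 0), hsv_thresholds(vh = 255)
  )
  for (th in wider) {
    out <- threshold_vegetation(hsv, th)
    expect_true(all(out[base == 255] == 255))
  }
  expect_error(hsv_thresholds(hl = 100, hh = 50), "lower bound")
})

test_that("opening and closing match the set-definition oracle", {
  se <- structuring_element(5)
  set.seed(11)
  for (i in 1:15) {
    mask <- random_mask(12, 12, density = stats::runif(1, 0.3, 0.7))
    expect_equal(morph_open(mask, se), oracle_open(mask, se))
    expect_equal(morph_close(mask, se), oracle_close(mask, se))
  }
  # disc-shaped element too
  sed <- structuring_element(5, "disc")
  mask <- random_mask(12, 12)
  expect_equal(morph_open(mask, sed), oracle_open(mask, sed))
})

test_that("opening/closing degenerate cases and order properties hold", {
  se <- structuring_element(5)
  empty <- matrix(0, 10, 10)
  expect_equal(morph_open(empty, se), empty)
  expect_equal(morph_close(empty, se), empty)
  # an isolated pixel vanishes under opening with a 5x5 element
  one <- empty; one[5, 5] <- 255
  expect_true(all(morph_open(one, se) == 0))
  # a pinhole in a solid rectangle is filled by closing
  rect <- matrix(0, 14, 14); rect[3:12, 3:12] <- 255
  hole <- rect; hole[7, 7] <- 0
  expect_equal(morph_close(hole, se), rect)
  # anti-extensive / extensive / idempotent; extensivity of closing needs the
  # foreground to keep an element-radius margin from the border (outside the
  # image counts as background)
  set.seed(21)
  for (i in 1:5) {
    mask <- matrix(0, 20, 20)
    mask[3:18, 3:18] <- random_mask(16, 16, 0.55)
    op <- morph_open(mask, se); cl <- morph_close(mask, se)
    expect_true(all(op <= mask))
    expect_true(all(cl >= mask))
    expect_equal(morph_open(op, se), op)
    expect_equal(morph_close(cl, se), cl)
  }
})

test_that("mask enhancement removes salt noise but keeps large blobs", {
  se <- structuring_element(5)
  mask <- matrix(0, 40, 40)
  mask[10:28, 10:28] <- 255                      # large solid blob
  salt <- cbind(c(2, 35, 5, 38), c(2, 3, 36, 37))
  noisy <- mask; noisy[salt] <- 255
  out <- enhance_mask(noisy, se)
  expect_equal(out, oracle_close(oracle_open(noisy, se), se))
  expect_true(all(out[salt] == 0))
  expect_true(all(out[12:26, 12:26] == 255))
  expect_equal(enhance_mask(matrix(0, 8, 8), se), matrix(0, 8, 8))
})
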