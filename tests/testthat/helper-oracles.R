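# Independent brute-force oracles used to check the fast implementations.
# These are deliberately naive (set definitions, per-pixel double loops,
# exhaustive enumeration) and share no code with the package internals.

# Erosion by the set definition: keep z iff the SE translated to z fits
# entirely inside the foreground (outside the image counts as background).
oracle_erode <- function(mask, se) {
  r <- (nrow(se) - 1) / 2
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    fits <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > m || jj < 1 || jj > n || mask[ii, jj] == 0) {
        fits <- FALSE
        break
      }
    }
    if (fits) out[i, j] <- 255
  }
  out
}

# Dilation by the set definition: keep z iff the reflected SE translated to z
# intersects the foreground.
oracle_dilate <- function(mask, se) {
  r <- (nrow(se) - 1) / 2
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    hit <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      if (se[r + 1 - di, r + 1 - dj] == 0) next   # reflected SE
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= m && jj >= 1 && jj <= n && mask[ii, jj] > 0) {
        hit <- TRUE
        break
      }
    }
    if (hit) out[i, j] <- 255
  }
  out
}

oracle_open <- function(mask, se) oracle_dilate(oracle_erode(mask, se), se)
oracle_close <- function(mask, se) oracle_erode(oracle_dilate(mask, se), se)

# Circular transition count by naive scan over adjacent pairs.
oracle_uniformity <- function(bits) {
  p <- length(bits)
  u <- 0L
  for (k in seq_len(p)) {
    nxt <- if (k == p) 1L else k + 1L
    if (bits[k] != bits[nxt]) u <- u + 1L
  }
  u
}

# riu2 histogram by a per-pixel double loop (integer-lattice case, P=8, R=1).
oracle_riu2_hist_81 <- function(gray) {
  m <- nrow(gray); n <- ncol(gray)
  counts <- rep(0, 10)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  for (i in 2:(m - 1)) for (j in 2:(n - 1)) {
    bits <- vapply(offs, function(o) {
      as.integer(gray[i + o[1], j + o[2]] >= gray[i, j])
    }, integer(1))
    code <- if (oracle_uniformity(bits) <= 2) sum(bits) else 9
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts / sum(counts)
}

# One-vs-rest metric recount straight from the label pairs.
oracle_metrics <- function(y_true, y_pred, cls) {
  tp <- sum(y_true == cls & y_pred == cls)
  fp <- sum(y_true != cls & y_pred == cls)
  fn <- sum(y_true == cls & y_pred != cls)
  tn <- sum(y_true != cls & y_pred != cls)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = pre, recall = rec, f1 = f1)
}

# Maximum geometric margin of a separable 2-D dataset by grid search over the
# boundary direction: for each direction the best margin is half the gap
# between the two classes' projections.
oracle_max_margin_2d <- function(x, t, n_angles = 2000) {
  best <- 0
  for (th in seq(0, pi, length.out = n_angles)) {
    w <- c(cos(th), sin(th))
    proj <- x %*% w
    gap1 <- min(proj[t == 1]) - max(proj[t == -1])
    gap2 <- min(proj[t == -1]) - max(proj[t == 1])
    best <- max(best, gap1 / 2, gap2 / 2)
  }
  best
}

random_mask <- function(m = 12, n = 12, density = 0.5) {
  matrix(ifelse(stats::runif(m * n) < density, 255, 0), m, n)
}

# Shared fixture: seeded synthetic scenes (generated once per test run).
.fixture_env <- new.env()
fixture_scenes <- function(n = 20, seed0 = 100) {
  key <- paste0("scenes_", n, "_", seed0)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- lapply(seq_len(n), function(i) {
      generate_scene(scene_params(seed = seed0 + i))
    })
  .fixture_env[[key]]
}

fixture_training_patches <- function() {
  if (is.null(.fixture_env$train_patches))
    .fixture_env$train_patches <- render_patch_set(seed = 5)
  .fixture_env$train_patches
}

fixture_lbp_config <- function() lbp_config(8, 1, image_size = 64, cell_size = 32)

# Linear SVM (C = 5) trained on the 400-patch rendered set.
fixture_svm_model <- function() {
  if (is.null(.fixture_env$svm_model)) {
    tr <- fixture_training_patches()
    cfg <- fixture_lbp_config()
    X <- t(vapply(tr$patches, featurize_patch, cfg = cfg,
                  FUN.VALUE = numeric(feature_length(cfg))))
    .fixture_env$svm_model <- train_multiclass(X, tr$labels, C = 5,
                                               fingerprint = lbp_fingerprint(cfg))
  }
  .fixture_env$svm_model
}
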