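# Transfer-learning classifier: a pluggable convolutional backbone whose
# weights stay frozen, and a trainable fully-connected head
#   d -> 512 (ReLU, dropout 0.5 at training time) -> n_classes (softmax),
# optimized with Adam on the categorical cross-entropy. Because the backbone
# is frozen its features are computed once per image and the head is trained
# on the cached feature matrix.

#' Tiny stand-in convolutional backbone
#'
#' Two blocks of 3x3 convolution (same padding) + ReLU + 2x2 max pooling with
#' fixed, randomly initialized filters (He scaling). It is a desk-scale
#' backbone exposing the same contract as a large pretrained network: a
#' deterministic, frozen feature extractor whose output feeds the
#' classification head. The final maps are summarized by per-channel block
#' statistics (mean and standard deviation over a `pool_grid x pool_grid`
#' partition) — an energy-pooling summary that makes the random filters act
#' as band-pass texture detectors — and standardized per image.
#'
#' @param input_size input image side length (images are resized to
#'   `input_size x input_size x 3`).
#' @param filters1,filters2 filter counts of the two blocks.
#' @param pool_grid side of the block-statistics grid (default 2).
#' @param seed seed for the fixed filter initialization.
#' @return an object of class `tiny_backbone` with the feature dimension in
#'   `$dim` (`2 * pool_grid^2 * filters2`).
#' @export
tiny_backbone <- function(input_size = 128, filters1 = 8, filters2 = 48,
                          pool_grid = 2, seed = 1) {
  old <- .Random.seed_save()
  set.seed(seed)
  w1 <- array(stats::rnorm(3 * 3 * 3 * filters1, sd = sqrt(2 / (3 * 3 * 3))),
              c(3, 3, 3, filters1))
  w2 <- array(stats::rnorm(3 * 3 * filters1 * filters2,
                           sd = sqrt(2 / (3 * 3 * filters1))),
              c(3, 3, filters1, filters2))
  .Random.seed_restore(old)
  structure(list(w1 = w1, w2 = w2, input_size = as.integer(input_size),
                 filters1 = filters1, filters2 = filters2,
                 pool_grid = as.integer(pool_grid),
                 dim = as.integer(2 * pool_grid^2 * filters2), seed = seed,
                 id = sprintf("tiny-%d-%d-%d-g%d-s%d", input_size, filters1,
                              filters2, pool_grid, seed)),
            class = "tiny_backbone")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(list = ".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

conv3x3_same <- function(x, w) {
  # x: h x w x c_in, w: 3 x 3 x c_in x c_out; zero padding
  h <- dim(x)[1]; wd <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  pad <- array(0, c(h + 2, wd + 2, cin))
  pad[2:(h + 1), 2:(wd + 1), ] <- x
  out <- array(0, c(h, wd, cout))
  for (k in seq_len(cout)) {
    acc <- matrix(0, h, wd)
    for (ci in seq_len(cin)) for (di in 0:2) for (dj in 0:2) {
      wkk <- w[di + 1, dj + 1, ci, k]
      if (wkk != 0)
        acc <- acc + wkk * pad[di + seq_len(h), dj + seq_len(wd), ci]
    }
    out[, , k] <- acc
  }
  out
}

maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L; ch <- dim(x)[3]
  out <- array(0, c(h, w, ch))
  ri <- 2 * seq_len(h); ci <- 2 * seq_len(w)
  for (k in seq_len(ch)) {
    m <- x[, , k]
    out[, , k] <- pmax(m[ri - 1, ci - 1], m[ri - 1, ci], m[ri, ci - 1], m[ri, ci])
  }
  out
}

#' Backbone features of one image
#'
#' @param backbone a `tiny_backbone`.
#' @param img RGB image array; resized to the backbone input size and scaled
#'   to `[0, 1]` before the convolutions.
#' @return numeric feature vector of length `backbone$dim`.
#' @export
backbone_features <- function(backbone, img) {
  stopifnot(inherits(backbone, "tiny_backbone"))
  rgb <- if (inherits(img, "roi_patch")) img$pixels else img
  validate_rgb(rgb)
  s <- backbone$input_size
  x <- array(0, c(s, s, 3))
  for (k in 1:3) x[, , k] <- resize_gray(rgb[, , k], s) / 255
  a1 <- maxpool2(pmax(conv3x3_same(x, backbone$w1), 0))
  a2 <- maxpool2(pmax(conv3x3_same(a1, backbone$w2), 0))
  g <- backbone$pool_grid
  side <- dim(a2)[1]; blk <- side %/% g
  mu <- numeric(0); sdv <- numeric(0)
  for (k in seq_len(dim(a2)[3])) for (i in seq_len(g)) for (j in seq_len(g)) {
    b <- a2[((i - 1) * blk + 1):(i * blk), ((j - 1) * blk + 1):(j * blk), k]
    mu <- c(mu, mean(b)); sdv <- c(sdv, stats::sd(b))
  }
  f <- c(mu, sdv)
  (f - mean(f)) / (stats::sd(f) + 1e-8)
}

#' Build the classification head
#'
#' Affine `d -> hidden` with ReLU and dropout, then affine
#' `hidden -> n_classes` with softmax. Weights use He/Glorot-style random
#' initialization from `seed`; biases start at zero.
#'
#' @param d input feature dimension.
#' @param n_classes number of output classes (default 3).
#' @param hidden hidden width (default 512).
#' @param dropout dropout rate applied to the hidden activations during
#'   training only (default 0.5).
#' @param seed seed for weight initialization.
#' @return an object of class `cnn_head`.
#' @export
build_head <- function(d, n_classes = 3, hidden = 512, dropout = 0.5, seed = 1) {
  if (d < 1 || hidden < 1 || n_classes < 1) stop("invalid dimensions")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  old <- .Random.seed_save()
  set.seed(seed)
  head <- list(
    W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * n_classes, sd = sqrt(1 / hidden)),
                hidden, n_classes),
    b2 = rep(0, n_classes),
    dropout = dropout, d = d, hidden = hidden, n_classes = n_classes
  )
  .Random.seed_restore(old)
  structure(head, class = "cnn_head")
}

#' Number of trainable head parameters
#'
#' @param head a `cnn_head`.
#' @return integer parameter count.
#' @export
head_param_count <- function(head) {
  stopifnot(inherits(head, "cnn_head"))
  length(head$W1) + length(head$b1) + length(head$W2) + length(head$b2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

head_forward <- function(head, X, drop_mask = NULL) {
  A1 <- pmax(sweep(X %*% head$W1, 2, head$b1, `+`), 0)
  H <- if (is.null(drop_mask)) A1 else A1 * drop_mask / (1 - head$dropout)
  Z <- sweep(H %*% head$W2, 2, head$b2, `+`)
  list(A1 = A1, H = H, P = softmax_rows(Z))
}

#' Training configuration for the transfer classifier
#'
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-4).
#' @param input_size input image side length (default 128, i.e.
#'   `128 x 128 x 3` inputs).
#' @param frozen keep backbone weights fixed (the default and only supported
#'   mode for the built-in backbone).
#' @param seed seed governing split, shuffling, dropout and initialization.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 16, lr = 1e-4,
                         input_size = 128, frozen = TRUE, seed = 42) {
  if (epochs < 0 || batch_size < 1) stop("invalid epochs/batch size")
  if (lr < 0) stop("learning rate must be non-negative")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, input_size = as.integer(input_size),
                 frozen = isTRUE(frozen), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the transfer-learning classifier
#'
#' Computes frozen backbone features for every patch, splits them 70/20/10
#' (stratified) into train/validation/test, and trains the head with Adam on
#' the categorical cross-entropy, recording per-epoch loss and accuracy on
#' the training and validation folds.
#'
#' @param patches list of `roi_patch` objects or RGB arrays.
#' @param labels class label per patch.
#' @param backbone a `tiny_backbone` (or any object supported by
#'   [backbone_features()]).
#' @param cfg a [train_config()].
#' @return an object of class `trained_classifier` with the head, class list,
#'   split indices and `history` (data frame: epoch, train_loss, train_acc,
#'   val_loss, val_acc).
#' @export
train_transfer <- function(patches, labels, backbone, cfg = train_config()) {
  labels <- as.character(labels)
  if (length(patches) != length(labels)) stop("patches/labels length mismatch")
  if (any(table(labels) < 3)) stop("every class needs at least 3 patches")
  if (!cfg$frozen)
    stop("the built-in backbone is a frozen feature extractor; unfreezing is not supported")
  classes <- sort(unique(labels))
  if (backbone$input_size != cfg$input_size)
    backbone <- tiny_backbone(cfg$input_size, backbone$filters1,
                              backbone$filters2, backbone$pool_grid,
                              backbone$seed)
  X <- t(vapply(patches, function(p) backbone_features(backbone, p),
                numeric(backbone$dim)))
  Y <- outer(labels, classes, `==`) * 1
  split <- stratified_split(labels, seed = cfg$seed)
  tr <- split$train; va <- split$validation
  # column-standardize features with training-fold statistics (stored with the
  # model and re-applied at inference)
  norm <- list(mu = colMeans(X[tr, , drop = FALSE]),
               sd = apply(X[tr, , drop = FALSE], 2, stats::sd) + 1e-8)
  X <- sweep(sweep(X, 2, norm$mu), 2, norm$sd, `/`)

  head <- build_head(backbone$dim, length(classes), seed = cfg$seed)
  opt <- adam_state(head)
  old <- .Random.seed_save()
  set.seed(cfg$seed + 1L)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    idx <- tr[sample.int(length(tr))]
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
      Xb <- X[bi, , drop = FALSE]; Yb <- Y[bi, , drop = FALSE]
      mask <- matrix(stats::runif(length(bi) * head$hidden) >= head$dropout,
                     length(bi), head$hidden) * 1
      fw <- head_forward(head, Xb, mask)
      dZ <- (fw$P - Yb) / nrow(Xb)
      gW2 <- t(fw$H) %*% dZ
      gb2 <- colSums(dZ)
      dH <- dZ %*% t(head$W2) * mask / (1 - head$dropout)
      dA1 <- dH * (fw$A1 > 0)
      gW1 <- t(Xb) %*% dA1
      gb1 <- colSums(dA1)
      upd <- adam_step(opt, head, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                       cfg$lr)
      head <- upd$head; opt <- upd$opt
    }
    hist[[ep]] <- data.frame(
      epoch = ep,
      train_loss = ce_loss(head, X[tr, , drop = FALSE], Y[tr, , drop = FALSE]),
      train_acc = fold_acc(head, X[tr, , drop = FALSE], labels[tr], classes),
      val_loss = ce_loss(head, X[va, , drop = FALSE], Y[va, , drop = FALSE]),
      val_acc = fold_acc(head, X[va, , drop = FALSE], labels[va], classes)
    )
  }
  .Random.seed_restore(old)
  structure(list(backbone = backbone, head = head, classes = classes,
                 norm = norm, cfg = cfg, split = split,
                 history = if (cfg$epochs > 0) do.call(rbind, hist) else
                   data.frame(epoch = integer(0))),
            class = "trained_classifier")
}

adam_state <- function(head) {
  z <- lapply(head[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  list(m = z, v = z, t = 0)
}

adam_step <- function(opt, head, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    head[[nm]] <- head[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(head = head, opt = opt)
}

ce_loss <- function(head, X, Y) {
  P <- head_forward(head, X)$P
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

fold_acc <- function(head, X, labels, classes) {
  P <- head_forward(head, X)$P
  mean(classes[max.col(P, ties.method = "first")] == labels)
}

#' Predict class probabilities for patches
#'
#' Dropout is disabled at inference; the label is the argmax class (lowest
#' index on exact ties).
#'
#' @param model a `trained_classifier`.
#' @param patches a single patch/RGB array or a list of them.
#' @return a list with `probs` (matrix, one row per patch, columns named by
#'   class) and `labels` (character vector).
#' @export
predict_cnn <- function(model, patches) {
  stopifnot(inherits(model, "trained_classifier"))
  if (!is.list(patches) || inherits(patches, "roi_patch"))
    patches <- list(patches)
  X <- t(vapply(patches, function(p) backbone_features(model$backbone, p),
                numeric(model$backbone$dim)))
  if (!is.null(model$norm))
    X <- sweep(sweep(X, 2, model$norm$mu), 2, model$norm$sd, `/`)
  P <- head_forward(model$head, X)$P
  colnames(P) <- model$classes
  list(probs = P, labels = model$classes[max.col(P, ties.method = "first")])
}
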