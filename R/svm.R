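# Soft-margin support vector machine, trained in the dual:
#   maximize  sum_i a_i - 1/2 sum_ij a_i a_j t_i t_j K(x_i, x_j)
#   subject to 0 <= a_i <= C,  sum_i a_i t_i = 0,
# solved as a box-constrained QP by kernlab's interior-point solver. The
# penalty C enters as the box bound on the multipliers; with the linear
# kernel the primal weights are recovered as w = sum_i a_i t_i x_i and new
# points are classified by the sign of y(x) = w'x + b.

#' Kernel constructors
#'
#' `linear_kernel()` gives `K(x, z) = x'z`; `rbf_kernel(gamma)` gives
#' `K(x, z) = exp(-gamma ||x - z||^2)` (available as a hook, untuned).
#'
#' @param gamma RBF width parameter (> 0).
#' @return an object of class `svm_kernel`.
#' @export
linear_kernel <- function() {
  structure(list(id = "linear", params = list()), class = "svm_kernel")
}

#' @rdname linear_kernel
#' @export
rbf_kernel <- function(gamma = 1) {
  stopifnot(gamma > 0)
  structure(list(id = "rbf", params = list(gamma = gamma)), class = "svm_kernel")
}

kernel_matrix <- function(kernel, x, z = NULL) {
  if (is.null(z)) z <- x
  if (kernel$id == "linear") return(x %*% t(z))
  if (kernel$id == "rbf") {
    d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * x %*% t(z)
    return(exp(-kernel$params$gamma * pmax(d2, 0)))
  }
  stop("unknown kernel: ", kernel$id)
}

#' Train a binary soft-margin SVM
#'
#' Maximizes the dual objective under the box constraint `0 <= a_i <= C` and
#' the equality constraint `sum a_i t_i = 0`, then recovers the bias from the
#' margin support vectors (`0 < a_i < C`), for which `t_i y(x_i) = 1`.
#'
#' @param x numeric feature matrix, one row per sample.
#' @param t targets in `{-1, +1}`.
#' @param C box penalty (> 0), default 5.
#' @param kernel an `svm_kernel` (default linear).
#' @param tol multiplier tolerance used to identify support vectors.
#' @return an object of class `svm_binary` with elements `alpha`, `sv_x`,
#'   `sv_t`, `b`, `C`, `kernel`, and (linear kernel) the explicit weight
#'   vector `w`.
#' @export
train_binary_svm <- function(x, t, C = 5, kernel = linear_kernel(), tol = 1e-8) {
  x <- as.matrix(x)
  if (!all(t %in% c(-1, 1))) stop("targets must be -1/+1")
  if (length(unique(t)) < 2) stop("both classes must be present")
  if (any(!is.finite(x))) stop("features must be finite")
  if (C <= 0) stop("C must be positive")
  n <- nrow(x)
  K <- kernel_matrix(kernel, x)
  Q <- (t %o% t) * K + diag(1e-8, n)
  sol <- kernlab::ipop(c = matrix(-1, n), H = Q, A = t(t), b = 0,
                       l = matrix(0, n), u = matrix(C, n), r = 0)
  a <- pmin(pmax(kernlab::primal(sol), 0), C)
  # project exactly onto the equality constraint sum a_i t_i = 0 (clipping the
  # interior-point iterate can leave a tiny residual)
  free <- a > tol & a < C - tol
  if (any(free)) {
    resid <- sum(a * t)
    a[free] <- pmin(pmax(a[free] - t[free] * resid / sum(free), 0), C)
  }
  a[a < tol] <- 0
  sv <- a > 0
  f0 <- drop(K %*% (a * t))                 # decision values without bias
  margin <- a > C * 1e-5 & a < C * (1 - 1e-5)
  b <- if (any(margin)) mean(t[margin] - f0[margin]) else
    -(max(f0[t == -1]) + min(f0[t == 1])) / 2
  model <- list(alpha = a[sv], sv_x = x[sv, , drop = FALSE], sv_t = t[sv],
                b = b, C = C, kernel = kernel, dim = ncol(x))
  if (kernel$id == "linear")
    model$w <- drop(t(x) %*% (a * t))
  structure(model, class = "svm_binary")
}

#' Decision value of a binary SVM
#'
#' `y(x) = sum_i a_i t_i K(x_i, x) + b`; the sign of `y(x)` is the predicted
#' class.
#'
#' @param model an `svm_binary`.
#' @param x numeric vector or matrix (one row per sample).
#' @return numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "svm_binary"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim) stop("feature dimension mismatch")
  drop(kernel_matrix(model$kernel, x, model$sv_x) %*% (model$alpha * model$sv_t) + model$b)
}

#' Train a multiclass SVM by one-vs-one decomposition
#'
#' Fits one binary SVM per unordered class pair (the first class of the pair
#' coded +1). Prediction is by majority vote over the pairwise models; vote
#' ties are broken by the largest summed decision value toward the tied
#' classes, then by class order.
#'
#' @param x numeric feature matrix.
#' @param y class labels (character or factor).
#' @param C box penalty, default 5 (with the linear kernel the configuration
#'   that performed best for this task).
#' @param kernel an `svm_kernel` (default linear).
#' @param fingerprint optional feature-configuration fingerprint stored with
#'   the model (see [lbp_fingerprint()]).
#' @return an object of class `svm_multiclass`.
#' @export
train_multiclass <- function(x, y, C = 5, kernel = linear_kernel(),
                             fingerprint = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes are required")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    t <- ifelse(y[idx] == pr[1], 1, -1)
    train_binary_svm(x[idx, , drop = FALSE], t, C = C, kernel = kernel)
  })
  names(models) <- vapply(pairs, paste, collapse = "|", FUN.VALUE = "")
  structure(list(models = models, pairs = pairs, classes = classes, C = C,
                 kernel = kernel, dim = ncol(x), fingerprint = fingerprint),
            class = "svm_multiclass")
}

#' Predict classes with a multiclass SVM
#'
#' @param object an `svm_multiclass`.
#' @param x numeric vector or matrix (one row per sample).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.svm_multiclass <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != object$dim) stop("feature dimension mismatch")
  k <- length(object$classes)
  votes <- matrix(0, nrow(x), k, dimnames = list(NULL, object$classes))
  score <- matrix(0, nrow(x), k, dimnames = list(NULL, object$classes))
  for (i in seq_along(object$models)) {
    pr <- object$pairs[[i]]
    d <- decision_value(object$models[[i]], x)
    winner <- ifelse(d >= 0, pr[1], pr[2])
    votes[cbind(seq_len(nrow(x)), match(winner, object$classes))] <-
      votes[cbind(seq_len(nrow(x)), match(winner, object$classes))] + 1
    score[, pr[1]] <- score[, pr[1]] + d
    score[, pr[2]] <- score[, pr[2]] - d
  }
  vapply(seq_len(nrow(x)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(score[i, top])]
    object$classes[top]
  }, FUN.VALUE = "")
}

#' Per-class summed decision scores
#'
#' The tie-break scores used by [predict.svm_multiclass()]: for each class,
#' the sum of signed decision values of its pairwise models.
#'
#' @param model an `svm_multiclass`.
#' @param x numeric vector or matrix.
#' @return numeric matrix, one column per class.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "svm_multiclass"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  score <- matrix(0, nrow(x), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (i in seq_along(model$models)) {
    pr <- model$pairs[[i]]
    d <- decision_value(model$models[[i]], x)
    score[, pr[1]] <- score[, pr[1]] + d
    score[, pr[2]] <- score[, pr[2]] - d
  }
  score
}

#' @export
print.svm_multiclass <- function(x, ...) {
  cat("one-vs-one SVM over classes:", paste(x$classes, collapse = ", "),
      "\n  kernel:", x$kernel$id, " C:", x$C,
      " support vectors:", sum(vapply(x$models, function(m) length(m$alpha), 0L)),
      "\n")
  invisible(x)
}
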