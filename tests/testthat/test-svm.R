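test_that("the symmetric two-point problem gives a zero-bias boundary", {
  x <- matrix(c(-1, 1), 2, 1)
  t <- c(-1, 1)
  m <- train_binary_svm(x, t, C = 100)
  expect_equal(m$b, 0, tolerance = 1e-4)
  expect_equal(decision_value(m, matrix(0)), 0, tolerance = 1e-4)
  expect_true(decision_value(m, matrix(1)) > 0)
  expect_true(decision_value(m, matrix(-1)) < 0)
  expect_error(train_binary_svm(x, c(1, 1)), "both classes")
  expect_error(train_binary_svm(x, t, C = -1), "positive")
})

test_that("dual feasibility, box constraints and the weight identity hold", {
  set.seed(111)
  for (rep in 1:3) {
    n <- 30
    x <- rbind(matrix(stats::rnorm(n, -2), n / 2, 2),
               matrix(stats::rnorm(n, 2), n / 2, 2))
    t <- rep(c(-1, 1), each = n / 2)
    C <- c(1, 5, 50)[rep]
    m <- train_binary_svm(x, t, C = C)
    expect_lt(abs(sum(m$alpha * m$sv_t)), 1e-6)
    expect_true(all(m$alpha >= 0 & m$alpha <= C + 1e-9))
    # explicit linear weights equal the multiplier expansion
    expect_equal(m$w, drop(t(m$sv_x) %*% (m$alpha * m$sv_t)), tolerance = 1e-10)
    # decision values computed from w agree with the kernel expansion
    expect_equal(decision_value(m, x), drop(x %*% m$w + m$b), tolerance = 1e-8)
    # margin support vectors sit on the +-1 margin
    margin <- m$alpha > C * 1e-4 & m$alpha < C * (1 - 1e-4)
    if (any(margin)) {
      dv <- decision_value(m, m$sv_x[margin, , drop = FALSE])
      expect_equal(abs(dv * m$sv_t[margin]), rep(1, sum(margin)),
                   tolerance = 1e-3)
    }
  }
})

test_that("maximum margin matches a direction grid-search oracle", {
  set.seed(121)
  x <- rbind(matrix(stats::rnorm(20, -3, 0.6), 10, 2),
             matrix(stats::rnorm(20, 3, 0.6), 10, 2))
  t <- rep(c(-1, 1), each = 10)
  m <- train_binary_svm(x, t, C = 1e4)    # effectively hard margin
  expect_equal(mean(sign(decision_value(m, x)) == t), 1)
  geom_margin <- 1 / sqrt(sum(m$w^2))
  expect_equal(geom_margin, oracle_max_margin_2d(x, t), tolerance = 0.01)
})

test_that("training agrees with an independent SVM implementation", {
  set.seed(131)
  x <- rbind(matrix(stats::rnorm(40, -1.5), 20, 2),
             matrix(stats::rnorm(40, 1.5), 20, 2))
  t <- rep(c(-1, 1), each = 20)
  m <- train_binary_svm(x, t, C = 5)
  ref <- e1071::svm(x, factor(t), kernel = "linear", cost = 5, scale = FALSE)
  w_ref <- colSums(ref$coefs[, 1] * ref$SV)
  # e1071 orients its decision by internal level order; align signs first
  s <- sign(sum(w_ref * m$w))
  expect_equal(m$w, s * w_ref, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m$b, s * -ref$rho, tolerance = 1e-3)
})

test_that("one-vs-one multiclass separates three Gaussian clusters", {
  set.seed(141)
  centers <- list(c(0, 6), c(-5, -3), c(5, -3))
  mk <- function(mu, n) cbind(stats::rnorm(n, mu[1], 0.8), stats::rnorm(n, mu[2], 0.8))
  x <- do.call(rbind, lapply(centers, mk, n = 30))
  y <- rep(c("Crop", "NLW", "BLW"), each = 30)
  sp <- stratified_split(y, seed = 1)
  m <- train_multiclass(x[sp$train, ], y[sp$train], C = 5)
  expect_length(m$models, 3)   # one per unordered pair
  held <- c(sp$validation, sp$test)
  acc <- mean(predict(m, x[held, ]) == y[held])
  expect_gte(acc, 0.95)
  # cluster centroids go to their own class
  for (i in 1:3)
    expect_equal(predict(m, matrix(centers[[i]], 1)),
                 c("Crop", "NLW", "BLW")[i])
  expect_error(train_multiclass(x, rep("Crop", nrow(x))), "two classes")
})

test_that("predictions respect class-permutation symmetry and are deterministic", {
  set.seed(151)
  x <- rbind(matrix(stats::rnorm(30, -3), 15, 2), matrix(stats::rnorm(30, 3), 15, 2),
             cbind(stats::rnorm(15, 0), stats::rnorm(15, 5)))
  y <- rep(c("A", "B", "C"), each = 15)
  perm <- c(A = "C", B = "A", C = "B")
  m1 <- train_multiclass(x, y, C = 5)
  m2 <- train_multiclass(x, unname(perm[y]), C = 5)
  xt <- matrix(stats::rnorm(20), 10, 2)
  expect_equal(unname(perm[predict(m1, xt)]), predict(m2, xt))
  # repeated prediction of the same points is identical (ties included)
  expect_identical(predict(m1, xt), predict(m1, xt))
  # batch equals single
  one_by_one <- vapply(seq_len(nrow(xt)),
                       function(i) predict(m1, xt[i, , drop = FALSE]), "")
  expect_equal(predict(m1, xt), one_by_one)
})

test_that("raising C on separable data does not hurt training accuracy", {
  set.seed(161)
  x <- rbind(matrix(stats::rnorm(24, -3), 12, 2), matrix(stats::rnorm(24, 3), 12, 2))
  t <- rep(c(-1, 1), each = 12)
  accs <- vapply(c(0.01, 0.1, 1, 10), function(C) {
    m <- train_binary_svm(x, t, C = C)
    mean(sign(decision_value(m, x)) == t)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[4], 1)
})

test_that("the RBF kernel hook trains a nonlinear boundary", {
  set.seed(171)
  # concentric classes: not linearly separable
  th <- stats::runif(60, 0, 2 * pi)
  r <- c(stats::runif(30, 0, 1), stats::runif(30, 2.5, 3.5))
  x <- cbind(r * cos(th), r * sin(th))
  t <- rep(c(1, -1), each = 30)
  m <- train_binary_svm(x, t, C = 10, kernel = rbf_kernel(gamma = 1))
  expect_gte(mean(sign(decision_value(m, x)) == t), 0.95)
})
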