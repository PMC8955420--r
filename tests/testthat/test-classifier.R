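# Small-model tests for the native CNN/MLP engine. The acceptance suite
# exercises the full 62-channel architecture; here the configs are shrunk
# so each block runs in seconds.

test_that("flatten length matches the closed-form shape arithmetic", {
  expect_equal(cnn_flatten_length(62, 62), 3136L)  # 62->60->30->28->14
  expect_equal(cnn_flatten_length(32, 32), 576L)   # 32->30->15->13->6
  expect_error(cnn_flatten_length(7, 7), "too small")
  expect_error(cnn_flatten_length(8, 8), "too small")  # second pool empties
  m <- build_model(cnn_config(), head_config(n_classes = 3), c(62, 62, 5))
  expect_equal(m$flatten_length, 3136L)
  expect_error(build_model(cnn_config(), head_config(), c(7, 7, 1)),
               "too small")
})

test_that("extract_features returns the flatten-stage matrix deterministically", {
  m <- build_model(cnn_config(conv1_maps = 4, conv2_maps = 3),
                   head_config(c(8, 8), n_classes = 2), c(14, 14, 2))
  set.seed(9)
  x <- array(runif(14 * 14 * 2 * 6), c(14, 14, 2, 6))
  ft <- extract_features(m, x)
  expect_equal(dim(ft), c(6, cnn_flatten_length(14, 14, 3)))
  expect_true(all(is.finite(ft)))
  # identical inputs give identical rows; constant input stays finite
  x[, , , 2] <- x[, , , 1]
  ft2 <- extract_features(m, x)
  expect_identical(ft2[1, ], ft2[2, ])
  xc <- array(0.5, c(14, 14, 2, 1))
  expect_true(all(is.finite(extract_features(m, xc))))
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("asmapr")
  set.seed(33)
  m <- build_model(cnn_config(conv1_maps = 3, conv2_maps = 2,
                              dropout_rate = 0),
                   head_config(c(5, 4), n_classes = 3), c(12, 12, 2))
  N <- 4
  x <- array(runif(12 * 12 * 2 * N), c(12, 12, 2, N))
  y <- matrix(0, N, 3); y[cbind(1:N, sample(3, N, TRUE))] <- 1
  loss_at <- function(p) ns$cross_entropy(ns$nn_forward(m, x, params = p)$probs, y)
  cache <- ns$nn_forward(m, x, training = TRUE)
  g <- ns$nn_backward(m, cache, y)
  eps <- 1e-5
  for (nm in names(g)) {
    p <- m$params
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training is seeded and reaches high accuracy on separable data", {
  set.seed(8)
  N <- 60
  x <- array(runif(12 * 12 * 1 * N), c(12, 12, 1, N))
  lab <- rep(c("a", "b"), each = N / 2)
  x[3:6, 3:6, 1, lab == "b"] <- x[3:6, 3:6, 1, lab == "b"] + 2
  mk <- function() build_model(cnn_config(conv1_maps = 4, conv2_maps = 4),
                               head_config(c(16, 16), n_classes = 2),
                               c(12, 12, 1))
  cfg <- train_config(batch_size = 16, max_epochs = 30, seed = 11)
  m1 <- train_model(mk(), x, lab, cfg)
  # dropout-free inference on the training examples
  expect_gte(mean(predict(m1, x) == lab), 0.95)
  # same seed, same data -> identical split and identical weights
  m2 <- train_model(mk(), x, lab, cfg)
  expect_identical(m1$split$val_idx, m2$split$val_idx)
  expect_equal(m1$params, m2$params)
  # a different seed gives a different split
  m3 <- train_model(mk(), x, lab, train_config(batch_size = 16,
                                               max_epochs = 1, seed = 12))
  expect_false(identical(m1$split$val_idx, m3$split$val_idx))
})

test_that("training rejects degenerate label sets and shape mismatches", {
  m <- build_model(cnn_config(conv1_maps = 2, conv2_maps = 2),
                   head_config(c(4, 4), n_classes = 2), c(12, 12, 1))
  x <- array(runif(12 * 12 * 1 * 4), c(12, 12, 1, 4))
  expect_error(train_model(m, x, c("a", "a", "a", "b"), train_config()),
               ">= 2 examples")
  xbad <- array(runif(10 * 10 * 1 * 4), c(10, 10, 1, 4))
  expect_error(train_model(m, xbad, rep(c("a", "b"), 2), train_config()),
               "shape")
})

test_that("evaluation report satisfies its accounting invariants", {
  set.seed(13)
  N <- 48
  x <- array(runif(12 * 12 * 1 * N), c(12, 12, 1, N))
  lab <- rep(c("a", "b", "c"), each = N / 3)
  for (cl in 2:3)  # strong class-specific offsets -> near-perfect model
    x[1:4, (cl * 2):(cl * 2 + 2), 1, lab == c("a", "b", "c")[cl]] <-
      x[1:4, (cl * 2):(cl * 2 + 2), 1, lab == c("a", "b", "c")[cl]] + 2
  m <- build_model(cnn_config(conv1_maps = 4, conv2_maps = 4),
                   head_config(c(16, 16), n_classes = 3), c(12, 12, 1))
  m <- train_model(m, x, lab, train_config(batch_size = 16, max_epochs = 25,
                                           seed = 5))
  rep <- evaluate_model(m, x, lab)
  expect_equal(sum(rep$confusion), rep$n_test)
  expect_equal(unname(rowSums(rep$confusion)), unname(table(lab)[m$classes]),
               ignore_attr = TRUE)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / rep$n_test)
  expect_length(rep$per_class_recall, 3)
  expect_error(evaluate_model(m, x[, , , 0, drop = FALSE], character(0)),
               "empty test set")
})

test_that("label-shuffled training stays at chance (permutation sanity)", {
  set.seed(14)
  N <- 60
  x <- array(runif(12 * 12 * 1 * N), c(12, 12, 1, N))
  lab <- sample(rep(c("a", "b"), each = N / 2))
  m <- build_model(cnn_config(conv1_maps = 3, conv2_maps = 3),
                   head_config(c(8, 8), n_classes = 2), c(12, 12, 1))
  m <- train_model(m, x, lab, train_config(batch_size = 16, max_epochs = 10,
                                           seed = 3))
  acc <- tail(m$history$val_accuracy, 1)
  # 95% binomial interval around 0.5 for the 12-example validation split
  expect_gte(acc, 0.5 - 1.96 * sqrt(0.25 / 12))
  expect_lte(acc, 0.5 + 1.96 * sqrt(0.25 / 12))
})

test_that("dense-head model handles baseline feature vectors", {
  set.seed(15)
  N <- 80; D <- 20
  x <- matrix(rnorm(N * D), N)
  lab <- rep(c("lo", "hi"), each = N / 2)
  x[lab == "hi", 1:5] <- x[lab == "hi", 1:5] + 2
  m <- build_dense_model(head_config(c(32, 32), n_classes = 2), D)
  m <- train_model(m, x, lab, train_config(batch_size = 16, max_epochs = 20,
                                           seed = 2))
  expect_gte(evaluate_model(m, x, lab)$accuracy, 0.9)
  expect_error(extract_features(m, x), "CNN")
})

test_that("model checkpoints round-trip through HDF5", {
  set.seed(16)
  x <- matrix(rnorm(40 * 6), 40)
  lab <- rep(c("a", "b"), each = 20)
  x[lab == "b", ] <- x[lab == "b", ] + 1.5
  m <- build_dense_model(head_config(c(8, 8), n_classes = 2), 6)
  m <- train_model(m, x, lab, train_config(batch_size = 10, max_epochs = 5,
                                           seed = 1))
  f <- tempfile(fileext = ".h5")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, x, type = "prob"), predict(m, x, type = "prob"))
  expect_identical(m2$classes, m$classes)
})
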