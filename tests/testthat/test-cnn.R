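test_that("architecture variants match their layer specifications", {
  m1 <- build_cnn(1, n_classes = 2, input_dim = 310)
  types <- function(m) vapply(m$layers, `[[`, character(1), "type")
  expect_equal(types(m1), c("conv1d", "maxpool1d", "dropout", "flatten",
                            "dense"))
  expect_equal(m1$layers[[1]]$filters, 64)
  expect_equal(m1$layers[[1]]$kernel, 3)
  expect_equal(m1$layers[[1]]$activation, "relu")
  expect_equal(m1$layers[[2]]$width, 2)
  expect_equal(m1$layers[[3]]$rate, 0.5)
  expect_equal(m1$layers[[5]]$units, 1)           # logistic head for 2 classes
  expect_equal(m1$layers[[5]]$activation, "sigmoid")

  m2 <- build_cnn(2, n_classes = 7, input_dim = 310)
  expect_equal(types(m2), c("conv1d", "dropout", "maxpool1d", "flatten",
                            "dense", "dropout", "dense"))
  expect_equal(m2$layers[[2]]$rate, 0.25)
  expect_equal(m2$layers[[5]]$units, 128)
  expect_equal(m2$layers[[6]]$rate, 0.25)
  expect_equal(m2$layers[[7]]$units, 7)
  expect_equal(m2$layers[[7]]$activation, "softmax")

  m3 <- build_cnn(3, n_classes = 4, input_dim = 310)
  expect_equal(m3$layers[[2]]$rate, 0.5)
  expect_equal(m3$layers[[6]]$rate, 0.5)

  # variant 2 has the extra dense-128 stage, hence more parameters
  expect_gt(n_parameters(build_cnn(2, 2, 310)), n_parameters(build_cnn(1, 2, 310)))
  expect_error(build_cnn(4, 2), "unknown model variant")
})

test_that("softmax probabilities are normalized and predictions stay in-scheme", {
  set.seed(1)
  X <- matrix(rnorm(30 * 40), 30, 40)
  y <- factor(sample(c("a", "b", "c"), 30, TRUE), levels = c("a", "b", "c"))
  m <- cnn_fit(X, y, variant = 2, epochs = 2, seed = 1)
  pr <- predict(m, X, type = "prob")
  expect_equal(dim(pr), c(30L, 3L))
  expect_equal(rowSums(pr), rep(1, 30), tolerance = 1e-6)
  expect_true(all(predict(m, X) %in% c("a", "b", "c")))
  expect_error(predict(m, X[, 1:10]), "features")
})

test_that("binary head maps probability >= 0.5 to the positive class", {
  m <- build_cnn(1, n_classes = 2, input_dim = 10, seed = 1)
  m$fitted <- TRUE
  m$classes <- c("HA", "LA")
  m$positive <- "HA"
  # zero weights + zero bias give probability exactly 0.5 -> positive class
  m$weights$W1[] <- 0; m$weights$Wout[] <- 0
  p <- predict(m, matrix(rnorm(50), 5, 10), type = "prob")
  expect_equal(unname(p[, "HA"]), rep(0.5, 5))
  expect_equal(as.character(predict(m, matrix(rnorm(50), 5, 10))),
               rep("HA", 5))
})

test_that("a 40-trial separable set is memorized within 50 epochs", {
  set.seed(1)
  n <- 40; d <- 310
  y <- factor(rep(c("HA", "LA"), each = n / 2), levels = c("HA", "LA"))
  mu <- matrix(0, 2, d); mu[1, 1:50] <- 1.5; mu[2, 1:50] <- -1.5
  X <- mu[as.integer(y), ] + matrix(rnorm(n * d), n, d)
  m <- cnn_fit(X, y, variant = 1, epochs = 50, seed = 7, positive = "HA")
  expect_gte(mean(predict(m, X) == y), 0.95)
  expect_length(m$loss_history, 50L)
  expect_true(all(is.finite(m$loss_history)))
})

test_that("training is deterministic given the seed", {
  set.seed(2)
  X <- matrix(rnorm(60 * 40), 60, 40)
  y <- factor(sample(c("HA", "LA"), 60, TRUE))
  m1 <- cnn_fit(X, y, variant = 1, epochs = 10, seed = 5, positive = "HA")
  m2 <- cnn_fit(X, y, variant = 1, epochs = 10, seed = 5, positive = "HA")
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$weights, m2$weights)
  m3 <- cnn_fit(X, y, variant = 1, epochs = 10, seed = 6, positive = "HA")
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("full-batch training is equivariant to sample order", {
  set.seed(3)
  X <- matrix(rnorm(24 * 20), 24, 20)
  y <- factor(sample(c("HA", "LA"), 24, TRUE), levels = c("HA", "LA"))
  perm <- sample(24)
  # dropout masks are position-indexed, so the check runs without them
  m1 <- cnn_fit(X, y, variant = 1, epochs = 5, batch_size = 24, seed = 4,
                positive = "HA", dropout = FALSE)
  m2 <- cnn_fit(X[perm, ], y[perm], variant = 1, epochs = 5, batch_size = 24,
                seed = 4, positive = "HA", dropout = FALSE)
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-4)
})

test_that("missing classes after aggressive cleaning raise a warning", {
  set.seed(4)
  X <- matrix(rnorm(20 * 30), 20, 30)
  y <- factor(rep("a", 20), levels = c("a", "b", "c"))
  m <- build_cnn(2, n_classes = 3, input_dim = 30)
  expect_warning(cnn_train(m, X, y, epochs = 1, seed = 1), "absent")
})
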