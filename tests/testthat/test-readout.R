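# Linear and CNN readout heads, prediction, CAM and weight quantisation.

test_that("the linear readout separates a separable toy and converges to a stationary point", {
  d <- toy_two_cluster()
  m <- train_linear(d, l2 = 0.01)
  expect_identical(m$train_accuracy, 1)
  pr <- predict(m, d)
  expect_equal(unname(rowSums(pr$scores)), rep(1, nrow(d$X)), tolerance = 1e-12)
  # oracle: central finite-difference gradient of the penalised loss
  X <- scale(d$X); attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  Y <- diag(2)[as.integer(d$y), ]
  theta <- c(as.numeric(m$W), m$b)
  loss_at <- function(th) {
    W <- matrix(th[1:(ncol(X) * 2)], ncol(X), 2); b <- th[ncol(X) * 2 + 1:2]
    Z <- sweep(X %*% W, 2, -b); Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    -sum(Y * log(P)) / nrow(X) + 0.01 / 2 * sum(W^2)
  }
  h <- 1e-6
  num_grad <- vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta; tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(num_grad^2)), 1e-5)
})

test_that("with overwhelming regularisation predictions collapse to class priors", {
  withr::with_seed(14, {
    X <- matrix(rnorm(100 * 3), 100, 3)
    d <- labeled_states(X, rep(c("a", "b"), c(70, 30)))
  })
  m <- train_linear(d, l2 = 1e6)
  expect_lt(max(abs(m$W)), 1e-4)
  pr <- predict(m, d)
  expect_equal(unname(colMeans(pr$scores)), c(0.7, 0.3), tolerance = 0.01)
})

test_that("single-class data is rejected", {
  X <- matrix(rnorm(20), 10, 2)
  d <- labeled_states(X, rep("a", 10))
  expect_error(train_linear(d), class = "fibrc_input_error")
})

test_that("batch prediction equals per-sample prediction", {
  d <- toy_two_cluster()
  m <- train_linear(d, l2 = 0.01)
  pr_all <- predict(m, d)
  for (i in c(1, 17, 60)) {
    pr_one <- predict(m, d$X[i, , drop = FALSE])
    expect_identical(pr_one$labels, pr_all$labels[i])
    expect_equal(unname(pr_one$scores[1, ]), unname(pr_all$scores[i, ]), tolerance = 1e-12)
  }
})

test_that("relabelling classes permutes the prediction scores", {
  d <- toy_two_cluster()
  m1 <- train_linear(d, l2 = 0.01)
  d2 <- labeled_states(d$X, ifelse(as.character(d$y) == "a", "z", "y"))
  m2 <- train_linear(d2, l2 = 0.01)
  p1 <- predict(m1, d)$scores
  p2 <- predict(m2, d)$scores
  expect_equal(unname(p1[, "a"]), unname(p2[, "z"]), tolerance = 1e-6)
  expect_equal(unname(p1[, "b"]), unname(p2[, "y"]), tolerance = 1e-6)
})

test_that("the linear CAM is an exact additive decomposition of the logit", {
  d <- small_stage3_states(6)
  m <- train_linear(d, l2 = 1)
  x <- d$X[3, , drop = FALSE]
  for (cl in m$classes) {
    cm <- cam(m, x, class = cl)
    expect_identical(dim(cm), c(64L, 16L))
    ci <- match(cl, m$classes)
    xs <- (x[1, ] - m$scaler$center) / m$scaler$scale
    logit <- sum(xs * m$W[, ci]) + m$b[ci]
    expect_equal(sum(cm) + attr(cm, "bias"), logit, tolerance = 1e-9)
  }
  # zero state gives a zero CAM (scaler folded into the weights)
  zc <- cam(m, matrix(0, 1, ncol(d$X)), class = m$classes[1])
  expect_true(all(zc == 0))
  # argmax of the CAM is the largest |weight x state| cell
  cm <- cam(m, x, class = m$classes[2])
  we <- m$W[, 2] / m$scaler$scale
  expect_identical(which.max(abs(as.numeric(t(cm)))), which.max(abs(we * x[1, ])))
})

test_that("the CNN readout learns nothing from constant inputs and is reproducible", {
  X <- matrix(1, 30, 8 * 4)
  d <- labeled_states(X, rep(c("a", "b", "c"), c(15, 9, 6)))
  d$layout <- c(8L, 4L)
  m <- suppressMessages(train_cnn(d, epochs = 30, seed = 1))
  expect_equal(m$train_accuracy, 0.5)   # majority class frequency
  m2 <- suppressMessages(train_cnn(d, epochs = 30, seed = 1))
  expect_identical(m$params, m2$params)
})

test_that("full-batch gradient descent with a small step decreases the CNN loss monotonically", {
  d <- small_stage3_states(4)
  m <- train_cnn(d, epochs = 40, lr = 0.01, momentum = 0, seed = 3)
  expect_true(all(diff(m$loss_curve) <= 1e-8))
})

test_that("a grid too small to pool falls back to a single conv layer", {
  withr::with_seed(17, X <- matrix(rnorm(20 * 6), 20, 6))
  d <- labeled_states(X, rep(c("a", "b"), 10))
  d$layout <- c(1L, 6L)
  expect_message(m <- train_cnn(d, epochs = 5, seed = 2), "single conv")
  expect_true(m$arch$single)
  expect_identical(dim(predict(m, d)$scores), c(20L, 2L))
})

test_that("weight quantisation is idempotent on the level grid and bounded by half a step", {
  d <- toy_two_cluster()
  m <- train_linear(d, l2 = 0.01)
  q <- quantize_weights(m, 16)
  step <- q$level_values$W[2] - q$level_values$W[1]
  expect_true(all(abs(q$model$W - m$W) <= step / 2 + 1e-15))
  # idempotence: quantising an already-quantised model changes nothing
  q2 <- quantize_weights(q$model, 16)
  expect_equal(q2$model$W, q$model$W, tolerance = 1e-15)
  # every quantised magnitude sits on the level grid
  expect_true(all(vapply(abs(as.numeric(q$model$W)), function(v)
    min(abs(v - q$level_values$W)) < 1e-12, logical(1))))
  expect_error(quantize_weights(m, 1), class = "fibrc_config_error")
})

test_that("quantized models report an accuracy delta on evaluation data", {
  d <- toy_two_cluster()
  m <- train_linear(d, l2 = 0.01)
  q <- quantize_weights(m, 16, eval_data = d)
  expect_identical(q$accuracy_before, 1)
  expect_gte(q$accuracy_after, 0.95)
  expect_identical(q$accuracy_delta, q$accuracy_after - q$accuracy_before)
})
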