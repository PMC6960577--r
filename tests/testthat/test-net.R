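test_that("initialization is deterministic with chained layer shapes", {
  spec <- network_spec(50, c(83, 83), 5, seed = 12)
  m1 <- init_network(spec)
  m2 <- init_network(spec)
  expect_identical(m1$weights, m2$weights)
  expect_equal(dim(m1$weights[[1]]), c(83L, 50L))
  expect_equal(dim(m1$weights[[2]]), c(83L, 83L))
  expect_equal(dim(m1$weights[[3]]), c(5L, 83L))
  expect_true(all(vapply(m1$biases, function(b) all(b == 0), logical(1))))
  m3 <- init_network(network_spec(50, c(83, 83), 5, seed = 13))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("the forward pass computes induced local fields and activations", {
  spec <- network_spec(2, c(3), 5, seed = 1)
  m <- init_network(spec)
  m$weights <- lapply(m$weights, function(w) w * 0)
  out <- mlp_forward(m, c(0.3, -0.8))
  expect_equal(as.numeric(out), rep(0.5, 5))   # sigmoid(0) = 0.5

  # single neuron: v = w.x + b = 1*3 + 2*4 = 11
  m1 <- init_network(network_spec(2, c(1), 1, seed = 1))
  m1$weights[[1]] <- matrix(c(1, 2), 1, 2)
  m1$weights[[2]] <- matrix(1, 1, 1)
  m1$biases <- list(0, 0)
  fp <- affectflight:::.forward_pass(m1, matrix(c(3, 4), 1))
  expect_equal(as.numeric(fp$fields[[1]]), 11)

  # classification head: softmax rows sum to one
  mc <- init_network(network_spec(4, c(6), 5, output_mode = "classification",
                                  seed = 3))
  set.seed(2)
  out <- mlp_forward(mc, matrix(rnorm(40), 10, 4))
  expect_equal(rowSums(out), rep(1, 10), tolerance = 1e-12)

  expect_error(mlp_forward(m, c(1, 2, 3)), "width")
})

test_that("analytic gradients match central finite differences", {
  fd_check <- function(activation, output_mode) {
    spec <- network_spec(3, c(2), 2, activation = activation,
                         output_mode = output_mode, seed = 42)
    m <- init_network(spec)
    set.seed(7)
    X <- matrix(rnorm(15), 5, 3)
    D <- matrix(runif(10), 5, 2)
    g <- net_gradients(m, X, D)
    h <- 1e-6
    worst <- 0
    for (l in seq_along(m$weights)) {
      for (i in seq_along(m$weights[[l]])) {
        mp <- m; mp$weights[[l]][i] <- mp$weights[[l]][i] + h
        mm <- m; mm$weights[[l]][i] <- mm$weights[[l]][i] - h
        fd <- (net_loss(mp, X, D) - net_loss(mm, X, D)) / (2 * h)
        worst <- max(worst, abs(fd - g$gW[[l]][i]) / max(1e-8, abs(fd)))
      }
      for (i in seq_along(m$biases[[l]])) {
        mp <- m; mp$biases[[l]][i] <- mp$biases[[l]][i] + h
        mm <- m; mm$biases[[l]][i] <- mm$biases[[l]][i] - h
        fd <- (net_loss(mp, X, D) - net_loss(mm, X, D)) / (2 * h)
        worst <- max(worst, abs(fd - g$gb[[l]][i]) / max(1e-8, abs(fd)))
      }
    }
    worst
  }
  expect_lt(fd_check("sigmoid", "regression"), 1e-5)
  expect_lt(fd_check("relu", "regression"), 1e-5)
  expect_lt(fd_check("sigmoid", "classification"), 1e-5)
})

test_that("targets equal to the initial outputs are a fixed point", {
  spec <- network_spec(4, c(3), 5, optimizer = "sgd", lr = 0.5,
                       epochs = 10, seed = 5)
  m <- init_network(spec)
  set.seed(9)
  X <- matrix(rnorm(20), 5, 4)
  D <- mlp_forward(m, X)
  trained <- train_network(m, X, D)
  expect_equal(trained$weights, m$weights, tolerance = 1e-12)
  expect_equal(max(trained$trace), 0, tolerance = 1e-20)
})

test_that("one tiny sgd step decreases the loss by eta times the gradient norm", {
  spec <- network_spec(3, c(4), 2, optimizer = "sgd", lr = 1e-4,
                       momentum = 0, epochs = 1, seed = 8)
  m <- init_network(spec)
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  D <- matrix(runif(20), 10, 2)
  g <- net_gradients(m, X, D)
  gnorm2 <- sum(unlist(lapply(g$gW, function(x) sum(x^2)))) +
    sum(unlist(lapply(g$gb, function(x) sum(x^2))))
  before <- net_loss(m, X, D)
  after <- net_loss(train_network(m, X, D), X, D)
  expect_equal(before - after, spec$lr * gnorm2, tolerance = 0.1)
})

test_that("delta-rule training solves an XOR-style intensity task", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  D <- cbind(c(0.1, 0.9, 0.9, 0.1), c(0.9, 0.1, 0.1, 0.9))
  spec <- network_spec(2, c(8), 2, optimizer = "sgd", lr = 0.9,
                       momentum = 0.9, epochs = 6000, seed = 3)
  m <- train_network(init_network(spec), X, D)
  expect_lt(rmse(D, mlp_forward(m, X)), 0.1)
  # error energy decreases over training
  n10 <- ceiling(length(m$trace) * 0.1)
  expect_lt(mean(utils::tail(m$trace, n10)), mean(utils::head(m$trace, n10)))
})

test_that("adam training reduces the error energy on separable data", {
  set.seed(14)
  X <- matrix(rnorm(200), 40, 5)
  D <- matrix(runif(200, 0.2, 0.8), 40, 5)
  spec <- network_spec(5, c(10), 5, optimizer = "adam", lr = 0.02,
                       epochs = 300, seed = 2)
  m <- train_network(init_network(spec), X, D)
  n10 <- ceiling(length(m$trace) * 0.1)
  expect_lt(mean(utils::tail(m$trace, n10)), mean(utils::head(m$trace, n10)))
})

test_that("prediction is deterministic, bounded and name-checked", {
  set.seed(20)
  X <- matrix(rnorm(60), 12, 5)
  colnames(X) <- paste0("f", 1:5)
  D <- matrix(runif(60, 0.1, 0.9), 12, 5)
  spec <- network_spec(5, c(6), 5, optimizer = "adam", lr = 0.02,
                       epochs = 50, seed = 4)
  m <- train_network(init_network(spec), X, D)
  p1 <- predict_emotions(m, X)
  p2 <- predict_emotions(m, X)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(colnames(p1), EMOTIONS)
  Xbad <- X; colnames(Xbad) <- paste0("g", 1:5)
  expect_error(predict_emotions(m, Xbad), "manifest")
  expect_error(train_network(init_network(spec), X, D + 1), "\\[0, 1\\]")
})
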