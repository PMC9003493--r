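test_that("count_weights reproduces the reference architecture table", {
  archs <- list(list(h = 1L, n = 8L), list(h = 2L, n = 15L),
                list(h = 3L, n = 22L), list(h = 4L, n = 29L),
                list(h = 5L, n = 36L), list(h = 20L, n = 141L))
  for (a in archs)
    expect_equal(count_weights(net_architecture(5, a$h, 1)), a$n)
  expect_equal(count_weights(net_architecture(5, c(20, 15), 1)), 451L)
  # no hidden layer: plain 5 weights + 1 bias
  expect_equal(count_weights(net_architecture(5, integer(0), 1)), 6L)
})

test_that("instantiated networks carry exactly the counted parameters", {
  set.seed(3)
  for (h in list(integer(0), 1L, 3L, c(20L, 15L))) {
    arch <- net_architecture(5, h, 1)
    expect_equal(n_parameters(new_dense_net(arch)), count_weights(arch))
  }
})

test_that("forward pass matches closed-form and loop oracles", {
  # zero weights everywhere: sigmoid(0) = 0.5 for any input
  arch <- net_architecture(5, 3, 1)
  zero <- new_dense_net(arch,
                        weights = list(matrix(0, 5, 3), matrix(0, 3, 1)),
                        biases = list(rep(0, 3), 0))
  expect_equal(predict_proba(zero, rnorm(5)), 0.5)

  # single-layer model, hand-set weights: proba = sigmoid(2)
  lin <- new_dense_net(net_architecture(5, integer(0), 1),
                       weights = list(matrix(c(1, 0, 0, 0, 0), 5, 1)),
                       biases = list(0))
  expect_equal(predict_proba(lin, c(2, 9, 9, 9, 9)), 1 / (1 + exp(-2)))

  # random small networks vs the independent loop oracle
  set.seed(11)
  for (rep in 1:100) {
    d <- sample(2:6, 1)
    h <- if (runif(1) < 0.3) integer(0) else sample(1:8, sample(1:2, 1))
    m <- new_dense_net(net_architecture(d, h, 1),
                       scaler_mean = rnorm(d), scaler_scale = runif(d, 0.5, 2))
    X <- matrix(rnorm(5 * d), ncol = d)
    expect_equal(predict_proba(m, X), oracle_forward(m, X), tolerance = 1e-12)
  }
})

test_that("classify applies the decision threshold", {
  lin <- new_dense_net(net_architecture(1, integer(0), 1),
                       weights = list(matrix(1, 1, 1)), biases = list(0))
  # sigmoid(-0.04) ~ 0.49 -> class 0; sigmoid(0) = 0.5 -> class 1
  expect_equal(classify(lin, matrix(-0.04)), 0L)
  expect_equal(classify(lin, matrix(0)), 1L)
  expect_error(predict_proba(lin, matrix(rnorm(4), ncol = 2)), "dimension")
})

test_that("training learns a linearly separable problem and is deterministic", {
  set.seed(5)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(X$x1 + X$x2 > 0)
  # the data are separable: logistic regression is the separability oracle
  # perfect separation makes glm complain while still ranking correctly
  glm_fit <- suppressWarnings(glm(y ~ x1 + x2, data = cbind(X, y = y),
                                  family = binomial))
  glm_acc <- mean((predict(glm_fit) > 0) == (y == 1))
  expect_gte(glm_acc, 0.95)

  cfg <- train_config("sgd", epochs = 500, batch_size = 10, seed = 0)
  m1 <- train_dense_net(X, y, net_architecture(2, 2, 1), cfg)
  expect_gte(m1$training$validation$accuracy, 0.95)

  m2 <- train_dense_net(X, y, net_architecture(2, 2, 1), cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)

  expect_error(train_dense_net(X, rep(1L, n), net_architecture(2, 2, 1), cfg),
               "both classes")
  Xbad <- X; Xbad$x1[1] <- NaN
  expect_error(train_dense_net(Xbad, y, net_architecture(2, 2, 1), cfg),
               "non-finite")
})

test_that("training loss trends downward over epochs", {
  set.seed(6)
  n <- 100
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.integer(X$a - 0.5 * X$b > 0)
  m <- train_dense_net(X, y, net_architecture(2, 3, 1),
                       train_config("sgd", epochs = 100, batch_size = 10, seed = 1))
  loss <- m$training$epoch_loss
  expect_lt(loss[length(loss)], loss[1])
})
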