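test_that("softmax output is normalized and shift-invariant", {
  net <- network_config(c(4, 3, 2), dropout_rate = 0)
  params <- withr::with_seed(1, dtiscope:::nn_init(net))
  x <- withr::with_seed(2, matrix(rnorm(40), ncol = 4))
  prob <- nn_forward(params, x, net)$prob
  expect_equal(rowSums(prob), rep(1, 10), tolerance = 1e-9)
  expect_true(all(prob >= 0))

  # logits (0, 0) -> (0.5, 0.5); shifting both logits leaves the row unchanged
  expect_equal(as.numeric(dtiscope:::softmax_rows(matrix(c(0, 0), 1))), c(0.5, 0.5))
  z <- matrix(c(1.3, -0.4), 1)
  expect_equal(dtiscope:::softmax_rows(z), dtiscope:::softmax_rows(z + 7.7),
               tolerance = 1e-12)
  expect_equal(dtiscope:::softmax_rows(matrix(c(1000, 1001), 1)),
               dtiscope:::softmax_rows(matrix(c(0, 1), 1)), tolerance = 1e-12)
})

test_that("forward pass matches a by-hand computation on a toy net", {
  net <- network_config(c(2, 1, 2), dropout_rate = 0)
  params <- list(
    weights = list(matrix(c(1, 2), nrow = 1), matrix(c(0.4, -0.2), nrow = 2)),
    biases = list(0.1, c(0.05, -0.05))
  )
  x <- matrix(c(1, 0.5), nrow = 1)
  # hidden: relu(1*1 + 2*0.5 + 0.1) = 2.1
  # logits: (0.4*2.1 + 0.05, -0.2*2.1 - 0.05) = (0.89, -0.47)
  z <- c(0.89, -0.47)
  expected <- exp(z) / sum(exp(z))
  prob <- nn_forward(params, x, net)$prob
  expect_equal(as.numeric(prob), expected, tolerance = 1e-12)

  # negative pre-activation is cut by ReLU: output falls back to the biases
  x2 <- matrix(c(-1, -1), nrow = 1)
  z2 <- c(0.05, -0.05)
  expect_equal(as.numeric(nn_forward(params, x2, net)$prob),
               exp(z2) / sum(exp(z2)), tolerance = 1e-12)

  expect_error(nn_forward(params, matrix(0, 1, 3), net), "width")
})

test_that("penalized loss evaluates the objective exactly", {
  # one positive predicted perfectly: cross-entropy 0, no penalty
  expect_equal(penalized_loss(matrix(c(0, 1), 1), labels = 1, eta = 5), 0,
               tolerance = 1e-6)
  # one negative predicted perfectly at eta = 10: 0 - 10 * 1 = -10
  expect_equal(penalized_loss(matrix(c(1, 0), 1), labels = 0, eta = 10), -10,
               tolerance = 1e-6)
  expect_error(penalized_loss(matrix(c(0.5, 0.5), 1), labels = 2, eta = 1),
               "labels")
})

test_that("loss equals an independent scalar re-implementation", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      p1 <- runif(6, 0.01, 0.99)
      prob <- cbind(1 - p1, p1)
      y <- rbinom(6, 1, 0.5)
      eta <- runif(1, 0, 20)
      expect_equal(penalized_loss(prob, y, eta), loss_oracle(prob, y, eta),
                   tolerance = 1e-10)
      # eta = 0 reduces to plain cross-entropy
      expect_equal(penalized_loss(prob, y, 0),
                   mean(-y * log(p1) - (1 - y) * log(1 - p1)),
                   tolerance = 1e-10)
    }
  })
})

test_that("analytic gradients match central differences", {
  net <- network_config(c(4, 3, 2), dropout_rate = 0)
  params <- withr::with_seed(3, dtiscope:::nn_init(net))
  x <- withr::with_seed(4, matrix(rnorm(20), ncol = 4))
  y <- c(1, 0, 0, 1, 0)
  for (eta in c(0, 10)) {
    fwd <- nn_forward(params, x, net)
    analytic <- flatten_params(dtiscope:::nn_gradient(params, fwd, y, eta))
    theta <- flatten_params(params)
    h <- 1e-5
    numeric_grad <- vapply(seq_along(theta), function(j) {
      up <- theta; up[j] <- up[j] + h
      dn <- theta; dn[j] <- dn[j] - h
      lu <- penalized_loss(nn_forward(unflatten_params(up, params), x, net)$prob, y, eta)
      ld <- penalized_loss(nn_forward(unflatten_params(dn, params), x, net)$prob, y, eta)
      (lu - ld) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(numeric_grad), 1e-3)
    expect_lt(max(abs(analytic - numeric_grad) / denom), 1e-4)
  }
})

test_that("training is reproducible and records its history", {
  pool <- small_pool(seed = 7)
  x <- pool_features(pool)
  y <- as.integer(pool$samples$label == "positive")
  net <- network_config(c(32, 8, 2), dropout_rate = 0.5)
  tc <- train_config(eta = 1, learning_rate = 1e-3, epochs = 15,
                     batch_size = 16, seed = 99)
  a <- train_dnn(x, y, net, tc)
  b <- train_dnn(x, y, net, tc)
  expect_identical(a$params, b$params)
  expect_equal(nrow(a$history), 15)
  expect_true(all(c("loss", "train_accuracy") %in% names(a$history)))

  expect_error(train_dnn(x, rep(0, length(y)), net, tc), "single class")

  g <- glance(a)
  expect_equal(g$epochs_trained, 15)
  td <- tidy(a)
  expect_equal(td$n_parameters, c(32 * 8 + 8, 8 * 2 + 2))
})

test_that("inference is deterministic, normalized and per-sample", {
  pool <- small_pool(seed = 7)
  x <- pool_features(pool)
  y <- as.integer(pool$samples$label == "positive")
  net <- network_config(c(32, 8, 2), dropout_rate = 0.5)
  fit <- train_dnn(x, y, net, train_config(eta = 1, learning_rate = 1e-3,
                                           epochs = 5, batch_size = 32, seed = 1))
  big <- withr::with_seed(8, matrix(rnorm(1000 * 32), ncol = 32))
  p1 <- predict(fit, big)
  p2 <- predict(fit, big)
  expect_identical(p1, p2)
  expect_equal(p1$p_negative + p1$p_positive, rep(1, 1000), tolerance = 1e-9)

  # permuting the input rows permutes the output rows identically
  perm <- withr::with_seed(9, sample.int(1000))
  expect_equal(predict(fit, big[perm, ]), p1[perm, ], ignore_attr = TRUE)
})

test_that("inverted dropout keeps inference-time activations unscaled", {
  net <- network_config(c(6, 40, 2), dropout_rate = 0.5)
  params <- withr::with_seed(5, dtiscope:::nn_init(net))
  x <- withr::with_seed(6, matrix(rnorm(6), nrow = 1))
  clean <- nn_forward(params, x, net)$activations[[2]]
  avg <- withr::with_seed(7, {
    runs <- replicate(4000,
      nn_forward(params, x, net, train_mode = TRUE)$activations[[2]])
    apply(runs, c(1, 2), mean)
  })
  # E[mask * a / (1 - rate)] = a: train-mode activations are unbiased
  expect_equal(mean(abs(avg - clean)) / mean(abs(clean)), 0, tolerance = 0.05)
})

test_that("raising the penalty weight makes negatives more confidently negative", {
  pool <- small_pool(seed = 7)
  x <- pool_features(pool)
  y <- as.integer(pool$samples$label == "positive")
  net <- network_config(c(32, 8, 2), dropout_rate = 0.5)
  mean_p1_neg <- function(eta, seed) {
    tc <- train_config(eta = eta, learning_rate = 1e-3, epochs = 30,
                       batch_size = 32, seed = seed)
    fit <- train_dnn(x, y, net, tc)
    mean(predict(fit, x)$p_positive[y == 0])
  }
  etas <- c(0, 10, 100)
  avg <- sapply(etas, function(e) mean(sapply(1:5, function(s) mean_p1_neg(e, s))))
  # trend over seeds: the mean positive-class probability on true negatives
  # must not increase with eta
  expect_lte(avg[2], avg[1] + 0.02)
  expect_lte(avg[3], avg[2] + 0.02)
  expect_lt(avg[3], avg[1])
})
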