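# Architecture accounting, forward-pass contracts, and gradient
# correctness of the network.

expected_lengths <- c(2698, 2696, 1348, 1346, 1344, 672, 670, 668, 666,
                      333, 331, 329, 327, 163, 161, 159, 157, 78)
expected_channels <- c(64, 64, 64, 128, 128, 128, 256, 256, 256, 256,
                       512, 512, 512, 512, 512, 512, 512, 512)
expected_params <- c(256, 12352, 0, 24704, 49280, 0, 98560, 196864,
                     196864, 0, 393728, 786944, 786944, 0, 786944,
                     786944, 786944, 0)

test_that("the canonical trace matches the published feature-learning table", {
  tr <- shape_trace(model_config(2))
  feat <- tr[1:18, ]
  expect_equal(feat$output_length, expected_lengths)
  expect_equal(feat$output_channels, expected_channels)
  expect_equal(feat$parameters, expected_params)
  expect_equal(tr$output_length[tr$name == "flatten"], 78 * 512)
  expect_equal(tr$parameters[tr$name == "dense1"], 39936 * 1000 + 1000)
  expect_equal(tr$parameters[tr$name == "dense2"], 1001000)
  expect_equal(tr$parameters[tr$name == "output"], 1001)
  expect_equal(count_parameters(model_config(2)), 45846329)
  expect_equal(sum(tr$parameters), count_parameters(model_config(2)))
})

test_that("the three-class head swaps in softmax with three units", {
  tr <- shape_trace(model_config(3))
  expect_equal(tr$parameters[tr$name == "output"], 3003)
  expect_equal(tr$output_length[tr$name == "output"], 3)
  # feature-learning stack identical
  expect_equal(tr$parameters[1:18], expected_params)
})

test_that("a single toy conv layer has length-3 output and 4 parameters", {
  cfg <- small_model_config(2, input_length = 5, filters = 1L,
                            dense = integer(0))
  tr <- shape_trace(cfg)
  expect_equal(tr$output_length[1], 3)
  expect_equal(tr$parameters[1], 4)
})

test_that("template violations are rejected naming the offending layer", {
  cfg <- model_config(2)
  cfg$layers[[4]]$kernel <- 5L
  expect_error(rhythm_cnn(cfg), "layer 4")
  cfg2 <- model_config(2)
  cfg2$layers[[3]]$size <- 3L
  expect_error(rhythm_cnn(cfg2), "layer 3")
  cfg3 <- model_config(2)
  cfg3$layers[[1]] <- NULL
  expect_error(rhythm_cnn(cfg3), "13 conv")
  cfg4 <- model_config(2)
  cfg4$layers[[22]]$activation <- "tanh"
  expect_error(rhythm_cnn(cfg4), "output head")
})

test_that("prediction is deterministic, ordered, bounded, with the stated tie rule", {
  net <- rhythm_cnn(tiny_config(), seed = 3)
  set.seed(1)
  X <- matrix(rnorm(10 * 64), 10, 64)
  p1 <- predict(net, X)
  p2 <- predict(net, X)
  expect_identical(p1, p2)
  expect_true(all(p1$p_AF >= 0 & p1$p_AF <= 1))
  expect_equal(p1$p_N + p1$p_AF, rep(1, 10))
  # batch order preserved: single-row predictions agree row-for-row
  singles <- vapply(1:10, function(i)
    predict(net, X[i, , drop = FALSE])$p_AF, numeric(1))
  expect_equal(p1$p_AF, singles, tolerance = 1e-12)
  expect_identical(p1$label, ifelse(p1$p_AF >= 0.5, "AF", "N"))

  net3 <- rhythm_cnn(tiny_config(3), seed = 3)
  p3 <- predict(net3, X)
  expect_equal(p3$p_N + p3$p_AF + p3$p_NON_AF, rep(1, 10))
  expect_true(all(p3$label %in% rhythm_classes()))
})

test_that("wrong episode lengths are rejected naming the offender", {
  net <- rhythm_cnn(tiny_config(), seed = 1)
  expect_error(predict(net, matrix(0, 2, 63)), "63")
  eps <- list(ecg_episode(numeric(64), length = 64),
              ecg_episode(numeric(32), length = 32))
  expect_error(predict(net, eps), "episode 2")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- small_model_config(2, input_length = 20, filters = c(3L, NA),
                            dense = 5L)
  net <- rhythm_cnn(cfg, seed = 11)
  set.seed(4)
  X <- matrix(rnorm(4 * 20), 4, 20)
  y <- matrix(c(1, 0, 1, 0), ncol = 1)
  w <- c(2, 1, 2, 1)
  loss_fn <- function(net) {
    p <- rhythmnet:::cnn_forward(net, X)$probs
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / nrow(X)
  }
  fw <- rhythmnet:::cnn_forward(net, X, keep_cache = TRUE)
  dZ <- (fw$probs - y) * (w / nrow(X))
  grads <- rhythmnet:::cnn_backward(net, fw$caches, dZ)
  h <- 1e-6
  for (li in seq_along(grads)) {
    if (is.null(grads[[li]]) || !length(grads[[li]])) next
    set.seed(li)
    for (probe in 1:4) {
      i <- sample(length(net$weights[[li]]$W), 1)
      np <- net; np$weights[[li]]$W[i] <- np$weights[[li]]$W[i] + h
      nm <- net; nm$weights[[li]]$W[i] <- nm$weights[[li]]$W[i] - h
      num <- (loss_fn(np) - loss_fn(nm)) / (2 * h)
      expect_equal(grads[[li]]$dW[i], num, tolerance = 1e-4)
    }
    i <- sample(length(net$weights[[li]]$b), 1)
    np <- net; np$weights[[li]]$b[i] <- np$weights[[li]]$b[i] + h
    nm <- net; nm$weights[[li]]$b[i] <- nm$weights[[li]]$b[i] - h
    expect_equal(grads[[li]]$db[i], (loss_fn(np) - loss_fn(nm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("softmax gradients also match numerical differentiation", {
  cfg <- small_model_config(3, input_length = 16, filters = 2L,
                            dense = 4L)
  net <- rhythm_cnn(cfg, seed = 2)
  set.seed(9)
  X <- matrix(rnorm(3 * 16), 3, 16)
  Y <- diag(3)
  loss_fn <- function(net) {
    p <- pmin(pmax(rhythmnet:::cnn_forward(net, X)$probs, 1e-12), 1)
    -sum(Y * log(p)) / nrow(X)
  }
  fw <- rhythmnet:::cnn_forward(net, X, keep_cache = TRUE)
  grads <- rhythmnet:::cnn_backward(net, fw$caches,
                                    (fw$probs - Y) / nrow(X))
  h <- 1e-6
  li <- which(vapply(grads, function(g) !is.null(g) && length(g) > 0,
                     TRUE))[1]
  for (i in c(1, 3)) {
    np <- net; np$weights[[li]]$W[i] <- np$weights[[li]]$W[i] + h
    nm <- net; nm$weights[[li]]$W[i] <- nm$weights[[li]]$W[i] - h
    expect_equal(grads[[li]]$dW[i], (loss_fn(np) - loss_fn(nm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip configuration and weights", {
  net <- rhythm_cnn(tiny_config(), seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  set.seed(2)
  X <- matrix(rnorm(3 * 64), 3, 64)
  expect_equal(predict(back, X)$p_AF, predict(net, X)$p_AF,
               tolerance = 1e-12)
})
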