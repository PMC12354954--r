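test_that("conv_output_side follows valid-convolution arithmetic", {
  expect_equal(conv_output_side(8, 5, 3), 2)  # human config geometry
  expect_equal(conv_output_side(8, 4, 2), 3)  # yeast/mouse geometry
  for (k in c(3, 5, 8)) expect_equal(conv_output_side(k, k, 1), 1)
  expect_error(conv_output_side(6, 7, 1), "exceeds")
})

test_that("map_input zero_pad appends the right number of zeros row-major", {
  v60 <- seq_len(60)
  g <- map_input(v60, 8, "zero_pad")
  expect_equal(dim(g), c(8, 8))
  expect_equal(sum(g == 0), 4)             # 64 - 60
  expect_equal(g[1, ], as.numeric(1:8))    # row-major layout
  expect_equal(g[8, 5:8], rep(0, 4))       # zeros land at the tail
  g40 <- map_input(seq_len(40), 8, "zero_pad")
  expect_equal(sum(g40 == 0), 24)
  expect_error(map_input(seq_len(40), 6, "zero_pad"), "zero_pad")
})

test_that("map_input dense_projection applies supplied affine weights", {
  expect_error(map_input(1:4, 2, "dense_projection"), "weights")
  W <- matrix(1:8, 4, 4)[, 1:4] * 0 + diag(4)
  g <- map_input(c(1, 2, 3, 4), 2, "dense_projection",
                 weights = list(W = diag(4), b = rep(1, 4)))
  expect_equal(g, matrix(c(2, 3, 4, 5), 2, 2, byrow = TRUE))
})

test_that("hyperparams validates its fields", {
  expect_s3_class(hyperparams(8, 5, 3, 2, 32, "SeLU"), "hyperparams")
  expect_error(hyperparams(6, 7, 1, 1, 4, "relu"), "exceeds")
  expect_error(hyperparams(8, 3, 1, 1, 4, "tanh"), "activation")
})

test_that("build_model resolves the published configurations' shapes", {
  human <- build_model(hyperparams(8, 5, 3, 2, 32, "selu"), 40,
                       quiet = TRUE)
  expect_equal(human$conv_side, 2)
  expect_equal(human$pool_side, 1)
  expect_false(human$pool_skipped)
  expect_equal(human$flat_size, 16)
  expect_equal(human$dropout, 0.30)

  yeast <- build_model(hyperparams(8, 4, 2, 1, 32, "relu"), 60,
                       quiet = TRUE)
  expect_equal(yeast$conv_side, 3)
  expect_equal(yeast$pool_side, 1)

  expect_no_error(build_model(hyperparams(8, 5, 3, 1, 4, "relu"), 40,
                              mode = "zero_pad", quiet = TRUE))
  expect_error(build_model(hyperparams(6, 5, 1, 1, 4, "relu"), 40,
                           mode = "zero_pad", quiet = TRUE), "illegal")
})

test_that("shape algebra is sound across the whole legal space", {
  for (rd in c(6, 7, 8)) for (kk in c(3, 4, 5)) for (st in 1:3) {
    for (input_dim in c(40, 60)) {
      spec <- build_model(hyperparams(rd, kk, st, 1, 4, "relu"),
                          input_dim, quiet = TRUE)
      expect_gte(spec$conv_side, 1)
      expect_gte(spec$pool_side, 1)
      expect_gt(spec$flat_size, 0)
      # a 1x1 conv map must skip pooling, larger maps must pool
      expect_equal(spec$pool_skipped, spec$conv_side < 2)
    }
  }
})

test_that("dense stack parameter count matches the stored weights", {
  for (hp in list(hyperparams(8, 5, 3, 2, 32, "selu"),
                  hyperparams(7, 3, 1, 3, 8, "relu"))) {
    spec <- build_model(hp, 40, quiet = TRUE)
    m <- train_cnn(spec, tiny_feature_set(n = 8, seed = 2)$X,
                   tiny_feature_set(n = 8, seed = 2)$y,
                   epochs = 1, seed = 1)
    dense_names <- c(paste0(rep(c("W", "b"), spec$dense_layers),
                            rep(seq_len(spec$dense_layers), each = 2)),
                     "Wout", "bout")
    stored <- sum(vapply(m$weights[dense_names], length, integer(1)))
    expect_equal(dense_param_count(spec), stored)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  # tiny network, full analytic-vs-numeric check on every parameter block
  hp <- hyperparams(4, 2, 2, 1, 3, "selu")
  spec <- build_model(hp, 5, filters = 2, quiet = TRUE)
  set.seed(99)
  w <- pseucnn:::init_weights(spec)
  cidx <- pseucnn:::conv_patch_index(spec$reshape_dim, spec$conv_kernel,
                                     spec$conv_stride)
  pidx <- pseucnn:::pool_patch_index(spec$conv_side)
  Xb <- matrix(stats::rnorm(5 * 5), 5, 5)
  y <- c(0L, 1L, 1L, 0L, 1L)
  Y <- cbind(1 - y, y)
  mask <- list(matrix(1, 5, 3))   # dropout disabled for the check
  loss_at <- function(w) {
    P <- pseucnn:::forward_pass(spec, w, Xb, cidx, pidx, mask)$P
    -mean(log(P[cbind(1:5, y + 1)]))
  }
  fw <- pseucnn:::forward_pass(spec, w, Xb, cidx, pidx, mask)
  g <- pseucnn:::backward_pass(spec, w, Xb, Y, fw, cidx, pidx, mask)
  eps <- 1e-6
  for (nm in names(w)) {
    for (i in seq_len(min(length(w[[nm]]), 12))) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-4,
                   label = paste0("d", nm, "[", i, "]"))
    }
  }
})

test_that("training learns strongly separable data and is deterministic", {
  blobs <- gaussian_blobs(30, 40, seed = 8)
  spec <- build_model(hyperparams(8, 5, 3, 2, 32, "selu"), 40,
                      quiet = TRUE)
  m1 <- train_cnn(spec, blobs$X, blobs$y, epochs = 30, seed = 4)
  p1 <- predict_proba(m1, blobs$X)
  expect_gte(mean((p1 > 0.5) == blobs$y), 0.99)
  expect_gt(mean(p1[blobs$y == 1]), 0.9)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # loss trend is downward on separable data
  expect_lt(m1$final_loss, m1$losses[1])
  # same seed -> identical model and predictions
  m2 <- train_cnn(spec, blobs$X, blobs$y, epochs = 30, seed = 4)
  expect_identical(predict_proba(m2, blobs$X), p1)
  # dropout is off at prediction: repeated calls identical
  expect_identical(predict_proba(m1, blobs$X), p1)
})

test_that("softmax probabilities are normalized per row", {
  fs <- tiny_feature_set(n = 10, seed = 9)
  spec <- build_model(hyperparams(7, 3, 2, 1, 8, "relu"), ncol(fs$X),
                      quiet = TRUE)
  m <- train_cnn(spec, fs$X, fs$y, epochs = 2, seed = 1)
  cidx <- pseucnn:::conv_patch_index(spec$reshape_dim, spec$conv_kernel,
                                     spec$conv_stride)
  pidx <- pseucnn:::pool_patch_index(spec$conv_side)
  P <- pseucnn:::forward_pass(spec, m$weights, fs$X, cidx, pidx, NULL)$P
  expect_equal(rowSums(P), rep(1, nrow(fs$X)), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("training rejects invalid inputs", {
  fs <- tiny_feature_set(n = 6, seed = 10)
  spec <- build_model(hyperparams(7, 3, 2, 1, 8, "relu"), ncol(fs$X),
                      quiet = TRUE)
  expect_error(train_cnn(spec, fs$X, rep(1L, nrow(fs$X)),
                         epochs = 1, seed = 1), "both classes")
  expect_error(train_cnn(spec, fs$X[, 1:10], fs$y, epochs = 1, seed = 1),
               "expects")
  m <- train_cnn(spec, fs$X, fs$y, epochs = 1, seed = 1)
  expect_error(predict_proba(m, fs$X[, 1:10]), "expects")
})

test_that("models survive the JSON save/load round-trip", {
  fs <- tiny_feature_set(n = 8, seed = 12)
  spec <- build_model(hyperparams(8, 4, 2, 1, 16, "relu"), ncol(fs$X),
                      quiet = TRUE)
  m <- train_cnn(spec, fs$X, fs$y, epochs = 3, seed = 2)
  p <- tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(predict_proba(m2, fs$X), predict_proba(m, fs$X))
  expect_equal(m2$spec, m$spec)
})
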