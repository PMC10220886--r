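test_that("the default conv stack has a 3.5 s receptive field at 32 Hz", {
  rf <- receptive_field(cnn_architecture())
  expect_equal(rf$samples, 112)
  expect_equal(rf$seconds, 3.5)
  # the audit formula holds for arbitrary stacks too
  a2 <- cnn_architecture(kernels = c(5, 9, 3), channels = c(4, 4, 4))
  expect_equal(receptive_field(a2)$samples, 1 + 4 + 8 + 2)
  expect_error(cnn_architecture(dense = c(64, 16)), "32, 16")
})

test_that("rotation sampling produces proper rotations; zero strength is identity", {
  expect_identical(sample_rotation(0), diag(3))
  set.seed(12)
  for (i in 1:1000) {
    R <- sample_rotation(runif(1))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
  }
  expect_error(sample_rotation(1.5), "\\[0, 1\\]")
  expect_error(sample_rotation(-0.1), "\\[0, 1\\]")
})

test_that("rotation sampling matches a step-by-step Gram-Schmidt oracle", {
  for (s in c(0.2, 0.7)) {
    set.seed(99)
    R <- sample_rotation(s)
    set.seed(99)
    M <- matrix(rnorm(9), 3, 3)
    B <- (1 - s) * diag(3) + s * M
    Q <- oracle_gram_schmidt(B)
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    expect_equal(R, Q, tolerance = 1e-12)
  }
})

test_that("small strengths give rotations near the identity", {
  set.seed(77)
  devs <- replicate(1000, max(abs(sample_rotation(1e-3) - diag(3))))
  expect_lt(max(devs), 0.05)
})

test_that("augmentation is identity in eval mode and norm-preserving in train", {
  set.seed(3)
  X <- array(rnorm(3 * 384 * 4), c(3, 384, 4))
  expect_identical(augment_batch(X, 0.5, 0.1, training = FALSE), X)
  set.seed(4)
  expect_identical(augment_batch(X, 0, 0, training = TRUE), X)
  set.seed(5)
  Xr <- augment_batch(X, 0.5, 0, training = TRUE)
  for (i in 1:4) {
    expect_equal(sqrt(colSums(Xr[, , i]^2)), sqrt(colSums(X[, , i]^2)),
                 tolerance = 1e-9)
  }
  expect_error(augment_batch(array(0, c(2, 10, 1)), 0, 0), "3 channels")
})

test_that("training drives the loss down on separable classes, deterministically", {
  ws <- separable_windows(80)
  arch <- cnn_architecture(kernels = c(8, 9, 9), channels = c(6, 6, 8))
  cfg <- train_config("idlab", epochs = 10L, lr = 3e-3, batch = 64L,
                      decay_every = 5L, seed = 9L)
  m1 <- train_cnn(ws, cfg, arch = arch)
  expect_lt(tail(m1$log$loss, 1), 0.5 * m1$log$loss[1])
  m2 <- train_cnn(ws, cfg, arch = arch)
  expect_identical(m1$params, m2$params)
  # training windows classified correctly
  ev <- evaluate_model(m1, ws)
  expect_gt(ev$summary$balanced_accuracy, 0.9)
})

test_that("freezing all layers returns the initialization untouched", {
  ws <- separable_windows(10)
  arch <- cnn_architecture(kernels = c(5, 5), channels = c(4, 4))
  cfg <- train_config("idlab", epochs = 3L, batch = 32L, seed = 2L)
  frozen <- har_layer_names(arch)
  m <- train_cnn(ws, cfg, arch = arch, freeze = frozen)
  init <- with_seed(cfg$seed, nn_init(arch, 2))
  expect_identical(m$params, init)
})

test_that("predictions are proper, deterministic probability vectors", {
  ws <- separable_windows(10)
  arch <- cnn_architecture(kernels = c(5, 5), channels = c(4, 4))
  m <- train_cnn(ws, train_config("idlab", epochs = 2L, batch = 32L),
                 arch = arch)
  p <- predict(m, ws)
  pm <- as.matrix(p[paste0(".pred_", m$vocabulary)])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
  expect_true(all(pm >= 0))
  # a duplicated window gets the identical output
  X <- ws$array[, , c(1, 1), drop = FALSE]
  p2 <- predict(m, X)
  expect_identical(p2[1, ], p2[2, ])
  # zeroed softmax layer -> uniform probabilities
  m0 <- m
  m0$params$softmax$W[] <- 0; m0$params$softmax$b[] <- 0
  p0 <- as.matrix(predict(m0, X)[paste0(".pred_", m$vocabulary)])
  expect_true(all(abs(p0 - 0.5) < 1e-12))
})

test_that("training labels outside the vocabulary are rejected", {
  ws <- separable_windows(5)
  expect_error(train_cnn(ws, train_config("idlab", epochs = 1L),
                         arch = cnn_architecture(kernels = c(5, 5),
                                                 channels = c(4, 4)),
                         vocabulary = c("other")), "vocabulary")
})

test_that("analytic gradients match finite differences", {
  arch <- cnn_architecture(kernels = c(3, 3), channels = c(4, 4))
  set.seed(2)
  X <- array(rnorm(3 * 20 * 5), c(3, 20, 5))
  y <- c(1L, 2L, 1L, 2L, 1L)
  params <- with_seed(8, nn_init(arch, 2))
  cfg <- train_config("idlab", spatial_dropout = 0, dense_dropout = 0,
                      input_noise_sd = 0, weight_noise_sd = 0,
                      rotation_strength = 0)
  trainable <- setNames(rep(TRUE, 5), nn_layer_names(arch))
  loss_of <- function(p) {
    fw <- nn_forward(p, arch, X, training = FALSE)
    -mean(log(pmax(fw$probs[cbind(y, 1:5)], 1e-15)))
  }
  fw <- nn_forward(params, arch, X, training = TRUE, cfg = cfg,
                   keep_cache = TRUE)
  Y <- matrix(0, 2, 5); Y[cbind(y, 1:5)] <- 1
  gr <- nn_backward(params, arch, fw$probs, Y, fw$cache, cfg, trainable)
  for (nm in names(params)) {
    for (idx in 1:4) {
      pp <- params
      pp[[nm]]$W[idx] <- pp[[nm]]$W[idx] + 1e-6
      num <- (loss_of(pp) - loss_of(params)) / 1e-6
      expect_equal(gr[[nm]]$W[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("model checkpoints round-trip", {
  ws <- separable_windows(10)
  arch <- cnn_architecture(kernels = c(5, 5), channels = c(4, 4))
  m <- train_cnn(ws, train_config("idlab", epochs = 2L, batch = 32L),
                 arch = arch)
  dir <- withr::local_tempdir()
  write_model(m, dir)
  back <- read_model(dir)
  expect_equal(back$params, m$params)
  expect_equal(back$vocabulary, m$vocabulary)
  p1 <- predict(m, ws$array[, , 1:3, drop = FALSE])
  p2 <- predict(back, ws$array[, , 1:3, drop = FALSE])
  expect_equal(p1, p2)
})

test_that("tidy and glance summarise fitted models", {
  ws <- separable_windows(10)
  arch <- cnn_architecture(kernels = c(5, 5), channels = c(4, 4))
  m <- train_cnn(ws, train_config("idlab", epochs = 2L, batch = 32L),
                 arch = arch, freeze = "conv1")
  td <- tidy(m)
  expect_equal(td$layer, c("conv1", "conv2", "dense1", "dense2", "softmax"))
  expect_true(td$frozen[1] && !any(td$frozen[-1]))
  gl <- glance(m)
  expect_equal(gl$epochs, 2L)
  expect_equal(gl$n_classes, 2L)
})

test_that("rotation augmentation buys rotation robustness at evaluation time", {
  ws <- separable_windows(80, seed = 6)
  arch <- cnn_architecture(kernels = c(8, 9, 9), channels = c(6, 6, 8))
  base <- train_config("idlab", epochs = 10L, lr = 3e-3, batch = 64L,
                       decay_every = 5L, seed = 9L)
  cfg_aug <- base; cfg_aug$rotation_strength <- 0.4
  cfg_none <- base; cfg_none$rotation_strength <- 0
  m_aug <- train_cnn(ws, cfg_aug, arch = arch)
  m_none <- train_cnn(ws, cfg_none, arch = arch)
  R <- rotation_about("z", 60) %*% rotation_about("x", 45)
  ws_rot <- ws
  for (i in seq_len(n_windows(ws))) {
    ws_rot$array[, , i] <- R %*% ws$array[, , i]
  }
  drop_of <- function(m) {
    evaluate_model(m, ws)$summary$balanced_accuracy -
      evaluate_model(m, ws_rot)$summary$balanced_accuracy
  }
  expect_lt(drop_of(m_aug), drop_of(m_none))
})
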