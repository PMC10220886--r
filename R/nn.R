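# Compact 1D CNN engine.
#
# Dense linear algebra formulated as im2col matrix products so the heavy
# lifting happens in BLAS. Layout conventions:
#   signals/activations: array (channels, time, batch)
#   conv weights:        matrix (C_out, C_in * k), bias length C_out
#   dense weights:       matrix (units_out, units_in)
# Convolutions are stride-1 and "valid" (no padding); the temporal receptive
# field of a stack is 1 + sum(k_i - 1) input samples.

unfold_cols <- function(Tn, To, N) {
  rep(seq_len(To), times = N) + rep((seq_len(N) - 1L) * Tn, each = To)
}

# Valid stride-1 1D convolution of a (C, T, N) batch with weights
# (C_out, C*k). Delegates to compiled im2col + GEMM.
conv1d_fwd <- function(A, W, b, k) {
  d <- dim(A)
  Am <- A; dim(Am) <- c(d[1], d[2] * d[3])
  .conv1d_fwd_cpp(Am, W, b, d[2], d[3], k)
}

# Gradients of conv1d_fwd. dZ: (C_out, To*N). Returns dW (same shape as W),
# db, and (optionally) dX as a (C, T, N) array.
conv1d_bwd <- function(A, W, k, dZ, need_dX = TRUE, need_dW = TRUE) {
  d <- dim(A)
  Am <- A; dim(Am) <- c(d[1], d[2] * d[3])
  out <- .conv1d_bwd_cpp(Am, W, dZ, d[2], d[3], k, need_dX, need_dW)
  if (need_dX) dim(out$dX) <- d
  list(dW = out$dW, db = if (need_dW) as.vector(out$db) else NULL,
       dX = if (need_dX) out$dX else NULL)
}

swish <- function(z) { s <- 1 / (1 + exp(-z)); list(a = z * s, s = s) }
swish_grad <- function(z, s) s * (1 + z * (1 - s))
relu <- function(z) pmax(z, 0)

gap_forward <- function(A) {   # (C, To, N) -> (C, N)
  d <- dim(A)
  B <- aperm(A, c(1, 3, 2)); dim(B) <- c(d[1] * d[3], d[2])
  P <- rowMeans(B); dim(P) <- c(d[1], d[3])
  P
}

gap_backward <- function(dP, To) {
  d <- dim(dP)
  dB <- matrix(dP / To, d[1] * d[2], To)
  dim(dB) <- c(d[1], d[2], To)
  aperm(dB, c(1, 3, 2))
}

nn_layer_names <- function(arch) {
  c(paste0("conv", seq_along(arch$kernels)), "dense1", "dense2", "softmax")
}

nn_init <- function(arch, n_classes, in_channels = 3) {
  params <- list()
  cin <- in_channels
  for (i in seq_along(arch$kernels)) {
    k <- arch$kernels[i]; cout <- arch$channels[i]
    sd <- sqrt(2 / (cin * k))
    params[[paste0("conv", i)]] <- list(
      W = matrix(rnorm(cout * cin * k, 0, sd), cout, cin * k),
      b = rep(0, cout))
    cin <- cout
  }
  sizes <- c(cin, arch$dense, n_classes)
  nm <- c("dense1", "dense2", "softmax")
  for (i in 1:3) {
    params[[nm[i]]] <- list(
      W = matrix(rnorm(sizes[i + 1] * sizes[i], 0, sqrt(2 / sizes[i])),
                 sizes[i + 1], sizes[i]),
      b = rep(0, sizes[i + 1]))
  }
  params
}

# Forward pass. When training, applies spatial (whole-channel) dropout after
# each conv activation, plain dropout after each dense activation, and
# transient Gaussian noise on the weights of the first two conv layers.
nn_forward <- function(params, arch, X, training = FALSE, cfg = NULL,
                       keep_cache = FALSE) {
  n_conv <- length(arch$kernels)
  N <- dim(X)[3]
  cache <- list(inputs = list(), Z = list(), S = list(), masks = list(),
                Wn = list())
  A <- X
  for (i in seq_len(n_conv)) {
    nm <- paste0("conv", i)
    W <- params[[nm]]$W
    if (training && i <= 2 && cfg$weight_noise_sd > 0) {
      W <- W + matrix(rnorm(length(W), 0, cfg$weight_noise_sd), nrow(W), ncol(W))
    }
    if (keep_cache) { cache$inputs[[nm]] <- A; cache$Wn[[nm]] <- W }
    k <- arch$kernels[i]
    To <- dim(A)[2] - k + 1
    Z <- conv1d_fwd(A, W, params[[nm]]$b, k)
    sw <- swish(Z)
    A <- sw$a
    if (training && cfg$spatial_dropout > 0) {
      m <- matrix(stats::rbinom(arch$channels[i] * N, 1, 1 - cfg$spatial_dropout),
                  arch$channels[i], N) / (1 - cfg$spatial_dropout)
      A <- A * m[, rep(seq_len(N), each = To)]
      if (keep_cache) cache$masks[[nm]] <- m
    }
    dim(A) <- c(arch$channels[i], To, N)
    if (keep_cache) { cache$Z[[nm]] <- Z; cache$S[[nm]] <- sw$s }
  }
  To_last <- dim(A)[2]
  P <- gap_forward(A)
  cache$To_last <- To_last
  H <- P
  for (i in 1:2) {
    nm <- paste0("dense", i)
    Z <- params[[nm]]$W %*% H + params[[nm]]$b
    if (keep_cache) { cache$inputs[[nm]] <- H; cache$Z[[nm]] <- Z }
    H <- relu(Z)
    if (training && cfg$dense_dropout > 0) {
      m <- matrix(stats::rbinom(length(H), 1, 1 - cfg$dense_dropout),
                  nrow(H), ncol(H)) / (1 - cfg$dense_dropout)
      H <- H * m
      if (keep_cache) cache$masks[[nm]] <- m
    }
  }
  if (keep_cache) cache$inputs$softmax <- H
  logits <- params$softmax$W %*% H + params$softmax$b
  logits <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                            byrow = TRUE)
  e <- exp(logits)
  probs <- e / matrix(colSums(e), nrow(e), ncol(e), byrow = TRUE)
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass for categorical cross-entropy. `trainable` is a named logical
# over layers; gradients are only materialized for trainable layers, and the
# downward pass stops below the deepest trainable conv layer.
nn_backward <- function(params, arch, probs, y_onehot, cache, cfg, trainable) {
  n_conv <- length(arch$kernels)
  N <- ncol(probs)
  grads <- list()
  dH <- (probs - y_onehot) / N              # dL/dlogits
  nm <- "softmax"
  if (trainable[nm]) {
    grads[[nm]] <- list(W = dH %*% t(cache$inputs[[nm]]), b = rowSums(dH))
  }
  dH <- crossprod(params[[nm]]$W, dH)
  for (i in 2:1) {
    nm <- paste0("dense", i)
    if (!is.null(cache$masks[[nm]])) dH <- dH * cache$masks[[nm]]
    dZ <- dH * (cache$Z[[nm]] > 0)
    if (trainable[nm]) {
      grads[[nm]] <- list(W = dZ %*% t(cache$inputs[[nm]]), b = rowSums(dZ))
    }
    dH <- crossprod(params[[nm]]$W, dZ)
  }
  lowest <- which(trainable[paste0("conv", seq_len(n_conv))])
  lowest <- if (length(lowest)) min(lowest) else n_conv + 1L
  dA <- gap_backward(dH, cache$To_last)     # (C, To, N)
  for (i in n_conv:1) {
    if (i < lowest) break
    nm <- paste0("conv", i)
    k <- arch$kernels[i]
    To <- dim(dA)[2]
    dAm <- dA; dim(dAm) <- c(arch$channels[i], To * N)
    if (!is.null(cache$masks[[nm]])) {
      dAm <- dAm * cache$masks[[nm]][, rep(seq_len(N), each = To)]
    }
    dZ <- dAm * swish_grad(cache$Z[[nm]], cache$S[[nm]])
    bw <- conv1d_bwd(cache$inputs[[nm]], cache$Wn[[nm]], k, dZ,
                     need_dX = i > lowest, need_dW = trainable[nm])
    if (trainable[nm]) grads[[nm]] <- list(W = bw$dW, b = bw$db)
    if (i > lowest) dA <- bw$dX
  }
  grads
}

adam_init <- function(params) {
  purrr::map(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                      mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhatW <- s$mW / (1 - beta1^t); vhatW <- s$vW / (1 - beta2^t)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    params[[nm]]$W <- params[[nm]]$W - lr * grads[[nm]]$W
    params[[nm]]$b <- params[[nm]]$b - lr * grads[[nm]]$b
  }
  params
}

# Core training loop shared by general training (Adam) and personalization
# (SGD with layer freezing).
nn_train <- function(params, arch, X, y_int, n_classes, cfg, trainable) {
  n <- dim(X)[3]
  if (n == 0) abort("empty training set")
  state <- if (cfg$optimizer == "adam") adam_init(params) else NULL
  log <- vector("list", cfg$epochs)
  t_step <- 0
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_decay^floor((epoch - 1) / cfg$decay_every)
    perm <- sample.int(n)
    losses <- c()
    for (b0 in seq(1, n, by = cfg$batch)) {
      ids <- perm[b0:min(b0 + cfg$batch - 1, n)]
      Xb <- X[, , ids, drop = FALSE]
      Xb <- augment_batch(Xb, strength = cfg$rotation_strength,
                          noise_sd = cfg$input_noise_sd, training = TRUE)
      fw <- nn_forward(params, arch, Xb, training = TRUE, cfg = cfg,
                       keep_cache = TRUE)
      Y <- matrix(0, n_classes, length(ids))
      Y[cbind(y_int[ids], seq_along(ids))] <- 1
      p_true <- pmax(fw$probs[cbind(y_int[ids], seq_along(ids))], 1e-15)
      losses <- c(losses, -mean(log(p_true)))
      grads <- nn_backward(params, arch, fw$probs, Y, fw$cache, cfg, trainable)
      t_step <- t_step + 1
      if (cfg$optimizer == "adam") {
        st <- adam_step(params, grads, state, lr, t_step)
        params <- st$params; state <- st$state
      } else {
        params <- sgd_step(params, grads, lr)
      }
    }
    log[[epoch]] <- tibble(epoch = epoch, loss = mean(losses), lr = lr)
  }
  list(params = params, log = dplyr::bind_rows(log))
}
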