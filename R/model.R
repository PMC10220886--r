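#' Default CNN architecture
#'
#' Seven stride-1 1D convolutional layers with swish activations, global
#' average pooling, two ReLU dense layers of 32 and 16 units, and a softmax
#' output. The default kernel sizes (16, 17, 17, 17, 17, 17, 17) give a
#' temporal receptive field of exactly `1 + sum(k - 1) = 112` input samples,
#' i.e. 3.5 s at 32 Hz - long enough to span several movement cycles of any
#' of the target activities. Channel widths are configurable; narrow stacks
#' train much faster on small synthetic cohorts with little loss.
#'
#' @param kernels Integer kernel sizes, one per conv layer.
#' @param channels Integer channel widths, one per conv layer.
#' @param dense Sizes of the two dense layers (fixed at 32 and 16).
#' @return A list of class `har_arch`.
#' @export
cnn_architecture <- function(kernels = c(16, 17, 17, 17, 17, 17, 17),
                             channels = c(32, 32, 64, 64, 64, 128, 128),
                             dense = c(32, 16)) {
  if (length(kernels) != length(channels)) {
    abort("kernels and channels must have one entry per conv layer")
  }
  if (!identical(as.integer(dense), c(32L, 16L))) {
    abort("the dense stack is fixed at sizes (32, 16)")
  }
  structure(list(kernels = as.integer(kernels),
                 channels = as.integer(channels),
                 dense = as.integer(dense), strides = rep(1L, length(kernels))),
            class = "har_arch")
}

#' Receptive field of a convolutional stack
#'
#' `1 + sum((k_i - 1) * prod(strides before layer i))` input samples; with
#' the default stride-1 stack this is `1 + sum(k - 1)`.
#'
#' @param arch A [cnn_architecture()].
#' @param rate Sampling rate for the seconds conversion (default 32 Hz).
#' @return A list with `samples` and `seconds`.
#' @export
receptive_field <- function(arch, rate = 32) {
  jumps <- cumprod(c(1, arch$strides[-length(arch$strides)]))
  samples <- 1 + sum((arch$kernels - 1) * jumps)
  list(samples = samples, seconds = samples / rate)
}

#' Training configuration for the two training regimes
#'
#' The `"idlab"` regime is tuned for large heterogeneous real-world cohorts:
#' 105 epochs of Adam at learning rate 8e-4 (decayed by 0.3 every 30
#' epochs), spatial/dense dropout 0.15, Gaussian input and weight noise 0.03,
#' rotation strength 0.2, batch 600. The `"controlled"` regime is tuned for
#' small clean protocol data: 270 epochs at 5e-3 (decay 0.3 every 50),
#' dropout 0.075, noise 0.015, rotation 0.1, batch 600. Any field can be
#' overridden.
#'
#' @param regime `"idlab"` or `"controlled"`.
#' @param ... Named overrides of any configuration field (`epochs`, `lr`,
#'   `optimizer`, `lr_decay`, `decay_every`, `batch`, `spatial_dropout`,
#'   `dense_dropout`, `input_noise_sd`, `weight_noise_sd`,
#'   `rotation_strength`, `seed`).
#' @return A list of class `har_train_config`.
#' @export
train_config <- function(regime = c("idlab", "controlled"), ...) {
  regime <- match.arg(regime)
  cfg <- if (regime == "idlab") {
    list(epochs = 105L, lr = 8e-4, optimizer = "adam", lr_decay = 0.3,
         decay_every = 30L, batch = 600L, spatial_dropout = 0.15,
         dense_dropout = 0.15, input_noise_sd = 0.03, weight_noise_sd = 0.03,
         rotation_strength = 0.2, seed = 1L)
  } else {
    list(epochs = 270L, lr = 5e-3, optimizer = "adam", lr_decay = 0.3,
         decay_every = 50L, batch = 600L, spatial_dropout = 0.075,
         dense_dropout = 0.075, input_noise_sd = 0.015,
         weight_noise_sd = 0.015, rotation_strength = 0.1, seed = 1L)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(sprintf("unknown train_config field '%s'", bad[1]))
  cfg[names(dots)] <- dots
  cfg$regime <- regime
  assert_positive(c(cfg$lr, cfg$batch), "lr/batch")
  assert_positive(cfg$epochs, "epochs", strict = FALSE)
  if (cfg$lr_decay <= 0 || cfg$lr_decay >= 1) abort("lr_decay must be in (0, 1)")
  structure(cfg, class = "har_train_config")
}

# Classical Gram-Schmidt orthonormalization of the columns of B.
gs_orthonormalize <- function(B) {
  Q <- B
  for (j in 1:ncol(B)) {
    v <- B[, j]
    if (j > 1) for (i in 1:(j - 1)) v <- v - sum(Q[, i] * B[, j]) * Q[, i]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(NULL)  # numerically rank deficient; caller redraws
    Q[, j] <- v / nv
  }
  Q
}

#' Sample a random proper rotation matrix
#'
#' Draws a 3x3 matrix of i.i.d. standard normals, blends it barycentrically
#' with the identity, `B = (1 - s) I + s M`, and Gram-Schmidt
#' orthonormalizes B's columns; if the result has determinant -1 the last
#' column is negated. `s = 0` returns the identity exactly; small `s` gives
#' small rotations. Used as the input augmentation layer: each training
#' window is left-multiplied by an independent draw, mimicking the wristband
#' sitting slightly differently on the wrist.
#'
#' @param strength Rotation strength `s` in `[0, 1]`.
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
sample_rotation <- function(strength) {
  if (length(strength) != 1 || is.na(strength) || strength < 0 || strength > 1) {
    abort("`strength` must be a single value in [0, 1]")
  }
  if (strength == 0) return(diag(3))
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    B <- (1 - strength) * diag(3) + strength * M
    R <- gs_orthonormalize(B)
    if (!is.null(R)) break
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

#' Apply rotational augmentation and input noise to a window batch
#'
#' In training mode each window is left-multiplied by an independently
#' sampled rotation ([sample_rotation()]) and perturbed with additive
#' Gaussian noise. In evaluation mode the batch passes through unchanged.
#'
#' @param X Array (3, n_samples, n_windows) or a single 3 x n matrix.
#' @param strength Rotation strength in `[0, 1]`.
#' @param noise_sd Additive noise standard deviation (g).
#' @param training Logical; augmentation only happens when TRUE.
#' @return The augmented array, same shape.
#' @export
augment_batch <- function(X, strength, noise_sd, training = TRUE) {
  single <- is.matrix(X)
  if (single) X <- array(X, c(dim(X), 1))
  if (dim(X)[1] != 3) abort("windows must have 3 channels")
  if (!training) return(if (single) X[, , 1] else X)
  n <- dim(X)[3]
  if (strength > 0) {
    for (i in seq_len(n)) X[, , i] <- sample_rotation(strength) %*% X[, , i]
  }
  if (noise_sd > 0) X <- X + array(rnorm(length(X), 0, noise_sd), dim(X))
  if (single) X[, , 1] else X
}

#' Train the CNN classifier on a window dataset
#'
#' Minimizes categorical cross-entropy with the regime's optimizer and
#' learning-rate schedule, applying rotational augmentation and input noise
#' to every training batch, transient Gaussian noise to the weights of the
#' first two conv layers, spatial (whole-channel) dropout between conv
#' layers and plain dropout between dense layers. Training is deterministic
#' for a fixed `config$seed`. Classes from `vocabulary` absent from the
#' training data are recorded in the provenance; the softmax always covers
#' the full vocabulary.
#'
#' @param windows A `har_windows` training set.
#' @param config A [train_config()].
#' @param arch A [cnn_architecture()].
#' @param vocabulary Class vocabulary (default: the dataset's).
#' @param freeze Character vector of layer names to freeze (see
#'   [har_layer_names()]); frozen parameters are returned bit-identical.
#' @param init Optional `har_model` whose parameters initialize training
#'   (used by transfer learning).
#' @param provenance Optional named list merged into the model's provenance.
#' @return A fitted model of class `har_model`.
#' @export
train_cnn <- function(windows, config = train_config("idlab"),
                      arch = cnn_architecture(), vocabulary = NULL,
                      freeze = NULL, init = NULL, provenance = list()) {
  if (n_windows(windows) == 0) abort("empty training set")
  vocabulary <- vocabulary %||% windows$vocabulary
  y_int <- match(windows$index$activity, vocabulary)
  if (anyNA(y_int)) abort("training labels outside the vocabulary")
  layer_nms <- nn_layer_names(arch)
  freeze <- freeze %||% character(0)
  bad <- setdiff(freeze, layer_nms)
  if (length(bad)) abort(sprintf("unknown layer '%s' in freeze", bad[1]))
  trainable <- setNames(!(layer_nms %in% freeze), layer_nms)
  missing_classes <- setdiff(vocabulary, unique(windows$index$activity))
  res <- with_seed(config$seed, {
    params <- if (is.null(init)) {
      nn_init(arch, length(vocabulary))
    } else {
      if (!identical(init$vocabulary, vocabulary)) {
        abort("vocabulary mismatch between `init` model and training data")
      }
      init$params
    }
    if (config$epochs == 0) {
      list(params = params, log = tibble(epoch = integer(0), loss = numeric(0),
                                         lr = numeric(0)))
    } else {
      nn_train(params, arch, windows$array, y_int, length(vocabulary),
               config, trainable)
    }
  })
  structure(list(
    arch = arch, params = res$params, vocabulary = vocabulary,
    freeze = freeze, log = res$log,
    provenance = c(list(regime = config$regime, seed = config$seed,
                        n_train = n_windows(windows),
                        missing_classes = missing_classes), provenance)
  ), class = "har_model")
}

#' Layer names of a CNN architecture
#' @param arch A [cnn_architecture()].
#' @return Character vector (`conv1`..`conv7`, `dense1`, `dense2`,
#'   `softmax`).
#' @export
har_layer_names <- function(arch = cnn_architecture()) nn_layer_names(arch)

#' @export
print.har_model <- function(x, ...) {
  rf <- receptive_field(x$arch)
  cat(sprintf("<har_model> %d conv layers (RF %.1f s), classes: %s\n",
              length(x$arch$kernels), rf$seconds,
              paste(x$vocabulary, collapse = ", ")))
  if (length(x$freeze)) cat("  frozen:", paste(x$freeze, collapse = ", "), "\n")
  if (nrow(x$log)) cat(sprintf("  trained %d epochs, final loss %.4f\n",
                               max(x$log$epoch), tail(x$log$loss, 1)))
  invisible(x)
}

#' Predict class probabilities for windows
#'
#' Augmentation, dropout and noise are all disabled: inference is
#' deterministic.
#'
#' @param object A `har_model`.
#' @param windows A `har_windows` (or bare array 3 x n x N).
#' @param batch Evaluation batch size (memory cap).
#' @param ... Unused.
#' @return A tibble with one probability column per class (`.pred_<class>`),
#'   the most probable class `.pred_class`, and, when available, the true
#'   `activity`, `subject` and `window_id`.
#' @export
predict.har_model <- function(object, windows, batch = 512, ...) {
  X <- if (inherits(windows, "har_windows")) windows$array else windows
  N <- dim(X)[3]
  probs <- matrix(0, length(object$vocabulary), N)
  for (b0 in seq(1, N, by = batch)) {
    ids <- b0:min(b0 + batch - 1, N)
    fw <- nn_forward(object$params, object$arch, X[, , ids, drop = FALSE],
                     training = FALSE)
    probs[, ids] <- fw$probs
  }
  out <- as_tibble(setNames(as.data.frame(t(probs)),
                            paste0(".pred_", object$vocabulary)))
  out$.pred_class <- object$vocabulary[apply(probs, 2, which.max)]
  if (inherits(windows, "har_windows")) {
    out <- dplyr::bind_cols(
      windows$index[c("window_id", "subject", "activity")], out)
    if (!all(out$activity %in% object$vocabulary)) {
      abort("window labels outside the model vocabulary")
    }
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted CNN: one row per layer
#' @param x A `har_model`.
#' @param ... Unused.
#' @return A tibble `layer, n_parameters, frozen`.
#' @export
tidy.har_model <- function(x, ...) {
  tibble(
    layer = names(x$params),
    n_parameters = vapply(x$params, function(p) length(p$W) + length(p$b),
                          numeric(1)),
    frozen = names(x$params) %in% x$freeze
  )
}

#' One-row summary of a fitted CNN
#' @param x A `har_model`.
#' @param ... Unused.
#' @return A tibble with regime, epochs, final loss, training size, classes.
#' @export
glance.har_model <- function(x, ...) {
  tibble(regime = x$provenance$regime %||% NA_character_,
         epochs = if (nrow(x$log)) max(x$log$epoch) else 0L,
         final_loss = if (nrow(x$log)) tail(x$log$loss, 1) else NA_real_,
         n_train = x$provenance$n_train %||% NA_integer_,
         n_classes = length(x$vocabulary))
}

#' Training-loss curve
#' @param object A `har_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.har_model <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' Save a model checkpoint
#'
#' Architecture, vocabulary and freeze mask as JSON; parameters as raw
#' little-endian float64 arrays; the training log as CSV
#' (`epoch,loss,lr`).
#'
#' @param model A `har_model`.
#' @param dir Checkpoint directory.
#' @return Invisibly, `dir`.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kernels = model$arch$kernels, channels = model$arch$channels,
               dense = model$arch$dense, vocabulary = model$vocabulary,
               freeze = model$freeze,
               shapes = purrr::map(model$params, function(p) dim(p$W)),
               provenance = model$provenance[c("regime", "seed", "n_train")])
  jsonlite::write_json(meta, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "params.bin"), "wb")
  for (nm in names(model$params)) {
    writeBin(as.vector(model$params[[nm]]$W), con, size = 8, endian = "little")
    writeBin(model$params[[nm]]$b, con, size = 8, endian = "little")
  }
  close(con)
  utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint written by [write_model()]
#' @param dir Checkpoint directory.
#' @return A `har_model`.
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  arch <- cnn_architecture(meta$kernels, meta$channels, meta$dense)
  con <- file(file.path(dir, "params.bin"), "rb")
  params <- list()
  for (nm in names(meta$shapes)) {
    d <- meta$shapes[[nm]]
    W <- matrix(readBin(con, "double", d[1] * d[2], size = 8, endian = "little"),
                d[1], d[2])
    b <- readBin(con, "double", d[1], size = 8, endian = "little")
    params[[nm]] <- list(W = W, b = b)
  }
  close(con)
  log <- as_tibble(utils::read.csv(file.path(dir, "training_log.csv")))
  structure(list(arch = arch, params = params, vocabulary = meta$vocabulary,
                 freeze = as.character(meta$freeze %||% character(0)),
                 log = log, provenance = as.list(meta$provenance)),
            class = "har_model")
}
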