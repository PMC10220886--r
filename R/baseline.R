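# Engineered-feature baseline: band-pass filtered 15 s windows summarized by
# 42 statistical features over X, Y, Z and the Euclidean norm (EN), fed to a
# gradient-boosted-tree classifier.

#' The canonical 42-feature inventory
#'
#' Per 15-second window: eight time-domain statistics (mean, min, max, sd,
#' kurtosis, skewness, RMS, IQR) on each of the four channels X, Y, Z and EN
#' (32 features); three spectral features (dominant frequency, spectral
#' energy, spectral entropy) on X, Y and Z (9); and the dominant frequency
#' of EN (1). Total 42. This list is the versioned reference layout - audits
#' of the baseline start here.
#'
#' @return Character vector of 42 feature names, in column order.
#' @export
har_feature_names <- function() {
  td <- c("mean", "min", "max", "sd", "kurtosis", "skewness", "rms", "iqr")
  sp <- c("domfreq", "specenergy", "specentropy")
  c(as.vector(outer(td, c("x", "y", "z", "en"), function(f, ch) paste(ch, f, sep = "_"))),
    as.vector(outer(sp, c("x", "y", "z"), function(f, ch) paste(ch, f, sep = "_"))),
    "en_domfreq")
}

channel_features <- function(v, rate, spectral = TRUE) {
  out <- c(mean = mean(v), min = min(v), max = max(v), sd = stats::sd(v),
           kurtosis = e1071::kurtosis(v, type = 2),
           skewness = e1071::skewness(v, type = 2),
           rms = sqrt(mean(v^2)), iqr = stats::IQR(v))
  out[!is.finite(out)] <- 0   # constant-signal degenerate cases
  if (!spectral) return(out)
  n <- length(v)
  pw <- Mod(stats::fft(v - mean(v)))^2 / n
  half <- 2:(floor(n / 2) + 1)          # exclude DC, keep up to Nyquist
  p <- pw[half]
  freqs <- (half - 1) * rate / n
  tot <- sum(p)
  pn <- if (tot > 0) p / tot else rep(1 / length(p), length(p))
  ent <- -sum(ifelse(pn > 0, pn * log(pn), 0)) / log(length(pn))
  c(out, domfreq = freqs[which.max(p)], specenergy = tot / length(p),
    specentropy = ent)
}

#' Extract baseline features from a labeled stream
#'
#' Band-pass filters X, Y, Z and the Euclidean norm, segments each cleaned
#' label interval into 15 s windows with 50% overlap (same full-containment
#' and gap rules as [segment_windows()]), and emits one 42-feature row per
#' window (see [har_feature_names()]).
#'
#' @param stream A rescaled stream.
#' @param timeline The subject's cleaned timeline.
#' @param window_s Window length (default 15 s).
#' @param overlap Fractional overlap (default 0.5).
#' @param band Band-pass corner frequencies in Hz (default 0.3-12: removes
#'   gravity/drift, keeps locomotion harmonics).
#' @param rate Sampling rate (default 32 Hz).
#' @param subject Subject id (defaults to the stream attribute).
#' @return A tibble: `subject, activity, start_s` plus the 42 feature
#'   columns.
#' @export
extract_features <- function(stream, timeline, window_s = 15, overlap = 0.5,
                             band = c(0.3, 12), rate = 32, subject = NULL) {
  if (any(band <= 0) || any(band >= rate / 2) || band[1] >= band[2]) {
    abort("band must satisfy 0 < low < high < rate/2")
  }
  subject <- subject %||% attr(stream, "subject_id") %||% "S?"
  stride_s <- window_s * (1 - overlap)
  ws <- segment_windows(stream, timeline, window_s = window_s,
                        stride_s = stride_s, rate = rate, subject = subject)
  if (n_windows(ws) == 0) {
    cols <- setNames(rep(list(numeric(0)), 42), har_feature_names())
    return(dplyr::bind_cols(tibble(subject = character(0),
                                   activity = character(0),
                                   start_s = numeric(0)), as_tibble(cols)))
  }
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  rows <- purrr::map(seq_len(n_windows(ws)), function(i) {
    m <- ws$array[, , i]
    en <- sqrt(colSums(m^2))
    ch <- rbind(m, en)
    filt <- t(apply(ch, 1, function(v) as.numeric(signal::filtfilt(bf, v))))
    feats <- c(
      purrr::flatten_dbl(purrr::map(1:4, function(j) {
        unname(channel_features(filt[j, ], rate, spectral = FALSE))
      })),
      purrr::flatten_dbl(purrr::map(1:3, function(j) {
        unname(channel_features(filt[j, ], rate, spectral = TRUE)[9:11])
      })),
      unname(channel_features(filt[4, ], rate, spectral = TRUE)[["domfreq"]])
    )
    feats
  })
  fm <- do.call(rbind, rows)
  colnames(fm) <- har_feature_names()
  dplyr::bind_cols(ws$index[c("subject", "activity", "start_s")], as_tibble(fm))
}

#' Fit / apply feature standardization
#'
#' Standardization (zero mean, unit variance per feature) is fit on training
#' data only and then applied to any feature table.
#'
#' @param features A feature tibble from [extract_features()].
#' @return `fit_standardizer`: a `har_standardizer` (means and sds);
#'   `apply_standardizer`: the standardized tibble.
#' @export
fit_standardizer <- function(features) {
  cols <- intersect(har_feature_names(), names(features))
  mu <- vapply(features[cols], mean, numeric(1))
  sd_ <- vapply(features[cols], stats::sd, numeric(1))
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  structure(list(columns = cols, mean = mu, sd = sd_),
            class = "har_standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer A `har_standardizer`.
#' @export
apply_standardizer <- function(features, standardizer) {
  for (cl in standardizer$columns) {
    features[[cl]] <- (features[[cl]] - standardizer$mean[[cl]]) /
      standardizer$sd[[cl]]
  }
  features
}

#' Train the gradient-boosted-tree baseline
#'
#' Leave-one-subject-out cross-validation over a grid of (number of trees,
#' learning rate, tree depth, L2 regularization), selecting the combination
#' with the best mean CV balanced accuracy, then a final refit on the full
#' dataset. Features are standardized with parameters fit on the respective
#' training folds only.
#'
#' @param features A feature tibble ([extract_features()]) with `subject`
#'   and `activity` columns; needs at least two subjects and two classes.
#' @param tuning_grid A data frame with columns `nrounds`, `eta`,
#'   `max_depth`, `lambda` (default: a single sensible combination).
#' @param seed Integer seed.
#' @return A list of class `har_gbt`: `booster`, `standardizer`,
#'   `vocabulary`, `cv` (per-combination CV table), `best`.
#' @export
train_gbt <- function(features,
                      tuning_grid = data.frame(nrounds = 50, eta = 0.3,
                                               max_depth = 4, lambda = 1),
                      seed = 1L) {
  subs <- unique(features$subject)
  if (length(subs) < 2) abort("leave-one-subject-out CV needs at least 2 subjects")
  vocab <- sort(unique(features$activity))
  if (length(vocab) < 2) abort("need at least 2 classes")
  cols <- intersect(har_feature_names(), names(features))
  y <- match(features$activity, vocab) - 1L
  cv_rows <- list()
  for (g in seq_len(nrow(tuning_grid))) {
    gp <- tuning_grid[g, ]
    bas <- vapply(subs, function(s) {
      tr <- features$subject != s
      std <- fit_standardizer(features[tr, ])
      Xtr <- as.matrix(apply_standardizer(features[tr, ], std)[cols])
      Xte <- as.matrix(apply_standardizer(features[!tr, ], std)[cols])
      bst <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = length(vocab), eta = gp$eta,
                      max_depth = gp$max_depth, lambda = gp$lambda,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(Xtr, label = y[tr]),
        nrounds = gp$nrounds, verbose = 0))
      pred <- predict(bst, xgboost::xgb.DMatrix(Xte))
      cm <- confusion_matrix(vocab[y[!tr] + 1], vocab[pred + 1], vocab)
      metrics_from_confusion(cm)$summary$balanced_accuracy
    }, numeric(1))
    cv_rows[[g]] <- dplyr::bind_cols(as_tibble(gp),
                                     tibble(cv_balanced_accuracy = mean(bas)))
  }
  cv <- dplyr::bind_rows(cv_rows)
  best <- cv[which.max(cv$cv_balanced_accuracy), ]
  std <- fit_standardizer(features)
  X <- as.matrix(apply_standardizer(features, std)[cols])
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(vocab),
                  eta = best$eta, max_depth = best$max_depth,
                  lambda = best$lambda, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = best$nrounds, verbose = 0))
  structure(list(booster = booster, standardizer = std, vocabulary = vocab,
                 cv = cv, best = best, columns = cols),
            class = "har_gbt")
}

#' Predict with the GBT baseline
#' @param object A `har_gbt`.
#' @param features A feature tibble.
#' @param ... Unused.
#' @return A tibble of class probabilities plus `.pred_class`.
#' @export
predict.har_gbt <- function(object, features, ...) {
  X <- as.matrix(apply_standardizer(features, object$standardizer)[object$columns])
  p <- predict(object$booster, xgboost::xgb.DMatrix(X))
  if (!is.matrix(p)) {
    p <- matrix(p, ncol = length(object$vocabulary), byrow = TRUE)
  }
  out <- as_tibble(setNames(as.data.frame(p),
                            paste0(".pred_", object$vocabulary)))
  out$.pred_class <- object$vocabulary[max.col(p, ties.method = "first")]
  if ("activity" %in% names(features)) {
    out <- dplyr::bind_cols(features[c("subject", "activity")], out)
  }
  out
}
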