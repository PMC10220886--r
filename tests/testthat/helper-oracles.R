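# Independent reference implementations used as oracles. These deliberately
# use naive scalar loops and a different algorithmic organisation from the
# package code.

# Overlap correction oracle: repeatedly find the earliest-starting pair of
# overlapping intervals and apply the interval-correction rules (excise the
# shared range from a partially overlapping pair; truncate the encloser and
# delete the nested interval; delete both members of an identical-span or
# shared-start pair), until no overlap remains.
oracle_correct <- function(iv) {
  iv <- iv[order(iv$start_s, iv$end_s), , drop = FALSE]
  repeat {
    iv <- iv[iv$end_s - iv$start_s > 1e-12, , drop = FALSE]
    iv <- iv[order(iv$start_s, iv$end_s), , drop = FALSE]
    hit <- NULL
    if (nrow(iv) >= 2) {
      for (i in seq_len(nrow(iv) - 1)) {
        if (iv$start_s[i + 1] < iv$end_s[i] - 1e-12) { hit <- i; break }
      }
    }
    if (is.null(hit)) return(iv)
    a <- iv[hit, ]; b <- iv[hit + 1, ]
    if (abs(a$start_s - b$start_s) < 1e-12) {
      iv <- iv[-c(hit, hit + 1), , drop = FALSE]        # shared start: both go
    } else if (b$end_s <= a$end_s + 1e-12) {            # nested
      iv$end_s[hit] <- b$start_s
      iv <- iv[-(hit + 1), , drop = FALSE]
    } else {                                            # partial
      ae <- a$end_s; bs <- b$start_s
      iv$end_s[hit] <- bs
      iv$start_s[hit + 1] <- ae
    }
  }
}

# Per-second labeling of integer-coordinate intervals over [0, horizon).
per_second_labels <- function(iv, horizon) {
  lab <- rep(NA_character_, horizon)
  for (i in seq_len(nrow(iv))) {
    s <- max(0L, ceiling(iv$start_s[i])); e <- min(horizon, floor(iv$end_s[i]))
    if (e > s) lab[(s + 1):e] <- iv$activity[i]
  }
  lab
}

random_timeline <- function(n_max = 12, horizon = 400) {
  n <- sample(2:n_max, 1)
  start <- sort(sample(0:(horizon - 10), n))
  len <- sample(5:80, n, replace = TRUE)
  tibble::tibble(start_s = as.numeric(start),
                 end_s = pmin(as.numeric(start + len), horizon),
                 activity = sample(c("walk", "sit", "run"), n, replace = TRUE))
}

# Scalar-loop metric oracle.
oracle_metrics <- function(truth, probs, vocab, strict = FALSE) {
  C <- length(vocab); N <- length(truth)
  pred <- vocab[apply(probs, 1, function(r) which(r == max(r))[1])]
  cm <- matrix(0, C, C)
  for (i in seq_len(N)) {
    cm[match(truth[i], vocab), match(pred[i], vocab)] <-
      cm[match(truth[i], vocab), match(pred[i], vocab)] + 1
  }
  prec <- rec <- f1 <- numeric(C)
  for (c_ in seq_len(C)) {
    tp <- cm[c_, c_]; fp <- sum(cm[, c_]) - tp; fn <- sum(cm[c_, ]) - tp
    prec[c_] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c_] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c_] <- if (prec[c_] + rec[c_] > 0) 2 * prec[c_] * rec[c_] / (prec[c_] + rec[c_]) else 0
  }
  support <- rowSums(cm)
  keep <- if (strict) rep(TRUE, C) else support > 0
  tp_all <- sum(diag(cm))
  gp <- tp_all / max(1, sum(cm)); gr <- tp_all / max(1, sum(cm))
  ll <- 0
  for (i in seq_len(N)) {
    ll <- ll - log(max(probs[i, match(truth[i], vocab)], 1e-15))
  }
  list(ba = mean(rec[keep]), f1_macro = mean(f1[keep]),
       f1_micro = if (gp + gr > 0) 2 * gp * gr / (gp + gr) else 0,
       f1_weighted = if (sum(support) > 0) sum(f1 * support) / sum(support) else 0,
       logloss = ll / N)
}

# Step-by-step classical Gram-Schmidt with explicit projection loops.
oracle_gram_schmidt <- function(B) {
  Q <- matrix(0, nrow(B), ncol(B))
  for (j in seq_len(ncol(B))) {
    v <- B[, j]
    if (j > 1) {
      for (i in seq_len(j - 1)) {
        proj <- (sum(Q[, i] * B[, j]) / sum(Q[, i] * Q[, i])) * Q[, i]
        v <- v - proj
      }
    }
    Q[, j] <- v / sqrt(sum(v * v))
  }
  Q
}

random_probs <- function(n, C) {
  p <- matrix(stats::rexp(n * C), n, C)
  p / rowSums(p)
}
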