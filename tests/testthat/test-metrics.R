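test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "b"), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(2L, 0L, 0L, 1L), 2, 2,
                                   dimnames = list(truth = c("a", "b"),
                                                   estimate = c("a", "b"))))
  cm0 <- confusion_matrix(character(0), character(0), c("a", "b"))
  expect_true(all(unclass(cm0) == 0))
  set.seed(1)
  truth <- sample(letters[1:4], 200, replace = TRUE)
  est <- sample(letters[1:4], 200, replace = TRUE)
  cm2 <- confusion_matrix(truth, est, letters[1:4])
  expect_equal(rowSums(unclass(cm2)), table(factor(truth, letters[1:4])) |>
                 as.vector() |> setNames(letters[1:4]))
  expect_error(confusion_matrix("a", "z", c("a", "b")), "vocabulary")
})

test_that("the worked confusion example gives balanced accuracy 0.7", {
  m <- metrics_from_confusion(matrix(c(8, 4, 2, 6), 2, 2,
                                     dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(m$summary$balanced_accuracy, (0.8 + 0.6) / 2)
})

test_that("perfect predictions score 1 everywhere and near-zero logloss", {
  truth <- rep(c("a", "b"), each = 5)
  probs <- matrix(rep(c(1 - 1e-12, 1e-12, 1e-12, 1 - 1e-12), each = 5), 10, 2)
  colnames(probs) <- c("a", "b")
  m <- har_metrics(truth, probs, c("a", "b"))
  expect_equal(m$summary$balanced_accuracy, 1)
  expect_equal(m$summary$f1_macro, 1)
  expect_equal(m$summary$f1_micro, 1)
  expect_lt(m$summary$logloss, 1e-9)
})

test_that("a half-confident single prediction has logloss ln 2", {
  m <- har_metrics("a", matrix(c(0.5, 0.5), 1, 2,
                               dimnames = list(NULL, c("a", "b"))),
                   c("a", "b"))
  expect_equal(m$summary$logloss, 0.693147, tolerance = 1e-6)
})

test_that("metrics agree with the scalar-loop oracle to 1e-9", {
  set.seed(21)
  vocabs <- list(c("a", "b"), letters[1:3], letters[1:5])
  for (rep in 1:100) {
    vocab <- vocabs[[sample(3, 1)]]
    n <- sample(5:60, 1)
    truth <- sample(vocab, n, replace = TRUE)
    probs <- random_probs(n, length(vocab))
    colnames(probs) <- vocab
    m <- har_metrics(truth, probs, vocab)
    o <- oracle_metrics(truth, probs, vocab)
    expect_equal(m$summary$balanced_accuracy, o$ba, tolerance = 1e-9)
    expect_equal(m$summary$f1_macro, o$f1_macro, tolerance = 1e-9)
    expect_equal(m$summary$f1_micro, o$f1_micro, tolerance = 1e-9)
    expect_equal(m$summary$f1_weighted, o$f1_weighted, tolerance = 1e-9)
    expect_equal(m$summary$logloss, o$logloss, tolerance = 1e-9)
  }
})

test_that("balanced accuracy agrees with an external reference", {
  skip_if_not_installed("caret")
  set.seed(31)
  truth <- factor(sample(letters[1:3], 120, replace = TRUE), letters[1:3])
  est <- factor(sample(letters[1:3], 120, replace = TRUE), letters[1:3])
  cm <- confusion_matrix(as.character(truth), as.character(est), letters[1:3])
  ours <- metrics_from_confusion(cm)$summary$balanced_accuracy
  ref <- caret::confusionMatrix(est, truth)
  expect_equal(ours, mean(ref$byClass[, "Sensitivity"]), tolerance = 1e-9)
})

test_that("F1-micro equals plain accuracy on single-label data", {
  set.seed(4)
  for (rep in 1:20) {
    vocab <- letters[1:4]
    truth <- sample(vocab, 50, replace = TRUE)
    est <- sample(vocab, 50, replace = TRUE)
    m <- metrics_from_confusion(confusion_matrix(truth, est, vocab))
    expect_equal(m$summary$f1_micro, mean(truth == est), tolerance = 1e-12)
  }
})

test_that("logloss ignores classes with zero support and zero mass", {
  set.seed(6)
  truth <- sample(c("a", "b"), 30, replace = TRUE)
  p2 <- random_probs(30, 2); colnames(p2) <- c("a", "b")
  p3 <- cbind(p2, c = 0)
  m2 <- har_metrics(truth, p2, c("a", "b"))
  m3 <- har_metrics(truth, p3, c("a", "b", "c"))
  expect_equal(m3$summary$logloss, m2$summary$logloss, tolerance = 1e-12)
  expect_equal(m3$zero_support_classes, "c")
  # zero-support class excluded from BA by default, included when strict
  m3s <- har_metrics(truth, p3, c("a", "b", "c"), strict_zero_support = TRUE)
  expect_equal(m3$summary$balanced_accuracy,
               mean(m3$per_class$recall[m3$per_class$support > 0]))
  expect_equal(m3s$summary$balanced_accuracy,
               (2 / 3) * m3$summary$balanced_accuracy, tolerance = 1e-12)
})

test_that("gain reports subtract general from personalized and antisymmetrize", {
  set.seed(8)
  truth <- sample(c("a", "b"), 40, replace = TRUE)
  pa <- random_probs(40, 2); colnames(pa) <- c("a", "b")
  pb <- random_probs(40, 2); colnames(pb) <- c("a", "b")
  ma <- har_metrics(truth, pa, c("a", "b"))
  mb <- har_metrics(truth, pb, c("a", "b"))
  expect_equal(gain_report(ma, ma)$delta_balanced_accuracy, 0)
  g1 <- gain_report(ma, mb); g2 <- gain_report(mb, ma)
  expect_equal(unlist(g1), -unlist(g2))
  mc <- har_metrics(truth[1:10], pa[1:10, ], c("a", "b"))
  expect_error(gain_report(ma, mc), "share")
})

test_that("cohort summaries format mean and sd study-style", {
  res <- tibble::tibble(cds = c(1, 1, 2, 2),
                        balanced_accuracy = c(0.7, 0.9, 0.5, 0.7),
                        f1_macro = c(0.6, 0.8, 0.4, 0.6),
                        f1_micro = c(0.7, 0.9, 0.5, 0.7),
                        logloss = c(0.5, 0.3, 0.9, 0.7))
  s <- cohort_summary(res, "cds")
  expect_equal(s$balanced_accuracy[1],
               fmt_mean_sd(0.8, stats::sd(c(0.7, 0.9))))
  expect_equal(nrow(s), 2)
})
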