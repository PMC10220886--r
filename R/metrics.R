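#' Confusion matrix over an activity vocabulary
#'
#' @param truth,estimate Character vectors of true and predicted labels.
#' @param vocabulary Class order of the matrix.
#' @return A `har_confusion`: C x C integer matrix, rows = truth, columns =
#'   prediction.
#' @export
confusion_matrix <- function(truth, estimate, vocabulary = NULL) {
  if (length(truth) != length(estimate)) abort("truth and estimate lengths differ")
  vocabulary <- vocabulary %||% sort(unique(c(truth, estimate)))
  if (!all(c(truth, estimate) %in% vocabulary)) {
    abort("labels outside the vocabulary")
  }
  m <- table(factor(truth, levels = vocabulary),
             factor(estimate, levels = vocabulary))
  m <- matrix(as.integer(m), nrow = length(vocabulary),
              dimnames = list(truth = vocabulary, estimate = vocabulary))
  structure(m, class = c("har_confusion", "matrix"))
}

#' Evaluation metrics for multiclass activity recognition
#'
#' Computes, from labels and predicted probabilities: per-class precision
#' `TP/(TP+FP)` and recall `TP/(TP+FN)`; F1-micro from globally pooled
#' precision/recall; F1-macro (unweighted mean of per-class F1) and
#' F1-weighted (support-weighted mean); balanced accuracy (mean per-class
#' recall); and logloss `-(1/N) sum_i sum_j y_ij log p_ij` with
#' probabilities floored at 1e-15.
#'
#' Hold-out sets legitimately lack some activities, so by default classes
#' with zero true support are excluded from the balanced-accuracy and
#' F1-macro averages (and listed in the result); with `strict_zero_support
#' = TRUE` they contribute a recall/F1 of 0 instead.
#'
#' @param truth Character vector of true labels.
#' @param probs Matrix or data frame of predicted probabilities, one row per
#'   sample, columns in `vocabulary` order (a [predict.har_model()] tibble
#'   is accepted directly).
#' @param vocabulary Class order.
#' @param strict_zero_support Include zero-support classes as zeros.
#' @return A list of class `har_metrics`: `summary` (one-row tibble),
#'   `per_class` tibble, `confusion`, `n`, `vocabulary`,
#'   `zero_support_classes`.
#' @export
har_metrics <- function(truth, probs, vocabulary = NULL,
                        strict_zero_support = FALSE) {
  if (is.data.frame(probs)) {
    pc <- grep("^\\.pred_", names(probs), value = TRUE)
    pc <- setdiff(pc, ".pred_class")
    vocabulary <- vocabulary %||% sub("^\\.pred_", "", pc)
    probs <- as.matrix(probs[paste0(".pred_", vocabulary)])
  }
  vocabulary <- vocabulary %||% colnames(probs) %||% sort(unique(truth))
  if (nrow(probs) != length(truth)) abort("probs rows must match truth length")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) abort("probability rows must sum to 1")
  estimate <- vocabulary[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(truth, estimate, vocabulary)
  met <- metrics_from_confusion(cm, strict_zero_support)
  # logloss
  y_idx <- match(truth, vocabulary)
  p_true <- pmax(probs[cbind(seq_along(truth), y_idx)], 1e-15)
  logloss <- -mean(log(p_true))
  summary <- dplyr::bind_cols(met$summary, tibble(logloss = logloss,
                                                  n = length(truth)))
  structure(list(summary = summary, per_class = met$per_class, confusion = cm,
                 n = length(truth), vocabulary = vocabulary,
                 zero_support_classes = met$zero_support),
            class = "har_metrics")
}

#' Metrics from a confusion matrix alone
#'
#' Everything in [har_metrics()] except logloss, for when only hard
#' predictions are available.
#'
#' @param cm A `har_confusion` (or plain square count matrix).
#' @param strict_zero_support See [har_metrics()].
#' @return A list with `summary` and `per_class` tibbles and `zero_support`.
#' @export
metrics_from_confusion <- function(cm, strict_zero_support = FALSE) {
  cm <- unclass(cm)
  C <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  zero <- support == 0
  keep <- if (strict_zero_support) rep(TRUE, C) else !zero
  gp <- sum(tp) / max(1, sum(tp) + sum(fp))
  gr <- sum(tp) / max(1, sum(tp) + sum(fn))
  f1_micro <- if (gp + gr > 0) 2 * gp * gr / (gp + gr) else 0
  per_class <- tibble(
    class = rownames(cm) %||% as.character(seq_len(C)),
    support = as.numeric(support), precision = prec, recall = rec, f1 = f1,
    zero_support = zero
  )
  summary <- tibble(
    balanced_accuracy = mean(rec[keep]),
    f1_macro = mean(f1[keep]),
    f1_micro = f1_micro,
    f1_weighted = if (sum(support) > 0) sum(f1 * support) / sum(support) else 0
  )
  list(summary = summary, per_class = per_class,
       zero_support = per_class$class[zero])
}

#' Evaluate a model on a window set
#'
#' Convenience wrapper: predict, then score.
#'
#' @param model A `har_model`.
#' @param windows A labeled `har_windows` (e.g. a hold-out set).
#' @param ... Passed to [har_metrics()].
#' @return A `har_metrics`.
#' @export
evaluate_model <- function(model, windows, ...) {
  pred <- predict(model, windows)
  har_metrics(pred$activity, pred, vocabulary = model$vocabulary, ...)
}

#' @export
print.har_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<har_metrics> n=%d  BA=%.3f  F1-macro=%.3f  F1-micro=%.3f  logloss=%.3f\n",
              x$n, s$balanced_accuracy, s$f1_macro, s$f1_micro,
              s$logloss %||% NA))
  if (length(x$zero_support_classes)) {
    cat("  zero-support classes excluded:",
        paste(x$zero_support_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-class metric table
#' @param x A `har_metrics`.
#' @param ... Unused.
#' @return The per-class tibble.
#' @export
tidy.har_metrics <- function(x, ...) x$per_class

#' One-row metric summary
#' @param x A `har_metrics`.
#' @param ... Unused.
#' @return The summary tibble.
#' @export
glance.har_metrics <- function(x, ...) x$summary

#' Confusion-matrix heatmap
#' @param object A `har_confusion` or `har_metrics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "estimate", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.har_confusion
#' @export
autoplot.har_metrics <- function(object, ...) autoplot(object$confusion, ...)

#' Metric deltas between a general and a personalized evaluation
#'
#' Both reports must come from the same hold-out windows and vocabulary.
#' Deltas are `personalized - general` per metric, so a positive balanced
#' accuracy delta is a personalization gain.
#'
#' @param general,personalized `har_metrics` over the identical hold-out
#'   set.
#' @return A one-row tibble of per-metric deltas.
#' @export
gain_report <- function(general, personalized) {
  if (general$n != personalized$n ||
      !identical(general$vocabulary, personalized$vocabulary)) {
    abort("reports must share the evaluation set and vocabulary")
  }
  g <- general$summary; p <- personalized$summary
  cols <- c("balanced_accuracy", "f1_macro", "f1_micro", "f1_weighted", "logloss")
  as_tibble(as.list(setNames(unlist(p[cols]) - unlist(g[cols]),
                             paste0("delta_", cols))))
}

#' Summarize metric tables across participants
#'
#' Formats cohort results the conventional cohort-table layout: mean +/- sd per
#' group.
#'
#' @param results A tibble with a grouping column and metric columns.
#' @param group Name of the grouping column (e.g. `"cds"` or `"fraction"`).
#' @param metrics Metric columns to summarize.
#' @return A tibble with `mean_*`, `sd_*` and formatted `"mean±sd"` columns.
#' @export
cohort_summary <- function(results, group,
                           metrics = c("balanced_accuracy", "f1_macro",
                                       "f1_micro", "logloss")) {
  metrics <- intersect(metrics, names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics),
                                   list(mean = ~mean(.x), sd = ~stats::sd(.x))),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_sd"),
                                ~dplyr::coalesce(.x, 0))) |>
    (\(d) {
      for (m in metrics) {
        d[[m]] <- fmt_mean_sd(d[[paste0(m, "_mean")]], d[[paste0(m, "_sd")]])
      }
      d
    })()
}
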