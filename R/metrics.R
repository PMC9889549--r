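# Evaluation metrics for K-class risk prediction: sensitivity, accuracy,
# specificity and AUROC, with macro one-vs-rest averaging for the
# class-wise metrics (the only convention that defines all four for K > 2)
# and fold-wise mean +/- std aggregation.

#' Confusion matrix of K-class predictions
#' @param labels,predicted Integer vectors in `[0, K)`.
#' @param K Number of classes.
#' @return `K x K` integer matrix; entry `(true, pred)` counts samples.
#' @export
confusion_matrix <- function(labels, predicted, K) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  if (any(labels < 0L | labels >= K) || any(predicted < 0L | predicted >= K)) {
    stop("labels and predictions must lie in [0, ", K, ")", call. = FALSE)
  }
  cm <- matrix(0L, K, K, dimnames = list(true = seq_len(K) - 1L,
                                         pred = seq_len(K) - 1L))
  for (i in seq_along(labels)) {
    cm[labels[i] + 1L, predicted[i] + 1L] <- cm[labels[i] + 1L,
                                                predicted[i] + 1L] + 1L
  }
  cm
}

# macro one-vs-rest AUROC by the rank-sum (Mann-Whitney) formulation with
# midrank tie handling; classes absent from the labels are skipped
auroc_macro <- function(labels, scores) {
  K <- ncol(scores)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(scores[, k])   # midranks
    aucs[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (anyNA(aucs)) {
    warning("class absent from labels; excluded from macro AUROC",
            call. = FALSE)
  }
  mean(aucs, na.rm = TRUE)
}

#' Multiclass classification metrics
#'
#' Sensitivity is the macro-averaged one-vs-rest recall, specificity the
#' macro-averaged one-vs-rest true-negative rate, accuracy the trace of the
#' confusion matrix over n, and AUROC the macro one-vs-rest area computed
#' by the rank-sum formulation with midranks.
#'
#' @param confusion `K x K` confusion matrix from [confusion_matrix()].
#' @param scores Optional `n x K` matrix of per-class probabilities
#'   (required for AUROC).
#' @param labels Integer labels matching `scores` rows.
#' @return One-row tibble with `sensitivity`, `accuracy`, `specificity`,
#'   `auroc` (AUROC is `NA` without scores).
#' @export
multiclass_metrics <- function(confusion, scores = NULL, labels = NULL) {
  K <- nrow(confusion)
  n <- sum(confusion)
  sens <- spec <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn > 0) sens[k] <- tp / (tp + fn)
    if (tn + fp > 0) spec[k] <- tn / (tn + fp)
  }
  if (anyNA(sens)) {
    warning("class absent from labels; excluded from macro sensitivity",
            call. = FALSE)
  }
  auroc <- if (!is.null(scores) && !is.null(labels)) {
    auroc_macro(labels, scores)
  } else NA_real_
  tibble::tibble(
    sensitivity = mean(sens, na.rm = TRUE),
    accuracy = sum(diag(confusion)) / n,
    specificity = mean(spec, na.rm = TRUE),
    auroc = auroc
  )
}

#' Aggregate per-fold metrics into mean +/- std
#'
#' @param fold_metrics Tibble with one row per fold and one column per
#'   metric (a `fold` column, if present, is ignored).
#' @return A `metrics_report` tibble with columns `metric`, `mean`, `sd`
#'   (population standard deviation over folds).
#' @export
aggregate_folds <- function(fold_metrics) {
  m <- dplyr::select(fold_metrics, -dplyr::any_of("fold"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- tibble::tibble(
    metric = names(m),
    mean = vapply(m, mean, numeric(1)),
    sd = vapply(m, pop_sd, numeric(1))
  )
  structure(out, class = c("metrics_report", class(out)))
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Cross-validated metrics (mean ± std over folds):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %.*f ± %.*f\n", x$metric[i], digits,
                x$mean[i], digits, x$sd[i]))
  }
  invisible(x)
}

# convenience: evaluate a fitted model on a held-out dataset
evaluate_fold <- function(model, dataset) {
  preds <- predict.risk_model(model, dataset)
  K <- model$cfg$K
  scores <- as.matrix(preds[, paste0(".pred_", seq_len(K) - 1L)])
  cm <- confusion_matrix(dataset$label, preds$.pred_class, K)
  multiclass_metrics(cm, scores = scores, labels = dataset$label)
}
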