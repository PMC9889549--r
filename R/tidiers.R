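# Broom-style tidiers, print methods and ggplot2 autoplot methods for the
# fitted-model and experiment-result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted risk model
#'
#' One row per parameter tensor with its size and L2 norm; a compact view
#' of where the model's capacity sits.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `n_values`, `l2_norm`.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    n_values = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' One-row summary of a fitted risk model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    variant = x$cfg$variant,
    n_classes = x$cfg$K,
    channels = x$cfg$C,
    n_heads = x$cfg$n_heads,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    n_iterations = nrow(x$trace),
    final_loss = if (nrow(x$trace)) x$trace$loss[nrow(x$trace)] else NA_real_,
    trained = isTRUE(x$trained)
  )
}

#' @export
print.risk_model <- function(x, ...) {
  g <- glance.risk_model(x)
  cat(sprintf(
    "<risk_model> %s fusion, K = %d, C = %d, %d heads, %d parameters\n",
    g$variant, g$n_classes, g$channels, g$n_heads, g$n_parameters))
  flags <- x$cfg$flags
  on <- names(flags)[vapply(flags, isTRUE, logical(1))]
  cat("  attention blocks:",
      if (length(on)) paste(on, collapse = " + ") else "none", "\n")
  if (g$trained) {
    cat(sprintf("  trained %d iterations, final loss %.4f\n",
                g$n_iterations, g$final_loss))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' Plot the training loss and learning-rate schedule
#' @param object A trained `risk_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_model <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("loss", "lr"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "optimizer step", y = NULL,
                  title = "Training trace") +
    ggplot2::theme_minimal()
}

#' @export
tidy.cv_result <- function(x, ...) {
  tidyr::pivot_longer(x$folds, -"fold", names_to = "metric",
                      values_to = "value")
}

#' @export
glance.cv_result <- function(x, ...) {
  wide <- stats::setNames(
    c(x$report$mean, x$report$sd),
    c(paste0(x$report$metric, "_mean"), paste0(x$report$metric, "_sd"))
  )
  tibble::as_tibble_row(wide)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold cross-validation (%s fusion)\n",
              max(x$folds$fold), x$config$fusion_variant))
  print(x$report)
  invisible(x)
}

#' Plot per-fold metrics of a cross-validation run
#' @param object A `cv_result`.
#' @param ... Unused.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidy.cv_result(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "value", colour = "fold",
                  title = "Cross-validated metrics") +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#' @param object An `ablation_result` from [run_ablation()].
#' @param metric Metric to display (default accuracy).
#' @param ... Unused.
#' @export
autoplot.ablation_result <- function(object, metric = "accuracy", ...) {
  df <- tibble::as_tibble(object)
  df$setting <- apply(df[, c("SAM", "TAM", "CAM")], 1, function(r) {
    on <- c("SAM", "TAM", "CAM")[as.logical(r)]
    if (length(on)) paste(on, collapse = "+") else "baseline"
  })
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$setting,
                                                      .data[[mcol]]),
                                   y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste(metric, "(mean ± std over folds)"),
                  title = "Attention-component ablation") +
    ggplot2::theme_minimal()
}

#' Plot a head-count sweep
#' @param object A `head_sweep_result` from [head_sweep()].
#' @param ... Unused.
#' @export
autoplot.head_sweep_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$skipped)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_heads,
                                   y = .data$accuracy_mean)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy_mean - .data$accuracy_sd,
      ymax = .data$accuracy_mean + .data$accuracy_sd)) +
    ggplot2::labs(x = "decoder heads", y = "accuracy (mean ± std)",
                  title = "Multi-head attention head-number sweep") +
    ggplot2::theme_minimal()
}

#' Plot a fusion-strategy comparison
#' @param object A `fusion_comparison` from [compare_fusion_variants()].
#' @param metric Metric to display.
#' @param ... Unused.
#' @export
autoplot.fusion_comparison <- function(object, metric = "accuracy", ...) {
  df <- tibble::as_tibble(object)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variant,
                                                      .data[[mcol]]),
                                   y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste(metric, "(mean ± std over folds)"),
                  title = "Fusion strategies") +
    ggplot2::theme_minimal()
}
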