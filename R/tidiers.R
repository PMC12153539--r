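#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar labs theme_minimal annotation_raster coord_fixed
#'   theme_void scale_colour_manual xlim ylim
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted ABMIL model
#'
#' @param x an `abmil_model`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`.
#' @export
tidy.abmil_model <- function(x, ...) {
  x$history
}

#' One-row fit summary of an ABMIL model
#'
#' @param x an `abmil_model`.
#' @param ... unused.
#' @return tibble with `epochs_trained`, `best_epoch`, `best_val_loss`,
#'   `final_train_loss`, `feature_dim`, `h1`, `h2`.
#' @export
glance.abmil_model <- function(x, ...) {
  tibble::tibble(
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = if (nrow(x$history)) dplyr::last(x$history$train_loss)
                       else NA_real_,
    feature_dim = x$params$feature_dim,
    h1 = x$params$hidden[1], h2 = x$params$hidden[2])
}

#' Training and validation loss curves
#'
#' @param object an `abmil_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.abmil_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    scale_colour_manual(values = c(train_loss = "grey40", val_loss = "#B2182B"),
                        labels = c("training", "validation"), name = NULL) +
    labs(x = "epoch", y = "class-weighted cross-entropy") +
    theme_minimal()
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return the summary tibble: `metric`, `estimate` and, when a bootstrap
#'   was run, `boot_mean`, `ci_low`, `ci_high`.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$summary
}

#' Headline metrics of a report as one row
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble with `n`, `accuracy`, `balanced_accuracy`, `auroc`,
#'   `f1_metastatic`.
#' @export
glance.metrics_report <- function(x, ...) {
  est <- setNames(x$summary$estimate, x$summary$metric)
  tibble::tibble(n = x$n,
                 accuracy = est[["accuracy"]],
                 balanced_accuracy = est[["balanced_accuracy"]],
                 auroc = est[["auroc"]],
                 f1_metastatic = est[["f1_metastatic"]])
}

#' Point estimates with bootstrap CIs, plotted
#'
#' @param object a `metrics_report` with a bootstrap.
#' @param metrics which metrics to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metrics_report <- function(object,
                                    metrics = c("accuracy",
                                                "balanced_accuracy", "auroc",
                                                "f1_metastatic"), ...) {
  df <- dplyr::filter(object$summary, .data$metric %in% metrics)
  p <- ggplot(df, aes(x = .data$metric, y = .data$estimate)) +
    geom_point(size = 2) +
    labs(x = NULL, y = "estimate") + ylim(0, 1) + theme_minimal()
  if ("ci_low" %in% names(df)) {
    p <- p + geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.15)
  }
  p
}

#' Tidy pooled out-of-fold predictions of a cross-validation run
#'
#' @param x a `wsimil_cv`.
#' @param ... unused.
#' @return the out-of-fold prediction tibble.
#' @export
tidy.wsimil_cv <- function(x, ...) {
  x$predictions
}

#' Headline cross-validation metrics
#'
#' @param x a `wsimil_cv`.
#' @param ... unused.
#' @return one-row tibble (see [glance.metrics_report()]).
#' @export
glance.wsimil_cv <- function(x, ...) {
  glance(x$report)
}

#' Plot an attention heatmap overlay
#'
#' @param object a `heatmap_overlay`.
#' @param ... unused.
#' @return a ggplot drawing the composited overlay at native aspect ratio.
#' @export
autoplot.heatmap_overlay <- function(object, ...) {
  h <- nrow(object$raster); w <- ncol(object$raster)
  ggplot() +
    annotation_raster(object$overlay, xmin = 0, xmax = w,
                      ymin = 0, ymax = h) +
    xlim(0, w) + ylim(0, h) + coord_fixed() + theme_void()
}
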