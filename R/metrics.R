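#' Confusion counts for a two-class slide classification
#'
#' @param y_true,y_pred character/factor vectors with values in
#'   `{benign, metastatic}`, equal length.
#' @return 2x2 integer matrix, rows = truth, columns = prediction.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  if (length(y_true) == 0) abort("empty input")
  m <- matrix(0L, 2, 2, dimnames = list(truth = CLASS_LEVELS,
                                        prediction = CLASS_LEVELS))
  for (tr in CLASS_LEVELS) for (pr in CLASS_LEVELS) {
    m[tr, pr] <- sum(y_true == tr & y_pred == pr)
  }
  m
}

counts_from_matrix <- function(counts, positive_class) {
  neg <- setdiff(CLASS_LEVELS, positive_class)
  list(TP = counts[positive_class, positive_class],
       FN = counts[positive_class, neg],
       FP = counts[neg, positive_class],
       TN = counts[neg, neg])
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class precision, sensitivity, specificity and F1
#'
#' `precision = TP/(TP+FP)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, and F1 is the harmonic mean of precision and
#' sensitivity. Undefined ratios (0/0) are reported as `NA`, never silently
#' as 0.
#'
#' @param counts 2x2 matrix from [confusion_counts()].
#' @param positive_class which class plays the positive role.
#' @return tibble with one row: `positive_class`, `precision`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
class_metrics <- function(counts, positive_class = "metastatic") {
  positive_class <- match.arg(positive_class, CLASS_LEVELS)
  k <- counts_from_matrix(counts, positive_class)
  precision <- safe_div(k$TP, k$TP + k$FP)
  sensitivity <- safe_div(k$TP, k$TP + k$FN)
  specificity <- safe_div(k$TN, k$TN + k$FP)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  tibble::tibble(positive_class = positive_class, precision = precision,
                 sensitivity = sensitivity, specificity = specificity,
                 f1 = f1)
}

#' Accuracy and balanced accuracy from confusion counts
#'
#' Balanced accuracy is the mean of the two per-class recalls, robust to
#' class imbalance.
#'
#' @param counts 2x2 matrix from [confusion_counts()].
#' @return tibble with `accuracy` and `balanced_accuracy`.
#' @export
accuracy_metrics <- function(counts) {
  total <- sum(counts)
  if (total == 0) abort("empty confusion matrix")
  acc <- sum(diag(counts)) / total
  rec <- vapply(CLASS_LEVELS, function(cl) {
    safe_div(counts[cl, cl], sum(counts[cl, ]))
  }, numeric(1))
  tibble::tibble(accuracy = acc, balanced_accuracy = mean(rec))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen metastatic slide receives a
#' higher score than a randomly chosen benign slide, with ties counted as
#' half. Computed from midranks, which is exactly the normalised
#' Mann-Whitney U statistic.
#'
#' @param y_true labels in `{benign, metastatic}`.
#' @param score_metastatic numeric scores (higher = more metastatic).
#' @return AUROC in \[0, 1\], or `NA` if either class is absent.
#' @export
auroc <- function(y_true, score_metastatic) {
  y_true <- check_labels(y_true, "y_true")
  if (length(y_true) != length(score_metastatic)) abort("lengths differ")
  pos <- y_true == "metastatic"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score_metastatic)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile mean and 95% CI for a classification metric
#'
#' Resamples slides with replacement `B` times, recomputes the metric on
#' each replicate, and returns the replicate mean with the 2.5 and 97.5
#' percentiles. Deterministic for a fixed seed. When
#' `needs_both_classes = TRUE`, replicates containing a single class are
#' redrawn (up to 100 attempts) so rank-based metrics stay defined at
#' small n. Errors if the metric is undefined on more than half of the
#' replicates.
#'
#' @param metric_fn function `(y_true, predictions) -> scalar`.
#' @param y_true label vector.
#' @param predictions vector (scores or predicted labels) aligned with
#'   `y_true`, resampled jointly with it.
#' @param B number of bootstrap iterations (>= 1); 10,000 by default.
#' @param seed integer seed.
#' @param needs_both_classes redraw single-class replicates?
#' @return tibble with `boot_mean`, `ci_low`, `ci_high`, `n_bootstrap`.
#' @export
bootstrap_ci <- function(metric_fn, y_true, predictions, B = 10000L,
                         seed = 1L, needs_both_classes = FALSE) {
  if (B < 1) abort("B must be >= 1")
  n <- length(y_true)
  if (length(predictions) != n) abort("predictions must align with y_true")
  y_true <- as.character(y_true)
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (needs_both_classes) {
        tries <- 0L
        while (length(unique(y_true[idx])) < 2 && tries < 100L) {
          idx <- sample.int(n, n, replace = TRUE)
          tries <- tries + 1L
        }
      }
      as.numeric(metric_fn(y_true[idx], predictions[idx]))
    }, numeric(1))
  })
  if (mean(is.na(vals)) > 0.5) {
    abort("metric undefined on more than 50% of bootstrap replicates")
  }
  q <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble::tibble(boot_mean = mean(vals, na.rm = TRUE),
                 ci_low = q[1], ci_high = q[2], n_bootstrap = as.integer(B))
}

# fast internal metric evaluation for the pooled bootstrap in metrics_report
metric_values <- function(ypos, ppos, score) {
  tp <- sum(ypos & ppos); fn <- sum(ypos & !ppos)
  fp <- sum(!ypos & ppos); tn <- sum(!ypos & !ppos)
  acc <- (tp + tn) / length(ypos)
  sens <- safe_div(tp, tp + fn)       # metastatic recall
  spec <- safe_div(tn, tn + fp)       # benign recall
  bal <- mean(c(sens, spec))
  prec_m <- safe_div(tp, tp + fp)
  prec_b <- safe_div(tn, tn + fn)
  f1 <- function(p, s) {
    if (is.na(p) || is.na(s) || (p + s) == 0) NA_real_ else 2 * p * s / (p + s)
  }
  f1_m <- f1(prec_m, sens)
  f1_b <- f1(prec_b, spec)
  n1 <- sum(ypos); n0 <- sum(!ypos)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(score)
    (sum(r[ypos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(accuracy = acc, balanced_accuracy = bal, auroc = auc,
    f1_metastatic = f1_m, f1_benign = f1_b,
    f1_macro = mean(c(f1_m, f1_b)),
    precision_metastatic = prec_m, sensitivity_metastatic = sens,
    specificity_metastatic = spec,
    precision_benign = prec_b, sensitivity_benign = spec,
    specificity_benign = sens)
}

#' Full metrics report with bootstrap confidence intervals
#'
#' Point estimates plus bootstrap mean and 95% percentile CI (default
#' 10,000 iterations) for accuracy, balanced accuracy, AUROC, F1
#' (metastatic-class and macro) and per-class precision / sensitivity /
#' specificity. The bootstrap resamples slides with replacement; one joint
#' index draw per replicate serves all metrics, and replicates containing a
#' single class are redrawn (up to 100 attempts) so the rank-based metrics
#' stay defined.
#'
#' @param y_true labels in `{benign, metastatic}`.
#' @param prob_metastatic predicted probability of the metastatic class.
#' @param y_pred predicted labels; defaults to the argmax rule
#'   (`prob_metastatic > 0.5` metastatic).
#' @param n_bootstrap bootstrap iterations; `0` skips the bootstrap.
#' @param seed bootstrap seed.
#' @return An object of class `metrics_report`: list with `counts` (2x2),
#'   `summary` (tibble: metric, estimate, boot_mean, ci_low, ci_high),
#'   `n`, `n_bootstrap`, `seed`.
#' @export
metrics_report <- function(y_true, prob_metastatic, y_pred = NULL,
                           n_bootstrap = 10000L, seed = 1L) {
  y_true <- check_labels(y_true, "y_true")
  n <- length(y_true)
  if (length(prob_metastatic) != n) abort("prob_metastatic must align with y_true")
  if (is.null(y_pred)) {
    y_pred <- ifelse(prob_metastatic > 0.5, "metastatic", "benign")
  }
  y_pred <- check_labels(y_pred, "y_pred")
  ypos <- y_true == "metastatic"
  ppos <- y_pred == "metastatic"
  point <- metric_values(ypos, ppos, prob_metastatic)

  boot <- NULL
  if (n_bootstrap > 0) {
    reps <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tries <- 0L
        while (length(unique(ypos[idx])) < 2 && tries < 100L) {
          idx <- sample.int(n, n, replace = TRUE)
          tries <- tries + 1L
        }
        metric_values(ypos[idx], ppos[idx], prob_metastatic[idx])
      }, point)
    })
    safe_q <- function(v, p) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else quantile(v, p, names = FALSE)
    }
    boot <- tibble::tibble(
      metric = names(point),
      boot_mean = unname(rowMeans(reps, na.rm = TRUE)),
      ci_low = unname(apply(reps, 1, safe_q, p = 0.025)),
      ci_high = unname(apply(reps, 1, safe_q, p = 0.975)))
  }
  summary <- tibble::tibble(metric = names(point), estimate = unname(point))
  if (!is.null(boot)) summary <- dplyr::left_join(summary, boot, by = "metric")
  structure(
    list(counts = confusion_counts(y_true, y_pred), summary = summary,
         n = n, n_bootstrap = as.integer(n_bootstrap),
         seed = as.integer(seed)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d slides, %d bootstrap iterations\n",
              x$n, x$n_bootstrap))
  print(x$counts)
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}
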