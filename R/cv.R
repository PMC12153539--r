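#' Case-level stratified five-fold cross-validation splits
#'
#' Partitions cases (patients) — never individual slides — into k folds,
#' stratified by case label, and derives a 60-20-20
#' training-validation-testing split per fold: fold `f` tests the cases of
#' fold `f`, validates on fold `f %% k + 1`, and trains on the remaining
#' `k - 2` folds. Every case is tested exactly once across the k folds, the
#' three roles are disjoint within each fold, and per-class counts in each
#' role are within one case of the stratified ideal. All slides of a case
#' follow it, which is what prevents leakage between roles.
#'
#' @param manifest tibble with at least `slide_id`, `case_id`, `label`.
#'   A case's label is metastatic if any of its slides is metastatic.
#' @param k number of folds (default 5, giving 60-20-20).
#' @param seed shuffle seed.
#' @return tibble with columns `fold`, `case_id`, `role`
#'   (`train`/`validation`/`test`), one row per case per fold.
#' @export
make_case_folds <- function(manifest, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 3) abort("k must be >= 3 so that train/validation/test are disjoint")
  cases <- manifest |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(label = if (any(.data$label == "metastatic"))
      "metastatic" else "benign", .groups = "drop")
  for (cl in CLASS_LEVELS) {
    if (sum(cases$label == cl) < k) {
      abort(sprintf("need at least %d '%s' cases for %d folds", k, cl, k))
    }
  }
  assignment <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(CLASS_LEVELS, function(cl) {
      ids <- sample(cases$case_id[cases$label == cl])
      tibble::tibble(case_id = ids,
                     fold_home = rep_len(seq_len(k), length(ids)))
    })
  })
  purrr::map_dfr(seq_len(k), function(f) {
    val_fold <- (f %% k) + 1L
    role <- dplyr::case_when(
      assignment$fold_home == f ~ "test",
      assignment$fold_home == val_fold ~ "validation",
      TRUE ~ "train")
    tibble::tibble(fold = f, case_id = assignment$case_id, role = role)
  })
}

# bags for the slides of the given cases, plus aligned labels
slides_of <- function(manifest, case_ids) {
  dplyr::filter(manifest, .data$case_id %in% case_ids)
}

pick_bags <- function(bags, slide_ids) {
  missing <- setdiff(slide_ids, names(bags))
  if (length(missing) > 0) {
    abort(sprintf("no feature bag for slide(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  bags[slide_ids]
}

#' Run case-level stratified cross-validation
#'
#' Trains one ABMIL model per fold on that fold's training cases (early
#' stopping on its validation cases) and predicts its held-out test cases.
#' Pooled out-of-fold predictions — exactly one per slide — are summarised
#' in a [metrics_report()] with bootstrap CIs.
#'
#' @param manifest slide manifest (`slide_id`, `case_id`, `label`, ...).
#' @param bags named list of [feature_bag]s keyed by `slide_id`.
#' @param config a [train_config()]; fold `f` trains with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @param k number of folds.
#' @param hidden hidden sizes passed to [abmil_init()].
#' @param n_bootstrap,seed bootstrap settings for the pooled report.
#' @return An object of class `wsimil_cv`: list with `models` (one
#'   `abmil_model` per fold), `folds`, `predictions` (tibble of out-of-fold
#'   predictions), `report`, `manifest`.
#' @export
run_cross_validation <- function(manifest, bags, config = train_config(),
                                 k = 5L, hidden = NULL,
                                 n_bootstrap = 10000L, seed = 1L) {
  folds <- make_case_folds(manifest, k = k, seed = seed)
  D <- pick_bags(bags, manifest$slide_id[1])[[1]]$feature_dim

  fit_fold <- function(f) {
    fr <- dplyr::filter(folds, .data$fold == f)
    tr <- slides_of(manifest, fr$case_id[fr$role == "train"])
    va <- slides_of(manifest, fr$case_id[fr$role == "validation"])
    te <- slides_of(manifest, fr$case_id[fr$role == "test"])
    cfg <- config
    cfg$seed <- config$seed + f
    model <- abmil_train(abmil_init(D, hidden = hidden, seed = cfg$seed),
                         pick_bags(bags, tr$slide_id), tr$label,
                         pick_bags(bags, va$slide_id), va$label,
                         config = cfg, case_ids = tr$case_id)
    preds <- predict_slides(model, pick_bags(bags, te$slide_id))
    preds$fold <- f
    preds$label <- te$label
    list(model = model, preds = preds)
  }
  fits <- lapply(seq_len(k), fit_fold)
  predictions <- dplyr::bind_rows(lapply(fits, `[[`, "preds"))
  if (nrow(predictions) != nrow(manifest)) {
    abort("out-of-fold predictions do not partition the manifest")
  }
  report <- metrics_report(predictions$label, predictions$prob_metastatic,
                           predictions$pred_label,
                           n_bootstrap = n_bootstrap, seed = seed)
  structure(
    list(models = lapply(fits, `[[`, "model"), folds = folds,
         predictions = predictions, report = report, manifest = manifest),
    class = "wsimil_cv"
  )
}

#' @export
print.wsimil_cv <- function(x, ...) {
  cat(sprintf("<wsimil_cv> %d folds, %d slides / %d cases\n",
              length(x$models), nrow(x$manifest),
              dplyr::n_distinct(x$manifest$case_id)))
  print(x$report)
  invisible(x)
}

#' Ensembled hold-out evaluation
#'
#' Predicts every hold-out slide with the element-wise average of the fold
#' models' probability vectors and reports metrics with bootstrap CIs.
#' Hold-out cases must be disjoint from every training case: any overlap is
#' a hard leakage error, not a warning.
#'
#' @param cv a `wsimil_cv` fit (or a bare list of models plus
#'   `train_manifest`).
#' @param holdout_manifest manifest of hold-out slides.
#' @param bags named list of [feature_bag]s covering the hold-out slides.
#' @param train_manifest manifest the models were trained on; defaults to
#'   the one stored in `cv`.
#' @param n_bootstrap,seed bootstrap settings.
#' @return list of class `wsimil_holdout` with `predictions` and `report`.
#' @export
run_holdout <- function(cv, holdout_manifest, bags, train_manifest = NULL,
                        n_bootstrap = 10000L, seed = 1L) {
  models <- if (inherits(cv, "wsimil_cv")) cv$models else cv
  train_manifest <- train_manifest %||%
    (if (inherits(cv, "wsimil_cv")) cv$manifest else
      abort("train_manifest required when cv is a bare model list"))
  overlap <- intersect(unique(holdout_manifest$case_id),
                       unique(train_manifest$case_id))
  if (length(overlap) > 0) {
    abort(sprintf("data leakage: hold-out case(s) present in training: %s",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  preds <- purrr::map_dfr(seq_len(nrow(holdout_manifest)), function(i) {
    sid <- holdout_manifest$slide_id[i]
    pr <- ensemble_predict(models, pick_bags(bags, sid)[[1]])
    tibble::tibble(slide_id = sid,
                   prob_benign = unname(pr$probs[1]),
                   prob_metastatic = unname(pr$probs[2]),
                   pred_label = pr$predicted_label,
                   label = holdout_manifest$label[i])
  })
  report <- metrics_report(preds$label, preds$prob_metastatic,
                           preds$pred_label, n_bootstrap = n_bootstrap,
                           seed = seed)
  structure(list(predictions = preds, report = report),
            class = "wsimil_holdout")
}

#' @export
print.wsimil_holdout <- function(x, ...) {
  cat(sprintf("<wsimil_holdout> %d slides, ensembled\n", nrow(x$predictions)))
  print(x$report)
  invisible(x)
}
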