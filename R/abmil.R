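#' Gated attention-based multiple-instance learning (ABMIL) classifier
#'
#' The slide classifier at the heart of the package. Each patch feature
#' vector `h_k` is projected (linear + ReLU) into an embedding; a gated
#' attention network — a tanh branch and a sigmoid branch, multiplied
#' elementwise and mapped to a scalar — scores every patch, and a softmax
#' across the bag turns the scores into attention weights in \[0, 1\] that
#' sum to 1. The slide-level feature is the attention-weighted average of
#' the embedded patches, and a fully connected layer with one output node
#' per class followed by a softmax yields the class probabilities; the
#' maximum is taken as the prediction.
#'
#' @name abmil
NULL

default_hidden <- function(feature_dim) {
  h1 <- min(feature_dim, 512L)
  c(h1, if (h1 < 512L) 128L else 256L)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize ABMIL parameters
#'
#' Glorot-uniform weight initialisation, zero biases; deterministic for a
#' fixed seed.
#'
#' @param feature_dim input (patch feature) dimension D.
#' @param hidden integer pair `c(H1, H2)`: embedding and attention hidden
#'   sizes. Defaults to `(512, 256)`, scaled down to `(min(D, 512), 128)`
#'   for small feature dimensions.
#' @param seed integer seed.
#' @return An object of class `abmil_params`.
#' @export
abmil_init <- function(feature_dim, hidden = NULL, seed = 1L) {
  feature_dim <- as.integer(feature_dim)
  hidden <- as.integer(hidden %||% default_hidden(feature_dim))
  if (feature_dim < 1 || any(hidden < 1)) abort("dimensions must be >= 1")
  H1 <- hidden[1]; H2 <- hidden[2]
  withr::with_seed(as.integer(seed), {
    structure(
      list(W1 = glorot(feature_dim, H1), b1 = numeric(H1),
           V = glorot(H1, H2), bv = numeric(H2),
           U = glorot(H1, H2), bu = numeric(H2),
           w = as.vector(glorot(H2, 1L)), bw = 0,
           Wc = glorot(H1, 2L), bc = numeric(2),
           feat_center = numeric(feature_dim), feat_scale = rep(1, feature_dim),
           feature_dim = feature_dim, hidden = c(H1, H2),
           seed = as.integer(seed)),
      class = "abmil_params"
    )
  })
}

#' @export
print.abmil_params <- function(x, ...) {
  cat(sprintf("<abmil_params> D = %d, hidden = (%d, %d), %d parameters\n",
              x$feature_dim, x$hidden[1], x$hidden[2],
              sum(vapply(x[weight_names()], length, 1L)) +
                sum(vapply(x[bias_names()], length, 1L))))
  invisible(x)
}

weight_names <- function() c("W1", "V", "U", "w", "Wc")
bias_names <- function() c("b1", "bv", "bu", "bw", "bc")
param_names <- function() c(weight_names(), bias_names())

check_bag_dim <- function(params, X) {
  if (ncol(X) != params$feature_dim) {
    abort(sprintf("bag feature dimension %d does not match model input %d",
                  ncol(X), params$feature_dim))
  }
}

bag_matrix <- function(bag) {
  if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
}

# standardise instance features with the model's stored constants
scale_features <- function(params, X) {
  check_bag_dim(params, X)
  sweep(sweep(X, 2, params$feat_center), 2, params$feat_scale, "/")
}

# forward pass on already-scaled X; drop_mask (N x H1) scaled by 1/(1-p), or NULL
abmil_forward <- function(params, X, drop_mask = NULL) {
  check_bag_dim(params, X)
  P <- sweep(X %*% params$W1, 2, params$b1, "+")
  H <- pmax(P, 0)
  Ht <- if (is.null(drop_mask)) H else H * drop_mask
  Tt <- sweep(Ht %*% params$V, 2, params$bv, "+")
  At <- tanh(Tt)
  Sg <- sweep(Ht %*% params$U, 2, params$bu, "+")
  As <- 1 / (1 + exp(-Sg))
  G <- At * As
  S <- as.vector(G %*% params$w) + params$bw
  a <- softmax(S)
  z <- as.vector(crossprod(Ht, a))
  logits <- as.vector(crossprod(params$Wc, z)) + params$bc
  p <- softmax(logits)
  list(P = P, H = H, Ht = Ht, At = At, As = As, G = G, S = S, a = a,
       z = z, logits = logits, p = p)
}

# analytic gradients of the class-weighted cross-entropy for one bag
abmil_backward <- function(params, X, fwd, y_idx, class_weight = 1,
                           drop_mask = NULL) {
  dlogits <- fwd$p
  dlogits[y_idx] <- dlogits[y_idx] - 1
  dlogits <- class_weight * dlogits
  dWc <- tcrossprod(fwd$z, dlogits)
  dbc <- dlogits
  dz <- as.vector(params$Wc %*% dlogits)
  da <- as.vector(fwd$Ht %*% dz)
  dHt <- tcrossprod(fwd$a, dz)
  dS <- fwd$a * (da - sum(fwd$a * da))
  dw <- as.vector(crossprod(fwd$G, dS))
  dbw <- sum(dS)
  dG <- tcrossprod(dS, params$w)
  dT <- dG * fwd$As * (1 - fwd$At^2)
  dSg <- dG * fwd$At * fwd$As * (1 - fwd$As)
  dV <- crossprod(fwd$Ht, dT)
  dbv <- colSums(dT)
  dU <- crossprod(fwd$Ht, dSg)
  dbu <- colSums(dSg)
  dHt <- dHt + tcrossprod(dT, params$V) + tcrossprod(dSg, params$U)
  dH <- if (is.null(drop_mask)) dHt else dHt * drop_mask
  dP <- dH * (fwd$P > 0)
  list(W1 = crossprod(X, dP), b1 = colSums(dP),
       V = dV, bv = dbv, U = dU, bu = dbu, w = dw, bw = dbw,
       Wc = dWc, bc = dbc)
}

#' Per-patch attention weights for one bag
#'
#' Raw gated-attention scores are normalised across the bag with a softmax,
#' so weights lie in \[0, 1\] and sum to 1; permuting the bag permutes the
#' weights identically.
#'
#' @param params `abmil_params` (or a fitted `abmil_model`).
#' @param bag a [feature_bag] or `N x D` matrix.
#' @return numeric vector of length N.
#' @export
attention_weights <- function(params, bag) {
  params <- as_abmil_params(params)
  abmil_forward(params, scale_features(params, bag_matrix(bag)))$a
}

#' Attention-weighted slide-level feature
#'
#' The weighted sum of the embedded (projected) patch features under the
#' given attention weights: uniform weights reduce it to the arithmetic
#' mean of the embeddings, a one-hot weight vector selects one patch.
#'
#' @inheritParams attention_weights
#' @param weights numeric vector of length N.
#' @return numeric vector of length H1.
#' @export
abmil_aggregate <- function(params, weights, bag) {
  params <- as_abmil_params(params)
  X <- scale_features(params, bag_matrix(bag))
  if (length(weights) != nrow(X)) abort("weights length must equal bag size")
  H <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  as.vector(crossprod(H, weights))
}

#' Class probabilities from a slide-level feature
#'
#' Softmax over the two class logits; invariant to adding a constant to
#' both logits.
#'
#' @inheritParams attention_weights
#' @param slide_feature numeric vector of length H1.
#' @return named probability vector `(benign, metastatic)`.
#' @export
abmil_classify <- function(params, slide_feature) {
  params <- as_abmil_params(params)
  if (!all(is.finite(slide_feature))) abort("slide feature must be finite")
  logits <- as.vector(crossprod(params$Wc, slide_feature)) + params$bc
  setNames(softmax(logits), CLASS_LEVELS)
}

as_abmil_params <- function(x) {
  if (inherits(x, "abmil_model")) x$params
  else if (inherits(x, "abmil_params")) x
  else abort("expected abmil_params or a fitted abmil_model")
}

#' Predict one slide from its feature bag
#'
#' Composition of attention scoring, attention-weighted aggregation and
#' classification, in evaluation mode (dropout off), so the output is a
#' deterministic, permutation-invariant function of the bag.
#'
#' @inheritParams attention_weights
#' @return An object of class `slide_prediction`: list with `slide_id`,
#'   `probs` (named, sums to 1), `predicted_label`, and `attention`
#'   (length-N, sums to 1).
#' @export
predict_slide <- function(params, bag) {
  params <- as_abmil_params(params)
  fwd <- abmil_forward(params, scale_features(params, bag_matrix(bag)))
  probs <- setNames(fwd$p, CLASS_LEVELS)
  structure(
    list(slide_id = if (inherits(bag, "feature_bag")) bag$slide_id else NULL,
         probs = probs,
         predicted_label = CLASS_LEVELS[which.max(probs)],
         attention = fwd$a),
    class = "slide_prediction"
  )
}

#' @export
print.slide_prediction <- function(x, ...) {
  cat(sprintf("<slide_prediction> %s  P(benign) = %.3f  P(metastatic) = %.3f  -> %s\n",
              x$slide_id %||% "(unnamed)", x$probs[1], x$probs[2],
              x$predicted_label))
  invisible(x)
}

#' Predict many slides into a tidy table
#'
#' @inheritParams attention_weights
#' @param bags named list of [feature_bag]s.
#' @return tibble with columns `slide_id`, `prob_benign`,
#'   `prob_metastatic`, `pred_label`.
#' @export
predict_slides <- function(params, bags) {
  purrr::map_dfr(bags, function(b) {
    pr <- predict_slide(params, b)
    tibble::tibble(slide_id = pr$slide_id %||% NA_character_,
                   prob_benign = unname(pr$probs[1]),
                   prob_metastatic = unname(pr$probs[2]),
                   pred_label = pr$predicted_label)
  })
}

#' Training configuration for the ABMIL classifier
#'
#' Dropout, weight decay and early stopping are the three regularisers used
#' during training. Optimisation is adaptive-moment gradient descent (Adam)
#' on the class-weighted cross-entropy, one bag per step.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient applied to weight matrices (not
#'   biases).
#' @param dropout dropout rate on the embedded patch features during
#'   training.
#' @param max_epochs maximum number of passes over the training bags.
#' @param patience epochs without validation-loss improvement tolerated
#'   after `min_epochs` before stopping.
#' @param min_epochs minimum number of epochs before early stopping may
#'   trigger.
#' @param class_weights `"inverse_frequency"` (default) weights each class
#'   by `n_total / (n_classes * n_class)`; `"none"` disables weighting.
#' @param seed seed governing shuffling, dropout and any other training
#'   randomness; identical seed + data gives identical parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-3, weight_decay = 1e-5,
                         dropout = 0.25, max_epochs = 200L, patience = 20L,
                         min_epochs = 50L,
                         class_weights = c("inverse_frequency", "none"),
                         seed = 1L) {
  if (learning_rate <= 0 || weight_decay < 0) abort("invalid optimiser settings")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         dropout = dropout, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), min_epochs = as.integer(min_epochs),
         class_weights = match.arg(class_weights), seed = as.integer(seed)),
    class = "train_config"
  )
}

compute_class_weights <- function(labels, scheme) {
  labels <- check_labels(labels)
  n <- length(labels)
  cw <- setNames(rep(1, 2), CLASS_LEVELS)
  if (scheme == "inverse_frequency") {
    for (cl in CLASS_LEVELS) cw[cl] <- n / (2 * sum(labels == cl))
  }
  cw
}

adam_state <- function(params) {
  st <- lapply(params[param_names()], function(p) {
    list(m = p * 0, v = p * 0)
  })
  st
}

adam_step <- function(params, grads, state, t, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in param_names()) {
    g <- grads[[nm]]
    if (wd > 0 && nm %in% weight_names()) g <- g + wd * params[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# mean class-weighted cross-entropy over pre-scaled bag matrices, eval mode
weighted_ce_loss <- function(params, Xs, y_idx, cw_vec) {
  losses <- purrr::map2_dbl(Xs, y_idx, function(X, y) {
    p <- abmil_forward(params, X)$p
    -cw_vec[y] * log(max(p[y], 1e-12))
  })
  mean(losses)
}

#' Train an ABMIL classifier
#'
#' Minimises the class-weighted cross-entropy by Adam, one bag per
#' optimisation step, with dropout on the embedded patch features and L2
#' weight decay. Instance features are standardised per dimension with
#' constants fitted on the pooled training instances and stored with the
#' parameters, so downstream prediction is self-contained. After each epoch
#' the validation loss is evaluated in evaluation mode; training stops once
#' it has not improved for `patience` epochs after `min_epochs`, and the
#' parameters of the best validation epoch are returned. Fully reproducible
#' given `config$seed`.
#'
#' @param params initial `abmil_params` (see [abmil_init()]).
#' @param bags list of training [feature_bag]s.
#' @param labels character/factor labels aligned with `bags`, values in
#'   `{benign, metastatic}`; both classes must be present.
#' @param val_bags,val_labels validation set (same requirements).
#' @param config a [train_config()].
#' @param case_ids optional case identifiers aligned with `bags`, recorded
#'   for provenance (splitting happens upstream, at the case level).
#' @return An object of class `abmil_model`: list with `params` (best
#'   epoch), `history` (tibble: epoch, train_loss, val_loss), `best_epoch`,
#'   `best_val_loss`, `config`, `class_weights`.
#' @export
abmil_train <- function(params, bags, labels, val_bags, val_labels,
                        config = train_config(), case_ids = NULL) {
  stopifnot(inherits(params, "abmil_params"), inherits(config, "train_config"))
  labels <- check_labels(labels)
  val_labels <- check_labels(val_labels)
  if (length(bags) != length(labels) || length(val_bags) != length(val_labels)) {
    abort("bags and labels must align")
  }
  for (cl in CLASS_LEVELS) {
    if (!cl %in% labels) abort(sprintf("class '%s' absent from training set", cl))
    if (!cl %in% val_labels) abort(sprintf("class '%s' absent from validation set", cl))
  }
  cw <- compute_class_weights(labels, config$class_weights)
  y_idx <- match(labels, CLASS_LEVELS)
  vy_idx <- match(val_labels, CLASS_LEVELS)
  H1 <- params$hidden[1]

  if (config$max_epochs == 0L) {
    return(structure(
      list(params = params, history = tibble::tibble(epoch = integer(0),
                                                     train_loss = numeric(0),
                                                     val_loss = numeric(0)),
           best_epoch = NA_integer_, best_val_loss = NA_real_,
           config = config, class_weights = cw, case_ids = case_ids),
      class = "abmil_model"))
  }

  # per-dimension standardisation constants fitted on the pooled training
  # instances and stored with the model, so prediction is self-contained
  pooled <- do.call(rbind, lapply(bags, bag_matrix))
  params$feat_center <- colMeans(pooled)
  params$feat_scale <- pmax(apply(pooled, 2, stats::sd), 1e-8)

  withr::with_seed(config$seed, {
    state <- adam_state(params)
    t_step <- 0L
    best <- list(loss = Inf, epoch = 0L, params = params)
    hist <- vector("list", config$max_epochs)
    Xs <- lapply(bags, function(b) scale_features(params, bag_matrix(b)))
    val_Xs <- lapply(val_bags, function(b) scale_features(params, bag_matrix(b)))

    for (epoch in seq_len(config$max_epochs)) {
      order_ <- sample.int(length(bags))
      ep_loss <- 0
      for (i in order_) {
        X <- Xs[[i]]
        dm <- NULL
        if (config$dropout > 0) {
          keep <- matrix(runif(nrow(X) * H1) >= config$dropout, nrow(X), H1)
          dm <- keep / (1 - config$dropout)
        }
        fwd <- abmil_forward(params, X, drop_mask = dm)
        ep_loss <- ep_loss - cw[y_idx[i]] * log(max(fwd$p[y_idx[i]], 1e-12))
        grads <- abmil_backward(params, X, fwd, y_idx[i],
                                class_weight = cw[y_idx[i]], drop_mask = dm)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, t_step,
                         config$learning_rate, config$weight_decay)
        params <- upd$params; state <- upd$state
      }
      val_loss <- weighted_ce_loss(params, val_Xs, vy_idx, cw)
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = ep_loss / length(bags),
                                      val_loss = val_loss)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, epoch = epoch, params = params)
      }
      if (epoch >= config$min_epochs && epoch - best$epoch >= config$patience) break
    }

    structure(
      list(params = best$params, history = dplyr::bind_rows(hist),
           best_epoch = best$epoch, best_val_loss = best$loss,
           config = config, class_weights = cw, case_ids = case_ids),
      class = "abmil_model")
  })
}

#' @export
print.abmil_model <- function(x, ...) {
  cat(sprintf("<abmil_model> D = %d, hidden = (%d, %d); trained %d epochs, best epoch %d (val loss %.4f)\n",
              x$params$feature_dim, x$params$hidden[1], x$params$hidden[2],
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Ensemble prediction by probability averaging
#'
#' Averages the member models' probability vectors elementwise (the label is
#' the argmax of the mean) and averages their attention vectors,
#' renormalised to sum to 1.
#'
#' @param members list of `abmil_params` / `abmil_model` objects (>= 1).
#' @param bag a [feature_bag] or matrix.
#' @return A `slide_prediction`.
#' @export
ensemble_predict <- function(members, bag) {
  if (length(members) < 1) abort("ensemble needs at least one member")
  preds <- lapply(members, predict_slide, bag = bag)
  probs <- rowMeans(vapply(preds, function(p) p$probs, numeric(2)))
  n_inst <- length(preds[[1]]$attention)
  att <- rowMeans(matrix(vapply(preds, function(p) p$attention,
                                numeric(n_inst)), nrow = n_inst))
  att <- att / sum(att)
  structure(
    list(slide_id = preds[[1]]$slide_id,
         probs = setNames(probs, CLASS_LEVELS),
         predicted_label = CLASS_LEVELS[which.max(probs)],
         attention = att),
    class = "slide_prediction"
  )
}
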