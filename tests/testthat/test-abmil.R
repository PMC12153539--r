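test_that("analytic gradients agree with central-difference numerics", {
  set.seed(99)
  p <- abmil_init(5, hidden = c(4, 3), seed = 3)
  X <- matrix(rnorm(6 * 5), 6, 5)
  for (y in 1:2) {
    cw <- c(1.3, 0.8)[y]
    loss_fn <- function(pp) {
      f <- wsimil:::abmil_forward(pp, X)
      -cw * log(f$p[y])
    }
    fwd <- wsimil:::abmil_forward(p, X)
    gr <- wsimil:::abmil_backward(p, X, fwd, y, class_weight = cw)
    eps <- 1e-6
    for (nm in wsimil:::param_names()) {
      num <- p[[nm]]
      for (i in seq_along(num)) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        num[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      }
      expect_equal(gr[[nm]], num, tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("initialisation is seeded and dimension mismatches are caught", {
  expect_identical(abmil_init(8, seed = 4), abmil_init(8, seed = 4))
  expect_false(identical(abmil_init(8, seed = 4)$W1, abmil_init(8, seed = 5)$W1))
  p <- abmil_init(8, seed = 4)
  expect_error(predict_slide(p, matrix(rnorm(10), 2, 5)), "does not match")
})

test_that("attention weights form a softmax over hand-computable scores", {
  p <- abmil_init(4, hidden = c(3, 2), seed = 2)
  # single instance: weight exactly 1
  expect_equal(attention_weights(p, matrix(rnorm(4), 1, 4)), 1)
  # identical instances: exactly uniform
  X <- matrix(rep(rnorm(4), each = 5), 5, 4)
  expect_equal(attention_weights(p, X), rep(1 / 5, 5))

  # two instances, hand-set parameters, independent scalar recomputation
  p$W1 <- diag(1, 4, 3); p$b1 <- rep(0, 3)
  p$V <- matrix(0.5, 3, 2); p$bv <- c(0.1, -0.2)
  p$U <- matrix(-0.3, 3, 2); p$bu <- c(0.2, 0.4)
  p$w <- c(1.5, -0.7); p$bw <- 0.05
  X <- rbind(c(0.2, -0.1, 0.3, 0.5), c(-0.4, 0.6, 0.1, -0.2))
  hand_score <- function(x) {
    h <- pmax(as.vector(x %*% diag(1, 4, 3)), 0)
    at <- tanh(as.vector(h %*% matrix(0.5, 3, 2)) + c(0.1, -0.2))
    as_ <- 1 / (1 + exp(-(as.vector(h %*% matrix(-0.3, 3, 2)) + c(0.2, 0.4))))
    sum(at * as_ * c(1.5, -0.7)) + 0.05
  }
  s <- c(hand_score(X[1, ]), hand_score(X[2, ]))
  expect_equal(attention_weights(p, X), exp(s) / sum(exp(s)))
})

test_that("aggregation is the attention-weighted average of embeddings", {
  p <- abmil_init(4, hidden = c(3, 2), seed = 6)
  X <- matrix(rnorm(3 * 4), 3, 4)
  H <- pmax(sweep(X %*% p$W1, 2, p$b1, "+"), 0)
  expect_equal(abmil_aggregate(p, rep(1 / 3, 3), X), colMeans(H))
  expect_equal(abmil_aggregate(p, c(0, 1, 0), X), H[2, ])
  expect_equal(abmil_aggregate(p, c(0.25, 0.75, 0), X),
               0.25 * H[1, ] + 0.75 * H[2, ])
  expect_error(abmil_aggregate(p, c(0.5, 0.5), X), "length")
})

test_that("classification is a shift-invariant two-class softmax", {
  p <- const_prob_params(0.5)
  expect_equal(unname(abmil_classify(p, rep(0, 3))), c(0.5, 0.5))
  # logits (ln 2, 0) -> (2/3, 1/3), closed form
  p$bc <- c(log(2), 0)
  expect_equal(unname(abmil_classify(p, rep(0, 3))), c(2 / 3, 1 / 3))
  p2 <- p; p2$bc <- p$bc + 10
  expect_equal(abmil_classify(p2, rep(0, 3)), abmil_classify(p, rep(0, 3)))
  expect_error(abmil_classify(p, c(NA, 1, 2)), "finite")
})

test_that("slide prediction is permutation- and duplication-invariant", {
  withr::with_seed(8, {
    p <- abmil_init(6, seed = 8)
    X <- matrix(rnorm(12 * 6), 12, 6)
    pr <- predict_slide(p, X)
    expect_equal(sum(pr$probs), 1)
    expect_equal(sum(pr$attention), 1)
    expect_true(all(pr$attention >= 0 & pr$attention <= 1))
    expect_identical(pr$predicted_label,
                     c("benign", "metastatic")[which.max(pr$probs)])

    for (k in 1:5) {
      perm <- sample(12)
      pr2 <- predict_slide(p, X[perm, ])
      expect_equal(pr2$probs, pr$probs)
      expect_equal(pr2$attention, pr$attention[perm])
    }
    # duplicating every patch halves each copy's weight, probabilities fixed
    pr3 <- predict_slide(p, rbind(X, X))
    expect_equal(pr3$probs, pr$probs)
    expect_equal(pr3$attention, rep(pr$attention / 2, 2))

    # single-patch bag: probs equal classify(aggregate(1, patch))
    x1 <- X[1, , drop = FALSE]
    pr4 <- predict_slide(p, x1)
    expect_equal(pr4$probs, abmil_classify(p, abmil_aggregate(p, 1, x1)))
  })
})

test_that("training is reproducible, improves the model, and guards its contract", {
  sim <- small_sim()
  p0 <- abmil_init(16, seed = 1)

  # zero epochs: identity
  m0 <- abmil_train(p0, sim$tr$bags, sim$tr$labels, sim$va$bags, sim$va$labels,
                    config = train_config(max_epochs = 0L))
  expect_identical(m0$params, p0)
  expect_equal(nrow(m0$history), 0)

  # identical seed + data -> identical parameters, twice
  m1 <- abmil_train(p0, sim$tr$bags, sim$tr$labels, sim$va$bags, sim$va$labels,
                    config = quick_config(seed = 7))
  m2 <- abmil_train(p0, sim$tr$bags, sim$tr$labels, sim$va$bags, sim$va$labels,
                    config = quick_config(seed = 7))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # training separates the separable simulation far above chance
  preds <- predict_slides(m1, sim$te$bags)
  expect_gt(auroc(sim$te$labels, preds$prob_metastatic), 0.9)

  # a class missing from either split is a hard error
  ben <- sim$tr$labels == "benign"
  expect_error(abmil_train(p0, sim$tr$bags[ben], sim$tr$labels[ben],
                           sim$va$bags, sim$va$labels, config = quick_config()),
               "absent from training")
  expect_error(abmil_train(p0, sim$tr$bags, sim$tr$labels,
                           sim$va$bags[sim$va$labels == "metastatic"],
                           sim$va$labels[sim$va$labels == "metastatic"],
                           config = quick_config()),
               "absent from validation")
})

test_that("tidiers summarise a fit without re-deriving anything", {
  sim <- small_sim()
  m <- abmil_train(abmil_init(16, seed = 1), sim$tr$bags, sim$tr$labels,
                   sim$va$bags, sim$va$labels, config = quick_config(seed = 3))
  td <- tidy(m)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$epochs_trained, nrow(td))
  expect_equal(gl$best_val_loss, min(td$val_loss))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})

test_that("ensembling averages probability vectors and renormalises attention", {
  X <- matrix(rnorm(8), 2, 4)
  m1 <- const_prob_params(0.2)   # probs (0.8, 0.2)
  m2 <- const_prob_params(0.4)   # probs (0.6, 0.4)
  pr <- ensemble_predict(list(m1, m2), X)
  expect_equal(unname(pr$probs), c(0.7, 0.3))
  expect_identical(pr$predicted_label, "benign")
  expect_equal(sum(pr$attention), 1)

  # identical members reproduce the member prediction
  same <- ensemble_predict(list(m1, m1, m1), X)
  expect_equal(same$probs, predict_slide(m1, X)$probs)

  # five members with known metastatic probabilities -> mean 0.71, metastatic
  members <- lapply(c(0.9, 0.8, 0.7, 0.6, 0.55), const_prob_params)
  pr5 <- ensemble_predict(members, X)
  expect_equal(unname(pr5$probs["metastatic"]), 0.71)
  expect_identical(pr5$predicted_label, "metastatic")
})
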