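rand_labels <- function(n) sample(c("benign", "metastatic"), n, replace = TRUE)

test_that("confusion counts match an exhaustive tally", {
  y <- c("benign", "benign", "metastatic")
  expect_equal(unname(diag(confusion_counts(y, y))), c(2, 1))
  expect_equal(sum(confusion_counts(y, y)) - sum(diag(confusion_counts(y, y))), 0)

  withr::with_seed(10, {
    for (rep in 1:5) {
      yt <- rand_labels(20); yp <- rand_labels(20)
      cm <- confusion_counts(yt, yp)
      for (tr in c("benign", "metastatic")) for (pr in c("benign", "metastatic")) {
        tally <- 0
        for (i in 1:20) if (yt[i] == tr && yp[i] == pr) tally <- tally + 1
        expect_equal(cm[tr, pr], tally)
      }
    }
  })
  expect_error(confusion_counts(c("benign", "weird"), c("benign", "benign")),
               "must be in")
})

test_that("class and accuracy metrics match their defining formulas", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      yt <- c("benign", "metastatic", rand_labels(18))  # both classes present
      yp <- rand_labels(20)
      cm <- confusion_counts(yt, yp)
      tp <- sum(yt == "metastatic" & yp == "metastatic")
      fp <- sum(yt == "benign" & yp == "metastatic")
      tn <- sum(yt == "benign" & yp == "benign")
      fn <- sum(yt == "metastatic" & yp == "benign")
      met <- class_metrics(cm, "metastatic")
      if (tp + fp > 0) expect_equal(met$precision, tp / (tp + fp))
      expect_equal(met$sensitivity, tp / (tp + fn))
      expect_equal(met$specificity, tn / (tn + fp))
      acc <- accuracy_metrics(cm)
      expect_equal(acc$accuracy, (tp + tn) / 20)
      expect_equal(acc$balanced_accuracy,
                   mean(c(tp / (tp + fn), tn / (tn + fp))))
    }
  })
})

test_that("undefined ratios surface as NA, never as silent zero", {
  # nothing ever called metastatic: metastatic precision is 0/0
  cm <- confusion_counts(c("benign", "metastatic"), c("benign", "benign"))
  m <- class_metrics(cm, "metastatic")
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$sensitivity, 0)
})

test_that("AUROC equals exhaustive pair counting, ties half-credited", {
  expect_equal(auroc(c("benign", "benign", "metastatic", "metastatic"),
                     c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c("benign", "metastatic", "benign", "metastatic"),
                     rep(0.5, 4)), 0.5)
  expect_true(is.na(auroc(c("benign", "benign"), c(0.1, 0.2))))

  pairwise_oracle <- function(y, s) {
    pos <- s[y == "metastatic"]; neg <- s[y == "benign"]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      y <- c("benign", "metastatic", rand_labels(n - 2))
      s <- round(runif(n), 1)   # coarse scores force ties
      expect_equal(auroc(y, s), pairwise_oracle(y, s))
    }
  })
})

test_that("AUROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (rep in 1:5) {
      y <- c("benign", "metastatic", rand_labels(28))
      s <- runif(30)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = y, predictor = s, levels = c("benign", "metastatic"),
        direction = "<", quiet = TRUE)))
      expect_equal(auroc(y, s), ref)
    }
  })
})

test_that("bootstrap CIs are seeded, degenerate when the metric is constant", {
  y <- rep(c("benign", "metastatic"), each = 10)
  acc_fn <- function(yt, yp) mean(yt == yp)
  b1 <- bootstrap_ci(acc_fn, y, y, B = 500, seed = 42)
  b2 <- bootstrap_ci(acc_fn, y, y, B = 500, seed = 42)
  expect_identical(b1, b2)
  # all predictions correct: every replicate scores 1
  expect_equal(b1$boot_mean, 1)
  expect_equal(b1$ci_high - b1$ci_low, 0)

  expect_error(bootstrap_ci(function(yt, yp) NA_real_, y, y, B = 50, seed = 1),
               "undefined")
})

test_that("bootstrap percentile intervals cover the point estimate", {
  withr::with_seed(14, {
    covered <- 0L
    for (rep in 1:40) {
      y <- c("benign", "metastatic", rand_labels(38))
      yp <- ifelse(runif(40) < 0.8, y, rand_labels(40))
      point <- mean(y == yp)
      ci <- bootstrap_ci(function(a, b) mean(a == b), y, yp, B = 200,
                         seed = rep)
      covered <- covered + (point >= ci$ci_low && point <= ci$ci_high)
    }
    expect_gte(covered / 40, 0.95)
  })
})

test_that("the metrics report is internally consistent", {
  withr::with_seed(15, {
    y <- rep(c("benign", "metastatic"), each = 20)
    prob <- clamp <- pmin(pmax(ifelse(y == "metastatic", 0.7, 0.3) +
                                 rnorm(40, 0, 0.2), 0), 1)
    rep_ <- metrics_report(y, prob, n_bootstrap = 500, seed = 3)
    s <- tidy(rep_)
    expect_true(all(s$ci_low <= s$boot_mean + 1e-12 &
                      s$boot_mean <= s$ci_high + 1e-12, na.rm = TRUE))
    expect_equal(sum(rep_$counts), 40)
    est <- setNames(s$estimate, s$metric)
    expect_equal(est[["accuracy"]],
                 accuracy_metrics(rep_$counts)$accuracy)
    expect_equal(est[["auroc"]], auroc(y, prob))
    expect_equal(est[["f1_metastatic"]],
                 class_metrics(rep_$counts, "metastatic")$f1)
    # derived per-class identities
    expect_equal(est[["sensitivity_benign"]], est[["specificity_metastatic"]])
    gl <- glance(rep_)
    expect_equal(gl$auroc, est[["auroc"]])
    expect_s3_class(ggplot2::autoplot(rep_), "ggplot")
  })
})
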