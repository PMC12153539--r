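make_test_manifest <- function(n_cases_per_class = 10, slides_per_case = 2) {
  purrr::map_dfr(c("benign", "metastatic"), function(cl) {
    purrr::map_dfr(seq_len(n_cases_per_class), function(i) {
      tibble::tibble(
        slide_id = sprintf("%s_c%02d_s%d", substr(cl, 1, 3), i,
                           seq_len(slides_per_case)),
        case_id = sprintf("%s_c%02d", substr(cl, 1, 3), i),
        cohort = "test", label = cl, mpp = 1, path = NA_character_)
    })
  })
}

test_that("case folds partition cases with stratified 60-20-20 roles", {
  man <- make_test_manifest(10, 2)
  folds <- make_case_folds(man, k = 5, seed = 3)

  # each case tested exactly once across the five folds
  tested <- dplyr::filter(folds, role == "test")
  expect_setequal(tested$case_id, unique(man$case_id))
  expect_equal(nrow(tested), dplyr::n_distinct(man$case_id))

  case_label <- dplyr::distinct(man, case_id, label)
  for (f in 1:5) {
    fr <- dplyr::filter(folds, fold == f)
    # disjoint roles covering every case exactly once
    expect_equal(sort(fr$case_id), sort(unique(man$case_id)))
    expect_equal(anyDuplicated(fr$case_id), 0)
    # 3:1:1 case counts (60-20-20) within rounding
    expect_equal(unname(table(fr$role)[c("train", "validation", "test")]),
                 c(12L, 4L, 4L), ignore_attr = TRUE)
    # stratification within one case of the ideal per role
    fr2 <- dplyr::left_join(fr, case_label, by = "case_id")
    for (rl in unique(fr2$role)) {
      tab <- table(fr2$label[fr2$role == rl])
      expect_lte(abs(tab[["benign"]] - tab[["metastatic"]]), 1)
    }
  }
  # determinism
  expect_identical(folds, make_case_folds(man, k = 5, seed = 3))
  expect_false(identical(folds, make_case_folds(man, k = 5, seed = 4)))
})

test_that("slides sharing a case never straddle roles (exhaustive audit)", {
  man <- make_test_manifest(8, 3)
  folds <- make_case_folds(man, k = 5, seed = 7)
  joined <- dplyr::left_join(man, folds, by = "case_id",
                             relationship = "many-to-many")
  audit <- dplyr::summarise(dplyr::group_by(joined, fold, case_id),
                            n_roles = dplyr::n_distinct(role), .groups = "drop")
  expect_true(all(audit$n_roles == 1))
})

test_that("too few cases in either class is an error", {
  man <- make_test_manifest(4, 1)   # 4 cases per class < k = 5
  expect_error(make_case_folds(man, k = 5, seed = 1), "at least 5")
})

test_that("cross-validation yields one out-of-fold prediction per slide", {
  sim <- small_sim()
  all_bags <- c(sim$tr$bags, sim$va$bags)
  man <- dplyr::bind_rows(sim_manifest(sim$tr, "a_"), sim_manifest(sim$va, "b_"))
  cv <- run_cross_validation(man, all_bags, config = quick_config(seed = 2),
                             k = 5, n_bootstrap = 200, seed = 2)
  expect_length(cv$models, 5)
  expect_equal(nrow(cv$predictions), nrow(man))
  expect_setequal(cv$predictions$slide_id, man$slide_id)
  expect_equal(anyDuplicated(cv$predictions$slide_id), 0)
  # the separable simulation is classified far above chance
  expect_gt(glance(cv)$auroc, 0.9)
  expect_equal(tidy(cv), cv$predictions)

  # hold-out on unseen cases works; overlapping cases are a hard error
  ho_man <- sim_manifest(sim$te)
  ho <- run_holdout(cv, ho_man, sim$te$bags, n_bootstrap = 200, seed = 2)
  expect_equal(nrow(ho$predictions), nrow(ho_man))
  expect_gt(glance(ho$report)$auroc, 0.9)
  leaky <- ho_man
  leaky$case_id[1] <- man$case_id[1]
  expect_error(run_holdout(cv, leaky, sim$te$bags), "leakage")
})

test_that("a perfect ensemble yields accuracy one with a degenerate CI", {
  members <- list(const_prob_params(0.9), const_prob_params(0.8))
  bags <- list(b1 = feature_bag("b1", matrix(rnorm(8), 2, 4)),
               b2 = feature_bag("b2", matrix(rnorm(8), 2, 4)))
  man <- tibble::tibble(slide_id = c("b1", "b2"), case_id = c("c1", "c2"),
                        label = c("metastatic", "metastatic"))
  train_man <- tibble::tibble(case_id = "c0")
  ho <- run_holdout(members, man, bags, train_manifest = train_man,
                    n_bootstrap = 100, seed = 1)
  est <- setNames(ho$report$summary$estimate, ho$report$summary$metric)
  expect_equal(est[["accuracy"]], 1)
  acc_row <- dplyr::filter(ho$report$summary, metric == "accuracy")
  expect_equal(acc_row$ci_low, 1)
  expect_equal(acc_row$ci_high, 1)
})
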