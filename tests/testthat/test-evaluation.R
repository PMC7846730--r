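test_that("repeated holdout honours split sizes and report invariants", {
  feats <- replication_features()
  ev <- suppressMessages(
    repeated_holdout(feats, c("linear_svm", "cosine_knn"), reps = 5,
                     seed = 7)
  )
  expect_equal(ev$protocol$n_train, 300)
  expect_equal(ev$protocol$n_test, 100)
  for (cl in c("linear_svm", "cosine_knn")) {
    cm <- ev$confusion[[cl]]
    expect_equal(dim(cm), c(9, 9))
    expect_equal(sum(cm), 5 * 100)
    reps <- ev$rep_accuracies$accuracy[ev$rep_accuracies$classifier == cl]
    row <- ev$accuracy[ev$accuracy$classifier == cl, ]
    expect_equal(row$mean_accuracy, mean(reps))
    expect_equal(row$pooled_accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("a threshold-separable label is classified perfectly", {
  withr::with_seed(9, {
    df <- tibble::tibble(
      f1 = runif(120, 0.3, 1) * sample(c(-1, 1), 120, replace = TRUE),
      f2 = rnorm(120, sd = 0.2)
    )
    df$label <- ifelse(df$f1 > 0, "pos", "neg")
  })
  ev <- repeated_holdout(df, c("linear_svm", "weighted_knn"), reps = 5,
                         seed = 3)
  expect_equal(ev$accuracy$mean_accuracy, c(1, 1))
})

test_that("evaluation is reproducible for a fixed seed", {
  feats <- replication_features()[seq(1, 400, by = 2), ]
  e1 <- suppressMessages(repeated_holdout(feats, "cosine_knn", reps = 3,
                                          seed = 11))
  e2 <- suppressMessages(repeated_holdout(feats, "cosine_knn", reps = 3,
                                          seed = 11))
  expect_identical(e1$accuracy, e2$accuracy)
  expect_identical(e1$confusion, e2$confusion)
  expect_identical(e1$rep_accuracies, e2$rep_accuracies)
})

test_that("degenerate evaluation inputs error", {
  feats <- replication_features()
  single <- feats[feats$label == "front", ]
  expect_error(repeated_holdout(single, "linear_svm", reps = 2),
               "two classes")
  unlabeled <- feats
  unlabeled$label <- NA_character_
  expect_error(repeated_holdout(unlabeled, "linear_svm"), "label")
  expect_error(repeated_holdout(feats, c("linear_svm", "linear_svm")),
               "duplicated")
})

test_that("adjacency error fraction handles the boundary cases", {
  lev <- orientation_levels()
  cm <- matrix(0L, 9, 9, dimnames = list(lev, lev))
  diag(cm) <- 10L
  expect_equal(suppressMessages(adjacency_error_fraction(cm)), 1)
  cm1 <- cm
  cm1["left", "front_left"] <- 1L
  expect_equal(adjacency_error_fraction(cm1), 1)
  cm2 <- cm
  cm2["left", "right"] <- 1L
  expect_equal(adjacency_error_fraction(cm2), 0)
  cm3 <- cm
  cm3["left", "front_left"] <- 3L
  cm3["left", "right"] <- 1L
  expect_equal(adjacency_error_fraction(cm3), 0.75)
})

test_that("tidy and glance summarise an evaluation", {
  ev <- replication_eval()
  td <- tidy(ev)
  expect_equal(nrow(td), 9)
  expect_setequal(td$classifier, classifier_names())
  expect_true(all(td$mean_accuracy >= td$mean_accuracy[nrow(td)]))
  gl <- glance(ev)
  expect_equal(gl$n_classifiers, 9)
  expect_equal(gl$best_accuracy, max(td$mean_accuracy))
  m <- fit_classifier(replication_features(), "weighted_knn")
  expect_equal(glance(m)$n_predictors, 6)
  expect_true("k" %in% tidy(m)$hyperparameter)
})

test_that("streaming classification labels segments as they complete", {
  cfg <- generator_config(seed = 55)
  cal <- generate_calibration_recording(cfg)
  prof <- calibrate(cal)
  rec <- generate_recording(
    motion_script(rep(c("left", "front", "right", "front"), 2), 1.2, 0.8),
    config = cfg
  )
  model <- fit_classifier(replication_features(), "linear_svm")
  out <- suppressMessages(classify_stream(rec, prof, model))
  expect_equal(nrow(out),
               (nrow(rec) - 550) %/% 300 + 1)
  expect_true(all(out$predicted %in% orientation_levels()))
  expect_gt(mean(out$predicted == out$label), 0.7)
})
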