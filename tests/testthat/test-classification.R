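test_that("a linear SVM separates well-separated blobs perfectly", {
  blobs <- make_blobs()
  m <- fit_classifier(blobs, "linear_svm")
  expect_equal(mean(as.character(predict(m, blobs)) == blobs$label), 1)
})

test_that("the Gaussian SVM kernel scale is the root of the predictor count", {
  m <- fit_classifier(replication_features()[1:60, ], "gaussian_svm")
  expect_equal(m$hyper$kernel_scale, sqrt(6))
  expect_equal(m$hyper$gamma, 1 / 6)
})

test_that("Gaussian naive Bayes recovers per-class means from Gaussian data", {
  n <- 1000
  truth <- list(a = c(0, 2), b = c(3, -1))
  df <- withr::with_seed(21, tibble::tibble(
    f1 = c(rnorm(n, truth$a[1]), rnorm(n, truth$b[1])),
    f2 = c(rnorm(n, truth$a[2]), rnorm(n, truth$b[2])),
    label = rep(c("a", "b"), each = n)
  ))
  m <- fit_classifier(df, "gaussian_nb")
  # undo the stored standardization to compare with generating means
  for (cl in c("a", "b")) {
    for (j in 1:2) {
      est <- m$fit$tables[[j]][cl, 1] * m$scale[j] + m$centre[j]
      expect_lt(abs(est - truth[[cl]][j]), 4 / sqrt(n))
    }
  }
})

test_that("naive Bayes posteriors are normalized", {
  feats <- replication_features()[seq(1, 400, by = 4), ]
  for (spec in c("gaussian_nb", "kernel_nb")) {
    m <- fit_classifier(feats, spec)
    post <- predict(m, feats[1:25, ], type = "prob")
    expect_equal(unname(rowSums(post)), rep(1, 25), tolerance = 1e-9)
  }
})

test_that("KNN identity and exact-match conventions hold", {
  blobs <- make_blobs(n_per_class = 10)
  m1 <- fit_classifier(blobs, classifier_spec("weighted_knn", k = 1))
  expect_equal(as.character(predict(m1, blobs)), blobs$label)
  # exact-match query dominates regardless of k
  mk <- fit_classifier(blobs, classifier_spec("weighted_knn", k = 15))
  expect_equal(as.character(predict(mk, blobs[3, ])), blobs$label[3])
})

test_that("cosine KNN follows angular distance", {
  # columns centred and with equal spread, so standardization preserves
  # directions up to a common factor
  train <- tibble::tibble(
    f1 = c(2, -2, 0, 0), f2 = c(0, 0, 2, -2),
    label = c("east", "west", "north", "south")
  )
  m <- fit_classifier(train, classifier_spec("cosine_knn", k = 1))
  q <- tibble::tibble(f1 = c(10, -0.2), f2 = c(0.4, -9))
  expect_equal(as.character(predict(m, q)), c("east", "south"))
  ref <- knn_reference(as.matrix(train[, 1:2]), train$label,
                       c(10, 0.4), k = 1, metric = "cosine")
  expect_equal(ref, "east")
})

test_that("production KNN agrees with the brute-force reference", {
  withr::with_seed(77, {
    train <- tibble::as_tibble(matrix(rnorm(50 * 6), 50, 6),
                               .name_repair = ~ paste0("f", 1:6))
    train$label <- sample(letters[1:4], 50, replace = TRUE)
    queries <- matrix(rnorm(40 * 6), 40, 6)
  })
  for (name in c("cosine_knn", "cubic_knn", "weighted_knn")) {
    spec <- classifier_spec(name)
    m <- fit_classifier(train, spec)
    prod <- as.character(predict(m, queries))
    xs_train <- sweep(sweep(as.matrix(train[, 1:6]), 2, m$centre), 2,
                      m$scale, "/")
    xs_q <- sweep(sweep(queries, 2, m$centre), 2, m$scale, "/")
    ref <- vapply(seq_len(nrow(xs_q)), function(i) {
      knn_reference(xs_train, train$label, xs_q[i, ], k = spec$hyper$k,
                    metric = spec$hyper$metric,
                    weighting = spec$hyper$weighting)
    }, character(1))
    expect_equal(prod, ref, info = name)
  }
})

test_that("predictions are invariant to affine rescaling of a feature", {
  feats <- replication_features()[seq(1, 400, by = 2), ]
  rescaled <- feats
  rescaled$delta_slash <- 100 * rescaled$delta_slash + 5
  for (spec in c("linear_svm", "weighted_knn", "cosine_knn")) {
    p0 <- predict(fit_classifier(feats, spec), feats)
    p1 <- predict(fit_classifier(rescaled, spec), rescaled)
    expect_equal(as.character(p0), as.character(p1), info = spec)
  }
})

test_that("degenerate training inputs are rejected", {
  blobs <- make_blobs()
  one_class <- blobs[blobs$label == "a", ]
  expect_error(fit_classifier(one_class, "linear_svm"), "single class")
  bad <- blobs
  bad$f1[3] <- NA
  expect_error(fit_classifier(bad, "linear_svm"), "missing")
  m <- fit_classifier(blobs, "linear_svm")
  expect_error(predict(m, matrix(1, 2, 5)), "feature columns")
  expect_error(predict(m, tibble::tibble(f1 = 1)), "lacks feature")
})
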