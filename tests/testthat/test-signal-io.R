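test_that("recordings round-trip through CSV", {
  cfg <- generator_config(seed = 12)
  rec <- generate_recording(motion_script(c("left", "front"), 0.3, 0.2),
                            config = cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  expect_equal(sampling_rate(back), sampling_rate(rec))

  unlabeled <- rec
  unlabeled$label <- NA_character_
  write_recording(unlabeled, path)
  expect_true(all(is.na(read_recording(path)$label)))
})

test_that("malformed recording files are rejected with a named column", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(time_s = (0:9) / 1000, ch_slash = rnorm(10))
  readr::write_csv(df, path)
  expect_error(read_recording(path), "ch_backslash")

  df2 <- tibble::tibble(time_s = sample((0:9) / 1000), ch_slash = 1:10,
                        ch_backslash = 1:10)
  readr::write_csv(df2, path)
  expect_error(read_recording(path), "increasing|non-uniform")

  df3 <- tibble::tibble(time_s = c(0:8, 10) / 1000, ch_slash = 1:10,
                        ch_backslash = 1:10)
  readr::write_csv(df3, path)
  expect_error(read_recording(path), "non-uniform")

  # header + 3 rows parses to a 3-sample recording
  df4 <- tibble::tibble(time_s = (0:2) / 1000, ch_slash = c(1, 2, 3),
                        ch_backslash = c(3, 2, 1),
                        label = c("front", "front", NA))
  readr::write_csv(df4, path, na = "")
  rec4 <- read_recording(path)
  expect_equal(nrow(rec4), 3)
  expect_equal(rec4$label, c("front", "front", NA))
})

test_that("calibration profiles round-trip through JSON", {
  prof <- calibrate(generate_calibration_recording(generator_config(seed = 13)))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_profile(prof, path)
  expect_equal(as.data.frame(read_calibration_profile(path)),
               as.data.frame(prof))
  bad <- prof
  bad$baseline <- bad$cal_max + 1
  expect_error(write_calibration_profile(bad, path), "degenerate")
})

test_that("feature tables round-trip through CSV", {
  feats <- replication_features()[1:20, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(feats))
})

test_that("evaluation reports round-trip through JSON", {
  ev <- suppressMessages(
    repeated_holdout(replication_features()[seq(1, 400, 2), ],
                     c("linear_svm", "cosine_knn", "gaussian_nb"),
                     reps = 3, seed = 5)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_report(ev, path)
  back <- read_report(path)
  expect_equal(back$accuracy, ev$accuracy)
  expect_equal(back$rep_accuracies, ev$rep_accuracies)
  expect_equal(back$confusion, ev$confusion)
  expect_equal(back$protocol[c("reps", "train_frac", "seed")],
               ev$protocol[c("reps", "train_frac", "seed")])
  expect_equal(length(back$confusion), 3)

  empty <- ev
  empty$protocol$reps <- 0
  empty$rep_accuracies <- ev$rep_accuracies[0, ]
  expect_error(write_report(empty, path), "empty report")
})

test_that("trained models survive the versioned container", {
  blobs <- make_blobs()
  m <- fit_classifier(blobs, "weighted_knn")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(as.character(predict(m2, blobs)),
               as.character(predict(m, blobs)))
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "not a threadmotion model")
})

test_that("simulation configs load from YAML with defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    generator = list(seed = 7, noise_sd = 2, baseline_raw = c(480, 470)),
    script = list(
      list(target = "left", dwell_s = 1, transition_s = 0.5),
      list(target = "front", dwell_s = 1, transition_s = 0.5)
    )
  ), path)
  sim <- read_simulation_config(path)
  expect_s3_class(sim$script, "motion_script")
  expect_equal(nrow(sim$script), 2)
  expect_equal(sim$config$seed, 7L)
  expect_equal(sim$config$noise_sd, 2)
  expect_equal(sim$config$baseline_raw, c(480, 470))
  # missing script section falls back to the default protocol
  yaml::write_yaml(list(generator = list(seed = 1)), path)
  sim2 <- read_simulation_config(path)
  expect_equal(nrow(sim2$script), 41)
})
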