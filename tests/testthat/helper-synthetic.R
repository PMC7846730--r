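# Shared fixtures, built once per test run and cached.
tm_cache <- new.env(parent = emptyenv())

# Full synthetic replication of the experimental session: calibration
# session -> calibration profile -> 120.25 s motion protocol -> feature
# table of 400 labeled segments.
replication_features <- function() {
  if (is.null(tm_cache$feats)) {
    cfg <- generator_config(seed = 101)
    cal <- generate_calibration_recording(cfg)
    prof <- calibrate(cal)
    rec <- generate_recording(default_experiment_script(), config = cfg)
    tm_cache$feats <- suppressMessages(compute_feature_table(rec, prof))
  }
  tm_cache$feats
}

# 100 x 75/25 repeated holdout of all nine classifiers on the replication.
replication_eval <- function() {
  if (is.null(tm_cache$eval)) {
    tm_cache$eval <- suppressMessages(
      repeated_holdout(replication_features(), reps = 100,
                       train_frac = 0.75, seed = 2024)
    )
  }
  tm_cache$eval
}

# Constant-channel recording of n samples, optionally labeled.
make_recording <- function(n, fs = 1000, slash = 0, backslash = 0,
                           label = NA_character_) {
  as_motion_recording(
    tibble::tibble(
      ch_slash = rep_len(slash, n),
      ch_backslash = rep_len(backslash, n),
      label = rep_len(label, n)
    ),
    sampling_rate = fs
  )
}

# Two well-separated Gaussian blobs in 2-D.
make_blobs <- function(n_per_class = 25, sep = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    f1 = c(rnorm(n_per_class), rnorm(n_per_class) + sep),
    f2 = c(rnorm(n_per_class), rnorm(n_per_class) + sep),
    label = rep(c("a", "b"), each = n_per_class)
  ))
}
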