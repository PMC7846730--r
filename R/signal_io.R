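#' Read a two-channel recording from CSV
#'
#' The on-disk schema has a mandatory header with columns `time_s`,
#' `ch_slash`, `ch_backslash` and an optional `label` column ("." decimal
#' separator, UTF-8). The channel names spell out the `/` and `\` threads
#' to avoid escape-character ambiguity. Time must be strictly increasing
#' and uniformly sampled; the sampling rate is inferred from the median
#' time step.
#'
#' @param path CSV file path.
#' @param time_tolerance_s Maximum deviation of any time step from the
#'   median step (seconds).
#' @return A `motion_recording`.
#' @export
read_recording <- function(path, time_tolerance_s = 1e-6) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_s", "ch_slash", "ch_backslash")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("recording schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop("recording format error: time_s must be strictly increasing",
         call. = FALSE)
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > time_tolerance_s)) {
    stop("recording format error: non-uniform sampling interval",
         call. = FALSE)
  }
  if (!"label" %in% names(df)) {
    df$label <- NA_character_
  } else {
    df$label <- as.character(df$label)
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  }
  new_motion_recording(
    tibble::as_tibble(df[, c("time_s", "ch_slash", "ch_backslash",
                             "label")]),
    sampling_rate = 1 / step
  )
}

#' Build a recording from a plain data frame
#'
#' Wraps an in-memory data frame as a `motion_recording`, validating the
#' schema used throughout the package. Either supply a `time_s` column
#' (strictly increasing, uniform) or a `sampling_rate` from which one is
#' built.
#'
#' @param df Data frame with columns `ch_slash`, `ch_backslash` and
#'   optionally `time_s` and `label`.
#' @param sampling_rate Sampling rate in Hz; required when `df` has no
#'   `time_s` column.
#' @return A `motion_recording`.
#' @export
as_motion_recording <- function(df, sampling_rate = NULL) {
  missing <- setdiff(c("ch_slash", "ch_backslash"), names(df))
  if (length(missing) > 0) {
    stop("recording schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  if (!"time_s" %in% names(df)) {
    if (is.null(sampling_rate)) {
      stop("need either a time_s column or a sampling_rate", call. = FALSE)
    }
    df$time_s <- (seq_len(n) - 1) / sampling_rate
  } else {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) {
      stop("time_s must be strictly increasing", call. = FALSE)
    }
    step <- stats::median(dt)
    if (any(abs(dt - step) > 1e-6)) {
      stop("non-uniform sampling interval", call. = FALSE)
    }
    sampling_rate <- sampling_rate %||% (1 / step)
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  new_motion_recording(
    tibble::as_tibble(df[, c("time_s", "ch_slash", "ch_backslash",
                             "label")]),
    sampling_rate = sampling_rate
  )
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]; missing labels are written as empty
#' fields.
#'
#' @param recording A `motion_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  check_recording(recording)
  readr::write_csv(tibble::as_tibble(recording), path, na = "",
                   progress = FALSE)
  invisible(path)
}

#' Read / write a calibration profile (JSON)
#'
#' Serialized as a channel-keyed object:
#' `{"slash": {"baseline": ..., "cal_max": ..., "cal_min": ...},
#'   "backslash": {...}}`.
#'
#' @param profile A `calibration_profile`.
#' @param path JSON file path.
#' @return `read_calibration_profile()` returns a `calibration_profile`;
#'   `write_calibration_profile()` returns `path` invisibly.
#' @export
write_calibration_profile <- function(profile, path) {
  check_calibration_profile(profile)
  obj <- lapply(seq_len(nrow(profile)), function(i) {
    list(baseline = profile$baseline[i], cal_max = profile$cal_max[i],
         cal_min = profile$cal_min[i])
  })
  names(obj) <- profile$channel
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_profile
#' @export
read_calibration_profile <- function(path) {
  obj <- jsonlite::read_json(path)
  profile <- tibble::tibble(
    channel = names(obj),
    baseline = vapply(obj, function(o) o$baseline, numeric(1)),
    cal_max = vapply(obj, function(o) o$cal_max, numeric(1)),
    cal_min = vapply(obj, function(o) o$cal_min, numeric(1))
  )
  check_calibration_profile(profile)
  structure(profile,
            class = c("calibration_profile", class(tibble::tibble())))
}

#' Read / write a feature table (CSV)
#'
#' Columns: `start_index`, `start_time_s`, the six features of
#' [motion_feature_names()], and `label` (empty when unlabeled).
#'
#' @param features A `motion_features` tibble.
#' @param path CSV file path.
#' @return `read_feature_table()` returns a `motion_features` tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(tibble::as_tibble(features), path, na = "",
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("start_index", "start_time_s", motion_feature_names())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("feature table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df$label <- as.character(df$label)
  structure(tibble::as_tibble(df[, c(required, "label")]),
            class = c("motion_features", class(tibble::tibble())))
}

#' Write an evaluation report (JSON)
#'
#' Serializes a [repeated_holdout()] result: per-classifier averaged and
#' pooled accuracy, the per-round accuracies, pooled confusion matrices
#' with orientation row/column names, and the protocol parameters.
#' [read_report()] reconstructs the `motion_eval` losslessly.
#'
#' @param report A `motion_eval`.
#' @param path JSON file path.
#' @return `read_report()` returns a `motion_eval`; `write_report()`
#'   returns `path` invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "motion_eval")) {
    stop("expected a motion_eval report", call. = FALSE)
  }
  if (report$protocol$reps < 1 || nrow(report$rep_accuracies) == 0) {
    stop("cannot write an empty report (zero repetitions)", call. = FALSE)
  }
  classifiers <- lapply(report$accuracy$classifier, function(cl) {
    reps <- report$rep_accuracies |>
      dplyr::filter(.data$classifier == cl) |>
      dplyr::arrange(.data$rep)
    row <- report$accuracy[report$accuracy$classifier == cl, ]
    list(
      mean_accuracy = row$mean_accuracy,
      pooled_accuracy = row$pooled_accuracy,
      rep_accuracies = reps$accuracy,
      confusion = apply(report$confusion[[cl]], 1, as.list, simplify = FALSE)
    )
  })
  names(classifiers) <- report$accuracy$classifier
  obj <- list(
    format = "threadmotion-report/1",
    protocol = report$protocol,
    orientation_order = report$protocol$levels,
    classifiers = classifiers
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lev <- unlist(obj$orientation_order)
  cls <- names(obj$classifiers)
  confusion <- lapply(obj$classifiers, function(o) {
    m <- do.call(rbind, lapply(o$confusion, function(r) unlist(r)))
    m <- matrix(as.integer(m), nrow(m), ncol(m))
    dimnames(m) <- list(true = lev, predicted = lev)
    m
  })
  acc <- tibble::tibble(
    classifier = cls,
    mean_accuracy = unname(vapply(obj$classifiers,
                                  function(o) o$mean_accuracy, numeric(1))),
    pooled_accuracy = unname(vapply(obj$classifiers,
                                    function(o) o$pooled_accuracy,
                                    numeric(1)))
  )
  acc_mat <- vapply(cls, function(cl) {
    unlist(obj$classifiers[[cl]]$rep_accuracies)
  }, numeric(length(obj$classifiers[[1]]$rep_accuracies)))
  acc_mat <- matrix(acc_mat, ncol = length(cls))
  reps <- tibble::tibble(
    rep = rep(seq_len(nrow(acc_mat)), each = length(cls)),
    classifier = rep(cls, nrow(acc_mat)),
    accuracy = as.vector(t(acc_mat))
  )
  protocol <- obj$protocol
  protocol$levels <- lev
  for (f in c("reps", "train_frac", "seed", "n_total", "n_train",
              "n_test", "n_resampled")) {
    protocol[[f]] <- as.numeric(protocol[[f]])
  }
  structure(
    list(accuracy = acc,
         rep_accuracies = reps[, c("rep", "classifier", "accuracy")],
         confusion = confusion, protocol = protocol),
    class = "motion_eval"
  )
}

#' Save / load a trained model
#'
#' Versioned portable container (RDS) holding the specification,
#' standardization statistics and fitted parameters.
#'
#' @param model A `motion_model`.
#' @param path File path.
#' @return `load_model()` returns a `motion_model`; `save_model()` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "motion_model"))
  saveRDS(list(format = "threadmotion-model/1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "threadmotion-model/1")) {
    stop("not a threadmotion model file", call. = FALSE)
  }
  obj$model
}

#' Read a motion script and generator configuration from YAML
#'
#' The configuration file has two top-level sections. `generator` holds
#' [generator_config()] fields (scalars, or two-element lists for the
#' per-channel fields); `script` is a list of steps, each with `target`,
#' `dwell_s` and `transition_s`:
#'
#' ```yaml
#' generator:
#'   seed: 7
#'   noise_sd: 5
#' script:
#'   - {target: left,  dwell_s: 2.0, transition_s: 1.1}
#'   - {target: front, dwell_s: 1.8, transition_s: 1.1}
#' ```
#'
#' Omitted generator fields keep their defaults; an omitted `script`
#' section falls back to [default_experiment_script()].
#'
#' @param path YAML file path.
#' @return A list with elements `script` (a `motion_script`) and `config`
#'   (a `generator_config`).
#' @export
read_simulation_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen_args <- obj$generator %||% list()
  gen_args <- lapply(gen_args, function(v) unlist(v))
  config <- do.call(generator_config, gen_args)
  script <- if (is.null(obj$script)) {
    default_experiment_script()
  } else {
    steps <- dplyr::bind_rows(lapply(obj$script, tibble::as_tibble))
    motion_script(steps$target, steps$dwell_s, steps$transition_s)
  }
  list(script = script, config = config)
}
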