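#' Repeated random-subsampling evaluation
#'
#' The evaluation protocol used throughout: for each of `reps` rounds, a
#' random `train_frac` share of the segments is selected as training data
#' (one shared split per round for all classifiers, so between-classifier
#' comparisons see identical data), every requested classifier is trained
#' on it and tested on the remainder, and per-round accuracies plus pooled
#' confusion matrices are accumulated. A round whose training split lacks
#' one of the classes present in the data is redrawn (and counted).
#'
#' @param features Feature table with a `label` column (e.g. from
#'   [extract_features()]).
#' @param specs Classifier names or [classifier_spec()] objects; default
#'   all nine configurations.
#' @param reps Number of rounds.
#' @param train_frac Fraction of segments used for training each round.
#' @param seed Integer seed making the whole evaluation reproducible.
#' @param feature_cols Predictor columns (see [fit_classifier()]).
#' @return A `motion_eval` object; see [tidy.motion_eval()] and
#'   [glance.motion_eval()].
#' @export
repeated_holdout <- function(features, specs = classifier_names(),
                             reps = 100, train_frac = 0.75, seed = 1,
                             feature_cols = NULL) {
  stopifnot(reps >= 1, train_frac > 0, train_frac < 1)
  specs <- lapply(specs, as_classifier_spec)
  spec_names <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(spec_names)) {
    stop("duplicated classifier specifications", call. = FALSE)
  }
  labs <- features$label
  if (is.null(labs) || anyNA(labs)) {
    stop("evaluation needs a complete label column", call. = FALSE)
  }
  lev <- if (all(labs %in% orientation_levels())) {
    orientation_levels()
  } else {
    sort(unique(as.character(labs)))
  }
  y <- factor(as.character(labs), levels = lev)
  n <- nrow(features)
  n_train <- round(train_frac * n)
  if (n_train < 1 || n_train >= n) {
    stop("train_frac leaves an empty training or test set", call. = FALSE)
  }
  if (nlevels(droplevels(y)) < 2) {
    stop("evaluation needs at least two classes", call. = FALSE)
  }
  present <- unique(as.character(y))
  n_resampled <- 0
  splits <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      for (try in 1:100) {
        idx <- sample.int(n, n_train)
        if (setequal(unique(as.character(y[idx])), present)) return(idx)
        n_resampled <<- n_resampled + 1
      }
      stop("could not draw a training split containing every class",
           call. = FALSE)
    })
  })
  if (n_resampled > 0) {
    rlang::inform(paste0(n_resampled,
                         " training split(s) redrawn to cover all classes"))
  }
  acc <- matrix(NA_real_, reps, length(specs),
                dimnames = list(NULL, spec_names))
  confusion <- lapply(specs, function(s) {
    matrix(0L, length(lev), length(lev), dimnames = list(true = lev,
                                                         predicted = lev))
  })
  names(confusion) <- spec_names
  for (r in seq_len(reps)) {
    idx <- splits[[r]]
    train <- features[idx, , drop = FALSE]
    test <- features[-idx, , drop = FALSE]
    y_test <- y[-idx]
    for (si in seq_along(specs)) {
      model <- fit_classifier(train, specs[[si]],
                              feature_cols = feature_cols)
      pred <- predict(model, test)
      pred <- factor(as.character(pred), levels = lev)
      acc[r, si] <- mean(pred == y_test)
      confusion[[si]] <- confusion[[si]] + table(y_test, pred)
    }
  }
  structure(
    list(
      accuracy = tibble::tibble(
        classifier = spec_names,
        mean_accuracy = unname(colMeans(acc)),
        pooled_accuracy = unname(vapply(confusion, function(m) {
          sum(diag(m)) / sum(m)
        }, numeric(1)))
      ),
      rep_accuracies = tidyr::pivot_longer(
        dplyr::mutate(tibble::as_tibble(acc), rep = dplyr::row_number()),
        -"rep", names_to = "classifier", values_to = "accuracy"
      ),
      confusion = confusion,
      protocol = list(reps = reps, train_frac = train_frac, seed = seed,
                      n_total = n, n_train = n_train,
                      n_test = n - n_train, n_resampled = n_resampled,
                      levels = lev)
    ),
    class = "motion_eval"
  )
}

#' Fraction of errors between axis-adjacent orientations
#'
#' Among all misclassified counts of a pooled confusion matrix, the
#' fraction whose (true, predicted) pair is adjacent along the horizontal
#' or vertical axis (see [adjacent_orientations()]). A matrix with no
#' errors returns 1 by convention (reported via a message): there are no
#' non-adjacent errors either.
#'
#' @param confusion A square confusion matrix with orientation dimnames.
#' @return Fraction in \[0, 1\].
#' @export
adjacency_error_fraction <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  lev <- rownames(confusion)
  off <- confusion
  diag(off) <- 0
  total <- sum(off)
  if (total == 0) {
    rlang::inform("confusion matrix has no errors; returning 1")
    return(1)
  }
  adj <- adjacent_orientations()
  adjacent_sum <- 0
  for (i in seq_len(nrow(adj))) {
    a <- adj$a[i]
    b <- adj$b[i]
    if (a %in% lev && b %in% lev) {
      adjacent_sum <- adjacent_sum + off[a, b] + off[b, a]
    }
  }
  adjacent_sum / total
}

#' @export
print.motion_eval <- function(x, ...) {
  p <- x$protocol
  cat("<motion_eval> ", p$reps, " x ", round(100 * p$train_frac), "/",
      round(100 * (1 - p$train_frac)), " repeated holdout on ",
      p$n_total, " segments\n", sep = "")
  df <- x$accuracy |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy)) |>
    dplyr::mutate(mean_accuracy = sprintf("%.1f%%",
                                          100 * .data$mean_accuracy))
  print(as.data.frame(df[, c("classifier", "mean_accuracy")]),
        row.names = FALSE)
  invisible(x)
}

#' Tidy a repeated-holdout evaluation
#'
#' @param x A `motion_eval`.
#' @param ... Unused.
#' @return One row per classifier: mean and pooled accuracy, standard
#'   deviation of per-round accuracies, and the adjacency fraction of its
#'   pooled errors.
#' @export
tidy.motion_eval <- function(x, ...) {
  sds <- x$rep_accuracies |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(sd_accuracy = stats::sd(.data$accuracy))
  adj <- vapply(x$confusion, function(m) {
    suppressMessages(adjacency_error_fraction(m))
  }, numeric(1))
  x$accuracy |>
    dplyr::left_join(sds, by = "classifier") |>
    dplyr::mutate(adjacent_error_fraction = adj[.data$classifier]) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy))
}

#' One-line summary of an evaluation
#'
#' @param x A `motion_eval`.
#' @param ... Unused.
#' @return A one-row tibble: protocol sizes, best/worst classifier and
#'   accuracy.
#' @export
glance.motion_eval <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    reps = x$protocol$reps,
    n_total = x$protocol$n_total,
    n_train = x$protocol$n_train,
    n_test = x$protocol$n_test,
    n_classifiers = nrow(td),
    best_classifier = td$classifier[1],
    best_accuracy = td$mean_accuracy[1],
    worst_classifier = td$classifier[nrow(td)],
    worst_accuracy = td$mean_accuracy[nrow(td)]
  )
}

#' Tidy a fitted classifier
#'
#' @param x A `motion_model`.
#' @param ... Unused.
#' @return One row per hyperparameter (name, value).
#' @export
tidy.motion_model <- function(x, ...) {
  h <- x$hyper
  if (length(h) == 0) {
    return(tibble::tibble(hyperparameter = character(),
                          value = character()))
  }
  tibble::tibble(
    hyperparameter = names(h),
    value = vapply(h, function(v) paste(format(v), collapse = ","),
                   character(1))
  )
}

#' One-line summary of a fitted classifier
#'
#' @param x A `motion_model`.
#' @param ... Unused.
#' @return A one-row tibble with the configuration name, predictor count
#'   and class count.
#' @export
glance.motion_model <- function(x, ...) {
  tibble::tibble(
    classifier = x$spec$name,
    n_predictors = length(x$feature_cols),
    n_classes = length(x$levels)
  )
}

#' Classify a recording segment by segment
#'
#' Streams a raw recording through the pipeline — filter, normalize,
#' segment, featurize — and predicts one orientation per segment with a
#' trained model, emulating on-line use where each newly completed window
#' is classified as it arrives.
#'
#' @param recording A raw `motion_recording`.
#' @param profile A `calibration_profile`.
#' @param model A `motion_model`.
#' @param config A [pipeline_config()].
#' @return A tibble with `start_time_s`, `predicted`, and (when the
#'   recording is labeled) the majority `label` of each segment.
#' @export
classify_stream <- function(recording, profile, model,
                            config = pipeline_config()) {
  feats <- compute_feature_table(recording, profile, config)
  tibble::tibble(
    start_time_s = feats$start_time_s,
    predicted = as.character(predict(model, feats)),
    label = feats$label
  )
}
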