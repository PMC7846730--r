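#' The nine classifier configurations
#'
#' @return Character vector of the nine supported classifier names.
#' @export
classifier_names <- function() {
  c("linear_svm", "quadratic_svm", "cubic_svm", "gaussian_svm",
    "gaussian_nb", "kernel_nb", "cosine_knn", "cubic_knn", "weighted_knn")
}

#' Build a classifier specification
#'
#' Fixed configurations mirroring a standard desktop classification
#' toolkit's presets: three SVMs with polynomial kernels of degree 1-3
#' (unit scale, box constraint `cost`), a Gaussian-kernel SVM whose kernel
#' scale is the square root of the number of predictors, Gaussian and
#' kernel naive Bayes, and three 10-nearest-neighbour variants (cosine
#' distance, cubic Minkowski distance, and Euclidean distance with
#' inverse-squared-distance vote weights). All SVMs use one-vs-one
#' multiclass reduction; features are standardized with training-split
#' statistics before SVM and KNN fits.
#'
#' @param name One of [classifier_names()].
#' @param k Neighbourhood size for the KNN variants.
#' @param cost SVM box constraint.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, k = 10, cost = 1) {
  name <- match.arg(name, classifier_names())
  hyper <- switch(
    name,
    linear_svm = list(kernel = "linear", cost = cost),
    quadratic_svm = list(kernel = "polynomial", degree = 2, gamma = 1,
                         coef0 = 1, cost = cost),
    cubic_svm = list(kernel = "polynomial", degree = 3, gamma = 1,
                     coef0 = 1, cost = cost),
    gaussian_svm = list(kernel = "radial", cost = cost),
    gaussian_nb = list(),
    kernel_nb = list(bandwidth = "silverman"),
    cosine_knn = list(k = k, metric = "cosine", weighting = "uniform"),
    cubic_knn = list(k = k, metric = "cubic", weighting = "uniform"),
    weighted_knn = list(k = k, metric = "euclidean",
                        weighting = "inverse_square")
  )
  structure(list(name = name, hyper = hyper), class = "classifier_spec")
}

as_classifier_spec <- function(spec) {
  if (inherits(spec, "classifier_spec")) spec else classifier_spec(spec)
}

resolve_feature_cols <- function(features, feature_cols) {
  if (!is.null(feature_cols)) return(feature_cols)
  canonical <- motion_feature_names()
  if (all(canonical %in% names(features))) return(canonical)
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  setdiff(num, c("start_index", "start_time_s"))
}

#' Train one classifier on a feature table
#'
#' Standardizes the predictors using training-set statistics (stored in
#' the returned model and re-applied at prediction time) and fits the
#' requested configuration. Deterministic given the data.
#'
#' @param features Data frame with predictor columns and a label column.
#' @param spec A [classifier_spec()] or a classifier name.
#' @param label_col Name of the label column.
#' @param feature_cols Predictor columns; defaults to the canonical six
#'   of [motion_feature_names()] when present, otherwise all numeric
#'   non-index columns.
#' @return A `motion_model`.
#' @export
#' @examples
#' feats <- tibble::tibble(
#'   x = c(0, 0.1, 1, 1.1), y = c(0, -0.1, 1, 0.9),
#'   label = c("a", "a", "b", "b")
#' )
#' m <- fit_classifier(feats, "linear_svm")
#' predict(m, feats)
fit_classifier <- function(features, spec, label_col = "label",
                           feature_cols = NULL) {
  spec <- as_classifier_spec(spec)
  feature_cols <- resolve_feature_cols(features, feature_cols)
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  if (anyNA(x)) stop("missing values in features", call. = FALSE)
  y <- features[[label_col]]
  if (is.null(y) || anyNA(y)) {
    stop("missing labels in training data", call. = FALSE)
  }
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  hyper <- spec$hyper
  fit <- switch(
    spec$name,
    linear_svm = ,
    quadratic_svm = ,
    cubic_svm = ,
    gaussian_svm = {
      if (spec$name == "gaussian_svm") {
        # kernel K(u, v) = exp(-||u - v||^2 / s^2), s = sqrt(p)
        hyper$kernel_scale <- sqrt(ncol(xs))
        hyper$gamma <- 1 / hyper$kernel_scale^2
      }
      args <- c(list(x = xs, y = y, type = "C-classification",
                     scale = FALSE),
                hyper[setdiff(names(hyper), "kernel_scale")])
      do.call(e1071::svm, args)
    },
    gaussian_nb = e1071::naiveBayes(as.data.frame(xs), y),
    kernel_nb = fit_kernel_nb(xs, y),
    cosine_knn = ,
    cubic_knn = ,
    weighted_knn = list(x = xs, y = y)
  )
  structure(
    list(spec = spec, hyper = hyper, centre = centre, scale = scale_,
         feature_cols = feature_cols, levels = levels(y), fit = fit),
    class = "motion_model"
  )
}

#' Predict orientations for new feature vectors
#'
#' @param object A `motion_model`.
#' @param new_data Data frame containing the model's predictor columns, or
#'   a numeric matrix with matching number of columns.
#' @param type `"class"` for labels; `"prob"` for class posteriors (naive
#'   Bayes models only).
#' @param ... Unused.
#' @return Factor of predicted orientations (or a posterior matrix).
#' @export
predict.motion_model <- function(object, new_data, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  if (is.data.frame(new_data)) {
    missing <- setdiff(object$feature_cols, names(new_data))
    if (length(missing) > 0) {
      stop("new data lacks feature column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(new_data[, object$feature_cols, drop = FALSE])
  } else {
    x <- as.matrix(new_data)
    if (ncol(x) != length(object$feature_cols)) {
      stop("expected ", length(object$feature_cols),
           " feature columns, got ", ncol(x), call. = FALSE)
    }
  }
  if (anyNA(x)) stop("missing values in features", call. = FALSE)
  xs <- sweep(sweep(x, 2, object$centre), 2, object$scale, "/")
  name <- object$spec$name
  if (name %in% c("cosine_knn", "cubic_knn", "weighted_knn")) {
    if (type == "prob") {
      stop("posterior probabilities are available for naive Bayes models",
           call. = FALSE)
    }
    return(knn_predict(object$fit$x, object$fit$y, xs,
                       k = object$hyper$k, metric = object$hyper$metric,
                       weighting = object$hyper$weighting))
  }
  if (name == "kernel_nb") {
    post <- predict_kernel_nb(object$fit, xs)
    if (type == "prob") return(post)
    return(factor(colnames(post)[max.col(post, ties.method = "first")],
                  levels = object$levels))
  }
  if (name == "gaussian_nb") {
    if (type == "prob") {
      return(stats::predict(object$fit, as.data.frame(xs), type = "raw"))
    }
    return(stats::predict(object$fit, as.data.frame(xs)))
  }
  if (type == "prob") {
    stop("posterior probabilities are available for naive Bayes models",
         call. = FALSE)
  }
  stats::predict(object$fit, xs)
}

# ---- KNN (production path: vectorized distance matrices) -----------------

knn_distance_matrix <- function(train_x, query_x, metric) {
  switch(
    metric,
    cosine = {
      qn <- sqrt(rowSums(query_x^2))
      tn <- sqrt(rowSums(train_x^2))
      s <- (query_x %*% t(train_x)) / outer(qn, tn)
      s[!is.finite(s)] <- 0   # zero-norm vectors: no direction, sim 0
      1 - s
    },
    cubic = {
      d3 <- matrix(0, nrow(query_x), nrow(train_x))
      for (j in seq_len(ncol(train_x))) {
        d3 <- d3 + abs(outer(query_x[, j], train_x[, j], "-"))^3
      }
      d3^(1 / 3)
    },
    euclidean = {
      d2 <- matrix(0, nrow(query_x), nrow(train_x))
      for (j in seq_len(ncol(train_x))) {
        d2 <- d2 + outer(query_x[, j], train_x[, j], "-")^2
      }
      sqrt(d2)
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

# Shared vote convention (documented, also used by the brute-force
# reference): neighbours are ranked by (distance, training index); vote
# ties are broken by the nearest neighbour carrying a tied label; a query
# coinciding with training points (distance 0) under inverse-squared-
# distance weighting takes the majority label among the coincident points.
knn_vote <- function(d, y, k, weighting) {
  ord <- order(d)
  nn <- ord[seq_len(min(k, length(d)))]
  labs <- as.character(y[nn])
  if (weighting == "inverse_square") {
    exact <- d[nn] < 1e-12
    if (any(exact)) {
      labs <- labs[exact]
      counts <- table(labs)
      winners <- names(counts)[counts == max(counts)]
      return(labs[match(TRUE, labs %in% winners)])
    }
    score <- tapply(1 / d[nn]^2, labs, sum)
  } else {
    score <- table(labs)
  }
  winners <- names(score)[score == max(score)]
  labs[match(TRUE, labs %in% winners)]
}

knn_predict <- function(train_x, train_y, query_x, k, metric, weighting) {
  d <- knn_distance_matrix(train_x, query_x, metric)
  out <- vapply(seq_len(nrow(query_x)),
                function(i) knn_vote(d[i, ], train_y, k, weighting),
                character(1))
  factor(out, levels = levels(train_y))
}

#' Brute-force K-nearest-neighbour reference
#'
#' Deliberately plain reference implementation used to cross-check the
#' production KNN path: distances are accumulated pairwise in explicit
#' loops and neighbours selected by a full sort. Supports cosine distance
#' (1 - cosine similarity), cubic Minkowski distance (exponent 3) and
#' Euclidean distance with uniform or inverse-squared-distance vote
#' weights, under the same deterministic tie-break convention as the
#' production path.
#'
#' @param train_x Numeric training matrix.
#' @param train_y Training labels.
#' @param query A single query vector.
#' @param k Neighbourhood size (<= rows of `train_x`).
#' @param metric `"cosine"`, `"cubic"` or `"euclidean"`.
#' @param weighting `"uniform"` or `"inverse_square"`.
#' @return Predicted label (character).
#' @export
knn_reference <- function(train_x, train_y, query, k,
                          metric = c("cosine", "cubic", "euclidean"),
                          weighting = c("uniform", "inverse_square")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  stopifnot(k >= 1, k <= nrow(train_x))
  n <- nrow(train_x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    a <- as.numeric(train_x[i, ])
    b <- as.numeric(query)
    d[i] <- switch(
      metric,
      cosine = {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0 || nb == 0) 1 else 1 - sum(a * b) / (na * nb)
      },
      cubic = {
        s <- 0
        for (j in seq_along(a)) s <- s + abs(b[j] - a[j])^3
        s^(1 / 3)
      },
      euclidean = {
        s <- 0
        for (j in seq_along(a)) s <- s + (b[j] - a[j])^2
        sqrt(s)
      }
    )
  }
  ord <- order(d)
  nn <- ord[seq_len(k)]
  labs <- as.character(train_y[nn])
  if (weighting == "inverse_square" && any(d[nn] < 1e-12)) {
    labs <- labs[d[nn] < 1e-12]
    counts <- table(labs)
    winners <- names(counts)[counts == max(counts)]
    return(labs[match(TRUE, labs %in% winners)])
  }
  score <- if (weighting == "inverse_square") {
    tapply(1 / d[nn]^2, labs, sum)
  } else {
    table(labs)
  }
  winners <- names(score)[score == max(score)]
  labs[match(TRUE, labs %in% winners)]
}

# ---- Kernel naive Bayes --------------------------------------------------

# Per-class, per-feature Gaussian kernel density estimates with
# normal-reference (Silverman) bandwidths.
fit_kernel_nb <- function(x, y) {
  classes <- levels(y)
  global_sd <- apply(x, 2, stats::sd)
  dens <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xc[, j]
      bw <- if (length(v) >= 2) stats::bw.nrd0(v) else 0
      if (!is.finite(bw) || bw <= 0) {
        bw <- max(1e-3 * global_sd[j], 1e-6)
      }
      list(values = v, bw = bw)
    })
  })
  names(dens) <- classes
  prior <- as.numeric(table(y)) / length(y)
  names(prior) <- classes
  list(classes = classes, prior = prior, dens = dens, p = ncol(x))
}

predict_kernel_nb <- function(fit, x) {
  nq <- nrow(x)
  logpost <- matrix(0, nq, length(fit$classes),
                    dimnames = list(NULL, fit$classes))
  for (ci in seq_along(fit$classes)) {
    cl <- fit$classes[ci]
    lp <- rep(log(fit$prior[[cl]]), nq)
    for (j in seq_len(fit$p)) {
      dj <- fit$dens[[cl]][[j]]
      f <- rowMeans(stats::dnorm(outer(x[, j], dj$values, "-"),
                                 sd = dj$bw))
      lp <- lp + log(pmax(f, 1e-300))
    }
    logpost[, ci] <- lp
  }
  post <- exp(logpost - apply(logpost, 1, max))
  post / rowSums(post)
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model> ", x$spec$name, "\n", sep = "")
  cat("  predictors: ", paste(x$feature_cols, collapse = ", "), "\n",
      sep = "")
  cat("  classes:    ", paste(x$levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
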