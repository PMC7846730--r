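#' Canonical feature names
#'
#' The six predictors computed from each segment, in canonical order:
#' per-channel segment means (`mu_slash`, `mu_backslash`), their
#' difference (`delta_mu = mu_slash - mu_backslash`), the Pearson
#' correlation between the channels (`rho`), and the per-channel min-max
#' ranges (`delta_slash`, `delta_backslash`).
#'
#' @return Character vector of length 6.
#' @export
motion_feature_names <- function() {
  c("mu_slash", "mu_backslash", "delta_mu", "rho",
    "delta_slash", "delta_backslash")
}

#' Segment mean
#' @param x Normalized samples of one channel within a segment.
#' @return Arithmetic mean.
#' @export
segment_mean <- function(x) {
  if (length(x) == 0) stop("empty segment", call. = FALSE)
  mean(x)
}

#' Difference in means
#'
#' The `backslash` channel's segment mean subtracted from the `slash`
#' channel's. Near zero for vertical motions (both threads move together)
#' and large in magnitude for horizontal ones.
#'
#' @param mu_slash,mu_backslash Per-channel segment means.
#' @return `mu_slash - mu_backslash`.
#' @export
mean_difference <- function(mu_slash, mu_backslash) mu_slash - mu_backslash

#' Between-channel correlation of a segment
#'
#' Pearson correlation between the two channels over the window. If either
#' channel is constant within the window the correlation is undefined; 0
#' (no linear relationship) is returned in that case.
#'
#' @param x_slash,x_backslash Channel samples, equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
segment_correlation <- function(x_slash, x_backslash) {
  if (length(x_slash) < 2 || length(x_backslash) < 2) {
    stop("correlation needs at least 2 samples", call. = FALSE)
  }
  if (stats::sd(x_slash) == 0 || stats::sd(x_backslash) == 0) return(0)
  stats::cor(x_slash, x_backslash)
}

#' Min-max range of a segment
#'
#' Absolute difference between the maximum and minimum sample within the
#' window; large during the rotating/flexing motion through intermediate
#' orientations, small while the head dwells at a settled position.
#'
#' @param x Channel samples, non-empty.
#' @return `max(x) - min(x)` (>= 0).
#' @export
minmax_range <- function(x) {
  if (length(x) == 0) stop("empty segment", call. = FALSE)
  max(x) - min(x)
}

#' Extract the six features from every segment
#'
#' Assembles the canonical feature vector for each row of a
#' [segment_stream()] result, carrying through segment start index, start
#' time and label for traceability.
#'
#' @param segments A `motion_segments` tibble.
#' @return A `motion_features` tibble with columns `start_index`,
#'   `start_time_s`, the six features of [motion_feature_names()], and
#'   `label`.
#' @export
extract_features <- function(segments) {
  if (!inherits(segments, "motion_segments")) {
    stop("expected a motion_segments object from segment_stream()",
         call. = FALSE)
  }
  feats <- segments |>
    dplyr::mutate(
      mu_slash = purrr::map_dbl(.data$ch_slash, segment_mean),
      mu_backslash = purrr::map_dbl(.data$ch_backslash, segment_mean),
      delta_mu = mean_difference(.data$mu_slash, .data$mu_backslash),
      rho = purrr::map2_dbl(.data$ch_slash, .data$ch_backslash,
                            segment_correlation),
      delta_slash = purrr::map_dbl(.data$ch_slash, minmax_range),
      delta_backslash = purrr::map_dbl(.data$ch_backslash, minmax_range)
    ) |>
    dplyr::select("start_index", "start_time_s",
                  dplyr::all_of(motion_feature_names()), "label")
  feats <- tibble::as_tibble(feats)
  for (a in c("window_len", "overlap_len", "sampling_rate")) {
    attr(feats, a) <- NULL
  }
  structure(feats, class = c("motion_features", class(tibble::tibble())))
}

#' Run the full feature pipeline on a raw recording
#'
#' Convenience chain: filter and normalize the raw recording against a
#' calibration profile, segment it, and extract the six features per
#' segment.
#'
#' @param recording A raw `motion_recording`.
#' @param profile A `calibration_profile` from [calibrate()].
#' @param config A [pipeline_config()].
#' @return A `motion_features` tibble.
#' @export
compute_feature_table <- function(recording, profile,
                                  config = pipeline_config()) {
  recording |>
    preprocess_recording(profile, config) |>
    segment_stream(config) |>
    extract_features()
}
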