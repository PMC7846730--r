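#' Pipeline configuration
#'
#' Filtering and windowing parameters of the processing pipeline. Defaults
#' follow the reference configuration: a 120-sample moving average at
#' 1 kHz, 550-sample segments (0.55 s) with 250 samples (0.25 s) of overlap
#' between adjacent segments, i.e. a hop of 300 samples.
#'
#' @param filter_len Moving-average length in samples (>= 1).
#' @param window_len Segment length in samples.
#' @param overlap_len Overlap between adjacent segments in samples
#'   (0 < overlap < window).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_len = 120,
                            window_len = 550,
                            overlap_len = 250,
                            sampling_rate = 1000) {
  cfg <- list(
    filter_len = as.integer(filter_len),
    window_len = as.integer(window_len),
    overlap_len = as.integer(overlap_len),
    sampling_rate = sampling_rate
  )
  if (cfg$filter_len < 1) stop("filter_len must be >= 1", call. = FALSE)
  if (cfg$overlap_len <= 0 || cfg$overlap_len >= cfg$window_len) {
    stop("need 0 < overlap_len < window_len", call. = FALSE)
  }
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  cfg$hop <- cfg$window_len - cfg$overlap_len
  structure(cfg, class = "pipeline_config")
}

#' Causal moving-average filter
#'
#' Smooths a signal with a trailing (causal) moving average:
#' `out[i] = mean(x[max(1, i - filter_len + 1) .. i])`. During warm-up the
#' window grows from one sample, so the output has the same length as the
#' input and needs no padding values. A causal filter uses no future
#' samples and therefore suits streaming use.
#'
#' @param x Numeric signal.
#' @param filter_len Window length in samples (>= 1).
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' moving_average(c(0, 3, 6), 2)  # 0, 1.5, 4.5
moving_average <- function(x, filter_len = 120) {
  filter_len <- as.integer(filter_len)
  if (is.na(filter_len) || filter_len < 1) {
    stop("filter_len must be >= 1", call. = FALSE)
  }
  n <- length(x)
  if (n == 0) stop("signal is empty", call. = FALSE)
  s <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - filter_len, 0L)
  (s[seq_len(n) + 1] - s[lo + 1]) / (seq_len(n) - lo)
}

#' Piecewise asymmetric normalization of one channel
#'
#' Maps raw impedance to the normalized scale anchored by the calibration
#' profile: the baseline (front-facing settled value) maps to 0, the
#' calibrated maximum to +1 and the calibrated minimum to -1. Values above
#' baseline are divided by `cal_max - baseline`, values below by
#' `baseline - cal_min`, so stretching and relaxing the thread — which
#' produce unequal raw impedance changes — are accounted equally. The map
#' is strictly increasing and continuous; values are *not* clipped to
#' \[-1, 1\] (the calibration extremes are empirical and can be exceeded);
#' the number of out-of-range samples is attached as attribute
#' `n_outside_unit`.
#'
#' @param x Raw signal (a.u.).
#' @param baseline,cal_max,cal_min Calibration anchors with
#'   `cal_min < baseline < cal_max`.
#' @return Normalized signal.
#' @export
#' @examples
#' normalize_channel(c(6, 10, 20, 8), baseline = 10, cal_max = 20, cal_min = 6)
normalize_channel <- function(x, baseline, cal_max, cal_min) {
  if (!(cal_min < baseline && baseline < cal_max)) {
    stop("degenerate calibration profile: need cal_min < baseline < cal_max",
         call. = FALSE)
  }
  s <- x - baseline
  out <- ifelse(s >= 0, s / (cal_max - baseline), s / (baseline - cal_min))
  n_out <- sum(out < -1 | out > 1)
  attr(out, "n_outside_unit") <- n_out
  out
}

#' Filter and normalize a recording
#'
#' Applies the causal moving average and the piecewise normalization to
#' both channels of a raw recording, using the per-channel anchors of a
#' [calibrate()] profile. If any normalized samples fall outside
#' \[-1, 1\] their count is reported via a message.
#'
#' @param recording A raw `motion_recording`.
#' @param profile A `calibration_profile`.
#' @param config A [pipeline_config()].
#' @return A normalized `motion_recording`.
#' @export
preprocess_recording <- function(recording, profile,
                                 config = pipeline_config()) {
  check_recording(recording)
  check_calibration_profile(profile)
  pr <- function(ch) profile[profile$channel == ch, ]
  out <- recording
  n_outside <- 0
  for (ch in c("slash", "backslash")) {
    col <- paste0("ch_", ch)
    p <- pr(ch)
    z <- normalize_channel(
      moving_average(recording[[col]], config$filter_len),
      p$baseline, p$cal_max, p$cal_min
    )
    n_outside <- n_outside + attr(z, "n_outside_unit")
    out[[col]] <- as.numeric(z)
  }
  if (n_outside > 0) {
    rlang::inform(paste0(n_outside,
                         " normalized sample(s) fall outside [-1, 1]"))
  }
  new_motion_recording(out, sampling_rate = sampling_rate(recording),
                       normalized = TRUE)
}

#' Divide a recording into overlapping segments
#'
#' Slices the two-channel stream into fixed-length windows: segment `k`
#' covers the 0-based half-open sample interval
#' `[k * hop, k * hop + window_len)` with `hop = window_len - overlap_len`;
#' a trailing partial window is discarded, so a stream of `N` samples
#' yields `floor((N - window_len) / hop) + 1` segments. When the recording
#' carries per-sample labels, each segment is labeled by the majority label
#' within its window; ties go to the label at the window's centre sample.
#'
#' @param recording A `motion_recording` (normally filtered and
#'   normalized).
#' @param config A [pipeline_config()].
#' @return A `motion_segments` tibble with columns `start_index` (0-based),
#'   `start_time_s`, list-columns `ch_slash` and `ch_backslash`, and
#'   `label`.
#' @export
segment_stream <- function(recording, config = pipeline_config()) {
  check_recording(recording)
  n <- nrow(recording)
  w <- config$window_len
  hop <- config$hop
  if (n < w) {
    stop("recording (", n, " samples) is shorter than one window (",
         w, " samples)", call. = FALSE)
  }
  n_seg <- (n - w) %/% hop + 1
  starts0 <- (seq_len(n_seg) - 1) * hop
  has_labels <- "label" %in% names(recording) &&
    !all(is.na(recording$label))
  seg_label <- function(s0) {
    if (!has_labels) return(NA_character_)
    lab <- recording$label[(s0 + 1):(s0 + w)]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) return(NA_character_)
    counts <- table(lab)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) return(winners)
    centre <- recording$label[s0 + w %/% 2 + 1]
    if (!is.na(centre) && centre %in% winners) centre else winners[1]
  }
  fs <- sampling_rate(recording)
  seg <- tibble::tibble(
    start_index = as.integer(starts0),
    start_time_s = starts0 / fs,
    ch_slash = purrr::map(starts0, ~ recording$ch_slash[(.x + 1):(.x + w)]),
    ch_backslash = purrr::map(starts0,
                              ~ recording$ch_backslash[(.x + 1):(.x + w)]),
    label = purrr::map_chr(starts0, seg_label)
  )
  structure(seg, class = c("motion_segments", class(tibble::tibble())),
            window_len = w, overlap_len = config$overlap_len,
            sampling_rate = fs)
}

check_recording <- function(recording) {
  if (!inherits(recording, "motion_recording")) {
    stop("expected a motion_recording", call. = FALSE)
  }
  invisible(recording)
}
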