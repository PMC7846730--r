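#' Calibration estimator parameters
#'
#' Tuning knobs of the calibration estimators. All thresholds are relative
#' to the observed signal, so calibration commutes with shifting or
#' rescaling the raw units.
#'
#' @param filter_len Moving-average length applied before estimation
#'   (samples).
#' @param min_dwell_s Minimum plateau duration (seconds).
#' @param flatness_window_s Length of the rolling window used to measure
#'   local flatness (seconds).
#' @param flatness_frac Plateau flatness threshold as a fraction of the
#'   filtered signal's observed range.
#' @param cluster_gap_frac Gap, as a fraction of the spread of plateau
#'   means, above which two plateau means belong to different level
#'   clusters.
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(filter_len = 120,
                               min_dwell_s = 1,
                               flatness_window_s = 0.25,
                               flatness_frac = 0.01,
                               cluster_gap_frac = 0.25) {
  structure(
    list(filter_len = as.integer(filter_len),
         min_dwell_s = min_dwell_s,
         flatness_window_s = flatness_window_s,
         flatness_frac = flatness_frac,
         cluster_gap_frac = cluster_gap_frac),
    class = "calibration_params"
  )
}

# Centred rolling standard deviation with edge-truncated windows, O(n) via
# cumulative sums. Population (1/n) denominator; only compared against a
# relative threshold.
rolling_sd <- function(x, half_window) {
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half_window, 1L)
  hi <- pmin(i + half_window, n)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  m <- hi - lo + 1
  mu <- (s1[hi + 1] - s1[lo]) / m
  v <- (s2[hi + 1] - s2[lo]) / m - mu^2
  sqrt(pmax(v, 0))
}

#' Detect settled plateaus in a filtered signal
#'
#' A plateau is a maximal run of samples, at least `min_dwell_s` long,
#' over which the centred rolling standard deviation (window
#' `flatness_window_s`) stays at or below the flatness threshold. The
#' default threshold is `flatness_frac` of the signal's observed range, so
#' a perfectly constant signal is one single plateau and a steady ramp
#' yields none.
#'
#' @param x Filtered numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param params A [calibration_params()].
#' @param flatness_threshold Absolute threshold override (a.u.); default
#'   derives from `params$flatness_frac`.
#' @return A tibble with 1-based inclusive sample indices `start`, `end`
#'   and the plateau `mean` (computed after trimming one flatness window
#'   from each edge, to exclude settling transients).
#' @export
detect_plateaus <- function(x, sampling_rate,
                            params = calibration_params(),
                            flatness_threshold = NULL) {
  stopifnot(params$min_dwell_s > 0, length(x) > 0)
  hw <- max(1L, round(params$flatness_window_s * sampling_rate / 2))
  if (is.null(flatness_threshold)) {
    flatness_threshold <- params$flatness_frac * diff(range(x))
  }
  flat <- rolling_sd(x, hw) <= flatness_threshold
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= params$min_dwell_s * sampling_rate
  starts <- starts[keep]
  ends <- ends[keep]
  trim <- 2 * hw
  mean_of <- function(s, e) {
    s2 <- min(s + trim, e)
    e2 <- max(e - trim, s2)
    mean(x[s2:e2])
  }
  tibble::tibble(
    start = as.integer(starts),
    end = as.integer(ends),
    mean = purrr::map2_dbl(starts, ends, mean_of)
  )
}

# Split sorted plateau means into clusters at gaps larger than
# gap_frac * spread; returns an integer cluster id per plateau.
cluster_plateau_means <- function(means, gap_frac) {
  ord <- order(means)
  sorted <- means[ord]
  spread <- diff(range(sorted))
  id_sorted <- if (length(sorted) == 1 || spread == 0) {
    rep(1L, length(sorted))
  } else {
    gaps <- diff(sorted)
    cumsum(c(1L, as.integer(gaps > gap_frac * spread)))
  }
  id <- integer(length(means))
  id[ord] <- id_sorted
  id
}

#' Estimate the front-facing baseline from plateaus
#'
#' The calibration protocol returns to the front position after every
#' excursion, so front dwells are the most frequent plateaus. Plateau
#' means are clustered along one dimension (split at gaps larger than a
#' fraction of their spread); the cluster with the most plateaus is taken
#' as the front level and its median plateau mean is the baseline.
#'
#' @param x Filtered signal (used only through `plateaus`).
#' @param plateaus Output of [detect_plateaus()].
#' @param params A [calibration_params()].
#' @return Baseline estimate (a.u.).
#' @export
estimate_baseline <- function(x, plateaus, params = calibration_params()) {
  if (nrow(plateaus) == 0) {
    stop("no settled plateaus found; record a longer calibration session ",
         "with clear front-facing pauses", call. = FALSE)
  }
  id <- cluster_plateau_means(plateaus$mean, params$cluster_gap_frac)
  counts <- table(id)
  front <- as.integer(names(counts)[which.max(counts)])
  stats::median(plateaus$mean[id == front])
}

#' Calibrated extremes of a signal
#'
#' The calibrated maximum and minimum are the global extremes of the
#' filtered calibration signal, reached when the head is pushed to the
#' limit of its range of motion.
#'
#' @param x Filtered signal, length >= 1.
#' @return Named numeric vector `c(cal_min, cal_max)`.
#' @export
estimate_extremes <- function(x) {
  stopifnot(length(x) >= 1)
  r <- range(x)
  if (r[1] == r[2]) {
    stop("signal is constant: no range of motion observed", call. = FALSE)
  }
  c(cal_min = r[1], cal_max = r[2])
}

#' Calibrate a two-channel recording
#'
#' Runs the full per-channel calibration: moving-average filtering, plateau
#' detection, baseline estimation from the front-level plateau cluster, and
#' extraction of the calibrated extremes. The resulting anchors satisfy
#' `cal_min < baseline < cal_max` or an error is raised.
#'
#' @param recording A raw `motion_recording` of a calibration session
#'   (excursions to all four extremes with front-facing returns).
#' @param params A [calibration_params()].
#' @return A `calibration_profile`: tibble with columns `channel`,
#'   `baseline`, `cal_max`, `cal_min`.
#' @export
#' @examples
#' rec <- generate_calibration_recording(generator_config(seed = 3))
#' calibrate(rec)
calibrate <- function(recording, params = calibration_params()) {
  check_recording(recording)
  fs <- sampling_rate(recording)
  one <- function(col) {
    filt <- moving_average(recording[[col]], params$filter_len)
    ext <- estimate_extremes(filt)
    plateaus <- detect_plateaus(filt, fs, params)
    base <- estimate_baseline(filt, plateaus, params)
    if (!(ext[["cal_min"]] < base && base < ext[["cal_max"]])) {
      stop("calibration failed for channel ", col,
           ": baseline does not lie strictly between the extremes ",
           "(recording may be missing excursions)", call. = FALSE)
    }
    c(baseline = base, ext)
  }
  s <- one("ch_slash")
  b <- one("ch_backslash")
  profile <- tibble::tibble(
    channel = c("slash", "backslash"),
    baseline = c(s[["baseline"]], b[["baseline"]]),
    cal_max = c(s[["cal_max"]], b[["cal_max"]]),
    cal_min = c(s[["cal_min"]], b[["cal_min"]])
  )
  structure(profile,
            class = c("calibration_profile", class(tibble::tibble())))
}

check_calibration_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("channel", "baseline", "cal_max", "cal_min") %in%
             names(profile)) ||
      !setequal(profile$channel, c("slash", "backslash"))) {
    stop("expected a calibration_profile with channels slash/backslash",
         call. = FALSE)
  }
  if (any(!(profile$cal_min < profile$baseline &
              profile$baseline < profile$cal_max))) {
    stop("degenerate calibration profile: need cal_min < baseline < cal_max",
         call. = FALSE)
  }
  invisible(profile)
}
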