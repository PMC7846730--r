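#' Configuration for the synthetic signal generator
#'
#' Bundles the physical parameters of the simulated sensor pair. Raw signals
#' are in arbitrary impedance units (a.u.), as delivered by the read-out
#' boards. A normalized level `l` maps to raw units as
#' `baseline_raw + l * span_pos` when `l >= 0` and
#' `baseline_raw + l * span_neg` when `l < 0`; `span_pos > span_neg`
#' reflects the threads' larger impedance change under stretch than under
#' relaxation.
#'
#' Randomness sources, all drawn from one generator seeded by `seed`:
#' per-sample Gaussian read-out noise (`noise_sd`), a slow linear drift
#' (`drift_rate`), Poisson-timed persistent step offsets emulating
#' spontaneous motion of the unsecured thread middles (`jump_prob` per
#' second, offsets with sd `jump_sd`), per-dwell level jitter emulating
#' imperfect repetition of a head pose (`level_jitter_sd`, normalized
#' units), and a slow common-mode micromotion shared by both channels
#' emulating small involuntary posture sway (`micro_sd` normalized units,
#' smoothed over `micro_smooth` samples).
#'
#' @param sampling_rate Samples per second (Hz).
#' @param baseline_raw Length-2 numeric, raw front-facing level of the
#'   `slash` and `backslash` channels (a.u.).
#' @param span_pos,span_neg Length-2 numeric, raw distance from baseline to
#'   the calibrated maximum / minimum per channel (a.u., both positive).
#' @param noise_sd Per-sample read-out noise standard deviation (a.u.).
#' @param drift_rate Linear drift (a.u. per second), applied to both channels.
#' @param jump_prob Expected number of spontaneous jumps per second.
#' @param jump_sd Standard deviation of a jump offset (a.u.).
#' @param level_jitter_sd Per-dwell jitter of the settled level (normalized
#'   units).
#' @param micro_sd Standard deviation of common-mode micromotion (normalized
#'   units).
#' @param micro_smooth Smoothing length of the micromotion process (samples).
#' @param intermediate_band Fraction of a front-to-extreme transition
#'   labeled as the intermediate orientation (centred band; default 0.6).
#' @param seed Integer seed; identical configurations produce identical
#'   recordings.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate = 1000,
                             baseline_raw = c(500, 460),
                             span_pos = c(200, 180),
                             span_neg = c(120, 110),
                             noise_sd = 5,
                             drift_rate = 0.02,
                             jump_prob = 0.02,
                             jump_sd = 1.5,
                             level_jitter_sd = 0.04,
                             micro_sd = 0.01,
                             micro_smooth = 250,
                             intermediate_band = 0.6,
                             seed = 1L) {
  rec2 <- function(x) if (length(x) == 1) rep(x, 2) else x
  cfg <- list(
    sampling_rate = sampling_rate,
    baseline_raw = rec2(baseline_raw),
    span_pos = rec2(span_pos),
    span_neg = rec2(span_neg),
    noise_sd = noise_sd,
    drift_rate = drift_rate,
    jump_prob = jump_prob,
    jump_sd = jump_sd,
    level_jitter_sd = level_jitter_sd,
    micro_sd = micro_sd,
    micro_smooth = as.integer(micro_smooth),
    intermediate_band = intermediate_band,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$sampling_rate > 0,
    all(cfg$span_pos > 0), all(cfg$span_neg > 0),
    cfg$noise_sd >= 0, cfg$jump_prob >= 0, cfg$jump_sd >= 0,
    cfg$level_jitter_sd >= 0, cfg$micro_sd >= 0,
    cfg$intermediate_band >= 0, cfg$intermediate_band < 1,
    length(cfg$baseline_raw) == 2
  )
  structure(cfg, class = "generator_config")
}

#' A noise-free generator configuration
#'
#' Convenience wrapper switching off every stochastic component (read-out
#' noise, drift, jumps, level jitter, micromotion), used for limit checks
#' such as exact calibration recovery.
#'
#' @param ... Passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
noiseless_config <- function(...) {
  generator_config(noise_sd = 0, drift_rate = 0, jump_prob = 0, jump_sd = 0,
                   level_jitter_sd = 0, micro_sd = 0, ...)
}

#' Build a motion script
#'
#' A motion script is the ordered protocol a (simulated) subject follows:
#' each step names a target orientation, how long to hold it (`dwell_s`),
#' and how long the movement into it takes (`transition_s`). The motion
#' starts from the front-facing position. A step whose target equals the
#' current orientation may have `transition_s = 0`; any actual movement
#' needs a strictly positive transition time. Consecutive targets must lie
#' on a common axis and may not jump across `front`.
#'
#' @param target Character vector of orientation names.
#' @param dwell_s Numeric vector of dwell durations (seconds, > 0).
#' @param transition_s Numeric vector of transition durations (seconds).
#' @return A tibble of class `motion_script`.
#' @export
#' @examples
#' motion_script(
#'   target = c("left", "front", "right", "front"),
#'   dwell_s = 2, transition_s = 1.1
#' )
motion_script <- function(target, dwell_s, transition_s) {
  script <- tibble::tibble(
    target = as.character(target),
    dwell_s = as.numeric(dwell_s),
    transition_s = as.numeric(transition_s)
  )
  class(script) <- c("motion_script", class(script))
  validate_motion_script(script)
}

validate_motion_script <- function(script) {
  if (nrow(script) == 0) stop("motion script is empty", call. = FALSE)
  unknown <- setdiff(script$target, orientation_levels())
  if (length(unknown) > 0) {
    stop("unknown orientation(s) in script: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(script$dwell_s <= 0)) {
    stop("dwell durations must be strictly positive", call. = FALSE)
  }
  if (any(script$transition_s < 0)) {
    stop("transition durations must be non-negative", call. = FALSE)
  }
  prev <- "front"
  for (i in seq_len(nrow(script))) {
    tgt <- script$target[i]
    if (tgt != prev) {
      path <- tryCatch(orientation_path(prev, tgt), error = function(e) e)
      if (inherits(path, "error")) {
        stop("step ", i, " (", prev, " -> ", tgt, "): ",
             conditionMessage(path), call. = FALSE)
      }
      if (script$transition_s[i] <= 0) {
        stop("step ", i, " (", prev, " -> ", tgt,
             "): moving steps need transition_s > 0", call. = FALSE)
      }
    }
    prev <- tgt
  }
  script
}

#' The default experimental motion protocol
#'
#' Reproduces the session layout used throughout the package's worked
#' examples: five repeats of front -> left -> front -> right -> front,
#' followed by five repeats of the same pattern on the vertical axis
#' (down / up). With the default timing (2 s extreme dwells, 1.8 s front
#' dwells, 1.1 s transitions, plus a short initial front hold) the protocol
#' lasts 120.25 s, which at 1 kHz segments into exactly 400 windows of 550
#' samples with hop 300.
#'
#' @param repeats Repeats per axis (default 5).
#' @param extreme_dwell_s,front_dwell_s,transition_s Timing of each leg.
#' @param lead_in_s Initial front-facing hold before the first motion.
#' @return A `motion_script`.
#' @export
default_experiment_script <- function(repeats = 5,
                                      extreme_dwell_s = 2.0,
                                      front_dwell_s = 1.8,
                                      transition_s = 1.1,
                                      lead_in_s = 0.25) {
  one_axis <- function(neg, pos) {
    tibble::tibble(
      target = rep(c(neg, "front", pos, "front"), repeats),
      dwell_s = rep(c(extreme_dwell_s, front_dwell_s), 2 * repeats),
      transition_s = transition_s
    )
  }
  steps <- dplyr::bind_rows(
    tibble::tibble(target = "front", dwell_s = lead_in_s, transition_s = 0),
    one_axis("left", "right"),
    one_axis("down", "up")
  )
  motion_script(steps$target, steps$dwell_s, steps$transition_s)
}

# Raised-cosine interpolation fraction for progress p in [0, 1].
raised_cosine <- function(p) (1 - cos(pi * p)) / 2

# Piecewise raised-cosine level path for one transition. `chain_levels` is
# an (m x 2) matrix of channel levels of the orientations traversed
# (m = 2 or 3); returns an (n x 2) matrix over n samples. Each leg of the
# chain receives an equal share of the transition time, and the path passes
# exactly through the intermediate orientation's level at the leg boundary.
transition_levels <- function(chain_levels, n) {
  m <- nrow(chain_levels)
  p <- seq_len(n) / n
  leg <- pmin(floor(p * (m - 1) - 1e-12) + 1, m - 1)
  p_leg <- p * (m - 1) - (leg - 1)
  f <- raised_cosine(p_leg)
  lev_from <- chain_levels[leg, , drop = FALSE]
  lev_to <- chain_levels[leg + 1, , drop = FALSE]
  lev_from + f * (lev_to - lev_from)
}

# Per-sample labels for one transition. Chains of length 3 (front <->
# extreme) carry the intermediate orientation over the central `band`
# fraction of the traversal; chains of length 2 switch labels at midpoint.
transition_labels <- function(chain, n, band) {
  p <- seq_len(n) / n
  if (length(chain) == 3) {
    lo <- 0.5 - band / 2
    hi <- 0.5 + band / 2
    out <- rep(chain[2], n)
    out[p <= lo] <- chain[1]
    out[p > hi] <- chain[3]
  } else {
    out <- ifelse(p <= 0.5, chain[1], chain[2])
  }
  out
}

# Smoothed common-mode micromotion: moving-average-filtered white noise
# rescaled to the requested sd.
micromotion <- function(n, sd, smooth) {
  if (sd <= 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n + smooth)
  m <- (cumsum(w)[(smooth + 1):(n + smooth)] -
          c(0, cumsum(w))[1:n]) / smooth
  m * sd / (1 / sqrt(smooth))
}

level_to_raw <- function(level, baseline, span_pos, span_neg) {
  baseline + ifelse(level >= 0, level * span_pos, level * span_neg)
}

# Core generator: turns a per-sample normalized level matrix plus labels
# into a raw two-channel recording by inverting the normalization map and
# layering noise, drift and jumps. Must run inside an active seed context.
assemble_recording <- function(levels, labels, config) {
  n <- nrow(levels)
  fs <- config$sampling_rate
  t_s <- (seq_len(n) - 1) / fs
  micro <- micromotion(n, config$micro_sd, config$micro_smooth)
  raw <- matrix(0, n, 2)
  for (ch in 1:2) {
    # the head cannot move past its range-of-motion limit, so instantaneous
    # levels (pose + sway) are bounded by the full-range extremes
    lev <- pmin(pmax(levels[, ch] + micro, -1), 1)
    x <- level_to_raw(lev, config$baseline_raw[ch],
                      config$span_pos[ch], config$span_neg[ch])
    x <- x + config$drift_rate * t_s
    n_jump <- stats::rpois(1, config$jump_prob * n / fs)
    if (n_jump > 0) {
      at <- sort(sample.int(n, n_jump, replace = TRUE))
      off <- stats::rnorm(n_jump, 0, config$jump_sd)
      step <- numeric(n)
      step[at] <- step[at] + off   # duplicated times accumulate
      x <- x + cumsum(step)
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    raw[, ch] <- x
  }
  rec <- tibble::tibble(
    time_s = t_s,
    ch_slash = raw[, 1],
    ch_backslash = raw[, 2],
    label = labels
  )
  new_motion_recording(rec, sampling_rate = fs)
}

new_motion_recording <- function(df, sampling_rate, normalized = FALSE) {
  structure(
    df,
    class = c("motion_recording", class(tibble::tibble())),
    sampling_rate = sampling_rate,
    normalized = normalized
  )
}

#' Sampling rate of a recording
#' @param recording A `motion_recording`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(recording) attr(recording, "sampling_rate")

#' Simulate a labeled two-channel impedance recording
#'
#' Executes a [motion_script()] against the per-orientation level profiles,
#' producing a raw (uncalibrated, unnormalized) two-channel recording with
#' per-sample orientation labels. Dwells sit at the orientation's level
#' (plus per-dwell jitter); transitions follow a raised-cosine path routed
#' through the intermediate orientation lying between front and an extreme,
#' and samples in the central band of such a traversal are labeled with the
#' intermediate orientation — intermediate-labeled spans therefore carry
#' the steep slopes and large within-window ranges characteristic of the
#' rotating/flexing motion itself. All randomness derives from
#' `config$seed`, so identical inputs yield bit-identical recordings.
#'
#' @param script A `motion_script`.
#' @param profiles Orientation level profiles, as
#'   [default_orientation_profiles()].
#' @param config A [generator_config()].
#' @return A `motion_recording` tibble with columns `time_s`, `ch_slash`,
#'   `ch_backslash`, `label` (raw impedance units).
#' @export
#' @examples
#' rec <- generate_recording(
#'   motion_script("front", 0.8, 0),
#'   config = generator_config(seed = 7)
#' )
#' head(rec)
generate_recording <- function(script,
                               profiles = default_orientation_profiles(),
                               config = generator_config()) {
  script <- validate_motion_script(script)
  check_profiles(profiles)
  stopifnot(inherits(config, "generator_config"))
  fs <- config$sampling_rate
  lev_of <- function(orient) {
    i <- match(orient, profiles$orientation)
    c(profiles$level_slash[i], profiles$level_backslash[i])
  }
  withr::with_seed(config$seed, {
    pieces_lev <- list()
    pieces_lab <- list()
    prev_orient <- "front"
    prev_lev <- lev_of("front")
    for (i in seq_len(nrow(script))) {
      tgt <- script$target[i]
      n_t <- round(script$transition_s[i] * fs)
      n_d <- round(script$dwell_s[i] * fs)
      tgt_lev <- lev_of(tgt) +
        stats::rnorm(2, 0, config$level_jitter_sd)
      if (tgt == prev_orient || n_t == 0) {
        # no motion: hold the previous level through any nominal transition
        tgt_lev <- prev_lev
        n_d <- n_d + n_t
        n_t <- 0
      } else {
        chain <- orientation_path(prev_orient, tgt)
        chain_lev <- rbind(prev_lev,
                           if (length(chain) == 3) {
                             lev_of(chain[2]) +
                               stats::rnorm(2, 0, config$level_jitter_sd)
                           },
                           tgt_lev)
        pieces_lev[[length(pieces_lev) + 1]] <-
          transition_levels(chain_lev, n_t)
        pieces_lab[[length(pieces_lab) + 1]] <-
          transition_labels(chain, n_t, config$intermediate_band)
      }
      pieces_lev[[length(pieces_lev) + 1]] <-
        matrix(tgt_lev, n_d, 2, byrow = TRUE)
      pieces_lab[[length(pieces_lab) + 1]] <- rep(tgt, n_d)
      prev_orient <- tgt
      prev_lev <- tgt_lev
    }
    levels <- do.call(rbind, pieces_lev)
    labels <- unlist(pieces_lab, use.names = FALSE)
    assemble_recording(levels, labels, config)
  })
}

#' Simulate a calibration recording
#'
#' Emulates the calibration protocol: starting front-facing, the subject
#' pushes the head to each of the four extremes (left, right, down, up) in
#' turn, each time to the greatest extent possible and each time returning
#' to and settling at the front position; the whole round is repeated
#' `reps` times. Full-range excursions drive each channel to its calibrated
#' extremes (normalized levels +1/-1), so in the noiseless limit the global
#' maximum and minimum of a channel equal `baseline_raw + span_pos` and
#' `baseline_raw - span_neg` exactly. Excursions carry no per-dwell level
#' jitter (the range-of-motion limit is a repeatable physical stop);
#' noise, drift, jumps and micromotion apply as configured.
#'
#' The true generating parameters are attached as attribute
#' `ground_truth` (a tibble with per-channel `baseline`, `cal_max`,
#' `cal_min`) for parameter-recovery experiments.
#'
#' @param config A [generator_config()].
#' @param reps Number of rounds over the four extremes (>= 1).
#' @param extreme_dwell_s,front_dwell_s,transition_s Timing of each leg.
#' @return An unlabeled `motion_recording` with attribute `ground_truth`.
#' @export
generate_calibration_recording <- function(config = generator_config(),
                                           reps = 3,
                                           extreme_dwell_s = 1.5,
                                           front_dwell_s = 1.5,
                                           transition_s = 0.6) {
  stopifnot(inherits(config, "generator_config"))
  if (reps < 1) stop("calibration needs at least one round of excursions",
                     call. = FALSE)
  fs <- config$sampling_rate
  # full-range excursion levels per channel: horizontal anti-correlated,
  # vertical correlated
  excursions <- list(
    left = c(1, -1), right = c(-1, 1), down = c(-1, -1), up = c(1, 1)
  )
  n_t <- round(transition_s * fs)
  n_de <- round(extreme_dwell_s * fs)
  n_df <- round(front_dwell_s * fs)
  withr::with_seed(config$seed + 1L, {
    pieces <- list(matrix(0, n_df, 2))
    for (r in seq_len(reps)) {
      for (lev in excursions) {
        pieces[[length(pieces) + 1]] <-
          transition_levels(rbind(c(0, 0), lev), n_t)
        pieces[[length(pieces) + 1]] <- matrix(lev, n_de, 2, byrow = TRUE)
        pieces[[length(pieces) + 1]] <-
          transition_levels(rbind(lev, c(0, 0)), n_t)
        pieces[[length(pieces) + 1]] <- matrix(0, n_df, 2)
      }
    }
    levels <- do.call(rbind, pieces)
    rec <- assemble_recording(levels, rep(NA_character_, nrow(levels)),
                              config)
    attr(rec, "ground_truth") <- tibble::tibble(
      channel = c("slash", "backslash"),
      baseline = config$baseline_raw,
      cal_max = config$baseline_raw + config$span_pos,
      cal_min = config$baseline_raw - config$span_neg
    )
    rec
  })
}
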