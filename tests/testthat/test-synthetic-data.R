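test_that("orientation taxonomy has nine members with axis adjacency", {
  lev <- orientation_levels()
  expect_length(lev, 9)
  expect_true("front" %in% lev)
  adj <- adjacent_orientations()
  expect_equal(nrow(adj), 8)
  expect_setequal(unique(c(adj$a, adj$b)), lev)
})

test_that("default profiles respect the documented per-orientation bands", {
  p <- default_orientation_profiles()
  expect_setequal(p$orientation, orientation_levels())
  lev <- function(o, ch) p[[ch]][p$orientation == o]
  expect_equal(lev("front", "level_slash"), 0)
  expect_equal(lev("front", "level_backslash"), 0)
  # "/" channel bands across the horizontal axis
  expect_true(lev("right", "level_slash") >= -1 &&
                lev("right", "level_slash") <= -0.8)
  expect_true(lev("front_right", "level_slash") >= -0.8 &&
                lev("front_right", "level_slash") <= -0.2)
  expect_true(lev("front_left", "level_slash") >= 0.2 &&
                lev("front_left", "level_slash") <= 0.6)
  expect_true(lev("left", "level_slash") >= 0.4 &&
                lev("left", "level_slash") <= 1)
  # "\" channel: opposite ordering
  expect_true(lev("right", "level_backslash") >= 0.3 &&
                lev("right", "level_backslash") <= 1)
  expect_true(lev("left", "level_backslash") >= -1 &&
                lev("left", "level_backslash") <= -0.8)
  horiz <- c("left", "front_left", "front", "front_right", "right")
  s <- vapply(horiz, lev, numeric(1), ch = "level_slash")
  b <- vapply(horiz, lev, numeric(1), ch = "level_backslash")
  expect_true(all(diff(s) < 0))
  expect_true(all(diff(b) > 0))
  # vertical axis: both channels monotone increasing from down to up
  vert <- c("down", "front_down", "front", "front_up", "up")
  expect_true(all(diff(vapply(vert, lev, numeric(1),
                              ch = "level_slash")) > 0))
  expect_true(all(diff(vapply(vert, lev, numeric(1),
                              ch = "level_backslash")) > 0))
  expect_setequal(p$orientation[p$is_intermediate],
                  c("front_left", "front_right", "front_up", "front_down"))
})

test_that("a noiseless front-only script is constant at baseline", {
  cfg <- noiseless_config(seed = 5)
  rec <- generate_recording(motion_script("front", 1, 0), config = cfg)
  expect_equal(nrow(rec), 1000)
  expect_true(all(rec$ch_slash == cfg$baseline_raw[1]))
  expect_true(all(rec$ch_backslash == cfg$baseline_raw[2]))
  expect_true(all(rec$label == "front"))
})

test_that("generation is deterministic for identical config and seed", {
  cfg <- generator_config(seed = 42)
  script <- motion_script(c("left", "front"), c(0.5, 0.5), c(0.3, 0.3))
  r1 <- generate_recording(script, config = cfg)
  r2 <- generate_recording(script, config = cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  c1 <- generate_calibration_recording(cfg)
  c2 <- generate_calibration_recording(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("noiseless dwell levels invert through normalization", {
  cfg <- noiseless_config(seed = 1)
  profiles <- default_orientation_profiles()
  truth <- list(
    ch_slash = c(cfg$baseline_raw[1], cfg$baseline_raw[1] + cfg$span_pos[1],
                 cfg$baseline_raw[1] - cfg$span_neg[1]),
    ch_backslash = c(cfg$baseline_raw[2],
                     cfg$baseline_raw[2] + cfg$span_pos[2],
                     cfg$baseline_raw[2] - cfg$span_neg[2])
  )
  for (o in orientation_levels()) {
    rec <- generate_recording(motion_script(o, 0.2, 0.2), config = cfg)
    last <- nrow(rec)
    for (ch in c("ch_slash", "ch_backslash")) {
      anchors <- truth[[ch]]
      lev <- normalize_channel(rec[[ch]][last], anchors[1], anchors[2],
                               anchors[3])
      want <- profiles[[if (ch == "ch_slash") "level_slash" else
        "level_backslash"]][profiles$orientation == o]
      expect_equal(as.numeric(lev), want, tolerance = 1e-9)
    }
  }
})

test_that("channel correlation is negative for horizontal, positive for vertical motion", {
  cfg <- noiseless_config(seed = 2)
  horiz <- motion_script(rep(c("left", "front", "right", "front"), 3),
                         0.4, 0.3)
  vert <- motion_script(rep(c("down", "front", "up", "front"), 3),
                        0.4, 0.3)
  rh <- generate_recording(horiz, config = cfg)
  rv <- generate_recording(vert, config = cfg)
  expect_lte(cor(rh$ch_slash, rh$ch_backslash), 0)
  expect_gte(cor(rv$ch_slash, rv$ch_backslash), 0)
})

test_that("transitions carry intermediate labels with steep slopes", {
  cfg <- noiseless_config(seed = 3)
  rec <- generate_recording(motion_script(c("left", "front"), 0.5, 0.5),
                            config = cfg)
  expect_true("front_left" %in% rec$label)
  # intermediate-labeled spans change much more than dwell spans
  rng <- function(lab) {
    x <- rec$ch_slash[rec$label == lab]
    max(x) - min(x)
  }
  expect_gt(rng("front_left"), 2 * rng("left"))
})

test_that("invalid scripts are rejected with the offending step named", {
  expect_error(motion_script(character(), numeric(), numeric()), "empty")
  expect_error(motion_script(c("left", "up"), c(1, 1), c(0.5, 0.5)),
               "step 2")
  expect_error(motion_script(c("left", "right"), c(1, 1), c(0.5, 0.5)),
               "step 2.*front")
  expect_error(motion_script("left", 1, 0), "transition_s > 0")
  expect_error(motion_script("left", -1, 0.5), "positive")
  expect_error(motion_script("sideways", 1, 0.5), "unknown orientation")
})

test_that("calibration recording reaches the exact extremes when noiseless", {
  cfg <- noiseless_config(seed = 4)
  rec <- generate_calibration_recording(cfg)
  expect_equal(max(rec$ch_slash), cfg$baseline_raw[1] + cfg$span_pos[1])
  expect_equal(min(rec$ch_slash), cfg$baseline_raw[1] - cfg$span_neg[1])
  expect_equal(max(rec$ch_backslash),
               cfg$baseline_raw[2] + cfg$span_pos[2])
  truth <- attr(rec, "ground_truth")
  expect_equal(truth$baseline, cfg$baseline_raw)
  expect_error(generate_calibration_recording(cfg, reps = 0),
               "at least one")
})
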