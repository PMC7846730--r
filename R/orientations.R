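#' The nine head orientations
#'
#' The system classifies head position into nine orientations arranged along
#' two axes through the neutral front-facing position: rotation along the
#' horizontal axis (`left`, `front_left`, `front`, `front_right`, `right`)
#' and flexion along the vertical axis (`down`, `front_down`, `front`,
#' `front_up`, `up`). `front` is shared between the axes. The four
#' `front_*` positions are *intermediate* orientations: they are traversed
#' while the head is rotating or flexing and are characterised by steep
#' signal slopes rather than settled levels.
#'
#' The canonical ordering returned here (horizontal axis left to right, then
#' the vertical axis) is used for confusion-matrix rows and columns so that
#' reports diff stably.
#'
#' @return Character vector of the nine orientation names in canonical order.
#' @export
#' @examples
#' orientation_levels()
orientation_levels <- function() {
  c(
    "left", "front_left", "front", "front_right", "right",
    "front_up", "up", "front_down", "down"
  )
}

# Signed coordinate of each orientation along its axis: extremes at +/-2,
# intermediates at +/-1, front at 0. Used for script validation and for
# routing transitions through the intermediate position they traverse.
orientation_axis_coord <- function() {
  tibble::tribble(
    ~orientation,  ~axis,        ~coord,
    "left",        "horizontal", -2,
    "front_left",  "horizontal", -1,
    "front",       "horizontal",  0,
    "front_right", "horizontal",  1,
    "right",       "horizontal",  2,
    "down",        "vertical",   -2,
    "front_down",  "vertical",   -1,
    "front",       "vertical",    0,
    "front_up",    "vertical",    1,
    "up",          "vertical",    2
  )
}

#' Axis-adjacent orientation pairs
#'
#' Two orientations are adjacent when they sit next to each other along one
#' axis (e.g. `left` and `front_left`, or `front` and `front_down`). Most
#' classification errors in practice fall between adjacent orientations,
#' which [adjacency_error_fraction()] quantifies.
#'
#' @return A tibble with columns `a` and `b`, one row per unordered adjacent
#'   pair (8 pairs).
#' @export
adjacent_orientations <- function() {
  tibble::tribble(
    ~a,            ~b,
    "left",        "front_left",
    "front_left",  "front",
    "front",       "front_right",
    "front_right", "right",
    "down",        "front_down",
    "front_down",  "front",
    "front",       "front_up",
    "front_up",    "up"
  )
}

# The chain of orientations traversed when moving from `from` to `to`.
# Both must lie on a common axis and the path must not cross front unless
# front is an endpoint (a natural head motion returns to front between
# excursions to opposite sides). Returns a character vector of length 2
# (directly adjacent) or 3 (an intermediate orientation lies between).
orientation_path <- function(from, to) {
  coords <- orientation_axis_coord()
  shared <- intersect(coords$axis[coords$orientation == from],
                      coords$axis[coords$orientation == to])
  if (length(shared) == 0) {
    stop("orientations '", from, "' and '", to,
         "' lie on different axes; return to 'front' between them",
         call. = FALSE)
  }
  axis <- shared[[1]]
  ax <- coords[coords$axis == axis, ]
  c_from <- ax$coord[ax$orientation == from]
  c_to <- ax$coord[ax$orientation == to]
  if (c_from * c_to < 0) {
    stop("transition '", from, "' -> '", to,
         "' crosses 'front'; script 'front' as an explicit step",
         call. = FALSE)
  }
  lo <- min(c_from, c_to)
  hi <- max(c_from, c_to)
  chain <- ax$orientation[ax$coord >= lo & ax$coord <= hi]
  chain <- chain[order(ax$coord[ax$coord >= lo & ax$coord <= hi])]
  if (c_from > c_to) chain <- rev(chain)
  chain
}

#' Default normalized signal levels for each orientation
#'
#' Each orientation is associated with a settled, normalized level on each
#' sensor channel (the `"/"` and `"\"` threads crossed on the back of the
#' neck). Levels live on the normalized scale where the front-facing
#' baseline is 0 and the calibrated extremes are -1/+1. Horizontal motion
#' stretches one thread while relaxing the other, so the two channels have
#' opposite ordering across the horizontal axis; vertical motion drives both
#' threads together, so the vertical levels share one ordering and increase
#' monotonically from `down` to `up`.
#'
#' The horizontal levels are placed inside the per-orientation segment-mean
#' bands observed for this sensor layout (e.g. the `/` channel near -0.9
#' when facing right, near +0.7 when facing left). The vertical levels are
#' a design choice constrained only by monotonicity, with a small asymmetry
#' between channels to mimic imperfect thread matching.
#'
#' @return A tibble with columns `orientation`, `level_slash`,
#'   `level_backslash`, `is_intermediate`.
#' @export
#' @examples
#' default_orientation_profiles()
default_orientation_profiles <- function() {
  tibble::tribble(
    ~orientation,  ~level_slash, ~level_backslash, ~is_intermediate,
    "left",               0.70,            -0.90,  FALSE,
    "front_left",         0.40,            -0.60,  FALSE,
    "front",              0.00,             0.00,  FALSE,
    "front_right",       -0.50,             0.05,  FALSE,
    "right",             -0.90,             0.65,  FALSE,
    "front_up",           0.45,             0.42,  FALSE,
    "up",                 0.80,             0.75,  FALSE,
    "front_down",        -0.45,            -0.42,  FALSE,
    "down",              -0.90,            -0.85,  FALSE
  ) |>
    dplyr::mutate(is_intermediate = .data$orientation %in%
                    c("front_left", "front_right", "front_up", "front_down"))
}

check_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  need <- c("orientation", "level_slash", "level_backslash")
  missing <- setdiff(need, names(profiles))
  if (length(missing) > 0) {
    stop("orientation profiles lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!setequal(profiles$orientation, orientation_levels())) {
    stop("orientation profiles must cover exactly the nine orientations",
         call. = FALSE)
  }
  invisible(profiles)
}
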