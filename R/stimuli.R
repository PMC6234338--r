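#' @title Task stimulus generators
#' @description Generators for the non-pattern stimuli: 2-back shape
#'   streams, vigilance-task intervals, action-task target placement and
#'   object-tracking initial arrays. All draw from R's global RNG, so runs
#'   are reproducible under [set.seed()].
#' @name stimuli
NULL

#' The six 2-back shapes
#' @export
SNAP_SHAPES <- c("circle", "hexagon", "rhombus", "square", "star", "triangle")

#' Generate a 2-back shape stream
#'
#' Shapes are drawn i.i.d. uniformly over the six symbols. Position `i`
#' is a match when it equals the shape two positions earlier; the first
#' two positions are never matches. The stream is truncated at the item
#' carrying the `max_matches`-th match flag (or at `max_len` as a safety
#' bound).
#'
#' @param max_matches number of matches after which the stream stops
#'   (default 10, the session rule).
#' @param max_len safety cap on stream length.
#' @return a list with `shapes` (character) and `match_flags` (logical).
#' @export
generate_shape_stream <- function(max_matches = 10L, max_len = 400L) {
  stopifnot(max_matches >= 1L, max_len >= 3L)
  shapes <- sample(SNAP_SHAPES, max_len, replace = TRUE)
  flags <- c(FALSE, FALSE, shapes[-(1:2)] == shapes[seq_len(max_len - 2L)])
  cum <- cumsum(flags)
  stop_at <- match(max_matches, cum)
  if (!is.na(stop_at)) {
    shapes <- shapes[seq_len(stop_at)]
    flags <- flags[seq_len(stop_at)]
  }
  list(shapes = shapes, match_flags = flags)
}

#' Sample a vigilance-task foreperiod
#'
#' The interval between trial onset and the go signal is uniform on 2 to
#' 7 seconds.
#'
#' @param n number of draws.
#' @return numeric vector of seconds in `[2, 7]`.
#' @export
sample_react_interval <- function(n = 1L) {
  stats::runif(n, 2, 7)
}

#' Place a circular action-task target
#'
#' The arena is the unit square; the target is a circle covering exactly
#' 5% of its area (radius `sqrt(0.05/pi)`), with its center uniform over
#' the positions that keep the circle fully inside the arena. The ball
#' covers half the target's area, giving ball radius `r / sqrt(2)`; this
#' is carried as metadata.
#'
#' @param area_fraction fraction of arena area covered by the target.
#' @return a list of class `hotspot_target` with `center`, `radius`,
#'   `ball_radius` and `area_fraction`.
#' @export
place_hotspot_target <- function(area_fraction = 0.05) {
  stopifnot(area_fraction > 0, area_fraction < 1)
  r <- sqrt(area_fraction / pi)
  center <- stats::runif(2, min = r, max = 1 - r)
  structure(list(center = center, radius = r, ball_radius = r / sqrt(2),
                 area_fraction = area_fraction),
            class = "hotspot_target")
}

#' Initialize a multiple-object-tracking array
#'
#' Places `set_size` non-overlapping balls uniformly inside the unit
#' arena (rejection sampling) and marks 3 of them as targets.
#'
#' @param set_size number of balls; one of 8, 9, 11.
#' @param radius ball radius in arena units.
#' @param base_speed initial speed in arena units per second.
#' @return a `track_state` list: `positions` (n x 2), `velocities`
#'   (n x 2), `radius`, `target_ids` (3 indices), `t` (elapsed seconds).
#' @export
init_track_array <- function(set_size, radius = 0.035, base_speed = 0.25) {
  if (length(set_size) != 1L || !set_size %in% c(8L, 9L, 11L))
    stop("`set_size` must be one of 8, 9, 11")
  n <- as.integer(set_size)
  pos <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place non-overlapping balls")
    cand <- stats::runif(2, min = radius, max = 1 - radius)
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1L] - cand[1L])^2 +
            (pos[seq_len(placed), 2L] - cand[2L])^2
      ok <- all(d2 >= (2 * radius)^2)
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  theta <- stats::runif(n, 0, 2 * pi)
  vel <- base_speed * cbind(cos(theta), sin(theta))
  structure(list(positions = pos, velocities = vel, radius = radius,
                 target_ids = sort(sample.int(n, 3L)), t = 0),
            class = "track_state")
}
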