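#' Advance the object-tracking physics by one frame
#'
#' Each ball's speed and heading are independently jittered every frame
#' (multiplicative speed factor and additive heading angle, both uniform
#' within configured bounds, speed clamped to `speed_range`), positions
#' are advanced by `dt`, and wall and ball-ball collisions are resolved
#' by reflection plus positional correction so that no ball ever overlaps
#' another or leaves the arena.
#'
#' @param s a `track_state` from [init_track_array()].
#' @param dt frame duration in seconds.
#' @param speed_jitter range of the per-frame multiplicative speed factor.
#' @param heading_jitter_deg max absolute per-frame heading change, degrees.
#' @param speed_range allowed speed range, arena units per second.
#' @return the updated `track_state` (with `t` advanced by `dt`).
#' @export
step_track_physics <- function(s, dt = 1 / 60,
                               speed_jitter = c(0.9, 1.1),
                               heading_jitter_deg = 10,
                               speed_range = c(0.1, 0.4)) {
  pos <- s$positions
  vel <- s$velocities
  n <- nrow(pos)
  r <- s$radius

  speed <- sqrt(rowSums(vel^2))
  heading <- atan2(vel[, 2L], vel[, 1L])
  speed <- speed * stats::runif(n, speed_jitter[1L], speed_jitter[2L])
  speed <- pmin(pmax(speed, speed_range[1L]), speed_range[2L])
  heading <- heading + stats::runif(n, -1, 1) * heading_jitter_deg * pi / 180
  vel <- speed * cbind(cos(heading), sin(heading))

  pos <- pos + vel * dt

  lo <- r
  hi <- 1 - r
  for (iter in 1:20) {
    # walls: reflect position about the boundary and point velocity inward
    for (k in 1:2) {
      below <- pos[, k] < lo
      above <- pos[, k] > hi
      pos[below, k] <- 2 * lo - pos[below, k]
      vel[below, k] <- abs(vel[below, k])
      pos[above, k] <- 2 * hi - pos[above, k]
      vel[above, k] <- -abs(vel[above, k])
    }
    pos[, 1L] <- pmin(pmax(pos[, 1L], lo), hi)
    pos[, 2L] <- pmin(pmax(pos[, 2L], lo), hi)

    # ball-ball: separate overlapping pairs and exchange approaching
    # normal velocity components (equal masses)
    any_overlap <- FALSE
    for (i in seq_len(n - 1L)) {
      dx <- pos[(i + 1L):n, 1L] - pos[i, 1L]
      dy <- pos[(i + 1L):n, 2L] - pos[i, 2L]
      d2 <- dx * dx + dy * dy
      hit <- which(d2 < (2 * r)^2)
      for (h in hit) {
        j <- i + h
        any_overlap <- TRUE
        d <- sqrt(d2[h])
        if (d < 1e-12) {           # coincident centers: pick an arbitrary normal
          nvec <- c(1, 0)
          d <- 1e-12
        } else nvec <- c(dx[h], dy[h]) / d
        push <- (2 * r - d) / 2 + 1e-9
        pos[i, ] <- pos[i, ] - nvec * push
        pos[j, ] <- pos[j, ] + nvec * push
        vi <- sum(vel[i, ] * nvec)
        vj <- sum(vel[j, ] * nvec)
        if (vi - vj > 0) {         # approaching: swap normal components
          vel[i, ] <- vel[i, ] + (vj - vi) * nvec
          vel[j, ] <- vel[j, ] + (vi - vj) * nvec
        }
      }
    }
    if (!any_overlap &&
        all(pos[, 1L] >= lo & pos[, 1L] <= hi &
            pos[, 2L] >= lo & pos[, 2L] <= hi)) break
  }

  s$positions <- pos
  s$velocities <- vel
  s$t <- s$t + dt
  s
}

#' Run one full object-tracking session
#'
#' Six trials at set sizes 8, 8, 9, 9, 11, 11 (increasing order). Each
#' trial shows a static 3 s preview with targets marked, simulates 5 s of
#' motion at the tick rate, then asks the responder for up to three tap
#' selections. Each correctly tapped target scores 2.5 points, so the
#' session maximum is 45. Non-responses count as incorrect.
#'
#' The responder is called as `responder(state, trial)` where `trial` is
#' a list with `index`, `set_size` and `target_ids`, and must return an
#' integer vector of at most 3 distinct ball indices (possibly empty).
#' A responder with `attr(responder, "needs_state") = FALSE` is called
#' with the initial (pre-motion) state and the motion phase is skipped;
#' this is exact for responders whose taps do not depend on trajectories.
#'
#' @param responder responder function (see Details).
#' @param points_per_ball points per correctly identified ball.
#' @param preview_s,motion_s preview and motion durations, seconds.
#' @param hz simulation tick rate.
#' @param radius,base_speed passed to [init_track_array()].
#' @return a `game_score` list (see [game_score()]).
#' @export
run_track_session <- function(responder, points_per_ball = 2.5,
                              preview_s = 3, motion_s = 5, hz = 60,
                              radius = 0.035, base_speed = 0.25) {
  sizes <- c(8L, 8L, 9L, 9L, 11L, 11L)
  needs_state <- !isFALSE(attr(responder, "needs_state"))
  detail <- vector("list", length(sizes))
  total <- 0
  n_correct <- 0L
  for (i in seq_along(sizes)) {
    state <- init_track_array(sizes[i], radius = radius, base_speed = base_speed)
    targets <- state$target_ids
    if (needs_state) {
      nsteps <- round(motion_s * hz)
      for (step in seq_len(nsteps)) state <- step_track_physics(state, 1 / hz)
    }
    taps <- responder(state, list(index = i, set_size = sizes[i],
                                  target_ids = targets))
    taps <- unique(as.integer(taps))
    if (length(taps) > 3L) stop("responder returned more than 3 taps")
    if (length(taps) && (any(taps < 1L) || any(taps > sizes[i])))
      stop("responder tapped a ball index outside the array")
    hits <- length(intersect(taps, targets))
    pts <- points_per_ball * hits
    total <- total + pts
    n_correct <- n_correct + hits
    detail[[i]] <- list(set_size = sizes[i], n_hits = hits, points = pts)
  }
  game_score("track", score = total, n_correct = n_correct,
             trial_detail = detail)
}
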