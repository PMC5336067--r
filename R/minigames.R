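#' Mini-game configurations
#'
#' Each configuration derives its geometry from the avatar skeleton so that
#' game targets always sit inside the avatar's (and hence, through the
#' amplifier, every calibrated player's) reach.
#'
#' @param avatar_model Avatar `skeleton_model`.
#' @param n_rungs Number of ladder rungs to climb.
#' @param band Fraction of the calibrated vertical range a hand must cover
#'   for a grab (the grab rope triggers within `(1 - band)` of the maximum
#'   point). The default of 0.8 leaves headroom for the range-estimation
#'   bias that sensor jitter induces at high gain.
#' @param max_duration Session cap in seconds (`NULL`: trace length).
#' @return A config list (class `game_config`).
#' @export
ladder_config <- function(avatar_model, n_rungs = 10, band = 0.8,
                          max_duration = NULL) {
  ropes <- list()
  for (side in c("left", "right")) {
    limb <- paste0("hand_", side)
    rng <- avatar_required_ranges(avatar_model, limb)["pos", "z"]
    maxpt <- avatar_model$rest_pose[limb, ] + c(0, 0, rng)
    ropes[[side]] <- rope(limb, maxpt, trigger_length = (1 - band) * rng,
                          mode = "below", id = paste0("grab_", side))
  }
  structure(list(game = "ladder", n_rungs = n_rungs, band = band,
                 ropes = ropes, max_duration = max_duration),
            class = "game_config")
}

#' @rdname ladder_config
#' @param course_length Rowing course length in metres.
#' @param stroke_advance Metres the boat advances per completed stroke.
#' @export
boat_config <- function(avatar_model, course_length = 30, stroke_advance = 3,
                        max_duration = NULL) {
  ropes <- list()
  for (side in c("left", "right")) {
    limb <- paste0("hand_", side)
    rng <- avatar_required_ranges(avatar_model, limb)
    rest <- avatar_model$rest_pose[limb, ]
    for (dir in c("fore", "aft")) {
      r <- if (dir == "fore") rng["pos", "x"] else rng["neg", "x"]
      pt <- rest + c(if (dir == "fore") 0.7 * r else -0.7 * r, 0, 0)
      ropes[[paste(side, dir, sep = "_")]] <-
        rope(limb, pt, trigger_length = 0.4 * r, mode = "below",
             id = paste("row", side, dir, sep = "_"))
    }
  }
  structure(list(game = "boat", course_length = course_length,
                 stroke_advance = stroke_advance, ropes = ropes,
                 max_duration = max_duration),
            class = "game_config")
}

#' @rdname ladder_config
#' @param n_moles Moles spawned over the session (default 20).
#' @param duration Session length in seconds (default 120).
#' @param hole_offsets 4 x 3 matrix of hole positions in units of the
#'   avatar's right-hand movement range, relative to the right-hand rest
#'   point.
#' @param hole_radius Hit radius around the hole centre, metres.
#' @param min_hit_speed Minimum hammer speed for a valid hit, m/s.
#' @param visibility Seconds each mole stays out of its hole.
#' @export
mole_config <- function(avatar_model, n_moles = 20, duration = 120,
                        hole_offsets = rbind(c(0.30, 0.70, 0.30),
                                             c(0.30, -0.70, 0.30),
                                             c(0.50, 0.35, 0.80),
                                             c(0.50, -0.35, 0.80)),
                        hole_radius = 0.12, min_hit_speed = 0.4,
                        visibility = 3) {
  limb <- "hand_right"
  rng <- avatar_required_ranges(avatar_model, limb)
  scale <- ifelse(hole_offsets >= 0,
                  matrix(rng["pos", ], nrow(hole_offsets), 3, byrow = TRUE),
                  matrix(rng["neg", ], nrow(hole_offsets), 3, byrow = TRUE))
  holes <- sweep(hole_offsets * scale, 2, avatar_model$rest_pose[limb, ], "+")
  colnames(holes) <- c("x", "y", "z")
  structure(list(game = "mole", n_moles = n_moles, duration = duration,
                 hole_offsets = hole_offsets, holes = holes,
                 hole_radius = hole_radius, min_hit_speed = min_hit_speed,
                 visibility = visibility),
            class = "game_config")
}

#' @rdname ladder_config
#' @param forward_speed Constant forward speed of the bird, m/s.
#' @param yaw_gain Turn rate per metre of hand-height difference,
#'   rad/(s*m). The yaw angle is measured towards the right hand's side,
#'   so a lower left hand (negative height difference) turns the bird left.
#' @param pitch_gain Pitch angle per radian of trunk lean; leaning forward
#'   pitches the bird down.
#' @param rings List of rings, each `list(center, radius, normal)`.
#' @export
bird_config <- function(forward_speed = 5, yaw_gain = 2, pitch_gain = 1,
                        rings = default_rings(), max_duration = NULL) {
  structure(list(game = "bird", forward_speed = forward_speed,
                 yaw_gain = yaw_gain, pitch_gain = pitch_gain,
                 rings = rings, max_duration = max_duration),
            class = "game_config")
}

#' Default ring course for the flying game
#' @param n Number of rings.
#' @param spacing Spacing along the flight axis, metres.
#' @param radius Ring radius, metres.
#' @return List of rings.
#' @export
default_rings <- function(n = 5, spacing = 25, radius = 3) {
  lapply(seq_len(n), function(i)
    list(center = c(i * spacing,
                    4 * sin(i * 1.3),
                    30 + 3 * cos(i * 0.9)),
         radius = radius, normal = c(1, 0, 0)))
}

#' Deterministic mole spawn schedule
#'
#' One mole at a time: mole i pops out of a uniformly drawn hole at
#' `(i - 1) * duration / n_moles` seconds and stays visible for the
#' configured window. The same seed always yields the same schedule.
#'
#' @param config A [mole_config()].
#' @param seed Integer seed.
#' @return Data frame with `time` and `hole` (1-4), carrying the config's
#'   `hole_offsets` as an attribute.
#' @export
mole_schedule <- function(config, seed) {
  set.seed(derive_seed(seed, 17))
  sched <- data.frame(
    time = (seq_len(config$n_moles) - 1) * config$duration / config$n_moles,
    hole = sample.int(nrow(config$holes), config$n_moles, replace = TRUE))
  attr(sched, "hole_offsets") <- config$hole_offsets
  sched
}

# --- per-frame state machines ---------------------------------------------

#' Initialise / advance the Ladder state machine
#'
#' The climb scores a rung when the active hand's grab rope activates (the
#' hand reaches the band around its calibrated maximum); hands then
#' alternate, and a hand must release its rope before it can grab again.
#'
#' @param config A [ladder_config()].
#' @param state Game state from `ladder_init()` / a previous step.
#' @param pose Avatar `skeleton_pose` for the current frame.
#' @param dt Frame interval in seconds.
#' @return Updated state; `state$done`, `state$rungs`, `state$finish_time`
#'   carry the outcome.
#' @export
ladder_init <- function(config) {
  list(config = config, rungs = 0L, active = "left", done = FALSE,
       finish_time = NA_real_, elapsed = 0,
       ropes = lapply(config$ropes, rope_state))
}

#' @rdname ladder_init
#' @export
step_ladder <- function(state, pose, dt) {
  if (state$done) return(state)
  state$elapsed <- state$elapsed + dt
  t <- attr(pose, "time")
  for (side in names(state$ropes)) {
    len <- rope_length(pose, state$config$ropes[[side]])
    state$ropes[[side]] <- rope_step(state$ropes[[side]], len, t)
    ev <- state$ropes[[side]]$event
    if (!is.null(ev) && ev$kind == "activated" && side == state$active) {
      state$rungs <- state$rungs + 1L
      state$active <- if (side == "left") "right" else "left"
      if (state$rungs >= state$config$n_rungs) {
        state$done <- TRUE
        state$finish_time <- state$elapsed
      }
    }
  }
  state
}

#' Initialise / advance the Boat state machine
#'
#' Four ropes (fore and aft on each side) watch the rowing motion; a stroke
#' completes when all four have activated since the last stroke, in any
#' order, advancing the boat by the configured stroke length.
#'
#' @inheritParams ladder_init
#' @param config A [boat_config()].
#' @export
boat_init <- function(config) {
  list(config = config, distance = 0, done = FALSE, finish_time = NA_real_,
       elapsed = 0, strokes = 0L,
       flags = stats::setNames(rep(FALSE, length(config$ropes)),
                               names(config$ropes)),
       ropes = lapply(config$ropes, rope_state))
}

#' @rdname boat_init
#' @export
step_boat <- function(state, pose, dt) {
  if (state$done) return(state)
  state$elapsed <- state$elapsed + dt
  t <- attr(pose, "time")
  for (nm in names(state$ropes)) {
    len <- rope_length(pose, state$config$ropes[[nm]])
    state$ropes[[nm]] <- rope_step(state$ropes[[nm]], len, t)
    ev <- state$ropes[[nm]]$event
    if (!is.null(ev) && ev$kind == "activated") state$flags[nm] <- TRUE
  }
  if (all(state$flags)) {
    state$strokes <- state$strokes + 1L
    state$distance <- state$distance + state$config$stroke_advance
    state$flags[] <- FALSE
    if (state$distance >= state$config$course_length) {
      state$done <- TRUE
      state$finish_time <- state$elapsed
    }
  }
  state
}

#' Initialise / advance the Whack-a-Mole state machine
#'
#' A mole is hit when the hammer tip (the avatar's right hand) is inside
#' the active hole's radius while moving downward at or above the minimum
#' hit speed, as measured by an accelerometer gadget over a short backward
#' window.
#'
#' @inheritParams ladder_init
#' @param config A [mole_config()].
#' @param seed Seed for the spawn schedule.
#' @export
mole_init <- function(config, seed = 1) {
  sched <- mole_schedule(config, seed)
  list(config = config, schedule = sched,
       resolved = rep(FALSE, nrow(sched)), score = 0L, elapsed = 0,
       hist = NULL, speed_window = 2L, done = FALSE)
}

#' @rdname mole_init
#' @export
step_mole <- function(state, pose, dt) {
  state$elapsed <- state$elapsed + dt
  if (state$elapsed > state$config$duration) { state$done <- TRUE; return(state) }
  hand <- as.numeric(pose["hand_right", ])
  hist <- rbind(state$hist, hand)
  w <- state$speed_window
  if (nrow(hist) > w + 1L) hist <- hist[-1L, , drop = FALSE]
  state$hist <- hist
  t <- attr(pose, "time")
  sched <- state$schedule
  i <- findInterval(t, sched$time)
  if (i >= 1 && !state$resolved[i] && t < sched$time[i] + state$config$visibility &&
      nrow(hist) == w + 1L) {
    hole <- state$config$holes[sched$hole[i], ]
    dist <- sqrt(sum((hand - hole)^2))
    v <- (hand - hist[1L, ]) / (w * dt)
    spd <- sqrt(sum(v^2))
    if (dist <= state$config$hole_radius &&
        spd >= state$config$min_hit_speed && v[3] < 0) {
      state$score <- state$score + 1L
      state$resolved[i] <- TRUE
    }
  }
  state
}

#' Initialise / advance the Paper-Bird state machine
#'
#' The bird flies forward at constant speed; the difference in hand heights
#' steers it (lower left hand: left turn), the trunk lean controls the
#' pitch (lean forward: dive). A ring counts as passed when the flight path
#' crosses the ring's plane inside its radius; each ring counts once.
#'
#' @inheritParams ladder_init
#' @param config A [bird_config()].
#' @param rest_pose Avatar rest pose (reference for hand heights and lean).
#' @export
bird_init <- function(config, rest_pose) {
  list(config = config, rest = rest_pose,
       pos = c(0, 0, 30), yaw = 0, elapsed = 0,
       passed = rep(FALSE, length(config$rings)), done = FALSE)
}

#' @rdname bird_init
#' @export
step_bird <- function(state, pose, dt) {
  state$elapsed <- state$elapsed + dt
  cfg <- state$config
  dz <- (pose["hand_left", 3] - state$rest["hand_left", 3]) -
    (pose["hand_right", 3] - state$rest["hand_right", 3])
  v_tr <- pose["shoulder_center", ] - pose["hip_center", ]
  lean <- atan2(v_tr[1], v_tr[3])        # forward lean positive (x-z plane)
  yaw_rate <- cfg$yaw_gain * dz          # positive: towards the right side
  state$yaw <- state$yaw + yaw_rate * dt
  pitch <- max(-0.6, min(0.6, -cfg$pitch_gain * lean))
  vel <- cfg$forward_speed * c(cos(pitch) * cos(state$yaw),
                               -cos(pitch) * sin(state$yaw),
                               sin(pitch))
  p0 <- state$pos
  p1 <- p0 + vel * dt
  for (r in seq_along(cfg$rings)) {
    if (state$passed[r]) next
    ring <- cfg$rings[[r]]
    s0 <- sum((p0 - ring$center) * ring$normal)
    s1 <- sum((p1 - ring$center) * ring$normal)
    if ((s0 < 0 && s1 >= 0) || (s0 > 0 && s1 <= 0)) {
      tc <- s0 / (s0 - s1)
      pt <- p0 + tc * (p1 - p0)
      rad <- pt - ring$center
      rad <- rad - sum(rad * ring$normal) * ring$normal
      if (sqrt(sum(rad^2)) <= ring$radius) state$passed[r] <- TRUE
    }
  }
  state$pos <- p1
  state
}

#' Count ring passes of a flight path
#'
#' Segment-by-segment crossing test of a polyline against a set of rings
#' (disc of a given radius in the plane through `center` with the given
#' `normal`); each ring counts at most once.
#'
#' @param path n x 3 matrix of flight positions.
#' @param rings List of rings as in [bird_config()].
#' @return Integer number of rings passed.
#' @export
count_ring_passes <- function(path, rings) {
  passed <- rep(FALSE, length(rings))
  for (i in seq_len(nrow(path) - 1L)) {
    p0 <- path[i, ]; p1 <- path[i + 1L, ]
    for (r in seq_along(rings)) {
      if (passed[r]) next
      ring <- rings[[r]]
      s0 <- sum((p0 - ring$center) * ring$normal)
      s1 <- sum((p1 - ring$center) * ring$normal)
      if ((s0 < 0 && s1 >= 0) || (s0 > 0 && s1 <= 0)) {
        tc <- s0 / (s0 - s1)
        pt <- p0 + tc * (p1 - p0)
        rad <- pt - ring$center
        rad <- rad - sum(rad * ring$normal) * ring$normal
        if (sqrt(sum(rad^2)) <= ring$radius) passed[r] <- TRUE
      }
    }
  }
  sum(passed)
}

#' Smooth a motion trace
#'
#' Centred moving average per joint and axis; the game layer applies this
#' before event detection to tame amplified sensor jitter (the amplifier
#' itself is stateless and never filters).
#'
#' @param trace A `motion_trace`.
#' @param window Window length in seconds.
#' @return Smoothed `motion_trace`.
#' @export
smooth_trace <- function(trace, window = 1 / 6) {
  k <- round(window * trace$rate)
  if (k <= 1) return(trace)
  pos <- trace$positions
  for (j in seq_len(dim(pos)[2]))
    for (ax in 1:3)
      pos[, j, ax] <- moving_average(pos[, j, ax], k)
  motion_trace(trace$time, pos, rate = trace$rate, check_rate = FALSE)
}

#' Run one mini-game session
#'
#' The session pipeline: retarget the user trace onto the avatar through
#' the calibration profile (identity factors if `amplify = FALSE`), smooth
#' the avatar stream, then drive the game's state machine frame by frame.
#' Deterministic for fixed trace, config and seed.
#'
#' @param game `"ladder"`, `"boat"`, `"mole"` or `"bird"`.
#' @param trace User `motion_trace`.
#' @param profile A `calibration` for this user.
#' @param avatar_model Avatar `skeleton_model`.
#' @param config Game config; defaults to the game's default config for
#'   this avatar.
#' @param seed Integer seed (mole spawn schedule).
#' @param amplify Apply the calibrated amplification (`FALSE` runs the
#'   ablation: the avatar mirrors raw displacements).
#' @param subject Subject identifier for the result record.
#' @param smooth Smoothing window in seconds for the game layer.
#' @return A `game_result`: list with `game`, `subject`, `elapsed_time`,
#'   `score`, `rings_passed`, `completed` and the per-game detail fields.
#' @export
run_session <- function(game = c("ladder", "boat", "mole", "bird"),
                        trace, profile, avatar_model, config = NULL,
                        seed = 1, amplify = TRUE, subject = "s1",
                        smooth = 1 / 6) {
  game <- match.arg(game)
  if (is.null(config))
    config <- switch(game,
                     ladder = ladder_config(avatar_model),
                     boat = boat_config(avatar_model),
                     mole = mole_config(avatar_model),
                     bird = bird_config())
  prof <- if (amplify) profile else profile_identity_factors(profile)
  avatar <- retarget_trace(trace, prof, avatar_model)
  avatar <- smooth_trace(avatar, smooth)
  n <- n_frames(avatar)
  dt <- if (n > 1) mean(diff(avatar$time)) else 1 / avatar$rate
  state <- switch(game,
                  ladder = ladder_init(config),
                  boat = boat_init(config),
                  mole = mole_init(config, seed),
                  bird = bird_init(config, avatar_model$rest_pose))
  stepf <- switch(game, ladder = step_ladder, boat = step_boat,
                  mole = step_mole, bird = step_bird)
  cap <- config$max_duration
  for (i in seq_len(n)) {
    state <- stepf(state, trace_pose_fast(avatar, i), dt)
    if (isTRUE(state$done)) break
    if (!is.null(cap) && state$elapsed >= cap) break
  }
  dur <- state$elapsed
  result <- switch(game,
    ladder = list(elapsed_time = if (state$done) state$finish_time else dur,
                  score = NA_integer_, rings_passed = NA_integer_,
                  completed = state$done, detail = list(rungs = state$rungs)),
    boat = list(elapsed_time = if (state$done) state$finish_time else dur,
                score = NA_integer_, rings_passed = NA_integer_,
                completed = state$done,
                detail = list(strokes = state$strokes,
                              distance = state$distance)),
    mole = list(elapsed_time = min(dur, config$duration),
                score = state$score, rings_passed = NA_integer_,
                completed = TRUE, detail = list(schedule = state$schedule)),
    bird = list(elapsed_time = dur, score = NA_integer_,
                rings_passed = sum(state$passed), completed = TRUE,
                detail = list(final_pos = state$pos)))
  structure(c(list(game = game, subject = subject), result),
            class = "game_result")
}

#' @export
print.game_result <- function(x, ...) {
  cat(sprintf("<game_result> %s / %s: %.2f s%s%s%s\n", x$game, x$subject,
              x$elapsed_time,
              if (!is.na(x$score)) sprintf(", score %d", x$score) else "",
              if (!is.na(x$rings_passed))
                sprintf(", rings %d", x$rings_passed) else "",
              if (isTRUE(x$completed)) ", completed" else ", not completed"))
  invisible(x)
}
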