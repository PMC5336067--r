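#' Synthetic player parameters
#'
#' Describes one simulated player for the seeded motion generator. The
#' amplitude scale `s` models muscle weakness: an impaired player's limbs
#' travel only a fraction `s` of the full movement range (a player who can
#' move only the hands with the arms resting has a small `s`). `jitter_sd`
#' models the per-joint, per-frame Gaussian scattering typical of depth
#' sensors; `seated` selects a wheelchair-style resting posture.
#'
#' @param s Amplitude scale in (0, 1].
#' @param cadence Movement cadence in Hz (raises per second when climbing,
#'   stroke rate when rowing).
#' @param jitter_sd Per-axis sensor jitter standard deviation in metres.
#' @param seated Seated (wheelchair) resting posture?
#' @param reaction_time Seconds between a game cue and movement onset.
#' @param aim_error Aim scatter as a fraction of the player's movement
#'   range; models the precision deficits that amplification cannot
#'   equalise.
#' @param play_duration Preferred free-play duration in seconds (used by
#'   the flying exercise, which has no goal).
#' @param seed Integer seed; every generated trace is deterministic in it.
#' @return An object of class `player_params`.
#' @export
player_params <- function(s = 1, cadence = 1, jitter_sd = 0.005,
                          seated = FALSE, reaction_time = 0.3,
                          aim_error = 0.15, play_duration = 120, seed = 1) {
  if (s <= 0 || s > 1) stop("`s` must be in (0, 1]", call. = FALSE)
  if (cadence <= 0) stop("`cadence` must be positive", call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  structure(list(s = s, cadence = cadence, jitter_sd = jitter_sd,
                 seated = seated, reaction_time = reaction_time,
                 aim_error = aim_error, play_duration = play_duration,
                 seed = as.integer(seed)),
            class = "player_params")
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 104729 * k) %% 2147483647)
}

#' Default rest poses and skeletons
#'
#' `default_rest_pose()` builds a plausible standing or seated 20-joint
#' rest pose (metres, z-up); `default_avatar()` is the standing skeleton
#' model used as the full-range avatar throughout the package.
#'
#' @param seated Seated (wheelchair) posture?
#' @return A `skeleton_pose` / `skeleton_model`.
#' @export
default_rest_pose <- function(seated = FALSE) {
  p <- matrix(NA_real_, 20, 3, dimnames = list(kinect_joints(),
                                               c("x", "y", "z")))
  # limbs rest clearly bent: a rest pose near full extension would leave no
  # kinematic slack for per-axis excursions
  if (!seated) {
    p["hip_center", ] <- c(0, 0, 0.95)
    p["spine", ] <- c(0, 0, 1.16)
    p["shoulder_center", ] <- c(0, 0, 1.38)
    p["head", ] <- c(0, 0, 1.58)
    for (side in c(1, -1)) {
      sfx <- if (side > 0) "left" else "right"
      p[paste0("shoulder_", sfx), ] <- c(0, side * 0.18, 1.38)
      p[paste0("elbow_", sfx), ] <- c(0.06, side * 0.26, 1.06)
      hand <- c(0.24, side * 0.20, 1.10)           # forearm forward, elbow bent
      p[paste0("hand_", sfx), ] <- hand
      p[paste0("wrist_", sfx), ] <-
        p[paste0("elbow_", sfx), ] + 0.75 * (hand - p[paste0("elbow_", sfx), ])
      p[paste0("hip_", sfx), ] <- c(0, side * 0.10, 0.92)
      p[paste0("knee_", sfx), ] <- c(0.18, side * 0.11, 0.55)
      foot <- c(0.08, side * 0.12, 0.12)
      p[paste0("foot_", sfx), ] <- foot
      p[paste0("ankle_", sfx), ] <-
        p[paste0("knee_", sfx), ] + 0.75 * (foot - p[paste0("knee_", sfx), ])
    }
  } else {
    p["hip_center", ] <- c(0, 0, 0.55)
    p["spine", ] <- c(0, 0, 0.78)
    p["shoulder_center", ] <- c(0, 0, 1.00)
    p["head", ] <- c(0, 0, 1.20)
    for (side in c(1, -1)) {
      sfx <- if (side > 0) "left" else "right"
      p[paste0("shoulder_", sfx), ] <- c(0, side * 0.18, 1.00)
      p[paste0("elbow_", sfx), ] <- c(0.06, side * 0.26, 0.70)
      hand <- c(0.26, side * 0.20, 0.70)           # resting on the lap
      p[paste0("hand_", sfx), ] <- hand
      p[paste0("wrist_", sfx), ] <-
        p[paste0("elbow_", sfx), ] + 0.75 * (hand - p[paste0("elbow_", sfx), ])
      p[paste0("hip_", sfx), ] <- c(0, side * 0.10, 0.52)
      p[paste0("knee_", sfx), ] <- c(0.40, side * 0.11, 0.50)
      foot <- c(0.45, side * 0.12, 0.10)
      p[paste0("foot_", sfx), ] <- foot
      p[paste0("ankle_", sfx), ] <-
        p[paste0("knee_", sfx), ] + 0.75 * (foot - p[paste0("knee_", sfx), ])
    }
  }
  skeleton_pose(p, time = 0)
}

#' @rdname default_rest_pose
#' @export
default_avatar <- function() fit_skeleton_to_pose(default_rest_pose(FALSE))

# --- trace assembly -------------------------------------------------------

# quintic minimum-jerk interpolant, 0 -> 1 on [0, 1]
minjerk <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

# symmetric out-and-back bump, 0 -> 1 -> 0 on [0, 1]
bump <- function(u) {
  out <- numeric(length(u))
  up <- u >= 0 & u <= 0.5
  dn <- u > 0.5 & u <= 1
  out[up] <- minjerk(u[up] * 2)
  out[dn] <- minjerk(2 - u[dn] * 2)
  out
}

# out-hold-back bump: reach the extreme, hold it, return. The long hold is
# what a calibration needs: the range estimator averages scattering over the
# plateau instead of seeing a single noisy peak sample.
hold_bump <- function(u) {
  out <- numeric(length(u))
  up <- u >= 0 & u < 0.15
  hd <- u >= 0.15 & u <= 0.85
  dn <- u > 0.85 & u <= 1
  out[up] <- minjerk(u[up] / 0.15)
  out[hd] <- 1
  out[dn] <- minjerk((1 - u[dn]) / 0.15)
  out
}

# Build a trace from end-effector tracks: trunk rigid at rest (optionally
# with a lean schedule), limbs solved on the player's own skeleton by IK so
# intermediate joints stay kinematically plausible.
assemble_trace <- function(time, rest, limb_tracks, lean = NULL,
                           jitter_sd = 0, seed = 1, rate = 30) {
  n <- length(time)
  joints <- kinect_joints()
  pos <- array(rep(unclass(rest), each = n), c(n, 20, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  if (!is.null(lean)) {
    # rotate the upper trunk about the hip centre in the sagittal (x-z) plane
    hc <- rest["hip_center", ]
    for (j in c("spine", "shoulder_center", "head",
                "shoulder_left", "shoulder_right")) {
      v <- rest[j, ] - hc
      pos[, j, 1] <- hc[1] + cos(lean) * v[1] + sin(lean) * v[3]
      pos[, j, 2] <- hc[2] + v[2]
      pos[, j, 3] <- hc[3] - sin(lean) * v[1] + cos(lean) * v[3]
    }
  }
  model <- fit_skeleton_to_pose(rest)
  chains <- limb_chains()
  for (limb in names(limb_tracks)) {
    ch <- chains[[limb]]
    targets <- limb_tracks[[limb]]
    roots <- pos[, ch$root, , drop = TRUE]
    if (n == 1) roots <- matrix(roots, 1, 3)
    l_up <- unname(model$lengths[ch$mid])
    l_lo <- unname(model$lengths[ch$mid2] + model$lengths[ch$end])
    hint <- rest[ch$mid, ] - (rest[ch$root, ] + rest[limb, ]) / 2
    if (sqrt(sum(hint^2)) < 1e-6) hint <- c(1, 0, 0)
    hints <- matrix(hint, n, 3, byrow = TRUE)
    sol <- ik_solve_frames(roots, targets, l_up, l_lo, hints)
    pos[, ch$mid, ] <- sol$mid
    pos[, ch$end, ] <- sol$end
    seg <- sol$end - sol$mid
    frac <- unname(model$lengths[ch$mid2]) /
      pmax(sqrt(rowSums(seg^2)), 1e-12)
    pos[, ch$mid2, ] <- sol$mid + seg * frac
  }
  if (jitter_sd > 0) {
    set.seed(derive_seed(seed, 7))
    pos <- pos + array(stats::rnorm(length(pos), 0, jitter_sd), dim(pos))
  }
  motion_trace(time, pos, rate = rate, check_rate = FALSE)
}

# per-axis movement ranges this player can reach: s times the full-range
# requirement of the player's own skeleton
player_ranges <- function(params, rest) {
  model <- fit_skeleton_to_pose(rest)
  lapply(stats::setNames(nm = names(limb_chains())), function(limb)
    params$s * avatar_required_ranges(model, limb))
}

#' Generate a synthetic calibration trace
#'
#' A resting phase (default 2 s) followed by maximal excursions of hands
#' and feet along each axis in both directions, with amplitude `s` times
#' the player's full range and per-frame Gaussian jitter. Deterministic per
#' seed.
#'
#' @param params A [player_params()].
#' @param rest_duration Resting-phase length in seconds (the stretches
#'   that follow hold each extreme for several seconds).
#' @param rate Frame rate in Hz.
#' @return A `motion_trace`.
#' @export
generate_calibration_trace <- function(params, rest_duration = 5, rate = 30) {
  rest <- default_rest_pose(params$seated)
  ranges <- player_ranges(params, rest)
  seg <- 4                               # seconds per directed excursion
  total <- rest_duration + 6 * seg
  time <- seq(0, total - 1 / rate, by = 1 / rate)
  n <- length(time)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  tracks <- list()
  for (limb in names(limb_chains())) {
    amp_mat <- ranges[[limb]]           # 2 x 3 (pos/neg rows)
    track <- matrix(rep(rest[limb, ], each = n), n, 3)
    for (k in 1:6) {
      t0 <- rest_duration + (k - 1) * seg
      inwin <- time >= t0 & time < t0 + seg
      u <- (time[inwin] - t0) / seg
      d <- dirs[k, ]
      amp <- amp_mat[if (sum(d) > 0) "pos" else "neg", which(d != 0)]
      track[inwin, ] <- track[inwin, ] +
        outer(hold_bump(u) * amp, d)
    }
    tracks[[limb]] <- track
  }
  assemble_trace(time, rest, tracks, jitter_sd = params$jitter_sd,
                 seed = params$seed, rate = rate)
}

#' Generate a synthetic exercise trace
#'
#' Kinematically plausible 30 Hz joint streams for the four exercise
#' patterns:
#' \describe{
#'   \item{climb}{alternating hand raises to `s` times the vertical range
#'     at the given cadence (one raise per hand alternation);}
#'   \item{row}{bilateral fore-aft hand ellipses at the stroke cadence;}
#'   \item{whack}{reactive right-hand strikes towards cued hole positions
#'     (supply the cue `schedule`), starting `reaction_time` after each
#'     cue, with aim scatter `aim_error`;}
#'   \item{fly}{a schedule of hand-height differences and trunk lean
#'     (smooth seeded random walk unless `controls` is supplied).}
#' }
#'
#' @param pattern One of `"climb"`, `"row"`, `"whack"`, `"fly"`.
#' @param params A [player_params()].
#' @param duration Trace length in seconds.
#' @param schedule For `"whack"`: data frame with columns `time` (cue time,
#'   seconds) and `hole` (unit-offset matrix rows, see [mole_config()]),
#'   plus attribute `hole_offsets`.
#' @param controls For `"fly"`: data frame with columns `time`,
#'   `dz` (hand height difference, fraction of the vertical range in
#'   [-1, 1]) and `lean` (trunk lean, fraction of 0.35 rad). When omitted,
#'   a ring-seeking pilot generates the commands against `bird`.
#' @param bird For `"fly"` without explicit `controls`: the [bird_config()]
#'   the pilot plans against.
#' @param rate Frame rate in Hz.
#' @return A `motion_trace`.
#' @export
generate_exercise_trace <- function(pattern, params, duration,
                                    schedule = NULL, controls = NULL,
                                    bird = bird_config(), rate = 30) {
  pattern <- match.arg(pattern, c("climb", "row", "whack", "fly"))
  rest <- default_rest_pose(params$seated)
  ranges <- player_ranges(params, rest)
  time <- seq(0, duration - 1 / rate, by = 1 / rate)
  n <- length(time)
  tracks <- list()
  lean <- NULL

  if (pattern == "climb") {
    period <- 1 / params$cadence
    cyc <- floor(time / period)
    u <- time / period - cyc
    for (side in c("left", "right")) {
      limb <- paste0("hand_", side)
      amp <- ranges[[limb]]["pos", "z"]
      active <- if (side == "left") cyc %% 2 == 0 else cyc %% 2 == 1
      dz <- ifelse(active, bump(u) * amp, 0)
      track <- matrix(rep(rest[limb, ], each = n), n, 3)
      track[, 3] <- track[, 3] + dz
      tracks[[limb]] <- track
    }
  } else if (pattern == "row") {
    period <- 1 / params$cadence
    ramp <- minjerk(time / min(1, duration / 4))
    theta <- 2 * pi * time / period
    for (side in c("left", "right")) {
      limb <- paste0("hand_", side)
      ax <- ranges[[limb]][, "x"]        # pos / neg fore-aft amplitudes
      az <- 0.15 * ranges[[limb]]["pos", "z"]
      x <- ifelse(sin(theta) >= 0, ax["pos"], ax["neg"]) * sin(theta) * ramp
      z <- az * cos(theta) * ramp - az * ramp
      track <- matrix(rep(rest[limb, ], each = n), n, 3)
      track[, 1] <- track[, 1] + x
      track[, 3] <- track[, 3] + z
      tracks[[limb]] <- track
    }
  } else if (pattern == "whack") {
    if (is.null(schedule))
      stop("the whack pattern needs the cue `schedule`", call. = FALSE)
    limb <- "hand_right"
    rng <- ranges[[limb]]
    amp <- rng["pos", ]                  # per-axis positive range
    track <- matrix(rep(rest[limb, ], each = n), n, 3)
    set.seed(derive_seed(params$seed, 11))
    offs <- attr(schedule, "hole_offsets")
    for (i in seq_len(nrow(schedule))) {
      u_off <- offs[schedule$hole[i], ]
      aim <- stats::rnorm(3, 0, params$aim_error)
      tgt_frac <- u_off + aim            # in units of the player's range
      tgt <- ifelse(tgt_frac >= 0, rng["pos", ], rng["neg", ]) * tgt_frac
      hover <- tgt + c(0, 0, 0.5 * amp["z"])
      t0 <- schedule$time[i] + params$reaction_time
      move_d <- 0.5; strike_d <- 0.15; hold_d <- 0.1; back_d <- 0.5
      seg_add <- function(t_from, t_to, from, to) {
        inwin <- time >= t_from & time < t_to
        if (!any(inwin)) return()
        u <- (time[inwin] - t_from) / (t_to - t_from)
        track[inwin, ] <<- matrix(rest[limb, ], sum(inwin), 3, byrow = TRUE) +
          matrix(from, sum(inwin), 3, byrow = TRUE) +
          outer(minjerk(u), to - from)
      }
      seg_add(t0, t0 + move_d, c(0, 0, 0), hover)
      seg_add(t0 + move_d, t0 + move_d + strike_d, hover, tgt)
      seg_add(t0 + move_d + strike_d, t0 + move_d + strike_d + hold_d, tgt, tgt)
      seg_add(t0 + move_d + strike_d + hold_d,
              t0 + move_d + strike_d + hold_d + back_d, tgt, c(0, 0, 0))
    }
    tracks[[limb]] <- track
    # left hand stays at rest
    tracks[["hand_left"]] <- matrix(rep(rest["hand_left", ], each = n), n, 3)
  } else { # fly
    if (is.null(controls)) {
      cmd <- fly_pilot(params, time, bird)
      dz_user <- cmd$dz_user
      lean <- cmd$lean
    } else {
      dz_f <- smooth_schedule(time, controls$time, controls$dz)
      lean <- smooth_schedule(time, controls$time, controls$lean) * 0.35
      dz_user <- dz_f * params$s *
        avatar_required_ranges(fit_skeleton_to_pose(rest), "hand_left")["pos", "z"]
    }
    for (side in c("left", "right")) {
      limb <- paste0("hand_", side)
      # arms spread at shoulder height; the commanded height difference is
      # split between the hands
      base <- rest[limb, ] +
        c(0, sign(rest[limb, 2]) * 0.05, 0.5 * ranges[[limb]]["pos", "z"])
      half <- (if (side == "left") 0.5 else -0.5) * dz_user
      track <- matrix(rep(base, each = n), n, 3)
      track[, 3] <- track[, 3] + half
      tracks[[limb]] <- track
    }
  }
  assemble_trace(time, rest, tracks, lean = lean,
                 jitter_sd = params$jitter_sd, seed = params$seed,
                 rate = rate)
}

# Open-loop ring-seeking pilot for the flying exercise. The pilot plans
# against the standard avatar and the given game config: it forward-simulates
# the bird's control law under its own commands, steering the hand-height
# difference and trunk lean towards the next unpassed ring. Control accuracy
# degrades with the player's aim_error (slowly varying command noise), which
# is what separates cohorts on ring counts: gain equalises amplitude, not
# precision.
fly_pilot <- function(params, time, bird) {
  n <- length(time)
  dt <- if (n > 1) mean(diff(time)) else 1 / 30
  av <- default_avatar()
  a_rng <- avatar_required_ranges(av, "hand_left")["pos", "z"]
  own <- fit_skeleton_to_pose(default_rest_pose(params$seated))
  o_rng <- avatar_required_ranges(own, "hand_left")["pos", "z"]
  dz_max <- 0.8 * a_rng
  set.seed(derive_seed(params$seed, 13))
  # slowly varying control noise, stationary sd ~ 0.5 * aim_error * range
  rho <- 0.97
  innov_sd <- 0.8 * params$aim_error * a_rng * sqrt(1 - rho^2)
  pos <- c(0, 0, 30); yaw <- 0
  passed <- rep(FALSE, length(bird$rings))
  dz_user <- numeric(n); lean <- numeric(n)
  nz <- 0; nl <- 0
  for (i in seq_len(n)) {
    nxt <- which(!passed)[1]
    if (is.na(nxt)) { tgt <- pos + c(25, 0, 0) } else {
      tgt <- bird$rings[[nxt]]$center
    }
    delta <- tgt - pos
    psi_des <- atan2(-delta[2], delta[1])
    nz <- rho * nz + stats::rnorm(1, 0, innov_sd)
    nl <- rho * nl + stats::rnorm(1, 0, innov_sd / a_rng * 0.35)
    dz <- max(-dz_max, min(dz_max,
                           1.5 * (psi_des - yaw) / bird$yaw_gain + nz))
    dh <- sqrt(delta[1]^2 + delta[2]^2)
    pitch_des <- atan2(delta[3], max(dh, 1))
    ln <- max(-0.35, min(0.35, -pitch_des / bird$pitch_gain + nl))
    # forward-simulate the bird under these commands
    yaw <- yaw + bird$yaw_gain * dz * dt
    pitch <- max(-0.6, min(0.6, -bird$pitch_gain * ln))
    p1 <- pos + bird$forward_speed *
      c(cos(pitch) * cos(yaw), -cos(pitch) * sin(yaw), sin(pitch)) * dt
    if (!is.na(nxt)) {
      ring <- bird$rings[[nxt]]
      s0 <- sum((pos - ring$center) * ring$normal)
      s1 <- sum((p1 - ring$center) * ring$normal)
      if ((s0 < 0 && s1 >= 0) || (s0 > 0 && s1 <= 0)) passed[nxt] <- TRUE
    }
    pos <- p1
    dz_user[i] <- dz * params$s * o_rng / a_rng
    lean[i] <- ln
  }
  list(dz_user = dz_user, lean = lean)
}

# piecewise minimum-jerk interpolation through (kt, kv) keypoints
smooth_schedule <- function(time, kt, kv) {
  out <- numeric(length(time))
  for (i in seq_along(time)) {
    t <- time[i]
    k <- findInterval(t, kt)
    if (k <= 0) out[i] <- kv[1]
    else if (k >= length(kt)) out[i] <- kv[length(kv)]
    else {
      u <- (t - kt[k]) / (kt[k + 1] - kt[k])
      out[i] <- kv[k] + minjerk(u) * (kv[k + 1] - kv[k])
    }
  }
  out
}

#' Generate a synthetic cohort of players
#'
#' Draws per-subject player parameters for a control group (full-range,
#' standing) and a target group (impaired, seated), reproducibly from one
#' seed. The default distributions: control amplitude scale
#' s ~ U(0.9, 1), target s ~ U(0.05, 0.5); cadence U(0.8, 1.2) in both
#' groups (matched difficulty of intent); target reaction times and aim
#' scatter are larger, reflecting precision and speed deficits that gain
#' cannot equalise.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param control_dist,target_dist Named lists overriding the default
#'   parameter ranges; each element is a length-2 numeric range (uniform
#'   draw) or a single value, for any of `s`, `cadence`, `jitter_sd`,
#'   `reaction_time`, `aim_error`, `play_duration`, `seated`.
#' @param seed Integer seed.
#' @return Data frame (one row per subject) with the drawn parameters,
#'   `subject` id and `group` label; use [player_params()] rows via
#'   `cohort_params()`.
#' @export
generate_cohort <- function(n_per_group = 8, control_dist = list(),
                            target_dist = list(), seed = 1) {
  if (n_per_group < 2) stop("need at least 2 subjects per group", call. = FALSE)
  defaults <- list(
    control = list(s = c(0.9, 1), cadence = c(0.8, 1.2), jitter_sd = 0.005,
                   reaction_time = c(0.2, 0.4), aim_error = c(0.10, 0.20),
                   play_duration = c(100, 150), seated = FALSE),
    target = list(s = c(0.05, 0.5), cadence = c(0.8, 1.2), jitter_sd = 0.005,
                  reaction_time = c(0.5, 1.2), aim_error = c(0.25, 0.45),
                  play_duration = c(150, 250), seated = TRUE))
  defaults$control[names(control_dist)] <- control_dist
  defaults$target[names(target_dist)] <- target_dist
  set.seed(derive_seed(seed, 3))
  draw <- function(spec, n) {
    if (is.logical(spec)) rep(spec, n)
    else if (length(spec) == 2) stats::runif(n, spec[1], spec[2])
    else rep(spec, n)
  }
  rows <- do.call(rbind, lapply(c("control", "target"), function(g) {
    d <- defaults[[g]]
    data.frame(subject = paste0(substr(g, 1, 1), seq_len(n_per_group)),
               group = g,
               s = draw(d$s, n_per_group),
               cadence = draw(d$cadence, n_per_group),
               jitter_sd = draw(d$jitter_sd, n_per_group),
               seated = draw(d$seated, n_per_group),
               reaction_time = draw(d$reaction_time, n_per_group),
               aim_error = draw(d$aim_error, n_per_group),
               play_duration = draw(d$play_duration, n_per_group))
  }))
  rows$seed <- derive_seed(seed, 100 + seq_len(nrow(rows)))
  rownames(rows) <- NULL
  rows
}

#' Player parameters for one cohort row
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param i Row index.
#' @return A [player_params()].
#' @export
cohort_params <- function(cohort, i) {
  r <- cohort[i, ]
  player_params(s = r$s, cadence = r$cadence, jitter_sd = r$jitter_sd,
                seated = r$seated, reaction_time = r$reaction_time,
                aim_error = r$aim_error, play_duration = r$play_duration,
                seed = r$seed)
}
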