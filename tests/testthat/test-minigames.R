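ladder_subject <- function(s, seed, cadence = 1, jitter = 0, seated = FALSE,
                           band = NULL, amplify = TRUE, n_rungs = 10) {
  p <- player_params(s = s, cadence = cadence, jitter_sd = jitter,
                     seated = seated, seed = seed)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  cfg <- if (is.null(band)) ladder_config(AVATAR, n_rungs = n_rungs)
         else ladder_config(AVATAR, n_rungs = n_rungs, band = band)
  dur <- ceiling(n_rungs / cadence * 1.8) + 4
  tr <- generate_exercise_trace("climb", p, dur)
  run_session("ladder", tr, prof, AVATAR, cfg, seed = seed,
              amplify = amplify)
}

test_that("a full-range climber at 1 grab/s finishes 10 rungs in about 10 s", {
  res <- ladder_subject(s = 1, seed = 61)
  expect_true(res$completed)
  expect_equal(res$elapsed_time, 10, tolerance = 0.15)
  expect_equal(res$detail$rungs, 10L)
})

test_that("ladder completion time is invariant to amplitude scale (noiseless)", {
  base <- ladder_subject(s = 1, seed = 62)
  for (s in c(0.1, 0.3, 0.6)) {
    res <- ladder_subject(s = s, seed = 62)
    expect_true(res$completed)
    expect_lt(abs(res$elapsed_time - base$elapsed_time), 1 / 30 + 1e-9)
  }
})

test_that("a hand reaching only 90 % of its maximum scores no rung at a 95 % band", {
  p <- player_params(s = 1, jitter_sd = 0, seed = 63)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  cfg <- ladder_config(AVATAR, band = 0.95)
  # shrink the climb to 90 % of the calibrated amplitude
  p90 <- player_params(s = 0.9, jitter_sd = 0, seed = 63)
  tr <- generate_exercise_trace("climb", p90, 8)
  res <- run_session("ladder", tr, prof, AVATAR, cfg, smooth = 0)
  expect_equal(res$detail$rungs, 0L)
  expect_false(res$completed)
})

test_that("disabling amplification strands an impaired climber", {
  res <- ladder_subject(s = 0.15, seed = 64, amplify = FALSE)
  expect_false(res$completed)
  expect_equal(res$detail$rungs, 0L)
})

test_that("motionless ladder session runs out the trace without finishing", {
  p <- player_params(s = 1, jitter_sd = 0, seed = 65)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  tr <- const_trace(REST_STANDING, n = 90)
  res <- run_session("ladder", tr, prof, AVATAR, ladder_config(AVATAR))
  expect_false(res$completed)
  expect_equal(res$elapsed_time, 3, tolerance = 0.05)
})

test_that("rowing advances one stroke per period and needs all four ropes", {
  p <- player_params(s = 1, cadence = 1, jitter_sd = 0, seed = 66)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  cfg <- boat_config(AVATAR, course_length = 30, stroke_advance = 3)
  tr <- generate_exercise_trace("row", p, 25)
  res <- run_session("boat", tr, prof, AVATAR, cfg)
  expect_true(res$completed)
  # 10 strokes at one per second, plus the ramp-in
  expect_equal(res$elapsed_time, 10, tolerance = 1.5)
  expect_equal(res$detail$strokes, 10L)

  # one arm only: the other side's ropes never fire, no progress
  tr1 <- tr
  n <- n_frames(tr1)
  for (j in c("hand_left", "wrist_left", "elbow_left"))
    tr1$positions[, j, ] <- matrix(REST_STANDING[j, ], n, 3, byrow = TRUE)
  res1 <- run_session("boat", tr1, prof, AVATAR, cfg)
  expect_equal(res1$detail$strokes, 0L)
  expect_false(res1$completed)
})

test_that("a diagonal/circular stroke touching all four ropes still progresses", {
  # build a circular hand path through fore/aft points of both sides
  p <- player_params(s = 1, jitter_sd = 0, seed = 67)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  cfg <- boat_config(AVATAR, course_length = 9, stroke_advance = 3)
  n <- 600
  t <- seq(0, by = 1 / 30, length.out = n)
  pose <- REST_STANDING
  own <- fit_skeleton_to_pose(pose)
  pos <- array(rep(unclass(pose), each = n), c(n, 20, 3),
               dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  for (side in c("left", "right")) {
    limb <- paste0("hand_", side)
    rng <- avatar_required_ranges(own, limb)
    theta <- 2 * pi * t
    # diagonal ellipse: fore-aft plus sideways drift (the failure mode seen
    # with strict stroke ordering)
    pos[, limb, 1] <- pose[limb, 1] +
      ifelse(sin(theta) >= 0, rng["pos", "x"], rng["neg", "x"]) * sin(theta)
    pos[, limb, 2] <- pose[limb, 2] + 0.3 * rng["pos", "y"] * cos(theta)
  }
  tr <- motion_trace(t, pos, check_rate = FALSE)
  res <- run_session("boat", tr, prof, AVATAR, cfg, smooth = 0)
  expect_gt(res$detail$strokes, 0L)
  expect_true(res$completed)
})

test_that("mole hits require position, downward motion and speed", {
  cfg <- mole_config(AVATAR, n_moles = 4, duration = 24)
  p <- player_params(s = 1, jitter_sd = 0, aim_error = 0,
                     reaction_time = 0.2, seed = 68)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  sched <- mole_schedule(cfg, 68)
  tr <- generate_exercise_trace("whack", p, 24, schedule = sched)
  res <- run_session("mole", tr, prof, AVATAR, cfg, seed = 68)
  expect_equal(res$score, 4L)
  # same positions an order of magnitude slower: under the speed gate
  slow <- tr
  idx <- seq(1, n_frames(tr), by = 8)
  slow$positions <- tr$positions[idx, , , drop = FALSE]
  slow$time <- tr$time[seq_along(idx)] * 8
  slow <- motion_trace(slow$time, slow$positions, rate = 30 / 8,
                       check_rate = FALSE)
  cfg_slow <- cfg
  res_slow <- run_session("mole", slow, prof, AVATAR, cfg_slow, seed = 68)
  expect_equal(res_slow$score, 0L)
})

test_that("mole score is monotone in hit-speed threshold", {
  p <- player_params(s = 1, jitter_sd = 0.003, aim_error = 0.1,
                     reaction_time = 0.3, seed = 69)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  scores <- sapply(c(0.2, 0.6, 1.2, 3), function(v) {
    cfg <- mole_config(AVATAR, n_moles = 5, duration = 30, min_hit_speed = v)
    sched <- mole_schedule(cfg, 69)
    tr <- generate_exercise_trace("whack", p, 30, schedule = sched)
    run_session("mole", tr, prof, AVATAR, cfg, seed = 69)$score
  })
  expect_true(all(diff(scores) <= 0))
})

test_that("mole spawn schedule is deterministic per seed", {
  cfg <- mole_config(AVATAR)
  expect_identical(mole_schedule(cfg, 7), mole_schedule(cfg, 7))
  expect_false(identical(mole_schedule(cfg, 7)$hole,
                         mole_schedule(cfg, 8)$hole))
})

test_that("bird control law: level hands fly straight, lower left hand turns left", {
  cfg <- bird_config(rings = list())
  st <- bird_init(cfg, AVATAR$rest_pose)
  pose <- trace_pose(const_trace(AVATAR$rest_pose, n = 1), 1)
  for (i in 1:30) st <- step_bird(st, pose, 1 / 30)
  expect_equal(st$yaw, 0)
  expect_equal(st$pos[2], 0, tolerance = 1e-9)
  expect_equal(st$pos[3], 30, tolerance = 1e-9)
  expect_equal(st$pos[1], cfg$forward_speed, tolerance = 1e-9)
  # lower the left hand: bird turns towards the left (+y here)
  p2 <- unclass(AVATAR$rest_pose)
  p2["hand_left", 3] <- p2["hand_left", 3] - 0.2
  pose2 <- skeleton_pose(p2)
  st2 <- bird_init(cfg, AVATAR$rest_pose)
  for (i in 1:30) st2 <- step_bird(st2, pose2, 1 / 30)
  expect_lt(st2$yaw, 0)
  expect_gt(st2$pos[2], 0)
})

test_that("ring counting matches a scripted 3-of-5 trajectory", {
  rings <- default_rings(5)
  # straight path along x at the height/side of rings 1, 3, 4 only
  path <- cbind(seq(0, 130, by = 0.5), 0, 30)
  hit <- sapply(rings, function(r)
    sqrt(sum((c(0, r$center[2:3]) - c(0, 0, 30))^2)) <= r$radius)
  expect_equal(count_ring_passes(path, rings), sum(hit))
  # a path threaded exactly through rings 1, 3 and 5 of a straight course,
  # detouring around rings 2 and 4
  course <- lapply(1:5, function(i)
    list(center = c(10 * i, 0, 0), radius = 2, normal = c(1, 0, 0)))
  wx <- c(0, 14, 16, 24, 26, 34, 36, 44, 46, 55)
  wy <- c(0, 0, 10, 10, 0, 0, 10, 10, 0, 0)
  path2 <- do.call(rbind, lapply(seq_len(length(wx) - 1), function(i)
    cbind(seq(wx[i], wx[i + 1], length.out = 20),
          seq(wy[i], wy[i + 1], length.out = 20), 0)))
  expect_equal(count_ring_passes(path2, course), 3L)
})

test_that("sessions are deterministic: same trace, config and seed", {
  p <- player_params(s = 0.3, jitter_sd = 0.005, seated = TRUE, seed = 70)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  tr <- generate_exercise_trace("climb", p, 12)
  a <- run_session("ladder", tr, prof, AVATAR, seed = 5)
  b <- run_session("ladder", tr, prof, AVATAR, seed = 5)
  expect_identical(a, b)
})
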