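test_that("rope length is the Euclidean distance between attachments", {
  pose <- trace_pose(const_trace(n = 1), 1)
  r <- rope(c(0, 0, 0), c(0, 0, 0.5), trigger_length = 0.1)
  expect_equal(rope_length(pose, r), 0.5)
  r2 <- rope("hand_left", "hand_left", trigger_length = 0.1)
  expect_equal(rope_length(pose, r2), 0)
  set.seed(41)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3)
    r3 <- rope(a, b, trigger_length = 1)
    expect_equal(rope_length(pose, r3), sqrt(sum((a - b)^2)),
                 tolerance = 1e-12)
  }
  expect_error(rope_length(pose, rope("nose", c(0, 0, 0), 1)),
               "cannot resolve")
})

clap_trace <- function(dists) {
  # hands separated by the given distances along y
  n <- length(dists)
  pose <- REST_STANDING
  pos <- array(rep(unclass(pose), each = n), c(n, 20, 3),
               dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  pos[, "hand_left", 2] <- dists / 2
  pos[, "hand_right", 2] <- -dists / 2
  motion_trace(seq(0, by = 1 / 30, length.out = n), pos, check_rate = FALSE)
}

test_that("rope events: handclap produces one activation and one release", {
  d <- c(seq(0.6, 0.02, length.out = 30), seq(0.02, 0.6, length.out = 30))
  tr <- clap_trace(d)
  r <- rope("hand_left", "hand_right", trigger_length = 0.05, mode = "below",
            id = "clap")
  ev <- rope_events(tr, r)
  expect_equal(ev$kind, c("activated", "released"))
  expect_equal(ev$gadget, c("clap", "clap"))
})

test_that("rope events: first frame below trigger activates immediately", {
  tr <- clap_trace(rep(0.02, 10))
  ev <- rope_events(tr, rope("hand_left", "hand_right", 0.05, mode = "below"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "activated")
  expect_equal(ev$time, 0)
})

test_that("oscillation inside the hysteresis band emits nothing extra", {
  # cross the trigger once, then oscillate between trigger and trigger+hyst
  d <- c(0.2, 0.04, 0.052, 0.047, 0.053, 0.048, 0.054, 0.2)
  tr <- clap_trace(d)
  r <- rope("hand_left", "hand_right", trigger_length = 0.05,
            hysteresis = 0.01, mode = "below")
  ev <- rope_events(tr, r)
  expect_equal(ev$kind, c("activated", "released"))
  expect_equal(nrow(ev), 2L)
})

test_that("activations and releases strictly alternate on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    d <- abs(0.3 + cumsum(rnorm(200, sd = 0.05)))
    tr <- clap_trace(d)
    mode <- if (i %% 2) "below" else "above"
    r <- rope("hand_left", "hand_right", trigger_length = 0.3, mode = mode)
    ev <- rope_events(tr, r)
    if (nrow(ev) > 0) {
      expect_equal(ev$kind[1], "activated")
      expect_true(all(ev$kind == rep(c("activated", "released"),
                                     length.out = nrow(ev))))
    }
  }
})

test_that("identity amplification does not perturb rope detection", {
  p <- player_params(s = 1, jitter_sd = 0, seed = 43)
  prof <- profile_identity_factors(calibrate(generate_calibration_trace(p),
                                             AVATAR))
  tr <- generate_exercise_trace("climb", p, 5)
  amp <- retarget_trace(tr, prof, AVATAR)
  r <- rope("hand_left", AVATAR$rest_pose["hand_left", ] + c(0, 0, 0.3),
            trigger_length = 0.1, mode = "below")
  expect_equal(rope_events(tr, r), rope_events(amp, r), tolerance = 1e-9)
})

test_that("accelerometer speed: static, constant velocity, window averaging", {
  acc <- accelerometer("hand_left", window = 1)
  tr <- const_trace(n = 10)
  expect_equal(speed(tr, 5, acc), 0)
  # uniform motion of 0.01 m per frame at 30 Hz is 0.3 m/s
  n <- 30
  track <- matrix(rep(REST_STANDING["hand_left", ], each = n), n, 3)
  track[, 3] <- track[, 3] + 0.01 * (seq_len(n) - 1)
  tru <- tracked_trace("hand_left", track)
  expect_equal(speed(tru, 10, acc), 0.3, tolerance = 1e-9)
  expect_error(speed(tru, 1, acc), "undefined")
  # a wider window averages noise: closer to the true speed
  set.seed(44)
  noisy <- track
  noisy[, 3] <- noisy[, 3] + rnorm(n, sd = 0.004)
  trn <- tracked_trace("hand_left", noisy)
  e1 <- abs(sapply(5:25, function(i) speed(trn, i, accelerometer("hand_left", 1))) - 0.3)
  e3 <- abs(sapply(5:25, function(i) speed(trn, i, accelerometer("hand_left", 3))) - 0.3)
  expect_lt(mean(e3), mean(e1))
})

test_that("speed is invariant under rigid translation of the trace", {
  p <- player_params(s = 0.5, jitter_sd = 0.002, seed = 45)
  tr <- generate_exercise_trace("row", p, 4)
  tr2 <- tr
  tr2$positions <- tr$positions + rep(c(1.5, -2, 0.7), each = n_frames(tr) * 20)
  acc <- accelerometer("hand_right", window = 2)
  for (i in c(5, 30, 70))
    expect_equal(speed(tr, i, acc), speed(tr2, i, acc), tolerance = 1e-9)
})

test_that("dwell gestures fire after the dwell and re-arm after release", {
  # hand near head for 2 s, away, then again for 2 s
  n <- 240
  pose <- REST_STANDING
  head <- pose["head", ]
  track <- matrix(rep(pose["hand_left", ], each = n), n, 3)
  hold1 <- 31:90   # 2 s
  hold2 <- 151:210
  for (w in list(hold1, hold2))
    track[w, ] <- matrix(rep(head + c(0, 0.05, 0), each = length(w)),
                         length(w), 3)
  tr <- tracked_trace("hand_left", track)
  near_head <- function(p) sqrt(sum((p["hand_left", ] - p["head", ])^2)) < 0.1
  ev <- detect_control_gesture(tr, near_head, dwell = 1.5)
  act <- ev[ev$kind == "activated", ]
  expect_equal(nrow(act), 2L)
  expect_equal(act$time[1], tr$time[hold1[1]] + 1.5, tolerance = 1 / 30)
  # a 1 s hold with a 1.5 s dwell fires nothing
  track3 <- track
  track3[61:90, ] <- matrix(rep(pose["hand_left", ], each = 30), 30, 3)
  ev3 <- detect_control_gesture(tracked_trace("hand_left", track3[1:120, ]),
                                near_head, dwell = 1.5)
  expect_equal(nrow(ev3[ev3$kind == "activated", ]), 0L)
  expect_error(detect_control_gesture(tr, near_head, dwell = 0.2),
               "0.5")
})
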