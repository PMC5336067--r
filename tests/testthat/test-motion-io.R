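test_that("joint streams round-trip in both dialects and parse identically", {
  set.seed(31)
  n <- 100
  pos <- array(rnorm(n * 20 * 3), c(n, 20, 3),
               dimnames = list(NULL, kinect_joints(), c("x", "y", "z")))
  tr <- motion_trace(seq(0, by = 1 / 30, length.out = n), pos)
  csv <- tempfile(fileext = ".csv")
  jsl <- tempfile(fileext = ".jsonl")
  write_joint_stream(tr, csv)
  write_joint_stream(tr, jsl)
  back_csv <- read_joint_stream(csv)
  back_jsl <- read_joint_stream(jsl)
  expect_equal(back_csv$positions, tr$positions, tolerance = 1e-12)
  expect_equal(back_csv$time, tr$time, tolerance = 1e-12)
  # the two dialects parse to identical traces
  expect_identical(back_csv$positions, back_jsl$positions)
  expect_identical(back_csv$time, back_jsl$time)
  unlink(c(csv, jsl))
})

test_that("zero input and malformed joint streams", {
  tr0 <- const_trace(n = 2)
  tr0$positions[] <- 0
  f <- tempfile(fileext = ".csv")
  write_joint_stream(tr0, f)
  back <- read_joint_stream(f)
  expect_equal(n_frames(back), 2L)
  expect_true(all(back$positions == 0))
  # unknown joint name is rejected, naming the row
  lines <- readLines(f)
  lines[3] <- sub("spine", "elbow_left_typo", lines[3])
  writeLines(lines, f)
  expect_error(read_joint_stream(f), "elbow_left_typo")
  # missing joint in a frame
  write_joint_stream(tr0, f)
  writeLines(readLines(f)[-3], f)
  expect_error(read_joint_stream(f), "missing joint")
  # non-monotonic time
  write_joint_stream(tr0, f)
  lines <- readLines(f)
  lines <- c(lines[1], lines[22:41], lines[2:21])
  writeLines(lines, f)
  expect_error(read_joint_stream(f), "ordered by time")
  unlink(f)
})

test_that("BVH round trip preserves positions to well under 1e-6 m", {
  p <- player_params(s = 0.6, jitter_sd = 0.002, seed = 33)
  tr <- generate_exercise_trace("climb", p, 3)
  model <- fit_skeleton_to_pose(trace_pose(tr, 1))
  f <- tempfile(fileext = ".bvh")
  write_bvh(model, tr, f)
  back <- read_bvh(f)
  expect_lt(max(abs(back$trace$positions - tr$positions)), 1e-6)
  expect_equal(back$model$lengths, model$lengths, tolerance = 1e-6)
  unlink(f)
})

test_that("BVH with all channels zero reproduces the rest offsets", {
  model <- AVATAR
  tr <- const_trace(model$rest_pose, n = 1)
  f <- tempfile(fileext = ".bvh")
  write_bvh(model, tr, f)
  back <- read_bvh(f)
  expect_equal(back$trace$positions[1, , ], unclass(model$rest_pose),
               tolerance = 1e-8, ignore_attr = TRUE)
  unlink(f)
})

test_that("BVH rotation channels follow standard forward kinematics", {
  # write a rest-pose file, then inject a 90 degree Z rotation at the left
  # shoulder; the left arm subtree must rotate about the shoulder
  model <- AVATAR
  rest <- model$rest_pose
  f <- tempfile(fileext = ".bvh")
  write_bvh(model, const_trace(rest, n = 1), f)
  lines <- readLines(f)
  # give every joint rotation channels instead of position channels
  lines <- gsub("CHANNELS 3 Xposition Yposition Zposition",
                "CHANNELS 3 Zrotation Xrotation Yrotation", lines)
  vals <- rep(0, 6 + 19 * 3)
  joint_order <- amplimotion:::bvh_joint_order(kinect_parents())
  vals[1:3] <- rest["hip_center", ]
  k <- which(joint_order == "shoulder_left")
  vals[6 + (k - 2) * 3 + 1] <- 90          # Zrotation of shoulder_left
  lines[length(lines)] <- paste(sprintf("%.9f", vals), collapse = " ")
  writeLines(lines, f)
  back <- read_bvh(f)
  got <- back$trace$positions[1, , ]
  # oracle: rotate the subtree offsets by hand
  rotz <- function(v) c(-v[2], v[1], v[3])
  sh <- rest["shoulder_left", ]
  expected_elbow <- sh + rotz(rest["elbow_left", ] - sh)
  expect_equal(got["elbow_left", ], expected_elbow, tolerance = 1e-9,
               ignore_attr = TRUE)
  expected_hand <- sh + rotz(rest["hand_left", ] - sh)
  expect_equal(got["hand_left", ], expected_hand, tolerance = 1e-9,
               ignore_attr = TRUE)
  # untouched subtree unchanged
  expect_equal(got["hand_right", ], rest["hand_right", ],
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(f)
})

test_that("unmappable BVH joints raise a mapping error", {
  model <- AVATAR
  f <- tempfile(fileext = ".bvh")
  write_bvh(model, const_trace(model$rest_pose, n = 1), f)
  lines <- readLines(f)
  lines <- sub("JOINT Spine", "JOINT Torso", lines)
  writeLines(lines, f)
  expect_error(read_bvh(f), "Torso")
  unlink(f)
})

test_that("calibration profiles survive a JSON round trip", {
  p <- player_params(s = 0.2, jitter_sd = 0.003, seated = TRUE, seed = 35)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  f <- tempfile(fileext = ".json")
  save_profile(prof, f)
  back <- load_profile(f)
  for (limb in names(prof$limbs)) {
    expect_equal(back$limbs[[limb]]$factors, prof$limbs[[limb]]$factors,
                 tolerance = 1e-12)
    expect_equal(back$limbs[[limb]]$resting, prof$limbs[[limb]]$resting,
                 tolerance = 1e-12)
    expect_equal(back$limbs[[limb]]$offset, prof$limbs[[limb]]$offset,
                 tolerance = 1e-12)
    expect_identical(back$limbs[[limb]]$usable, prof$limbs[[limb]]$usable)
  }
  expect_equal(back$trunk_resting, prof$trunk_resting, tolerance = 1e-12)
  # a boundary factor of 25 survives
  prof$limbs$hand_left$factors[] <- 25
  save_profile(prof, f)
  expect_true(all(load_profile(f)$limbs$hand_left$factors == 25))
  unlink(f)
})

test_that("profile schema violations are explicit errors", {
  p <- player_params(s = 1, jitter_sd = 0, seed = 36)
  prof <- calibrate(generate_calibration_trace(p), AVATAR)
  f <- tempfile(fileext = ".json")
  save_profile(prof, f)
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  obj$version <- "9.9"
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(load_profile(f), "version")
  obj$version <- "1.0"
  obj$limbs$hand_left$resting <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(load_profile(f), "resting")
  unlink(f)
})
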