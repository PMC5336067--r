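#' Canonical joint set
#'
#' The 20-joint skeleton tracked by first-generation depth sensors. Joint
#' positions are expressed in metres with the z axis vertical (up), the y
#' axis lateral in the viewing plane, and the x axis along the depth
#' direction towards the sensor.
#'
#' @return Character vector of the 20 canonical joint names.
#' @export
kinect_joints <- function() {
  c("hip_center", "spine", "shoulder_center", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right")
}

#' Parent of each joint in the skeleton tree
#'
#' @return Named character vector mapping every joint except the root
#'   (`hip_center`) to its parent.
#' @export
kinect_parents <- function() {
  c(spine = "hip_center", shoulder_center = "spine", head = "shoulder_center",
    shoulder_left = "shoulder_center", elbow_left = "shoulder_left",
    wrist_left = "elbow_left", hand_left = "wrist_left",
    shoulder_right = "shoulder_center", elbow_right = "shoulder_right",
    wrist_right = "elbow_right", hand_right = "wrist_right",
    hip_left = "hip_center", knee_left = "hip_left",
    ankle_left = "knee_left", foot_left = "ankle_left",
    hip_right = "hip_center", knee_right = "hip_right",
    ankle_right = "knee_right", foot_right = "ankle_right")
}

# joints that are copied through to the avatar without amplification
trunk_joints <- function() {
  c("hip_center", "spine", "shoulder_center", "head",
    "shoulder_left", "shoulder_right", "hip_left", "hip_right")
}

# limb chains solved by two-bone IK; "mid2" rides on the mid->end segment
limb_chains <- function() {
  list(
    hand_left  = list(root = "shoulder_left",  mid = "elbow_left",
                      mid2 = "wrist_left",  end = "hand_left"),
    hand_right = list(root = "shoulder_right", mid = "elbow_right",
                      mid2 = "wrist_right", end = "hand_right"),
    foot_left  = list(root = "hip_left",  mid = "knee_left",
                      mid2 = "ankle_left",  end = "foot_left"),
    foot_right = list(root = "hip_right", mid = "knee_right",
                      mid2 = "ankle_right", end = "foot_right")
  )
}

#' Construct a single skeleton pose
#'
#' @param positions Numeric 20 x 3 matrix of joint positions in metres; row
#'   names must be the canonical joint names (any order), columns x, y, z.
#' @param time Timestamp in seconds.
#' @return An object of class `skeleton_pose`: the position matrix in
#'   canonical joint order with a `time` attribute.
#' @export
skeleton_pose <- function(positions, time = 0) {
  joints <- kinect_joints()
  if (!is.matrix(positions) || ncol(positions) != 3L)
    stop("`positions` must be a 20 x 3 numeric matrix", call. = FALSE)
  if (is.null(rownames(positions)) || !setequal(rownames(positions), joints))
    stop("`positions` must have the 20 canonical joint names as row names",
         call. = FALSE)
  positions <- positions[joints, , drop = FALSE]
  colnames(positions) <- c("x", "y", "z")
  if (!all(is.finite(positions)))
    stop("joint positions must be finite", call. = FALSE)
  attr(positions, "time") <- as.numeric(time)
  class(positions) <- c("skeleton_pose", class(positions))
  positions
}

#' Construct a motion trace
#'
#' A motion trace is an ordered sequence of skeleton poses sampled at a
#' nominal frame rate (30 Hz by default, the nominal rate of the Kinect V1).
#'
#' @param time Numeric vector of strictly increasing timestamps in seconds.
#' @param positions Numeric array of dimension `c(n_frames, 20, 3)` with the
#'   canonical joint names on the second dimension.
#' @param rate Nominal frame rate in Hz.
#' @param check_rate Verify that timestamps are uniform at `rate` to within
#'   1 ms (the default); disable for irregularly sampled input.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(time, positions, rate = 30, check_rate = TRUE) {
  joints <- kinect_joints()
  if (length(dim(positions)) != 3L || dim(positions)[2] != 20L ||
      dim(positions)[3] != 3L)
    stop("`positions` must be an n x 20 x 3 array", call. = FALSE)
  if (dim(positions)[1] != length(time))
    stop("length(time) must match the number of frames", call. = FALSE)
  jn <- dimnames(positions)[[2]]
  if (is.null(jn) || !setequal(jn, joints))
    stop("the second dimension must be named with the 20 canonical joints",
         call. = FALSE)
  positions <- positions[, joints, , drop = FALSE]
  dimnames(positions)[[3]] <- c("x", "y", "z")
  if (!all(is.finite(positions)))
    stop("joint positions must be finite", call. = FALSE)
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    if (check_rate && any(abs(dt - 1 / rate) > 1e-3))
      stop("timestamps deviate from the nominal rate by more than 1 ms",
           call. = FALSE)
  }
  structure(list(time = as.numeric(time), positions = positions,
                 rate = rate),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, %.4g s at %g Hz, 20 joints\n",
              n_frames(x), diff(range(x$time)), x$rate))
  invisible(x)
}

#' Number of frames in a motion trace
#' @param trace A `motion_trace`.
#' @return Integer frame count.
#' @export
n_frames <- function(trace) length(trace$time)

#' Extract one frame of a trace as a skeleton pose
#' @param trace A `motion_trace`.
#' @param i Frame index.
#' @return A `skeleton_pose`.
#' @export
trace_pose <- function(trace, i) {
  skeleton_pose(trace$positions[i, , ], time = trace$time[i])
}

# unchecked pose extraction for hot loops (trace already validated)
trace_pose_fast <- function(trace, i) {
  m <- trace$positions[i, , ]
  attr(m, "time") <- trace$time[i]
  class(m) <- c("skeleton_pose", class(m))
  m
}

#' Positions of one joint across all frames
#' @param trace A `motion_trace`.
#' @param joint Canonical joint name.
#' @return n x 3 matrix of positions.
#' @export
joint_track <- function(trace, joint) {
  if (!joint %in% kinect_joints())
    stop(sprintf("unknown joint '%s'", joint), call. = FALSE)
  trace$positions[, joint, , drop = TRUE]
}

#' Fit a skeleton model to a pose
#'
#' Adapts the skeleton to the player's physical appearance: every bone
#' length is set to the inter-joint distance observed in the given pose,
#' and the pose itself is retained as the model's rest pose.
#'
#' @param pose A `skeleton_pose`.
#' @return An object of class `skeleton_model` with elements `parents`
#'   (named character vector), `lengths` (bone lengths in metres, named by
#'   child joint) and `rest_pose`.
#' @export
fit_skeleton_to_pose <- function(pose) {
  parents <- kinect_parents()
  lens <- vapply(names(parents), function(child) {
    sqrt(sum((pose[child, ] - pose[parents[[child]], ])^2))
  }, numeric(1))
  if (any(lens <= 0)) {
    bad <- names(lens)[lens <= 0][1]
    stop(sprintf("invalid pose: joint '%s' coincides with its parent '%s'",
                 bad, parents[[bad]]), call. = FALSE)
  }
  structure(list(parents = parents, lengths = lens, rest_pose = pose),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model> 20 joints, arm reach %.3f m, leg reach %.3f m\n",
              limb_reach(x, "hand_left"), limb_reach(x, "foot_left")))
  invisible(x)
}

# total chain length root -> end for a limb
limb_reach <- function(model, limb) {
  ch <- limb_chains()[[limb]]
  unname(model$lengths[ch$mid] + model$lengths[ch$mid2] +
           model$lengths[ch$end])
}

#' Analytic two-bone inverse kinematics
#'
#' Places the middle joint (elbow/knee) and the end joint (wrist/foot) of a
#' two-segment limb so that the end reaches `target`, preserving both
#' segment lengths exactly. If the target is outside the annulus of
#' reachable distances, the end joint is clamped to the nearest reachable
#' point on the root-to-target line. The bend plane is the plane through
#' root, target and `bend_hint`; if the hint is (numerically) collinear
#' with the root-target axis an arbitrary perpendicular is chosen.
#'
#' @param root Position of the fixed joint (shoulder/hip), 3-vector.
#' @param target Desired end position, 3-vector.
#' @param len_upper,len_lower Segment lengths in metres, both positive.
#' @param bend_hint Direction the middle joint should bend towards.
#'   Defaults to the depth axis (towards the sensor).
#' @return List with elements `mid` and `end` (3-vectors).
#' @export
solve_two_bone_ik <- function(root, target, len_upper, len_lower,
                              bend_hint = c(1, 0, 0)) {
  if (len_upper <= 0 || len_lower <= 0)
    stop("segment lengths must be positive", call. = FALSE)
  root <- as.numeric(root); target <- as.numeric(target)
  v <- target - root
  d <- sqrt(sum(v^2))
  if (d < 1e-12) {
    # degenerate: no direction to the target; extend along the bend hint
    u <- bend_hint / sqrt(sum(bend_hint^2))
    d_eff <- abs(len_upper - len_lower)
  } else {
    u <- v / d
    d_eff <- min(max(d, abs(len_upper - len_lower)), len_upper + len_lower)
  }
  end <- root + d_eff * u
  # law of cosines for the root angle of the (upper, lower, d_eff) triangle
  cos_a <- (len_upper^2 + d_eff^2 - len_lower^2) / (2 * len_upper * d_eff)
  cos_a <- min(1, max(-1, cos_a))
  sin_a <- sqrt(max(0, 1 - cos_a^2))
  # perpendicular in the bend plane
  w <- bend_hint - sum(bend_hint * u) * u
  wn <- sqrt(sum(w^2))
  if (wn < 1e-9) {
    # hint collinear with the chain axis: pick any perpendicular
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * u) * u
    wn <- sqrt(sum(w^2))
  }
  w <- w / wn
  mid <- root + len_upper * (cos_a * u + sin_a * w)
  list(mid = mid, end = end)
}

# Vectorised two-bone IK over frames. roots/targets/hints: n x 3 matrices.
# Returns list(mid, end), each n x 3. Must agree with solve_two_bone_ik().
ik_solve_frames <- function(roots, targets, len_upper, len_lower, hints) {
  v <- targets - roots
  d <- sqrt(rowSums(v^2))
  degen <- d < 1e-12
  u <- v / pmax(d, 1e-12)
  if (any(degen)) {
    hn <- hints[degen, , drop = FALSE]
    u[degen, ] <- hn / sqrt(rowSums(hn^2))
  }
  d_eff <- pmin(pmax(d, abs(len_upper - len_lower)), len_upper + len_lower)
  d_eff[degen] <- abs(len_upper - len_lower)
  end <- roots + u * d_eff
  cos_a <- (len_upper^2 + d_eff^2 - len_lower^2) / (2 * len_upper * d_eff)
  cos_a <- pmin(1, pmax(-1, cos_a))
  sin_a <- sqrt(pmax(0, 1 - cos_a^2))
  w <- hints - u * rowSums(hints * u)
  wn <- sqrt(rowSums(w^2))
  bad <- wn < 1e-9
  if (any(bad)) {
    alt <- matrix(rep(c(1, 0, 0), each = sum(bad)), ncol = 3)
    swap <- abs(u[bad, 1]) >= 0.9
    alt[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    ub <- u[bad, , drop = FALSE]
    alt <- alt - ub * rowSums(alt * ub)
    w[bad, ] <- alt
    wn[bad] <- sqrt(rowSums(alt^2))
  }
  w <- w / wn
  mid <- roots + len_upper * (u * cos_a + w * sin_a)
  list(mid = mid, end = end)
}
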