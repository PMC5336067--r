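#' Rope gadget: a virtual elastic band measuring distance
#'
#' Two attachment points (joint names or fixed world points) mark the ends
#' of an imaginary elastic rope. Crossing the trigger length fires an
#' event; re-crossing by the hysteresis margin releases it. In `"below"`
#' mode the rope activates when the ends come closer than the trigger
#' (handclap detection); in `"above"` mode when they separate beyond it
#' (stretch detection).
#'
#' @param end_a,end_b Joint name (character) or fixed world point
#'   (numeric 3-vector).
#' @param trigger_length Trigger distance in metres, positive.
#' @param hysteresis Release margin in metres; defaults to 10 % of the
#'   trigger length (sensor jitter would otherwise chatter).
#' @param mode `"below"` or `"above"`.
#' @param id Gadget identifier used in emitted events.
#' @return An object of class `rope`.
#' @export
rope <- function(end_a, end_b, trigger_length, hysteresis = 0.1 * trigger_length,
                 mode = c("below", "above"), id = "rope") {
  if (trigger_length <= 0) stop("trigger_length must be positive", call. = FALSE)
  if (hysteresis < 0) stop("hysteresis must be >= 0", call. = FALSE)
  structure(list(end_a = end_a, end_b = end_b,
                 trigger_length = trigger_length, hysteresis = hysteresis,
                 mode = match.arg(mode), id = id),
            class = "rope")
}

resolve_attachment <- function(pose, end) {
  if (is.character(end)) {
    if (!end %in% kinect_joints())
      stop(sprintf("cannot resolve attachment '%s'", end), call. = FALSE)
    as.numeric(pose[end, ])
  } else as.numeric(end)
}

#' Length of a rope in a pose
#'
#' @param pose A `skeleton_pose`.
#' @param rope A [rope()].
#' @return Euclidean distance between the resolved endpoints, metres.
#' @export
rope_length <- function(pose, rope) {
  a <- resolve_attachment(pose, rope$end_a)
  b <- resolve_attachment(pose, rope$end_b)
  sqrt(sum((a - b)^2))
}

# rope lengths across all frames of a trace (vectorised)
rope_lengths <- function(trace, rope) {
  n <- n_frames(trace)
  a <- if (is.character(rope$end_a)) joint_track(trace, rope$end_a)
       else matrix(as.numeric(rope$end_a), n, 3, byrow = TRUE)
  b <- if (is.character(rope$end_b)) joint_track(trace, rope$end_b)
       else matrix(as.numeric(rope$end_b), n, 3, byrow = TRUE)
  if (n == 1) { a <- matrix(a, 1, 3); b <- matrix(b, 1, 3) }
  sqrt(rowSums((a - b)^2))
}

#' Rope activation/release events over a trace
#'
#' The first frame is evaluated directly against the trigger; afterwards an
#' activation requires crossing the trigger in the rope's direction and a
#' release requires re-crossing by at least the hysteresis margin, so
#' activations and releases strictly alternate and oscillation inside the
#' hysteresis band emits nothing.
#'
#' @param trace A `motion_trace`.
#' @param rope A [rope()].
#' @return Data frame with columns `time`, `gadget`, `kind`
#'   (`"activated"`/`"released"`) and `value` (rope length, metres).
#' @export
rope_events <- function(trace, rope) {
  if (n_frames(trace) == 0) stop("empty trace", call. = FALSE)
  len <- rope_lengths(trace, rope)
  st <- rope_state(rope)
  out <- vector("list", length(len))
  for (i in seq_along(len)) {
    st <- rope_step(st, len[i], trace$time[i])
    out[[i]] <- st$event
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev))
    return(data.frame(time = numeric(0), gadget = character(0),
                      kind = character(0), value = numeric(0)))
  rownames(ev) <- NULL
  ev
}

# incremental rope state machine (used by the games)
rope_state <- function(rope) list(rope = rope, active = FALSE, event = NULL)

rope_step <- function(st, len, time) {
  r <- st$rope
  st$event <- NULL
  trig <- if (r$mode == "below") len <= r$trigger_length
          else len >= r$trigger_length
  rel <- if (r$mode == "below") len >= r$trigger_length + r$hysteresis
         else len <= r$trigger_length - r$hysteresis
  if (!st$active && trig) {
    st$active <- TRUE
    st$event <- data.frame(time = time, gadget = r$id, kind = "activated",
                           value = len)
  } else if (st$active && rel) {
    st$active <- FALSE
    st$event <- data.frame(time = time, gadget = r$id, kind = "released",
                           value = len)
  }
  st
}

#' Accelerometer gadget: a speed probe
#'
#' Despite its name the gadget reports speed, not acceleration: the
#' magnitude of a backward finite difference of the attachment position
#' over `window` frames.
#'
#' @param attachment Joint name or fixed world point.
#' @param window Number of frames for the backward difference (>= 1;
#'   default 2, which suppresses some frame jitter at 30 Hz).
#' @param id Gadget identifier.
#' @return An object of class `accelerometer`.
#' @export
accelerometer <- function(attachment, window = 2, id = "accelerometer") {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  structure(list(attachment = attachment, window = as.integer(window),
                 id = id),
            class = "accelerometer")
}

#' Speed measured by an accelerometer gadget at a frame
#'
#' @param trace A `motion_trace`.
#' @param index Frame index; must be greater than the gadget's window.
#' @param gadget An [accelerometer()].
#' @return Speed in m/s.
#' @export
speed <- function(trace, index, gadget) {
  w <- gadget$window
  if (index <= w)
    stop(sprintf("speed undefined at frame %d: needs %d earlier frames",
                 index, w), call. = FALSE)
  p <- if (is.character(gadget$attachment))
    joint_track(trace, gadget$attachment) else
      stop("speed of a fixed world point is zero; attach to a joint",
           call. = FALSE)
  dt <- trace$time[index] - trace$time[index - w]
  sqrt(sum((p[index, ] - p[index - w, ])^2)) / dt
}

# vectorised speeds for all frames (NA where undefined)
speed_track <- function(trace, gadget) {
  w <- gadget$window
  p <- joint_track(trace, gadget$attachment)
  n <- n_frames(trace)
  out <- rep(NA_real_, n)
  idx <- (w + 1):n
  dt <- trace$time[idx] - trace$time[idx - w]
  out[idx] <- sqrt(rowSums((p[idx, , drop = FALSE] -
                              p[idx - w, , drop = FALSE])^2)) / dt
  out
}

#' Detect dwell-based game-control gestures
#'
#' Distinguishes game-control actions (opening a menu, pausing) from
#' exercise movements: a control gesture fires when a pose predicate (e.g.
#' "hand within 10 cm of the head") holds continuously for the dwell time.
#' An `activated` event is emitted at the moment the dwell completes and a
#' `released` event when the predicate first fails afterwards; exercise
#' processing for the involved limb should be suppressed between the two.
#'
#' @param trace A `motion_trace`.
#' @param predicate Function taking a `skeleton_pose`, returning `TRUE`
#'   while the control pose is held.
#' @param dwell Dwell time in seconds (>= 0.5).
#' @param id Gadget identifier.
#' @return Event data frame as in [rope_events()] (`value` is the held
#'   duration in seconds).
#' @export
detect_control_gesture <- function(trace, predicate, dwell = 1.5,
                                   id = "gesture") {
  if (dwell < 0.5) stop("dwell must be at least 0.5 s", call. = FALSE)
  n <- n_frames(trace)
  held <- vapply(seq_len(n),
                 function(i) isTRUE(predicate(trace_pose_fast(trace, i))),
                 logical(1))
  events <- list()
  start <- NA_real_
  fired <- FALSE
  for (i in seq_len(n)) {
    t <- trace$time[i]
    if (held[i]) {
      if (is.na(start)) start <- t
      if (!fired && t - start >= dwell) {
        fired <- TRUE
        events[[length(events) + 1]] <-
          data.frame(time = start + dwell, gadget = id, kind = "activated",
                     value = t - start)
      }
    } else {
      if (fired)
        events[[length(events) + 1]] <-
          data.frame(time = t, gadget = id, kind = "released",
                     value = t - start)
      start <- NA_real_
      fired <- FALSE
    }
  }
  ev <- do.call(rbind, events)
  if (is.null(ev))
    return(data.frame(time = numeric(0), gadget = character(0),
                      kind = character(0), value = numeric(0)))
  ev
}
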