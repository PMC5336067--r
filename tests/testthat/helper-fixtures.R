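# shared fixtures: one avatar model and small trace builders

AVATAR <- default_avatar()
REST_STANDING <- default_rest_pose(FALSE)

# constant-pose trace with optional jitter
const_trace <- function(pose = REST_STANDING, n = 60, rate = 30,
                        jitter_sd = 0, seed = 1) {
  pos <- array(rep(unclass(pose), each = n), c(n, 20, 3),
               dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  if (jitter_sd > 0) {
    set.seed(seed)
    pos <- pos + array(rnorm(length(pos), 0, jitter_sd), dim(pos))
  }
  motion_trace(seq(0, by = 1 / rate, length.out = n), pos, rate = rate,
               check_rate = FALSE)
}

# trace where one joint follows a supplied n x 3 track, others rest
tracked_trace <- function(joint, track, pose = REST_STANDING, rate = 30) {
  n <- nrow(track)
  pos <- array(rep(unclass(pose), each = n), c(n, 20, 3),
               dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  pos[, joint, ] <- track
  motion_trace(seq(0, by = 1 / rate, length.out = n), pos, rate = rate,
               check_rate = FALSE)
}

random_unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
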