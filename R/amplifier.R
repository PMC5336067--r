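#' Direct per-axis motion amplification
#'
#' Amplifies a limb displacement about its recorded resting point: the
#' returned position is `resting + f * (position - resting)` applied per
#' axis, where `f` on each axis is the factor for the sign of that axis'
#' displacement. Zero displacement is an exact fixed point, so the resting,
#' real and amplified markers coincide when the limb rests.
#'
#' @param resting Resting position (origin of the movement), 3-vector.
#' @param position Current limb position, 3-vector.
#' @param factors Either a length-3 vector of per-axis factors, or a 2 x 3
#'   matrix with rows `pos` and `neg` giving direction-specific factors.
#' @return Amplified position, 3-vector.
#' @export
amplify_direct <- function(resting, position, factors) {
  f <- as_factor_matrix(factors)
  d <- as.numeric(position) - as.numeric(resting)
  fa <- ifelse(d >= 0, f["pos", ], f["neg", ])
  as.numeric(resting) + fa * d
}

as_factor_matrix <- function(factors) {
  if (is.matrix(factors)) {
    stopifnot(nrow(factors) == 2L, ncol(factors) == 3L)
    if (is.null(rownames(factors))) rownames(factors) <- c("pos", "neg")
    return(factors)
  }
  f <- rbind(pos = as.numeric(factors), neg = as.numeric(factors))
  stopifnot(ncol(f) == 3L)
  f
}

#' Bone-chain amplifier
#'
#' The amplifier is realised as a chain of `n_bones` concatenated bones,
#' each copying the local displacement of its parent, so the first bone's
#' displacement accumulates `n_bones` times at the tip. A final bone
#' imitates the tip's global position through per-axis restriction factors
#' `f_res` in [0, 1], giving a global per-axis gain of `n_bones * f_res`.
#'
#' @param n_bones Number of bones in the chain (default 25, the design
#'   maximum gain).
#' @param f_res Per-axis restriction factors, length 3, each in [0, 1].
#' @return An object of class `amplifier_chain`.
#' @export
amplifier_chain <- function(n_bones = 25, f_res = c(1, 1, 1)) {
  f_res <- as.numeric(f_res)
  if (length(f_res) != 3L || any(f_res < 0) || any(f_res > 1))
    stop("`f_res` must be three values in [0, 1]", call. = FALSE)
  if (n_bones < 1) stop("`n_bones` must be >= 1", call. = FALSE)
  structure(list(n_bones = as.integer(n_bones), f_res = f_res),
            class = "amplifier_chain")
}

#' Amplify a displacement through the bone chain
#'
#' Closed form of the chain recurrence: the amplified displacement is
#' `n_bones * f_res * displacement` per axis. Exactly equivalent to
#' [amplify_chain_iterative()], which evaluates the parent-copy recurrence
#' bone by bone.
#'
#' @param chain An [amplifier_chain()].
#' @param displacement Real (captured) displacement, 3-vector.
#' @return Amplified displacement, 3-vector.
#' @export
amplify_chain <- function(chain, displacement) {
  chain$n_bones * chain$f_res * as.numeric(displacement)
}

#' Amplify via the explicit parent-copy recurrence
#'
#' Reference implementation of the chain: each bone copies the local
#' displacement of its parent into its own frame, so the displacement at
#' bone k is k times the input; the final bone then imitates the last
#' bone's position restricted per axis by `f_res`.
#'
#' @inheritParams amplify_chain
#' @return Amplified displacement, 3-vector.
#' @export
amplify_chain_iterative <- function(chain, displacement) {
  local <- as.numeric(displacement)
  tip <- c(0, 0, 0)
  for (k in seq_len(chain$n_bones)) tip <- tip + local
  chain$f_res * tip
}

#' Convert calibration factors to chain restriction factors
#'
#' Inverts the global-gain relation `f = n_bones * f_res`: each per-axis
#' factor becomes a restriction in [0, 1]. Factors above the chain's
#' maximum gain are a contract violation (calibration clips at the
#' ceiling) and raise an error.
#'
#' @param factors Per-axis amplification factors, each in (0, n_bones].
#' @param n_bones Chain length (default 25).
#' @return Numeric vector of restriction factors `factors / n_bones`.
#' @export
factors_to_restrictions <- function(factors, n_bones = 25) {
  factors <- as.numeric(factors)
  if (any(factors <= 0))
    stop("factors must be positive", call. = FALSE)
  if (any(factors > n_bones))
    stop(sprintf("factor exceeds the chain maximum of %d; calibration should have clipped it",
                 n_bones), call. = FALSE)
  factors / n_bones
}

#' Retarget a user pose onto the avatar skeleton
#'
#' For every calibrated outer limb (hands and feet) the user displacement
#' from its resting point is amplified by the profile's per-axis,
#' per-direction factors and applied at the avatar's resting point for that
#' limb (the user resting point shifted by the profile offset). The arm or
#' leg then follows via two-bone inverse kinematics; the intermediate
#' wrist/ankle joint is placed on the solved lower segment. Trunk, head,
#' shoulder and hip joints are copied with their unamplified displacement
#' onto the avatar's rest pose. Limbs missing from the profile are copied
#' unamplified with a warning.
#'
#' @param pose User `skeleton_pose`.
#' @param profile A calibration profile (see [calibrate()]).
#' @param avatar_model Avatar `skeleton_model`.
#' @return A `skeleton_pose` for the avatar with an attribute `markers`: a
#'   per-limb list of `resting` (red), `real` (green, unamplified) and
#'   `amplified` (yellow) marker points.
#' @export
retarget_pose <- function(pose, profile, avatar_model) {
  tr <- pose_to_trace(pose)
  out <- retarget_trace(tr, profile, avatar_model)
  res <- trace_pose(out, 1)
  mk <- attr(out, "markers")
  attr(res, "markers") <- lapply(mk, function(m)
    list(resting = m$resting, real = m$real[1, ], amplified = m$amplified[1, ]))
  res
}

pose_to_trace <- function(pose) {
  arr <- array(unclass(pose), dim = c(1, 20, 3),
               dimnames = list(NULL, rownames(pose), c("x", "y", "z")))
  motion_trace(attr(pose, "time"), arr, rate = 30, check_rate = FALSE)
}

#' Retarget a whole trace onto the avatar skeleton
#'
#' Vectorised version of [retarget_pose()] applied frame by frame.
#'
#' @param trace User `motion_trace`.
#' @inheritParams retarget_pose
#' @return Avatar `motion_trace` with a `markers` attribute (per-limb list
#'   of marker tracks).
#' @export
retarget_trace <- function(trace, profile, avatar_model) {
  stopifnot(inherits(profile, "calibration"))
  n <- n_frames(trace)
  joints <- kinect_joints()
  pos <- trace$positions
  out <- pos
  rest_av <- avatar_model$rest_pose

  # trunk block: avatar rest + unamplified user displacement
  for (j in trunk_joints()) {
    d <- pos[, j, , drop = TRUE] - matrix(profile$trunk_resting[j, ],
                                          n, 3, byrow = TRUE)
    out[, j, ] <- matrix(rest_av[j, ], n, 3, byrow = TRUE) + d
  }

  markers <- list()
  chains <- limb_chains()
  for (limb in names(chains)) {
    ch <- chains[[limb]]
    lp <- profile$limbs[[limb]]
    if (is.null(lp)) {
      warning(sprintf("limb '%s' missing from profile; copied unamplified", limb))
      for (j in c(ch$mid, ch$mid2, ch$end)) {
        d <- pos[, j, , drop = TRUE] - matrix(profile$trunk_resting[ch$root, ],
                                              n, 3, byrow = TRUE)
        out[, j, ] <- matrix(rest_av[ch$root, ], n, 3, byrow = TRUE) + d
      }
      next
    }
    d <- pos[, limb, , drop = TRUE] - matrix(lp$resting, n, 3, byrow = TRUE)
    if (n == 1) d <- matrix(d, 1, 3)
    fpos <- matrix(lp$factors["pos", ], n, 3, byrow = TRUE)
    fneg <- matrix(lp$factors["neg", ], n, 3, byrow = TRUE)
    amp <- ifelse(d >= 0, fpos, fneg) * d
    avatar_rest_pt <- lp$resting + lp$offset
    targets <- matrix(avatar_rest_pt, n, 3, byrow = TRUE) + amp
    real_pts <- matrix(avatar_rest_pt, n, 3, byrow = TRUE) + d

    roots <- out[, ch$root, , drop = TRUE]
    if (n == 1) roots <- matrix(roots, 1, 3)
    l_up <- unname(avatar_model$lengths[ch$mid])
    l_lo <- unname(avatar_model$lengths[ch$mid2] + avatar_model$lengths[ch$end])
    # bend hint: user's mid-joint offset from the root-target chord
    hints <- pos[, ch$mid, , drop = TRUE] -
      (pos[, ch$root, , drop = TRUE] + pos[, limb, , drop = TRUE]) / 2
    if (n == 1) hints <- matrix(hints, 1, 3)
    weak <- sqrt(rowSums(hints^2)) < 1e-6
    if (any(weak)) hints[weak, ] <- matrix(rep(c(1, 0, 0), each = sum(weak)),
                                           ncol = 3)
    sol <- ik_solve_frames(roots, targets, l_up, l_lo, hints)
    out[, ch$mid, ] <- sol$mid
    out[, ch$end, ] <- sol$end
    # wrist/ankle on the solved lower segment
    seg <- sol$end - sol$mid
    segn <- sqrt(rowSums(seg^2))
    frac <- unname(avatar_model$lengths[ch$mid2]) / pmax(segn, 1e-12)
    out[, ch$mid2, ] <- sol$mid + seg * frac
    markers[[limb]] <- list(resting = avatar_rest_pt, real = real_pts,
                            amplified = targets)
  }
  res <- motion_trace(trace$time, out, rate = trace$rate, check_rate = FALSE)
  attr(res, "markers") <- markers
  res
}
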