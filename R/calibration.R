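#' Record the resting position of a limb
#'
#' Finds the stillest window of the trace (minimum summed frame-to-frame
#' speed of the limb) and returns the per-axis median of the limb position
#' over that window. The median makes the estimate robust against the
#' scattering spikes typical of depth-sensor capture.
#'
#' @param trace A `motion_trace`.
#' @param limb Joint name of the tracked limb (e.g. `"hand_left"`).
#' @param window Window length in seconds (at least 1 s of frames).
#' @return Resting position, 3-vector.
#' @export
record_resting <- function(trace, limb, window = 2) {
  k <- max(2L, round(window * trace$rate))
  n <- n_frames(trace)
  if (n < k)
    stop(sprintf("trace (%d frames) shorter than the %g s resting window",
                 n, window), call. = FALSE)
  p <- joint_track(trace, limb)
  # locate the stillest window on a denoised copy: raw scattering swamps the
  # frame-to-frame speed and would make window selection arbitrary
  ps <- p
  if (n > 15) {
    ps <- apply(ps, 2, function(v) stats::runmed(v, 5, endrule = "median"))
    ps <- apply(ps, 2, moving_average, k = max(2L, round(trace$rate / 3)))
  }
  sp <- sqrt(rowSums(diff(ps)^2))         # per-step displacement
  csum <- c(0, cumsum(sp))
  # summed speed inside each window of k frames
  starts <- seq_len(n - k + 1L)
  tot <- csum[starts + k - 1L] - csum[starts]
  # earliest window within 10 % of the minimum: the protocol records rest
  # first, and near-ties (a weak user's stretch is almost as still as rest)
  # must not pull the window into a stretch plateau
  s0 <- starts[which(tot <= 1.1 * min(tot))[1]]
  apply(p[s0:(s0 + k - 1L), , drop = FALSE], 2, stats::median)
}

#' Measure per-axis, per-direction movement ranges
#'
#' For each axis and direction, the maximal displacement of the limb from
#' its resting point. Two defences against sensor scattering: the
#' displacement is first filtered (a 5-point running median that deletes
#' isolated spikes, then a moving average over `smooth` seconds), then,
#' within the top decile of filtered displacements, values beyond 3 median
#' absolute deviations of that decile's median are excluded before taking
#' the maximum. Without the filtering, the maximum of jittered samples
#' overestimates a weak user's range by several millimetres, which at high
#' gain translates into an unreachable in-game target.
#'
#' @param trace A `motion_trace` containing the stretch phase.
#' @param limb Joint name of the tracked limb.
#' @param resting Resting position from [record_resting()].
#' @param smooth Moving-average window in seconds (0 disables filtering).
#' @return A 2 x 3 matrix (rows `pos`, `neg`; columns x, y, z) of
#'   non-negative range magnitudes in metres.
#' @export
measure_range <- function(trace, limb, resting, smooth = 1.5) {
  if (n_frames(trace) == 0) stop("empty trace", call. = FALSE)
  p <- joint_track(trace, limb)
  d <- sweep(p, 2, as.numeric(resting))
  k <- round(smooth * trace$rate)
  if (k > 1 && nrow(d) > max(k, 5)) {
    d <- apply(d, 2, function(v) stats::runmed(v, 5, endrule = "median"))
    d <- apply(d, 2, moving_average, k = k)
  }
  r <- matrix(0, 2, 3, dimnames = list(c("pos", "neg"), c("x", "y", "z")))
  for (ax in 1:3) {
    r["pos", ax] <- robust_max(pmax(d[, ax], 0))
    r["neg", ax] <- robust_max(pmax(-d[, ax], 0))
  }
  r
}

# centred moving average; the ends use shrinking one-sided windows
moving_average <- function(v, k) {
  n <- length(v)
  half <- k %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# max after rejecting values beyond 3 MADs of the top decile
robust_max <- function(v) {
  if (all(v <= 0)) return(0)
  q <- stats::quantile(v, 0.9, names = FALSE)
  top <- v[v >= q]
  m <- stats::median(top)
  s <- stats::mad(top)
  keep <- v[v <= m + 3 * s]
  if (!length(keep)) m else max(keep)
}

#' Amplification factors from user and avatar ranges
#'
#' The factor on each axis and direction is the ratio of the avatar's
#' required range to the user's measured range, floored at 1 (a capable
#' user is never attenuated) and capped at 25 (the bone-chain maximum).
#' Axes with a user range below 1 cm are flagged unusable and get factor 1.
#'
#' @param user_ranges,avatar_ranges 2 x 3 matrices as returned by
#'   [measure_range()].
#' @return List with `factors` (2 x 3 matrix) and `usable` (2 x 3 logical).
#' @export
compute_factors <- function(user_ranges, avatar_ranges) {
  usable <- user_ranges >= 0.01
  f <- ifelse(usable, pmin(pmax(avatar_ranges / pmax(user_ranges, 1e-12), 1), 25), 1)
  dimnames(f) <- dimnames(usable) <-
    list(c("pos", "neg"), c("x", "y", "z"))
  list(factors = f, usable = usable)
}

#' Resting-point offset
#'
#' Translation that relocates the avatar's movement origin: e.g. a seated
#' user's hand resting at hip height maps onto the standing avatar's hand
#' hanging at its side.
#'
#' @param user_resting,avatar_resting Resting points, 3-vectors.
#' @return `avatar_resting - user_resting`, 3-vector.
#' @export
compute_offset <- function(user_resting, avatar_resting) {
  as.numeric(avatar_resting) - as.numeric(user_resting)
}

#' Required avatar movement ranges
#'
#' Derived from the avatar skeleton rather than hard-coded: for each axis
#' and direction, the distance the limb can travel in a straight line from
#' its rest position before the two-segment chain would have to over-extend
#' (leave the annulus of reachable distances from its root joint), capped
#' at a plausible fraction of the limb reach (80 % for hands, 30 % for
#' feet). The same rule applied to a player's own skeleton, scaled by the
#' amplitude scale, defines that player's full range, which is what makes
#' calibration factors recover 1/s exactly for a same-sized player.
#'
#' @param model Avatar `skeleton_model`.
#' @param limb Outer limb joint name.
#' @return 2 x 3 matrix of required range magnitudes (rows `pos`, `neg`).
#' @export
avatar_required_ranges <- function(model, limb) {
  ch <- limb_chains()[[limb]]
  l1 <- unname(model$lengths[ch$mid])
  l2 <- unname(model$lengths[ch$mid2] + model$lengths[ch$end])
  reach <- l1 + l2
  r_in <- abs(l1 - l2)
  r <- model$rest_pose[limb, ] - model$rest_pose[ch$root, ]
  cap <- if (grepl("^foot", limb)) 0.30 * reach else 0.80 * reach
  out <- matrix(0, 2, 3, dimnames = list(c("pos", "neg"), c("x", "y", "z")))
  for (ax in 1:3) for (sgn in c(1, -1)) {
    e <- c(0, 0, 0); e[ax] <- sgn
    re <- sum(r * e)
    d_out <- -re + sqrt(re^2 + reach^2 - sum(r^2))
    disc_in <- re^2 + r_in^2 - sum(r^2)
    if (disc_in >= 0) {
      d_in <- -re - sqrt(disc_in)
      if (d_in > 0) d_out <- min(d_out, d_in)
    }
    out[if (sgn > 0) "pos" else "neg", ax] <- min(d_out, cap)
  }
  out
}

#' Calibrate a user profile from a calibration trace
#'
#' Fits a per-user calibration from a trace containing a resting phase
#' followed by maximal stretches in all directions: for each tracked limb
#' the resting point, the per-axis/per-direction movement ranges, the
#' amplification factors against the avatar's required ranges, and the
#' offset relocating the resting point onto the avatar. Trunk resting
#' positions are recorded from the same resting window so whole-pose
#' retargeting is anchored.
#'
#' @param trace Calibration `motion_trace` (resting phase first).
#' @param avatar_model Avatar `skeleton_model` the profile targets.
#' @param limbs Outer limbs to calibrate (default hands and feet).
#' @param rest_window Length of the resting window in seconds.
#' @return An object of class `calibration` with elements `version`,
#'   `limbs` (per limb: `resting`, `range_pos`, `range_neg`, `factors`,
#'   `usable`, `offset`), `trunk_resting` and `avatar_ranges`.
#' @export
calibrate <- function(trace, avatar_model,
                      limbs = c("hand_left", "hand_right",
                                "foot_left", "foot_right"),
                      rest_window = 4) {
  chains <- limb_chains()
  stopifnot(all(limbs %in% names(chains)))
  rest_av <- avatar_model$rest_pose
  limb_fits <- list()
  avr <- list()
  for (limb in limbs) {
    resting <- record_resting(trace, limb, rest_window)
    rng <- measure_range(trace, limb, resting)
    a_rng <- avatar_required_ranges(avatar_model, limb)
    cf <- compute_factors(rng, a_rng)
    offset <- stats::setNames(compute_offset(resting, rest_av[limb, ]),
                               c("x", "y", "z"))
    limb_fits[[limb]] <- list(resting = resting,
                              range_pos = rng["pos", ],
                              range_neg = rng["neg", ],
                              factors = cf$factors,
                              usable = cf$usable,
                              offset = offset)
    avr[[limb]] <- a_rng
  }
  trunk <- t(vapply(trunk_joints(),
                    function(j) record_resting(trace, j, rest_window),
                    numeric(3)))
  colnames(trunk) <- c("x", "y", "z")
  structure(list(version = "1.0", limbs = limb_fits, trunk_resting = trunk,
                 avatar_ranges = avr),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> profile v%s, %d limbs\n", x$version,
              length(x$limbs)))
  for (limb in names(x$limbs)) {
    f <- x$limbs[[limb]]$factors
    cat(sprintf("  %-10s factors x %.2f/%.2f  y %.2f/%.2f  z %.2f/%.2f%s\n",
                limb, f["pos", 1], f["neg", 1], f["pos", 2], f["neg", 2],
                f["pos", 3], f["neg", 3],
                if (!all(x$limbs[[limb]]$usable)) "  [some axes unusable]" else ""))
  }
  invisible(x)
}

#' @export
summary.calibration <- function(object, ...) {
  limbs <- names(object$limbs)
  rows <- do.call(rbind, lapply(limbs, function(limb) {
    lp <- object$limbs[[limb]]
    data.frame(limb = limb,
               direction = c("pos", "neg"),
               range_x = c(lp$range_pos[1], lp$range_neg[1]),
               range_y = c(lp$range_pos[2], lp$range_neg[2]),
               range_z = c(lp$range_pos[3], lp$range_neg[3]),
               factor_x = lp$factors[, 1],
               factor_y = lp$factors[, 2],
               factor_z = lp$factors[, 3],
               usable = apply(lp$usable, 1, all))
  }))
  rownames(rows) <- NULL
  structure(list(table = rows, version = object$version),
            class = "summary.calibration")
}

#' @export
print.summary.calibration <- function(x, ...) {
  cat(sprintf("Calibration profile (schema v%s)\n", x$version))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.calibration <- function(object, ...) {
  do.call(rbind, lapply(names(object$limbs), function(limb) {
    f <- object$limbs[[limb]]$factors
    rownames(f) <- paste(limb, rownames(f), sep = ".")
    f
  }))
}

#' Apply a calibration: amplify and retarget a trace
#'
#' @param object A `calibration`.
#' @param trace User `motion_trace` to retarget.
#' @param avatar_model Avatar `skeleton_model` the profile was fitted
#'   against.
#' @param ... Unused.
#' @return Avatar `motion_trace` (see [retarget_trace()]).
#' @export
predict.calibration <- function(object, trace, avatar_model, ...) {
  retarget_trace(trace, object, avatar_model)
}

#' @export
plot.calibration <- function(x, ...) {
  f <- coef(x)
  graphics::barplot(t(f), beside = TRUE, las = 2,
                    legend.text = c("x", "y", "z"),
                    ylab = "amplification factor",
                    main = "Calibrated amplification factors", ...)
  graphics::abline(h = c(1, 25), lty = 3)
  invisible(x)
}

#' Identity-factor copy of a profile
#'
#' Returns the profile with every amplification factor set to 1 (offsets
#' and resting points kept), i.e. the avatar mirrors the user's raw
#' displacements. Used for amplification-off ablations.
#'
#' @param profile A `calibration`.
#' @return A `calibration` with unit factors.
#' @export
profile_identity_factors <- function(profile) {
  for (limb in names(profile$limbs))
    profile$limbs[[limb]]$factors[] <- 1
  profile
}
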