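#' Write a motion trace as a joint stream
#'
#' Long-format records, one per joint per frame, with columns
#' `time, joint, x, y, z` (seconds and metres). The CSV dialect writes a
#' header; the JSONL dialect writes one JSON object per line.
#'
#' @param trace A `motion_trace`.
#' @param path Output file path.
#' @param dialect `"csv"` or `"jsonl"`; inferred from the file extension
#'   when omitted.
#' @return `path`, invisibly.
#' @export
write_joint_stream <- function(trace, path, dialect = NULL) {
  dialect <- stream_dialect(path, dialect)
  joints <- kinect_joints()
  n <- n_frames(trace)
  df <- data.frame(
    time = rep(trace$time, each = 20L),
    joint = rep(joints, times = n),
    x = as.vector(t(trace$positions[, , 1])),
    y = as.vector(t(trace$positions[, , 2])),
    z = as.vector(t(trace$positions[, , 3])))
  if (dialect == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time,joint,x,y,z", con)
    writeLines(sprintf("%.17g,%s,%.17g,%.17g,%.17g",
                       df$time, df$joint, df$x, df$y, df$z), con)
  } else {
    writeLines(sprintf(
      '{"time":%.17g,"joint":"%s","x":%.17g,"y":%.17g,"z":%.17g}',
      df$time, df$joint, df$x, df$y, df$z), path)
  }
  invisible(path)
}

stream_dialect <- function(path, dialect) {
  if (!is.null(dialect)) return(match.arg(dialect, c("csv", "jsonl")))
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
}

#' Read a joint stream into a motion trace
#'
#' Malformed input is rejected, never repaired: unknown joint names,
#' non-monotonic time, missing joints within a frame and malformed rows all
#' raise errors naming the offending record.
#'
#' @param path Input file path.
#' @param dialect `"csv"` or `"jsonl"`; inferred from the extension when
#'   omitted.
#' @param rate Nominal frame rate in Hz.
#' @param check_rate Enforce timestamp uniformity at `rate` (1 ms
#'   tolerance).
#' @return A `motion_trace`.
#' @export
read_joint_stream <- function(path, dialect = NULL, rate = 30,
                              check_rate = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  dialect <- stream_dialect(path, dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!identical(names(df), c("time", "joint", "x", "y", "z")))
      stop("joint-stream header must be 'time,joint,x,y,z'", call. = FALSE)
  } else {
    lines <- readLines(path)
    recs <- lapply(seq_along(lines), function(i) {
      r <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("malformed JSONL record on line %d", i),
                           call. = FALSE))
      r
    })
    df <- data.frame(time = vapply(recs, function(r) as.numeric(r$time), 0),
                     joint = vapply(recs, function(r) as.character(r$joint), ""),
                     x = vapply(recs, function(r) as.numeric(r$x), 0),
                     y = vapply(recs, function(r) as.numeric(r$y), 0),
                     z = vapply(recs, function(r) as.numeric(r$z), 0))
  }
  if (anyNA(df))
    stop(sprintf("malformed row %d: non-numeric or missing field",
                 which(rowSums(is.na(df)) > 0)[1]), call. = FALSE)
  joints <- kinect_joints()
  bad <- !df$joint %in% joints
  if (any(bad))
    stop(sprintf("unknown joint name '%s' in row %d",
                 df$joint[bad][1], which(bad)[1]), call. = FALSE)
  if (any(df$time < 0)) stop("negative timestamps", call. = FALSE)
  times <- unique(df$time)
  if (is.unsorted(df$time))
    stop("records are not ordered by time", call. = FALSE)
  n <- length(times)
  pos <- array(NA_real_, dim = c(n, 20, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  fi <- match(df$time, times)
  ji <- match(df$joint, joints)
  if (anyDuplicated(cbind(fi, ji)))
    stop("duplicate joint record within a frame", call. = FALSE)
  pos[cbind(fi, ji, 1L)] <- df$x
  pos[cbind(fi, ji, 2L)] <- df$y
  pos[cbind(fi, ji, 3L)] <- df$z
  if (anyNA(pos)) {
    miss <- which(is.na(pos[, , 1]), arr.ind = TRUE)[1, ]
    stop(sprintf("frame %d (t=%.4g) is missing joint '%s'",
                 miss[1], times[miss[1]], joints[miss[2]]), call. = FALSE)
  }
  motion_trace(times, pos, rate = rate, check_rate = check_rate)
}

# default mapping from canonical joint names to BVH node names
bvh_name_map <- function() {
  joints <- kinect_joints()
  bvh <- vapply(strsplit(joints, "_"), function(p)
    paste0(toupper(substring(p, 1, 1)), substring(p, 2), collapse = ""),
    "")
  stats::setNames(bvh, joints)   # e.g. hand_left -> HandLeft
}

#' Write a skeleton model and trace as a BVH file
#'
#' Writes the standard HIERARCHY/MOTION layout with the rest pose's bone
#' vectors as offsets. Because the canonical data are joint positions, the
#' writer uses a position-channel dialect: the root carries six channels
#' and every other joint three position channels holding the residual
#' translation relative to its rest offset. [read_bvh()] reads this dialect
#' as well as conventional rotation-channel files, so a write/read round
#' trip reproduces positions exactly. Coordinates are interpreted z-up, in
#' metres.
#'
#' @param model A `skeleton_model`.
#' @param trace A `motion_trace` (positions in global coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(model, trace, path) {
  map <- bvh_name_map()
  parents <- model$parents
  rest <- model$rest_pose
  children_of <- split(names(parents), parents)
  lines <- c("HIERARCHY")
  emit <- function(joint, depth) {
    ind <- strrep("  ", depth)
    if (joint == "hip_center") {
      lines <<- c(lines, sprintf("ROOT %s", map[[joint]]), "{")
      off <- c(0, 0, 0)
      ch <- "CHANNELS 6 Xposition Yposition Zposition Zrotation Xrotation Yrotation"
    } else {
      lines <<- c(lines, sprintf("%sJOINT %s", ind, map[[joint]]),
                  sprintf("%s{", ind))
      off <- rest[joint, ] - rest[parents[[joint]], ]
      ch <- "CHANNELS 3 Xposition Yposition Zposition"
    }
    ind2 <- strrep("  ", depth + 1)
    lines <<- c(lines,
                sprintf("%sOFFSET %.9f %.9f %.9f", ind2, off[1], off[2], off[3]),
                paste0(ind2, ch))
    kids <- children_of[[joint]]
    if (is.null(kids)) {
      lines <<- c(lines, sprintf("%sEnd Site", ind2),
                  sprintf("%s{", ind2),
                  sprintf("%s  OFFSET 0 0 0", ind2),
                  sprintf("%s}", ind2))
    } else {
      for (k in kids) emit(k, depth + 1)
    }
    lines <<- c(lines, sprintf("%s}", ind))
  }
  emit("hip_center", 0)
  n <- n_frames(trace)
  dt <- if (n > 1) mean(diff(trace$time)) else 1 / trace$rate
  lines <- c(lines, "MOTION", sprintf("Frames: %d", n),
             sprintf("Frame Time: %.9f", dt))
  order <- bvh_joint_order(parents)
  rows <- vapply(seq_len(n), function(i) {
    vals <- numeric(0)
    for (j in order) {
      if (j == "hip_center") {
        vals <- c(vals, trace$positions[i, j, ], 0, 0, 0)
      } else {
        res <- trace$positions[i, j, ] - trace$positions[i, parents[[j]], ] -
          (rest[j, ] - rest[parents[[j]], ])
        vals <- c(vals, res)
      }
    }
    paste(sprintf("%.9f", vals), collapse = " ")
  }, "")
  writeLines(c(lines, rows), path)
  invisible(path)
}

# depth-first joint order matching the emitted hierarchy
bvh_joint_order <- function(parents) {
  children_of <- split(names(parents), parents)
  out <- character(0)
  walk <- function(j) {
    out <<- c(out, j)
    for (k in children_of[[j]]) walk(k)
  }
  walk("hip_center")
  out
}

#' Read a BVH motion file
#'
#' Parses the HIERARCHY and MOTION sections, maps node names onto the
#' canonical 20-joint set (via `name_map`, the inverse of the writer's
#' default map; matching is case-insensitive and ignores underscores) and
#' reconstructs global joint positions by forward kinematics over the
#' offsets and channels. Rotation channels (degrees, applied in the order
#' listed) and position channels are both supported.
#'
#' @param path BVH file path.
#' @param name_map Named character vector mapping canonical joint names to
#'   BVH node names; defaults to the writer's map.
#' @param rate Nominal frame rate for the returned trace; defaults to the
#'   file's frame time.
#' @return List with elements `model` (a `skeleton_model`) and `trace`
#'   (a `motion_trace`).
#' @export
read_bvh <- function(path, name_map = bvh_name_map(), rate = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!identical(lines[1], "HIERARCHY"))
    stop("not a BVH file: missing HIERARCHY", call. = FALSE)
  rev_map <- stats::setNames(names(name_map), normalize_name(name_map))

  nodes <- list()     # per node: name, parent, offset, channels
  stack <- character(0)
  i <- 2L
  cur <- NULL
  in_end_site <- FALSE
  while (i <= length(lines) && lines[i] != "MOTION") {
    ln <- lines[i]
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] %in% c("ROOT", "JOINT")) {
      nm <- normalize_name(tok[2])
      canon <- unname(rev_map[nm])
      if (is.na(canon))
        stop(sprintf("BVH joint '%s' cannot be mapped onto the canonical joint set",
                     tok[2]), call. = FALSE)
      nodes[[canon]] <- list(parent = if (length(stack)) stack[length(stack)] else NA,
                             offset = c(0, 0, 0), channels = character(0))
      cur <- canon
    } else if (tok[1] == "End") {
      in_end_site <- TRUE
    } else if (tok[1] == "{") {
      if (in_end_site) stack <- c(stack, ".end") else stack <- c(stack, cur)
    } else if (tok[1] == "}") {
      top <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (identical(top, ".end")) in_end_site <- FALSE
      cur <- if (length(stack)) stack[length(stack)] else NULL
    } else if (tok[1] == "OFFSET") {
      if (!in_end_site)
        nodes[[stack[length(stack)]]]$offset <- as.numeric(tok[2:4])
    } else if (tok[1] == "CHANNELS") {
      nodes[[stack[length(stack)]]]$channels <- tok[-(1:2)]
    }
    i <- i + 1L
  }
  if (!setequal(names(nodes), kinect_joints())) {
    missing <- setdiff(kinect_joints(), names(nodes))
    stop(sprintf("BVH hierarchy does not cover the canonical joints (missing: %s)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  # MOTION section
  if (lines[i] != "MOTION") stop("missing MOTION section", call. = FALSE)
  nfr <- as.integer(sub("Frames:\\s*", "", lines[i + 1L]))
  ft <- as.numeric(sub("Frame Time:\\s*", "", lines[i + 2L]))
  if (is.null(rate)) rate <- 1 / ft
  vals <- lapply(lines[(i + 3L):(i + 2L + nfr)],
                 function(l) as.numeric(strsplit(l, "\\s+")[[1]]))

  order <- names(nodes)   # declaration order == channel order
  joints <- kinect_joints()
  pos <- array(NA_real_, c(nfr, 20, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (f in seq_len(nfr)) {
    row <- vals[[f]]
    k <- 1L
    glob_p <- list(); glob_r <- list()
    for (j in order) {
      nd <- nodes[[j]]
      nch <- length(nd$channels)
      ch <- row[k:(k + nch - 1L)]; k <- k + nch
      trans <- c(0, 0, 0); rot <- diag(3)
      for (ci in seq_along(nd$channels)) {
        cn <- nd$channels[ci]
        if (cn == "Xposition") trans[1] <- ch[ci]
        else if (cn == "Yposition") trans[2] <- ch[ci]
        else if (cn == "Zposition") trans[3] <- ch[ci]
        else if (cn %in% c("Xrotation", "Yrotation", "Zrotation"))
          rot <- rot %*% axis_rotation(substr(cn, 1, 1), ch[ci])
      }
      if (is.na(nd$parent)) {
        p <- nd$offset + trans
        r <- rot
      } else {
        pr <- glob_r[[nd$parent]]
        p <- glob_p[[nd$parent]] + pr %*% (nd$offset + trans)
        r <- pr %*% rot
      }
      glob_p[[j]] <- as.numeric(p)
      glob_r[[j]] <- r
      pos[f, j, ] <- as.numeric(p)
    }
  }
  trace <- motion_trace(seq(0, by = ft, length.out = nfr), pos, rate = rate,
                        check_rate = FALSE)
  model <- fit_skeleton_to_pose(trace_pose(trace, 1))
  list(model = model, trace = trace)
}

normalize_name <- function(x) tolower(gsub("_", "", x))

axis_rotation <- function(axis, degrees) {
  a <- degrees * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Save a calibration profile as JSON
#'
#' @param profile A `calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration"))
  obj <- list(
    version = profile$version,
    limbs = lapply(profile$limbs, function(lp) list(
      resting = as.numeric(lp$resting),
      range_pos = as.numeric(lp$range_pos),
      range_neg = as.numeric(lp$range_neg),
      factors_pos = as.numeric(lp$factors["pos", ]),
      factors_neg = as.numeric(lp$factors["neg", ]),
      usable_pos = as.logical(lp$usable["pos", ]),
      usable_neg = as.logical(lp$usable["neg", ]),
      offset = as.numeric(lp$offset))),
    trunk_resting = stats::setNames(
      lapply(seq_len(nrow(profile$trunk_resting)),
             function(i) as.numeric(profile$trunk_resting[i, ])),
      rownames(profile$trunk_resting)),
    avatar_ranges = lapply(profile$avatar_ranges, function(m)
      list(pos = as.numeric(m["pos", ]), neg = as.numeric(m["neg", ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration profile from JSON
#'
#' @param path Profile path written by [save_profile()].
#' @return A `calibration`.
#' @export
load_profile <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$version))
    stop("profile schema error: missing 'version'", call. = FALSE)
  if (!identical(as.character(obj$version), "1.0"))
    stop(sprintf("unsupported profile schema version '%s'", obj$version),
         call. = FALSE)
  if (is.null(obj$limbs)) stop("profile schema error: missing 'limbs'",
                               call. = FALSE)
  ax <- c("x", "y", "z")
  limbs <- lapply(obj$limbs, function(lp) {
    for (key in c("resting", "range_pos", "range_neg", "factors_pos",
                  "factors_neg", "offset"))
      if (is.null(lp[[key]]))
        stop(sprintf("profile schema error: limb missing '%s'", key),
             call. = FALSE)
    f <- rbind(pos = as.numeric(lp$factors_pos),
               neg = as.numeric(lp$factors_neg))
    colnames(f) <- ax
    if (any(f < 0.95) || any(f > 25))
      stop("profile factors out of the valid range [0.95, 25]", call. = FALSE)
    u <- rbind(pos = as.logical(lp$usable_pos),
               neg = as.logical(lp$usable_neg))
    colnames(u) <- ax
    list(resting = stats::setNames(as.numeric(lp$resting), ax),
         range_pos = stats::setNames(as.numeric(lp$range_pos), ax),
         range_neg = stats::setNames(as.numeric(lp$range_neg), ax),
         factors = f, usable = u,
         offset = stats::setNames(as.numeric(lp$offset), ax))
  })
  trunk <- do.call(rbind, lapply(obj$trunk_resting, as.numeric))
  rownames(trunk) <- names(obj$trunk_resting)
  colnames(trunk) <- ax
  avr <- lapply(obj$avatar_ranges, function(m) {
    r <- rbind(pos = as.numeric(m$pos), neg = as.numeric(m$neg))
    colnames(r) <- ax
    r
  })
  structure(list(version = as.character(obj$version), limbs = limbs,
                 trunk_resting = trunk, avatar_ranges = avr),
            class = "calibration")
}
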