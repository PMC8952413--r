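## Upper-body skeleton model, pose sequences, pelvis-frame normalization and
## forward kinematics.

#' Upper-body skeleton definition
#'
#' A 15-segment articulated upper body rooted at the pelvis: spine chain
#' (Pelvis, L5, L3, T12, T8, Neck, Head) plus shoulder-arm chains on each
#' side. Each non-root segment stores a fixed offset vector in its own local
#' frame (metres); forward kinematics chains these offsets through the
#' per-segment orientations.
#'
#' The default offsets describe a neutral, metre-scale adult figure (straight
#' spine, arms hanging) in a right-handed, Z-up global frame with x forward
#' and y to the subject's left. Offsets are overridable per segment.
#'
#' @param offsets Optional 15 x 3 numeric matrix of per-segment offset
#'   vectors (metres) in segment-local frames, rows named like
#'   `upper_body_segments()`.
#' @return An object of class `upper_body_skeleton` with fields `segments`,
#'   `parent` (0 for the root) and `offsets`.
#' @export
upper_body_skeleton <- function(offsets = NULL) {
  segments <- upper_body_segments()
  parent <- c(0, 1, 2, 3, 4, 5, 6, 5, 8, 9, 10, 5, 12, 13, 14)
  default <- rbind(
    Pelvis        = c(0, 0, 0),
    L5            = c(0, 0, 0.10),
    L3            = c(0, 0, 0.10),
    T12           = c(0, 0, 0.10),
    T8            = c(0, 0, 0.12),
    Neck          = c(0, 0, 0.10),
    Head          = c(0, 0, 0.18),
    RightShoulder = c(0, -0.17, 0.02),
    RightUpperArm = c(0, 0, -0.28),
    RightForearm  = c(0, 0, -0.26),
    RightHand     = c(0, 0, -0.18),
    LeftShoulder  = c(0, 0.17, 0.02),
    LeftUpperArm  = c(0, 0, -0.28),
    LeftForearm   = c(0, 0, -0.26),
    LeftHand      = c(0, 0, -0.18))
  if (!is.null(offsets)) {
    offsets <- as.matrix(offsets)
    stopifnot(ncol(offsets) == 3, all(is.finite(offsets)))
    if (!is.null(rownames(offsets))) {
      miss <- setdiff(rownames(offsets), segments)
      if (length(miss) > 0) stop("unknown segment(s): ", paste(miss, collapse = ", "))
      default[rownames(offsets), ] <- offsets
    } else {
      stopifnot(nrow(offsets) == length(segments))
      default[] <- offsets
    }
  }
  lens <- sqrt(rowSums(default[-1, , drop = FALSE]^2))
  if (any(lens <= 0)) stop("non-root segments must have non-zero offsets")
  structure(list(segments = segments, parent = parent, offsets = default),
            class = "upper_body_skeleton")
}

#' Names of the 15 upper-body segments, pelvis first
#' @return Character vector of segment names in tree order.
#' @export
upper_body_segments <- function() {
  c("Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head",
    "RightShoulder", "RightUpperArm", "RightForearm", "RightHand",
    "LeftShoulder", "LeftUpperArm", "LeftForearm", "LeftHand")
}

#' Read / write a skeleton definition as JSON
#'
#' The file stores segment names, parent indices (0 for the root) and offset
#' vectors in metres.
#'
#' @param skel An `upper_body_skeleton`.
#' @param path File path.
#' @return `read_skeleton_json()` returns an `upper_body_skeleton`;
#'   `write_skeleton_json()` returns `path` invisibly.
#' @export
write_skeleton_json <- function(skel, path) {
  stopifnot(inherits(skel, "upper_body_skeleton"))
  jsonlite::write_json(list(
    segments = skel$segments,
    parent = skel$parent,
    offsets_m = apply(skel$offsets, 1, identity, simplify = FALSE)
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton_json
#' @export
read_skeleton_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  off <- do.call(rbind, x$offsets_m)
  rownames(off) <- x$segments
  skel <- upper_body_skeleton(off)
  if (!identical(skel$segments, as.character(x$segments)) ||
      !identical(skel$parent, as.numeric(x$parent)))
    stop("skeleton file does not match the expected 15-segment upper-body tree")
  skel
}

#' Construct a pose sequence
#'
#' A time-indexed set of per-segment orientations (unit quaternions) and
#' optional linear accelerations at a fixed frame rate, tagged with the frame
#' of reference the data are expressed in (`"global"` or `"pelvis"` for
#' pelvis-normalized data).
#'
#' @param orientation Array `[frames, segments, 4]` of scalar-first unit
#'   quaternions; the segment dimension must be named.
#' @param rate Frame rate in Hz.
#' @param acceleration Optional array `[frames, segments, 3]` of linear
#'   accelerations (m/s^2), aligned with `orientation`.
#' @param frame Frame-of-reference tag: `"global"` or `"pelvis"`.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(orientation, rate, acceleration = NULL,
                          frame = c("global", "pelvis")) {
  frame <- match.arg(frame)
  stopifnot(is.array(orientation), length(dim(orientation)) == 3,
            dim(orientation)[3] == 4, rate > 0)
  segs <- dimnames(orientation)[[2]]
  if (is.null(segs)) stop("orientation array must have named segments (dim 2)")
  nrm <- sqrt(apply(orientation^2, c(1, 2), sum))
  if (any(abs(nrm - 1) > 1e-6))
    stop("orientations must be unit quaternions (max norm deviation ",
         format(max(abs(nrm - 1))), ")")
  if (!is.null(acceleration)) {
    stopifnot(is.array(acceleration), length(dim(acceleration)) == 3,
              dim(acceleration)[3] == 3,
              dim(acceleration)[1] == dim(orientation)[1],
              dim(acceleration)[2] == dim(orientation)[2],
              all(is.finite(acceleration)))
    dimnames(acceleration) <- list(NULL, segs, c("ax", "ay", "az"))
  }
  dimnames(orientation) <- list(NULL, segs, c("qw", "qx", "qy", "qz"))
  structure(list(orientation = orientation, acceleration = acceleration,
                 rate = rate, frame = frame, segments = segs),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("pose_sequence: %d frames x %d segments @ %g Hz (%s frame)%s\n",
              n_frames(x), length(x$segments), x$rate, x$frame,
              if (is.null(x$acceleration)) "" else ", with accelerations"))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$orientation)[1]

## Orientation series for one segment as an n x 4 matrix.
segment_quat <- function(seq, segment) {
  if (!segment %in% seq$segments) stop("segment not present: ", segment)
  out <- seq$orientation[, segment, ]
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' Normalize segment orientations to the pelvis frame
#'
#' Re-expresses every segment orientation relative to the pelvis:
#' `R_PB = R_GP^-1 R_GB` per frame, where `R_GP` is the pelvis orientation in
#' the global frame. The pelvis itself becomes the identity rotation, which
#' removes global heading before model training.
#'
#' @param seq A `pose_sequence` in the global frame containing a `Pelvis`
#'   segment.
#' @return A `pose_sequence` tagged `"pelvis"`; accelerations (if present)
#'   are rotated by `R_GP^-1` as well.
#' @export
normalize_orientations <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame != "global") stop("sequence is already pelvis-normalized")
  if (!"Pelvis" %in% seq$segments) stop("pelvis segment is required for normalization")
  pinv <- qinv(segment_quat(seq, "Pelvis"))
  ori <- seq$orientation
  for (s in seq$segments) ori[, s, ] <- qmul(pinv, seq$orientation[, s, ])
  acc <- seq$acceleration
  if (!is.null(acc)) for (s in seq$segments) acc[, s, ] <- quat_rotate(pinv, seq$acceleration[, s, ])
  pose_sequence(ori, seq$rate, acc, frame = "pelvis")
}

#' Normalize accelerations to the pelvis frame
#'
#' Rotates each acceleration vector into the pelvis frame,
#' `a_norm = R_GP^-1 a`, leaving orientations untouched. Used when the
#' orientation channels are normalized elsewhere.
#'
#' @param seq A `pose_sequence` in the global frame with accelerations.
#' @return A `pose_sequence` with rotated accelerations (frame tag
#'   unchanged, since orientations are not modified).
#' @export
normalize_accelerations <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (is.null(seq$acceleration)) stop("sequence has no accelerations")
  if (!"Pelvis" %in% seq$segments) stop("pelvis segment is required for normalization")
  pinv <- qinv(segment_quat(seq, "Pelvis"))
  acc <- seq$acceleration
  for (s in seq$segments) acc[, s, ] <- quat_rotate(pinv, seq$acceleration[, s, ])
  out <- seq
  out$acceleration <- acc
  out
}

#' De-normalize a pelvis-relative sequence back to the global frame
#'
#' Inverse of [normalize_orientations()]: `R_GB = R_GP R_PB` using a supplied
#' pelvis orientation track, so predicted postures can be viewed in the
#' global frame.
#'
#' @param seq A `pose_sequence` tagged `"pelvis"`.
#' @param pelvis_track An n x 4 matrix of pelvis orientations (global frame),
#'   one row per frame of `seq`.
#' @return A `pose_sequence` in the global frame.
#' @export
denormalize <- function(seq, pelvis_track) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame != "pelvis") stop("sequence is not pelvis-normalized")
  pelvis_track <- as_quat_matrix(pelvis_track)
  if (nrow(pelvis_track) != n_frames(seq))
    stop("pelvis track length (", nrow(pelvis_track),
         ") does not match sequence frames (", n_frames(seq), ")")
  ori <- seq$orientation
  for (s in seq$segments) ori[, s, ] <- qmul(pelvis_track, seq$orientation[, s, ])
  acc <- seq$acceleration
  if (!is.null(acc)) for (s in seq$segments) acc[, s, ] <- quat_rotate(pelvis_track, seq$acceleration[, s, ])
  pose_sequence(ori, seq$rate, acc, frame = "global")
}

#' Forward kinematics of the upper body
#'
#' Computes per-frame segment endpoint positions by accumulating
#' `P_i = P_parent(i) + R_GB_i X_i` down the skeleton tree from a root
#' position.
#'
#' @param seq A `pose_sequence` in the global frame containing all skeleton
#'   segments.
#' @param skel An `upper_body_skeleton`.
#' @param root_position Global position of the pelvis root (metres).
#' @return Array `[frames, segments, 3]` of endpoint positions in metres.
#' @export
forward_kinematics <- function(seq, skel, root_position = c(0, 0, 0)) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(skel, "upper_body_skeleton"),
            length(root_position) == 3, all(is.finite(root_position)))
  if (seq$frame != "global")
    stop("forward kinematics needs global-frame orientations; denormalize first")
  miss <- setdiff(skel$segments, seq$segments)
  if (length(miss) > 0)
    stop("orientation missing for segment(s): ", paste(miss, collapse = ", "))
  nf <- n_frames(seq)
  pos <- array(0, dim = c(nf, length(skel$segments), 3),
               dimnames = list(NULL, skel$segments, c("x", "y", "z")))
  root <- matrix(root_position, nrow = nf, ncol = 3, byrow = TRUE)
  for (i in seq_along(skel$segments)) {
    s <- skel$segments[i]
    parent_pos <- if (skel$parent[i] == 0) root else pos[, skel$parent[i], , drop = TRUE]
    if (is.null(dim(parent_pos))) parent_pos <- matrix(parent_pos, nrow = nf)
    pos[, i, ] <- parent_pos + quat_rotate(seq$orientation[, s, ], skel$offsets[i, ])
  }
  pos
}
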