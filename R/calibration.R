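## Sensor-to-segment calibration: mapping standalone-IMU streams onto the
## motion-capture convention via per-session variable mappings and a
## cross-session fixed (quaternion-averaged) mapping.

#' Resample a pose sequence to a lower rate
#'
#' Nearest-frame decimation onto a uniform output grid. Orientation samples
#' are picked, not interpolated, which preserves unit norm exactly.
#'
#' @param seq A `pose_sequence`.
#' @param rate_out Target rate in Hz (must not exceed the input rate).
#' @return A `pose_sequence` at `rate_out`.
#' @export
resample_pose <- function(seq, rate_out) {
  stopifnot(inherits(seq, "pose_sequence"), rate_out > 0, rate_out <= seq$rate)
  n <- n_frames(seq)
  nout <- floor(n * rate_out / seq$rate)
  idx <- pmin(round((seq_len(nout) - 1) * seq$rate / rate_out) + 1, n)
  pose_sequence(seq$orientation[idx, , , drop = FALSE], rate_out,
                if (is.null(seq$acceleration)) NULL else
                  seq$acceleration[idx, , , drop = FALSE],
                frame = seq$frame)
}

#' Synchronize a motion-capture stream with a standalone-IMU stream
#'
#' Both streams are decimated to a common rate (default 40 Hz), then
#' aligned by the integer frame offset maximizing the cross-correlation of
#' their mean acceleration magnitudes (an automated stand-in for aligning on
#' a deliberate bump). If neither stream carries usable dynamics (constant
#' acceleration magnitude), the offset falls back to 0 with a warning.
#'
#' @param mvn A `pose_sequence` with accelerations (e.g. 240 Hz
#'   motion-capture convention).
#' @param dot A `pose_sequence` with accelerations (e.g. 60 Hz standalone
#'   IMU).
#' @param rate_out Common rate after decimation (Hz).
#' @param max_lag_s Largest alignment offset searched, in seconds.
#' @return List with the aligned equal-length sequences `mvn` and `dot`
#'   (both at `rate_out`) and the recovered `offset` in output frames
#'   (positive when the IMU stream starts later).
#' @export
synchronize_streams <- function(mvn, dot, rate_out = 40, max_lag_s = 2) {
  stopifnot(inherits(mvn, "pose_sequence"), inherits(dot, "pose_sequence"))
  if (is.null(mvn$acceleration) || is.null(dot$acceleration))
    stop("both streams need acceleration channels for synchronization")
  mvn40 <- resample_pose(mvn, rate_out)
  dot40 <- resample_pose(dot, rate_out)
  mag <- function(s) rowMeans(sqrt(apply(s$acceleration^2, c(1, 2), sum)))
  a <- mag(mvn40); b <- mag(dot40)
  max_lag <- min(round(max_lag_s * rate_out), length(a) - 2, length(b) - 2)
  offset <- 0L
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    warning("no dynamics found for alignment; falling back to offset 0")
  } else {
    lags <- -max_lag:max_lag
    min_overlap <- max(8, ceiling(min(length(a), length(b)) / 2))
    score <- vapply(lags, function(k) {
      ## correlate mvn[i + k] against dot[i]
      len <- min(length(a) - max(k, 0), length(b) + min(k, 0))
      if (len < min_overlap) return(-Inf)
      i <- seq_len(len)
      ia <- i + max(k, 0)
      ib <- i - min(k, 0)
      if (stats::sd(a[ia]) < 1e-12 || stats::sd(b[ib]) < 1e-12) return(-Inf)
      stats::cor(a[ia], b[ib])
    }, 1)
    offset <- lags[which.max(score)]
  }
  take <- function(s, idx) pose_sequence(
    s$orientation[idx, , , drop = FALSE], s$rate,
    s$acceleration[idx, , , drop = FALSE], frame = s$frame)
  na <- length(a); nb <- length(b)
  len <- min(na - max(offset, 0), nb + min(offset, 0))
  ia <- seq_len(len) + max(offset, 0)
  ib <- seq_len(len) - min(offset, 0)
  list(mvn = take(mvn40, ia), dot = take(dot40, ib), offset = as.integer(offset))
}

#' Compute the per-session variable mapping for one segment
#'
#' At a single calibration frame `n`, the orientation map is
#' `R_ori = R_mvn_segment[n] * R_imu_raw[n]^-1` and the acceleration map is
#' `R_acc = R_mvn_sensor[n] * R_imu_raw[n]^-1` (quaternion form). Applied to
#' the raw IMU stream these reproduce the motion-capture convention exactly
#' whenever the offset between the two is a truly fixed rotation.
#'
#' By default `n` is the frame with the smallest IMU acceleration magnitude
#' (quasi-static), which reduces sensitivity to dynamics; any frame gives
#' the same map when the offset is fixed.
#'
#' @param mvn Synchronized `pose_sequence` holding the motion-capture
#'   segment orientations.
#' @param dot Synchronized `pose_sequence` holding the raw IMU orientations
#'   (equal length and rate).
#' @param segment Segment name present in both streams.
#' @param n Calibration frame index; `NULL` picks the quasi-static frame.
#' @param mvn_sensor Optional `pose_sequence` with the motion-capture
#'   *sensor* orientations; defaults to `mvn` (sensor frame = segment
#'   frame).
#' @param session Session identifier stored in the map.
#' @return An object of class `calibration_map` with unit-quaternion fields
#'   `ori_map` and `acc_map`, plus `segment`, `session` and `frame`.
#' @export
compute_variable_mapping <- function(mvn, dot, segment, n = NULL,
                                     mvn_sensor = NULL, session = "session1") {
  stopifnot(inherits(mvn, "pose_sequence"), inherits(dot, "pose_sequence"))
  if (n_frames(mvn) != n_frames(dot)) stop("streams are not synchronized (length mismatch)")
  if (!segment %in% mvn$segments || !segment %in% dot$segments)
    stop("segment not present in both streams: ", segment)
  if (is.null(mvn_sensor)) mvn_sensor <- mvn
  if (is.null(n)) {
    n <- if (!is.null(dot$acceleration)) {
      am <- dot$acceleration[, segment, ]
      if (!is.matrix(am)) am <- matrix(am, nrow = 1)
      which.min(sqrt(rowSums(am^2)))
    } else 1L
  }
  if (n < 1 || n > n_frames(dot)) stop("calibration frame n = ", n, " is out of range")
  q_seg <- mvn$orientation[n, segment, ]
  q_sens <- mvn_sensor$orientation[n, segment, ]
  q_raw <- dot$orientation[n, segment, ]
  structure(list(segment = segment, session = session, frame = as.integer(n),
                 ori_map = qmul(q_seg, qinv(q_raw)),
                 acc_map = qmul(q_sens, qinv(q_raw))),
            class = "calibration_map")
}

#' Apply a calibration map to a raw IMU stream
#'
#' Left-multiplies the mapped segment's orientations by the orientation map
#' and rotates its acceleration vectors by the acceleration map, yielding a
#' stream in the motion-capture convention. Other segments are untouched.
#'
#' @param map A `calibration_map`.
#' @param dot A `pose_sequence` containing `map$segment`.
#' @return The `pose_sequence` with the mapped segment calibrated.
#' @export
apply_mapping <- function(map, dot) {
  stopifnot(inherits(map, "calibration_map"), inherits(dot, "pose_sequence"))
  if (!map$segment %in% dot$segments)
    stop("stream does not contain the mapped segment: ", map$segment)
  ori <- dot$orientation
  ori[, map$segment, ] <- qmul(map$ori_map, dot$orientation[, map$segment, ])
  acc <- dot$acceleration
  if (!is.null(acc))
    acc[, map$segment, ] <- quat_rotate(map$acc_map, dot$acceleration[, map$segment, ])
  pose_sequence(ori, dot$rate, acc, frame = dot$frame)
}

#' Cross-session fixed mapping by quaternion averaging
#'
#' Averages the orientation maps and the acceleration maps of several
#' per-session calibration maps for the same segment (eigenvector quaternion
#' average), giving one universal mapping usable across sessions.
#'
#' @param maps List of `calibration_map` objects for one segment.
#' @return A `calibration_map` with `session = "fixed"`.
#' @export
compute_fixed_mapping <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "calibration_map")))
  segs <- unique(vapply(maps, function(m) m$segment, ""))
  if (length(segs) != 1)
    stop("maps mix segments: ", paste(segs, collapse = ", "))
  structure(list(segment = segs, session = "fixed", frame = NA_integer_,
                 ori_map = quat_average(lapply(maps, function(m) m$ori_map)),
                 acc_map = quat_average(lapply(maps, function(m) m$acc_map))),
            class = "calibration_map")
}

#' Read / write calibration maps as JSON
#'
#' One file per session: segment name mapped to the quaternion pair
#' (orientation map, acceleration map) and the calibration frame index.
#'
#' @param maps List of `calibration_map` objects.
#' @param path File path.
#' @return `read_calibration_json()` returns a list of `calibration_map`;
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
write_calibration_json <- function(maps, path) {
  if (inherits(maps, "calibration_map")) maps <- list(maps)
  jsonlite::write_json(lapply(maps, function(m) list(
    segment = m$segment, session = m$session, frame = m$frame,
    ori_map = as.numeric(m$ori_map), acc_map = as.numeric(m$acc_map)
  )), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(m) structure(list(
    segment = m$segment, session = m$session,
    frame = if (is.null(m$frame)) NA_integer_ else as.integer(m$frame),
    ori_map = quat_normalize(as.numeric(unlist(m$ori_map))),
    acc_map = quat_normalize(as.numeric(unlist(m$acc_map)))
  ), class = "calibration_map"))
}
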