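## Synthetic motion streams: ground-truth pose sequences in the
## motion-capture convention (240 Hz) and degraded standalone-IMU streams
## (60 Hz) with mounting rotation, slow drift and sensor noise.

#' Motion generator configuration
#'
#' The generator draws, per segment, a band-limited random walk on
#' rotations: white angular-velocity noise low-pass filtered at
#' `smoothness_hz` and scaled so the per-frame angular speed never exceeds
#' `max_speed_deg_s`. It is deliberately not a biomechanical model; it
#' provides smooth, bounded, reproducible orientation streams with
#' consistent accelerations for exercising every downstream stage.
#'
#' @param duration_s Duration in seconds.
#' @param rate Frame rate in Hz (240 matches the motion-capture stream).
#' @param max_speed_deg_s Per-segment angular speed bound (deg/s).
#' @param smoothness_hz Low-pass cutoff of the angular-velocity noise (Hz).
#' @param include_gravity Add the gravity vector (0, 0, -9.81) m/s^2 to the
#'   generated accelerations (the synthetic stream makes the gravity
#'   convention explicit).
#' @param initial_spread_deg Standard deviation of the random initial
#'   orientation of each segment (degrees).
#' @param seed Integer seed fixing the whole stream.
#' @return A list of class `motion_config`.
#' @export
motion_config <- function(duration_s = 10, rate = 240, max_speed_deg_s = 90,
                          smoothness_hz = 1, include_gravity = FALSE,
                          initial_spread_deg = 20, seed = 1) {
  stopifnot(duration_s > 0, rate > 0, max_speed_deg_s >= 0,
            smoothness_hz > 0, initial_spread_deg >= 0)
  structure(list(duration_s = duration_s, rate = rate,
                 max_speed_deg_s = max_speed_deg_s,
                 smoothness_hz = smoothness_hz,
                 include_gravity = include_gravity,
                 initial_spread_deg = initial_spread_deg, seed = seed),
            class = "motion_config")
}

## Single-pole low-pass filter along columns.
lowpass <- function(x, cutoff_hz, rate) {
  a <- 2 * pi * cutoff_hz / rate
  a <- a / (1 + a)
  apply(x, 2, function(col) stats::filter(col * a, 1 - a,
                                          method = "recursive"))
}

#' Generate a ground-truth pose sequence
#'
#' Produces a global-frame `pose_sequence` for all skeleton segments at
#' `cfg$rate`: orientations follow the band-limited rotation random walk of
#' [motion_config()], and accelerations are the second time-derivative of
#' the forward-kinematics endpoint positions (plus gravity if configured),
#' expressed in the global frame.
#'
#' @param skel An `upper_body_skeleton`.
#' @param cfg A `motion_config`.
#' @return A `pose_sequence` (global frame, with accelerations).
#' @export
generate_pose_sequence <- function(skel, cfg = motion_config()) {
  stopifnot(inherits(skel, "upper_body_skeleton"), inherits(cfg, "motion_config"))
  set.seed(cfg$seed)
  nf <- max(2L, round(cfg$duration_s * cfg$rate))
  segs <- skel$segments
  dt <- 1 / cfg$rate
  ori <- array(0, dim = c(nf, length(segs), 4), dimnames = list(NULL, segs, NULL))
  for (si in seq_along(segs)) {
    q0 <- if (cfg$initial_spread_deg > 0) {
      axis <- stats::rnorm(3)
      quat_from_axis_angle(axis, stats::rnorm(1, sd = cfg$initial_spread_deg))
    } else quat_identity()
    if (cfg$max_speed_deg_s == 0) {
      ori[, si, ] <- matrix(q0, nf, 4, byrow = TRUE)
      next
    }
    w <- matrix(stats::rnorm(nf * 3), nf, 3)
    w <- lowpass(w, cfg$smoothness_hz, cfg$rate)
    speed <- sqrt(rowSums(w^2))
    w <- w * (cfg$max_speed_deg_s / max(speed, 1e-12))
    q <- q0
    ori[1, si, ] <- q
    for (t in 2:nf) {
      ang <- sqrt(sum(w[t, ]^2)) * dt          # degrees this frame
      if (ang > 0) q <- qmul(quat_from_axis_angle(w[t, ], ang), q)
      ori[t, si, ] <- q
    }
  }
  seq0 <- pose_sequence(ori, cfg$rate, frame = "global")
  pos <- forward_kinematics(seq0, skel)
  acc <- array(0, dim = dim(pos), dimnames = dimnames(pos))
  if (nf >= 3) {
    acc[2:(nf - 1), , ] <- (pos[3:nf, , , drop = FALSE] -
                            2 * pos[2:(nf - 1), , , drop = FALSE] +
                            pos[1:(nf - 2), , , drop = FALSE]) * cfg$rate^2
    acc[1, , ] <- acc[2, , ]
    acc[nf, , ] <- acc[nf - 1, , ]
  }
  if (cfg$include_gravity) acc[, , 3] <- acc[, , 3] - 9.81
  pose_sequence(ori, cfg$rate, acc, frame = "global")
}

#' Standalone-IMU emulation configuration
#'
#' @param mounting Per-segment mounting rotation: a single unit quaternion
#'   applied to every segment, or a named list of quaternions.
#' @param drift_deg_min Slow orientation drift rate (deg/min).
#' @param drift_axis Drift axis (length-3).
#' @param ori_noise_deg Per-frame orientation noise standard deviation
#'   (degrees).
#' @param acc_noise Per-axis acceleration noise standard deviation (m/s^2).
#' @param rate Output rate in Hz (60 matches the standalone IMU).
#' @param seed Integer seed for the noise draws.
#' @return A list of class `dot_config`.
#' @export
dot_config <- function(mounting = quat_identity(), drift_deg_min = 0,
                       drift_axis = c(0, 0, 1), ori_noise_deg = 0,
                       acc_noise = 0, rate = 60, seed = 1) {
  stopifnot(drift_deg_min >= 0, ori_noise_deg >= 0, acc_noise >= 0, rate > 0,
            length(drift_axis) == 3)
  structure(list(mounting = mounting, drift_deg_min = drift_deg_min,
                 drift_axis = drift_axis, ori_noise_deg = ori_noise_deg,
                 acc_noise = acc_noise, rate = rate, seed = seed),
            class = "dot_config")
}

#' Emulate a standalone-IMU stream from a ground-truth sequence
#'
#' Decimates the truth to the IMU rate and degrades it:
#' `orientation = drift(t) * mounting * truth` (quaternion composition) with
#' optional per-frame orientation noise, and accelerations rotated by the
#' same composed offset with additive noise. With zero drift and noise the
#' offset is a fixed rotation, the regime in which the per-session variable
#' mapping achieves exact recovery.
#'
#' @param truth A global-frame `pose_sequence` with accelerations (e.g.
#'   240 Hz).
#' @param cfg A `dot_config`.
#' @return A `pose_sequence` at `cfg$rate` in the raw IMU frame.
#' @export
emulate_dot_stream <- function(truth, cfg = dot_config()) {
  stopifnot(inherits(truth, "pose_sequence"), inherits(cfg, "dot_config"))
  if (truth$frame != "global") stop("truth must be in the global frame")
  set.seed(cfg$seed)
  dec <- resample_pose(truth, cfg$rate)
  nf <- n_frames(dec)
  t_s <- (seq_len(nf) - 1) / cfg$rate
  ori <- dec$orientation
  acc <- dec$acceleration
  for (s in dec$segments) {
    mount <- if (is.list(cfg$mounting)) {
      if (is.null(cfg$mounting[[s]])) quat_identity() else cfg$mounting[[s]]
    } else cfg$mounting
    drift_ang <- cfg$drift_deg_min * t_s / 60
    offs <- t(vapply(seq_len(nf), function(i) {
      d <- if (drift_ang[i] > 0) quat_from_axis_angle(cfg$drift_axis, drift_ang[i])
           else quat_identity()
      qmul(d, mount)
    }, numeric(4)))
    q <- qmul(offs, dec$orientation[, s, ])
    if (cfg$ori_noise_deg > 0) {
      noise <- t(vapply(seq_len(nf), function(i)
        quat_from_axis_angle(stats::rnorm(3), stats::rnorm(1, sd = cfg$ori_noise_deg)),
        numeric(4)))
      q <- qmul(noise, q)
    }
    ori[, s, ] <- q
    if (!is.null(acc)) {
      a <- quat_rotate(offs, dec$acceleration[, s, ])
      if (cfg$acc_noise > 0) a <- a + matrix(stats::rnorm(length(a), sd = cfg$acc_noise), nrow(a))
      acc[, s, ] <- a
    }
  }
  pose_sequence(ori, cfg$rate, acc, frame = "global")
}

#' Build a reproducible training corpus of feature windows
#'
#' Generates `n_sequences` ground-truth sequences (seeds derived from
#' `seed`), normalizes each to the pelvis frame, and windows them with
#' [build_windows()]. The per-sequence window count follows the floor
#' arithmetic of the windowing stride.
#'
#' @param n_sequences Number of independent sequences.
#' @param skel An `upper_body_skeleton`.
#' @param motion_cfg A `motion_config` (its `seed` field is overridden per
#'   sequence).
#' @param model_cfg A `model_config` controlling the windowing.
#' @param seed Integer base seed.
#' @return List with `windows` (all sequences pooled) and
#'   `n_windows_per_sequence`.
#' @export
make_training_corpus <- function(n_sequences, skel,
                                 motion_cfg = motion_config(),
                                 model_cfg = model_config(), seed = 1) {
  stopifnot(n_sequences >= 0)
  windows <- list()
  counts <- integer(n_sequences)
  for (i in seq_len(n_sequences)) {
    mc <- motion_cfg
    mc$seed <- seed * 1000 + i
    truth <- generate_pose_sequence(skel, mc)
    norm <- normalize_orientations(truth)
    w <- build_windows(norm, model_cfg)
    counts[i] <- length(w)
    windows <- c(windows, w)
  }
  list(windows = windows, n_windows_per_sequence = counts)
}
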