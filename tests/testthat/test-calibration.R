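## A divisor of both stream rates is used when decimating, so both streams
## sample identical ground-truth instants and recovery checks are exact.
sync_rate <- 20

test_that("a fixed rotation offset is recovered exactly at every frame", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 2, seed = 41))
  Q <- quat_from_axis_angle(c(1, -2, 0.5), 52)
  dot <- emulate_dot_stream(truth, dot_config(mounting = Q))
  sync <- synchronize_streams(truth, dot, rate_out = sync_rate)
  expect_equal(sync$offset, 0L)
  for (seg in c("Pelvis", "RightForearm")) {
    m <- compute_variable_mapping(sync$mvn, sync$dot, seg, n = 7)
    expect_equal(angle_between(m$ori_map, qinv(Q)), 0, tolerance = 1e-7)
    cal <- apply_mapping(m, sync$dot)
    err <- angle_between(cal$orientation[, seg, ],
                         sync$mvn$orientation[, seg, ])
    expect_lt(max(err), 1e-6)
    expect_equal(cal$acceleration[, seg, ], sync$mvn$acceleration[, seg, ],
                 tolerance = 1e-8)
  }
})

test_that("calibration is invariant to the calibration frame for fixed offsets", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 1.5, seed = 42))
  Q <- quat_from_axis_angle(c(0, 1, 1), 33)
  dot <- emulate_dot_stream(truth, dot_config(mounting = Q))
  sync <- synchronize_streams(truth, dot, rate_out = sync_rate)
  maps <- lapply(seq(1, n_frames(sync$dot), length.out = 10), function(n)
    compute_variable_mapping(sync$mvn, sync$dot, "LeftForearm", n = round(n)))
  for (m in maps[-1])
    expect_equal(angle_between(m$ori_map, maps[[1]]$ori_map), 0, tolerance = 1e-7)
})

test_that("alignment recovers a constructed frame shift", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 3, seed = 43))
  dot <- emulate_dot_stream(truth, dot_config())
  drop <- 12   # 0.2 s at 60 Hz = 4 frames at the 20 Hz analysis rate
  shifted <- pose_sequence(dot$orientation[-(1:drop), , , drop = FALSE], dot$rate,
                           dot$acceleration[-(1:drop), , , drop = FALSE])
  sync <- synchronize_streams(truth, shifted, rate_out = sync_rate)
  expect_equal(sync$offset, 4L)
  expect_equal(n_frames(sync$mvn), n_frames(sync$dot))
})

test_that("constant streams fall back to zero offset with a warning", {
  segs <- upper_body_segments()
  nf <- 240
  ori <- array(0, c(nf, length(segs), 4), dimnames = list(NULL, segs, NULL))
  for (s in segs) ori[, s, ] <- matrix(quat_identity(), nf, 4, byrow = TRUE)
  acc <- array(1, c(nf, length(segs), 3), dimnames = list(NULL, segs, NULL))
  mvn <- pose_sequence(ori, 240, acc)
  dot <- resample_pose(mvn, 60)
  expect_warning(sync <- synchronize_streams(mvn, dot), "offset 0")
  expect_equal(sync$offset, 0L)
})

test_that("a drifting offset degrades away from the calibration frame", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 4, seed = 44,
                                                      max_speed_deg_s = 0))
  dot <- emulate_dot_stream(truth, dot_config(drift_deg_min = 120))
  ## static pose has no dynamics, so alignment falls back to offset 0
  sync <- suppressWarnings(synchronize_streams(truth, dot, rate_out = sync_rate))
  n0 <- 1
  m <- compute_variable_mapping(sync$mvn, sync$dot, "T8", n = n0)
  cal <- apply_mapping(m, sync$dot)
  err <- angle_between(cal$orientation[, "T8", ], sync$mvn$orientation[, "T8", ])
  expect_lt(err[n0], 1e-6)
  ## error grows monotonically with temporal distance from the calibration
  ## frame under constant-rate drift
  expect_true(all(diff(err) > -1e-9))
  expect_gt(err[length(err)], err[5] + 1)
})

test_that("fixed mapping averages per-session maps", {
  mk <- function(q) structure(list(segment = "T8", session = "s", frame = 1L,
                                   ori_map = q, acc_map = q),
                              class = "calibration_map")
  q <- quat_from_axis_angle(c(0, 0, 1), 30)
  four <- compute_fixed_mapping(list(mk(q), mk(q), mk(q), mk(q)))
  expect_equal(angle_between(four$ori_map, q), 0, tolerance = 1e-9)
  expect_equal(four$session, "fixed")
  ## two maps 0 and 90 degrees about one axis average to 45 degrees
  two <- compute_fixed_mapping(list(mk(quat_identity()),
                                    mk(quat_from_axis_angle(c(0, 0, 1), 90))))
  expect_equal(angle_between(two$ori_map, quat_from_axis_angle(c(0, 0, 1), 45)),
               0, tolerance = 1e-7)
  bad <- mk(q); bad$segment <- "Head"
  expect_error(compute_fixed_mapping(list(mk(q), bad)), "mix")
})

test_that("fixed-mapping error is bounded by the session spread", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 1, seed = 45))
  dot0 <- emulate_dot_stream(truth, dot_config())
  sync <- synchronize_streams(truth, dot0, rate_out = sync_rate)
  ## four sessions with mounting rotations spread up to 16 degrees apart
  angles <- c(0, 6, 10, 16)
  maps <- lapply(angles, function(a) {
    d <- emulate_dot_stream(truth, dot_config(
      mounting = quat_from_axis_angle(c(0, 0, 1), a)))
    s <- synchronize_streams(truth, d, rate_out = sync_rate)
    compute_variable_mapping(s$mvn, s$dot, "T8", n = 3, session = paste0("s", a))
  })
  fixed <- compute_fixed_mapping(maps)
  spread <- max(vapply(maps, function(m)
    angle_between(m$ori_map, fixed$ori_map), 1))
  cal <- apply_mapping(fixed, sync$dot)
  err <- max(angle_between(cal$orientation[, "T8", ], sync$mvn$orientation[, "T8", ]))
  expect_lte(err, spread + 1e-6)
})

test_that("calibration maps round-trip through JSON", {
  m <- structure(list(segment = "Pelvis", session = "day1", frame = 12L,
                      ori_map = quat_from_axis_angle(c(1, 0, 0), 20),
                      acc_map = quat_from_axis_angle(c(0, 1, 0), -14)),
                 class = "calibration_map")
  path <- tempfile(fileext = ".json")
  write_calibration_json(list(m), path)
  rt <- read_calibration_json(path)[[1]]
  expect_equal(rt$ori_map, m$ori_map, tolerance = 1e-12)
  expect_equal(rt$acc_map, m$acc_map, tolerance = 1e-12)
  expect_equal(rt$segment, "Pelvis")
  expect_equal(rt$frame, 12L)
})

test_that("segment mismatches are rejected", {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(skel, motion_config(duration_s = 0.5, seed = 46))
  m <- structure(list(segment = "NoSuchSegment", session = "s", frame = 1L,
                      ori_map = quat_identity(), acc_map = quat_identity()),
                 class = "calibration_map")
  expect_error(apply_mapping(m, truth), "NoSuchSegment")
  expect_error(compute_variable_mapping(truth, truth, "NoSuchSegment"), "segment")
  expect_error(compute_variable_mapping(truth, truth, "T8", n = 10^6), "out of range")
})
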