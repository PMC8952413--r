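test_that("pelvis normalization reconstructs global orientations", {
  seq0 <- tiny_pose(frames = 8, seed = 3)
  norm <- normalize_orientations(seq0)
  expect_equal(norm$frame, "pelvis")
  ## pelvis becomes the identity rotation
  expect_equal(max(angle_between(norm$orientation[, "Pelvis", ],
                                 matrix(rep(quat_identity(), 8), ncol = 4, byrow = TRUE))),
               0, tolerance = 1e-9)
  ## R_GP * R_PB reconstructs R_GB
  rec <- denormalize(norm, seq0$orientation[, "Pelvis", ])
  expect_lt(max(angle_between(
    matrix(rec$orientation, ncol = 4), matrix(seq0$orientation, ncol = 4))), 1e-5)
  if (!is.null(seq0$acceleration))
    expect_equal(rec$acceleration, seq0$acceleration, tolerance = 1e-9)
})

test_that("identity pelvis leaves a sequence unchanged", {
  seq0 <- tiny_pose(frames = 5, seed = 4)
  seq0$orientation[, "Pelvis", ] <- matrix(rep(quat_identity(), 5), ncol = 4, byrow = TRUE)
  norm <- normalize_orientations(seq0)
  for (s in seq0$segments)
    expect_equal(max(angle_between(norm$orientation[, s, ], seq0$orientation[, s, ])),
                 0, tolerance = 1e-9)
  expect_equal(norm$acceleration, seq0$acceleration, tolerance = 1e-12)
})

test_that("acceleration normalization rotates by the inverse pelvis rotation", {
  segs <- upper_body_segments()
  ori <- array(0, c(1, length(segs), 4), dimnames = list(NULL, segs, NULL))
  for (s in segs) ori[1, s, ] <- quat_identity()
  ori[1, "Pelvis", ] <- quat_from_axis_angle(c(0, 0, 1), 90)
  acc <- array(0, c(1, length(segs), 3), dimnames = list(NULL, segs, NULL))
  acc[1, "T8", ] <- c(1, 0, 0)
  seq0 <- pose_sequence(ori, 240, acc, frame = "global")
  out <- normalize_accelerations(seq0)
  expect_equal(as.numeric(out$acceleration[1, "T8", ]), c(0, -1, 0), tolerance = 1e-9)
  expect_equal(as.numeric(out$acceleration[1, "Head", ]), c(0, 0, 0))
  seq0$acceleration <- NULL
  expect_error(normalize_accelerations(seq0), "acceleration")
})

test_that("forward kinematics chains offsets down the tree", {
  skel <- upper_body_skeleton()
  segs <- skel$segments
  nf <- 1
  ori <- array(0, c(nf, length(segs), 4), dimnames = list(NULL, segs, NULL))
  for (s in segs) ori[1, s, ] <- quat_identity()
  seq0 <- pose_sequence(ori, 240, frame = "global")
  pos <- forward_kinematics(seq0, skel)
  ## spine chain accumulates the z offsets with identity orientations
  expect_equal(as.numeric(pos[1, "L5", ]), c(0, 0, 0.10))
  expect_equal(as.numeric(pos[1, "T12", ]), c(0, 0, 0.30))
  expect_equal(as.numeric(pos[1, "Head", ]), c(0, 0, 0.70), tolerance = 1e-12)
  ## 180 degrees about x flips a segment's offset contribution
  ori[1, "Head", ] <- quat_from_axis_angle(c(1, 0, 0), 180)
  pos2 <- forward_kinematics(pose_sequence(ori, 240, frame = "global"), skel)
  expect_equal(as.numeric(pos2[1, "Head", ]), c(0, 0, 0.52 - 0.18), tolerance = 1e-9)
})

test_that("forward kinematics matches a brute-force traversal oracle", {
  skel <- upper_body_skeleton()
  seq0 <- tiny_pose(frames = 4, seed = 5)
  root <- c(0.5, -0.2, 1.0)
  pos <- forward_kinematics(seq0, skel, root_position = root)
  for (f in 1:4) {
    oracle <- matrix(0, length(skel$segments), 3)
    for (i in seq_along(skel$segments)) {
      p <- if (skel$parent[i] == 0) root else oracle[skel$parent[i], ]
      R <- quat_to_matrix(seq0$orientation[f, i, ])
      oracle[i, ] <- p + as.numeric(R %*% skel$offsets[i, ])
    }
    expect_equal(matrix(pos[f, , ], ncol = 3), oracle, tolerance = 1e-9)
  }
})

test_that("forward kinematics is translation-equivariant and rigid", {
  skel <- upper_body_skeleton()
  seq0 <- tiny_pose(frames = 3, seed = 6)
  p0 <- forward_kinematics(seq0, skel)
  p1 <- forward_kinematics(seq0, skel, root_position = c(1, 2, 3))
  shift <- p1 - p0
  expect_equal(range(shift[, , 1]), c(1, 1), tolerance = 1e-12)
  expect_equal(range(shift[, , 2]), c(2, 2), tolerance = 1e-12)
  expect_equal(range(shift[, , 3]), c(3, 3), tolerance = 1e-12)
  ## child-parent distance equals offset length for every pose
  for (i in seq_along(skel$segments)[-1]) {
    d <- sqrt(rowSums((p0[, i, ] - p0[, skel$parent[i], ])^2))
    expect_equal(d, rep(sqrt(sum(skel$offsets[i, ]^2)), 3), tolerance = 1e-9)
  }
})

test_that("skeleton JSON round-trips and malformed poses are rejected", {
  skel <- upper_body_skeleton()
  path <- tempfile(fileext = ".json")
  write_skeleton_json(skel, path)
  rt <- read_skeleton_json(path)
  expect_equal(rt$offsets, skel$offsets)
  expect_equal(rt$parent, skel$parent)
  ## missing pelvis rejected at normalization
  segs <- c("T8", "Head")
  ori <- array(rep(quat_identity(), each = 0), c(2, 2, 4), dimnames = list(NULL, segs, NULL))
  for (s in segs) for (f in 1:2) ori[f, s, ] <- quat_identity()
  expect_error(normalize_orientations(pose_sequence(ori, 60)), "[Pp]elvis")
})
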