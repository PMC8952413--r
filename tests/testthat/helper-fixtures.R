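## Shared fixtures, built in code.

random_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

## Small pose sequence over all 15 segments with accelerations.
tiny_pose <- function(frames = 12, rate = 240, seed = 1) {
  set.seed(seed)
  segs <- upper_body_segments()
  ori <- array(0, c(frames, length(segs), 4), dimnames = list(NULL, segs, NULL))
  for (s in seq_along(segs)) for (f in seq_len(frames)) ori[f, s, ] <- random_quat()
  acc <- array(stats::rnorm(frames * length(segs) * 3), c(frames, length(segs), 3),
               dimnames = list(NULL, segs, NULL))
  pose_sequence(ori, rate, acc, frame = "global")
}

## Windows for motion-model tests: enough frames for n windows.
tiny_windows <- function(n_windows = 4, seed = 2) {
  skel <- upper_body_skeleton()
  truth <- generate_pose_sequence(
    skel, motion_config(duration_s = n_windows * 30 / 240, seed = seed))
  suppressWarnings(build_windows(normalize_orientations(truth), model_config()))
}
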