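## Orientation and joint-angle evaluation.

## Coerce a pose_sequence or [n, frame, segment, 4] array to a
## frames x segments x 4 quaternion array with segment names.
eval_quat_array <- function(x) {
  if (inherits(x, "pose_sequence")) return(x$orientation)
  if (is.array(x) && length(dim(x)) == 4) {
    d <- dim(x)
    ## flatten windows to a single frame axis, preserving in-window order
    out <- array(0, c(d[1] * d[2], d[3], 4))
    k <- 0
    for (w in seq_len(d[1])) for (f in seq_len(d[2])) {
      k <- k + 1
      out[k, , ] <- x[w, f, , ]
    }
    dimnames(out) <- list(NULL, dimnames(x)[[3]], NULL)
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("expected a pose_sequence or a quaternion array")
}

#' Mean angular error between predicted and true orientations
#'
#' Averages the relative-rotation angle ([angle_between()]) over all frames
#' and segments; also reported per segment. Invariant to quaternion sign
#' and symmetric in its arguments.
#'
#' @param pred,truth `pose_sequence`s, `[window, frame, segment, 4]`
#'   prediction arrays, or `[frame, segment, 4]` arrays, with identical
#'   shapes.
#' @return List with `overall` (degrees) and `per_segment` (named vector of
#'   per-segment means).
#' @export
mean_angular_error <- function(pred, truth) {
  p <- eval_quat_array(pred)
  t_ <- eval_quat_array(truth)
  if (!all(dim(p) == dim(t_))) stop("prediction and truth shapes differ")
  segs <- dimnames(p)[[2]]
  per <- vapply(seq_len(dim(p)[2]), function(si) {
    mean(angle_between(matrix(p[, si, ], ncol = 4), matrix(t_[, si, ], ncol = 4)))
  }, 1)
  names(per) <- segs
  ## every segment contributes the same number of frame pairs, so the mean
  ## over all (frame, segment) pairs equals the mean of per-segment means
  list(overall = mean(per), per_segment = per)
}

#' Named joints of the upper body
#'
#' Elbows compare upper arm against forearm; shoulders compare the T8
#' (upper chest) segment against the upper arm, deliberately collapsing the
#' shoulder's three degrees of freedom into one relative-rotation angle.
#'
#' @return Named list of segment pairs.
#' @export
joint_definitions <- function() {
  list(right_elbow = c("RightUpperArm", "RightForearm"),
       left_elbow = c("LeftUpperArm", "LeftForearm"),
       right_shoulder = c("T8", "RightUpperArm"),
       left_shoulder = c("T8", "LeftUpperArm"))
}

#' Per-frame joint angle
#'
#' The smallest rotation angle between the orientations of the two segments
#' spanning the joint; for the elbow, 0 degrees is the arm straight.
#'
#' @param seq A `pose_sequence` (any frame of reference; the angle is
#'   relative).
#' @param joint A name from [joint_definitions()], or a character pair of
#'   segment names.
#' @return Numeric vector of per-frame angles in degrees.
#' @export
joint_angle <- function(seq, joint) {
  pair <- if (is.character(joint) && length(joint) == 2) joint
          else joint_definitions()[[joint]]
  if (is.null(pair)) stop("unknown joint: ", joint)
  q <- eval_quat_array(seq)
  miss <- setdiff(pair, dimnames(q)[[2]])
  if (length(miss) > 0) stop("segment(s) missing: ", paste(miss, collapse = ", "))
  angle_between(matrix(q[, pair[1], ], ncol = 4), matrix(q[, pair[2], ], ncol = 4))
}

#' Signed joint-angle error series
#'
#' Per frame, inferred angle minus ground-truth angle: negative values mean
#' the inferred joint was more acute (e.g. the arm closer to the side) than
#' the truth.
#'
#' @param pred,truth Aligned `pose_sequence`s (or quaternion arrays).
#' @param joint Joint name or segment pair (see [joint_angle()]).
#' @return List with `errors` (signed degrees per frame), `mean` and `sd`.
#' @export
joint_angle_error <- function(pred, truth, joint) {
  a_pred <- joint_angle(pred, joint)
  a_true <- joint_angle(truth, joint)
  if (length(a_pred) != length(a_true)) stop("prediction and truth lengths differ")
  err <- a_pred - a_true
  list(errors = err, mean = mean(err), sd = stats::sd(err))
}

#' Fixed-width histogram of error values
#'
#' Bins aligned to multiples of the bin width; counts conserve the sample
#' size.
#'
#' @param values Finite numeric values.
#' @param bin_width Positive bin width.
#' @return Data frame with `bin_left`, `bin_right`, `count`.
#' @export
error_histogram <- function(values, bin_width) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (!all(is.finite(values))) stop("values must be finite")
  lo <- floor(min(values) / bin_width)
  hi <- floor(max(values) / bin_width)
  lefts <- (lo:hi) * bin_width
  idx <- pmin(floor(values / bin_width) - lo + 1, length(lefts))
  count <- tabulate(idx, nbins = length(lefts))
  data.frame(bin_left = lefts, bin_right = lefts + bin_width, count = count)
}

#' Evaluation report for a prediction
#'
#' Bundles overall and per-segment mean angular error with joint-angle
#' error summaries and histograms, and can be written to JSON.
#'
#' @param pred,truth Aligned `pose_sequence`s or prediction arrays.
#' @param joints Joint names to evaluate (default all of
#'   [joint_definitions()]).
#' @param bin_width Histogram bin width in degrees.
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(pred, truth, joints = names(joint_definitions()),
                              bin_width = 2) {
  mae <- mean_angular_error(pred, truth)
  jerr <- lapply(joints, function(j) {
    e <- joint_angle_error(pred, truth, j)
    list(mean = e$mean, sd = e$sd,
         histogram = error_histogram(e$errors, bin_width))
  })
  names(jerr) <- joints
  structure(list(overall_deg = mae$overall, per_segment_deg = mae$per_segment,
                 joints = jerr), class = "evaluation_report")
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(list(
    overall_deg = report$overall_deg,
    per_segment_deg = as.list(report$per_segment_deg),
    joints = lapply(report$joints, function(j)
      list(mean = j$mean, sd = j$sd, histogram = j$histogram))
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
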