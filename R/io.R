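## File formats: motion / RSS time-series CSV with JSON sidecars, scene
## YAML, and the stick-figure pose export.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a motion time series as CSV
#'
#' Long-format CSV with header `time_s, stream_id, qw, qx, qy, qz, ax, ay,
#' az` (acceleration columns empty when absent) plus a JSON sidecar
#' (`<path>.json`) recording rate, frame of reference and units. Reading
#' validates the header, monotone time, sidecar rate against the median
#' sample spacing (1%), and quaternion unit norms (1e-6), reporting
#' offending line numbers.
#'
#' @param seq A `pose_sequence`.
#' @param path CSV file path (sidecar written next to it).
#' @return `read_pose_csv()` returns a `pose_sequence`; `write_pose_csv()`
#'   returns `path` invisibly.
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  nf <- n_frames(seq)
  t_s <- (seq_len(nf) - 1) / seq$rate
  rows <- lapply(seq$segments, function(s) {
    q <- matrix(seq$orientation[, s, ], ncol = 4)
    a <- if (is.null(seq$acceleration)) matrix(NA_real_, nf, 3)
         else matrix(seq$acceleration[, s, ], ncol = 3)
    data.frame(time_s = t_s, stream_id = s,
               qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
               ax = a[, 1], ay = a[, 2], az = a[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = seq$rate, frame = seq$frame,
                            units = list(time = "s", acceleration = "m/s^2"),
                            has_acceleration = !is.null(seq$acceleration)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("time_s", "stream_id", "qw", "qx", "qy", "qz", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  segs <- unique(df$stream_id)
  nf <- sum(df$stream_id == segs[1])
  t_s <- df$time_s[df$stream_id == segs[1]]
  if (nf > 1) {
    if (any(diff(t_s) <= 0)) {
      bad <- which(diff(t_s) <= 0)[1] + 1
      stop("non-monotone time at sample ", bad)
    }
    spacing <- stats::median(diff(t_s))
    if (abs(spacing - 1 / meta$rate_hz) > 0.01 / meta$rate_hz)
      stop(sprintf("sidecar rate %g Hz inconsistent with median spacing %g s",
                   meta$rate_hz, spacing))
  }
  ori <- array(0, c(nf, length(segs), 4), dimnames = list(NULL, segs, NULL))
  has_acc <- isTRUE(meta$has_acceleration)
  acc <- if (has_acc) array(0, c(nf, length(segs), 3), dimnames = list(NULL, segs, NULL))
  for (s in segs) {
    rows <- df[df$stream_id == s, ]
    if (nrow(rows) != nf) stop("unequal frame counts across streams")
    q <- as.matrix(rows[, c("qw", "qx", "qy", "qz")])
    nrm <- sqrt(rowSums(q^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      bad <- which(abs(nrm - 1) > 1e-6)[1]
      stop("quaternion norm violation for stream ", s, " at frame ", bad)
    }
    ori[, s, ] <- q
    if (has_acc) acc[, s, ] <- as.matrix(rows[, c("ax", "ay", "az")])
  }
  pose_sequence(ori, meta$rate_hz, acc,
                frame = if (identical(meta$frame, "pelvis")) "pelvis" else "global")
}

#' Write / read an RSS trace as CSV
#'
#' Long-format CSV with header `time_s, anchor_id, rss_dbm` plus a JSON
#' sidecar recording the sample rate and clipping state.
#'
#' @param trace An `rss_trace`.
#' @param path CSV file path.
#' @return `read_rss_csv()` returns an `rss_trace`; `write_rss_csv()`
#'   returns `path` invisibly.
#' @export
write_rss_csv <- function(trace, path) {
  stopifnot(inherits(trace, "rss_trace"))
  u <- ncol(trace$rss)
  n <- nrow(trace$rss)
  t_s <- if (is.null(trace$time_s)) seq_len(n) - 1 else trace$time_s
  df <- data.frame(time_s = rep(t_s, u),
                   anchor_id = rep(seq_len(u), each = n),
                   rss_dbm = as.numeric(trace$rss))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(n_anchors = u, clipped = isTRUE(trace$clipped)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rss_csv
#' @export
read_rss_csv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("time_s", "anchor_id", "rss_dbm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  u <- meta$n_anchors
  n <- nrow(df) / u
  if (n != floor(n)) stop("row count is not a multiple of the anchor count")
  rss <- matrix(df$rss_dbm, n, u)
  structure(list(rss = rss, time_s = df$time_s[seq_len(n)],
                 clipped = isTRUE(meta$clipped)), class = "rss_trace")
}

#' Write / read an anchor scene as YAML
#'
#' @param scene An `anchor_scene`.
#' @param path YAML file path.
#' @return `read_scene_yaml()` returns an `anchor_scene`;
#'   `write_scene_yaml()` returns `path` invisibly.
#' @export
write_scene_yaml <- function(scene, path) {
  stopifnot(inherits(scene, "anchor_scene"))
  yaml::write_yaml(list(
    bounds = as.numeric(scene$bounds),
    anchors = lapply(seq_len(scene$n_anchors), function(i) list(
      x = scene$anchors[i, 1], y = scene$anchors[i, 2],
      pt_dbm = scene$params$pt_dbm[i], pl0_db = scene$params$pl0_db[i],
      d0_m = scene$params$d0_m[i], exponent = scene$params$exponent[i],
      sigma_db = scene$params$sigma_db[i]))), path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  a <- do.call(rbind, lapply(x$anchors, function(z) c(z$x, z$y)))
  p <- do.call(rbind, lapply(x$anchors, function(z)
    data.frame(pt_dbm = z$pt_dbm, pl0_db = z$pl0_db, d0_m = z$d0_m,
               exponent = z$exponent, sigma_db = z$sigma_db)))
  anchor_scene(a, as.numeric(x$bounds), p)
}

#' Export a stick-figure line model of poses
#'
#' Runs forward kinematics and emits one row per frame and non-root
#' segment with the parent endpoint and the segment endpoint (metres),
#' ready for line plotting.
#'
#' @param seq A global-frame `pose_sequence` covering the skeleton.
#' @param skel An `upper_body_skeleton`.
#' @param path Optional CSV path; when given the table is also written.
#' @param root_position Root position passed to [forward_kinematics()].
#' @return Data frame with columns `frame`, `segment`, `parent_x/y/z`,
#'   `x/y/z` (empty for an empty frame set).
#' @export
export_stick_figure <- function(seq, skel, path = NULL,
                                root_position = c(0, 0, 0)) {
  cols <- c("frame", "segment", "parent_x", "parent_y", "parent_z",
            "x", "y", "z")
  if (n_frames(seq) == 0) {
    df <- as.data.frame(matrix(numeric(0), 0, 8, dimnames = list(NULL, cols)))
  } else {
    pos <- forward_kinematics(seq, skel, root_position)
    nf <- dim(pos)[1]
    rows <- list()
    for (i in seq_along(skel$segments)[-1]) {
      parent <- skel$parent[i]
      rows[[length(rows) + 1]] <- data.frame(
        frame = seq_len(nf), segment = skel$segments[i],
        parent_x = pos[, parent, 1], parent_y = pos[, parent, 2],
        parent_z = pos[, parent, 3],
        x = pos[, i, 1], y = pos[, i, 2], z = pos[, i, 3])
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$frame), ]
    rownames(df) <- NULL
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Write a histogram table as CSV
#'
#' @param hist Data frame from [error_histogram()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(all(c("bin_left", "bin_right", "count") %in% names(hist)))
  utils::write.csv(hist, path, row.names = FALSE)
  invisible(path)
}
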