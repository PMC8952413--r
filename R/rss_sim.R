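## Log-distance + shadowing RSS simulation along target trajectories.

#' Define an anchor scene
#'
#' A set of fixed Bluetooth anchors at known 2D coordinates inside a bounded
#' area, each with its own log-distance propagation parameters: transmit
#' power `pt_dbm`, reference path loss `pl0_db` at reference distance
#' `d0_m`, path-loss exponent `exponent`, and shadowing standard deviation
#' `sigma_db`.
#'
#' @param anchors U x 2 matrix of anchor coordinates (metres).
#' @param bounds Area bounds `c(xmin, xmax, ymin, ymax)` (metres).
#' @param params Data frame with one row per anchor and columns `pt_dbm`,
#'   `pl0_db`, `d0_m`, `exponent`, `sigma_db`.
#' @return An object of class `anchor_scene`.
#' @export
anchor_scene <- function(anchors, bounds, params) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2, nrow(anchors) >= 1, all(is.finite(anchors)),
            length(bounds) == 4, bounds[1] < bounds[2], bounds[3] < bounds[4])
  need <- c("pt_dbm", "pl0_db", "d0_m", "exponent", "sigma_db")
  stopifnot(is.data.frame(params), nrow(params) == nrow(anchors),
            all(need %in% names(params)),
            all(params$d0_m > 0), all(params$sigma_db >= 0))
  inside <- anchors[, 1] >= bounds[1] & anchors[, 1] <= bounds[2] &
            anchors[, 2] >= bounds[3] & anchors[, 2] <= bounds[4]
  if (!all(inside)) stop("all anchors must lie within the area bounds")
  structure(list(anchors = anchors, bounds = bounds,
                 params = params[, need], n_anchors = nrow(anchors)),
            class = "anchor_scene")
}

#' Default rehabilitation-centre scene
#'
#' A 50 m by 50 m area divided into ten subcentres with one anchor at the
#' middle of each (a 5 x 2 grid of anchor positions). Propagation parameters
#' are typical of indoor Bluetooth low energy: 0 dBm transmit power, 40 dB
#' path loss at the 1 m reference distance, and per-anchor path-loss
#' exponents spread evenly over 2.0 to 3.5 so each anchor has its own
#' channel character.
#'
#' @param sigma_db Shadowing standard deviation in dB applied to every
#'   anchor; the default is the training condition (shadowing variance
#'   7.5 dB^2).
#' @return An `anchor_scene` with 10 anchors.
#' @export
default_anchor_scene <- function(sigma_db = sqrt(7.5)) {
  xs <- c(5, 15, 25, 35, 45)
  ys <- c(12.5, 37.5)
  anchors <- as.matrix(expand.grid(x = xs, y = ys))
  u <- nrow(anchors)
  params <- data.frame(
    pt_dbm = rep(0, u),
    pl0_db = rep(40, u),
    d0_m = rep(1, u),
    exponent = 2 + 1.5 * (seq_len(u) - 1) / (u - 1),
    sigma_db = rep(sigma_db, u))
  anchor_scene(anchors, bounds = c(0, 50, 0, 50), params = params)
}

#' Bounded random walk trajectory
#'
#' Gaussian steps reflected at the area bounds, emulating a person moving
#' inside the monitored area. One RSS vector is observed per step; the step
#' interval models the beacon broadcast period (0.1 s for 10 Hz beacons).
#'
#' @param bounds `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_steps Number of steps.
#' @param step_sd Standard deviation of each step component (metres).
#' @param seed Optional integer seed fixing the path.
#' @param start Optional starting position; defaults to the area centre.
#' @param dt Step interval in seconds.
#' @return An object of class `trajectory` with fields `positions`
#'   (n_steps x 2), `time_s` and `dt`.
#' @export
bounded_random_walk <- function(bounds, n_steps, step_sd, seed = NULL,
                                start = NULL, dt = 0.1) {
  stopifnot(length(bounds) == 4, n_steps >= 1, step_sd >= 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- c(mean(bounds[1:2]), mean(bounds[3:4]))
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  steps <- matrix(stats::rnorm(2 * n_steps, sd = step_sd), ncol = 2)
  pos <- apply(steps, 2, cumsum)
  if (n_steps == 1) pos <- matrix(pos, ncol = 2)
  pos[, 1] <- reflect(start[1] + pos[, 1], bounds[1], bounds[2])
  pos[, 2] <- reflect(start[2] + pos[, 2], bounds[3], bounds[4])
  structure(list(positions = pos, time_s = (seq_len(n_steps) - 1) * dt, dt = dt),
            class = "trajectory")
}

#' Distances from trajectory positions to every anchor
#' @param scene An `anchor_scene`.
#' @param traj A `trajectory`.
#' @return T x U matrix of Euclidean distances (metres).
#' @export
anchor_distances <- function(scene, traj) {
  pos <- traj$positions
  d <- outer(pos[, 1], scene$anchors[, 1], "-")^2 +
       outer(pos[, 2], scene$anchors[, 2], "-")^2
  sqrt(d)
}

#' Simulate RSS along a trajectory
#'
#' Per anchor and time step,
#' `rss = pt - pl0 - 10 * exponent * log10(d / d0) + N(0, sigma^2)` in dBm,
#' the log-distance path-loss model with i.i.d. log-normal shadowing.
#' Distances below the reference distance are floored at `d0` with a
#' warning.
#'
#' @param scene An `anchor_scene`.
#' @param traj A `trajectory`.
#' @param seed Optional integer seed for the shadowing draws.
#' @param sigma_db Optional scalar overriding every anchor's shadowing
#'   standard deviation (dB), e.g. to test at a different severity than
#'   trained.
#' @return An object of class `rss_trace`: list with `rss` (T x U matrix,
#'   dBm), `time_s`, and `clipped = FALSE`.
#' @export
simulate_rss <- function(scene, traj, seed = NULL, sigma_db = NULL) {
  stopifnot(inherits(scene, "anchor_scene"), inherits(traj, "trajectory"))
  if (!is.null(seed)) set.seed(seed)
  p <- scene$params
  sig <- if (is.null(sigma_db)) p$sigma_db else rep(sigma_db, scene$n_anchors)
  stopifnot(all(sig >= 0))
  d <- anchor_distances(scene, traj)
  if (any(d == 0)) warning("target coincides with an anchor; distance floored at d0")
  d <- pmax(d, rep(p$d0_m, each = nrow(d)))
  mean_rss <- rep(p$pt_dbm - p$pl0_db, each = nrow(d)) -
    10 * rep(p$exponent, each = nrow(d)) * log10(d / rep(p$d0_m, each = nrow(d)))
  shadow <- matrix(stats::rnorm(length(d)), nrow(d)) * rep(sig, each = nrow(d))
  structure(list(rss = mean_rss + shadow, time_s = traj$time_s, clipped = FALSE),
            class = "rss_trace")
}

#' Clip an RSS trace to the receiver's dynamic range
#'
#' Clamps every value to the interval \[-100, -50\] dBm, the range assumed
#' by the feature scaling of the proximity classifiers.
#'
#' @param trace An `rss_trace` (or bare matrix of dBm values).
#' @return The clipped trace, with `clipped = TRUE`.
#' @export
clip_rss <- function(trace) {
  if (is.matrix(trace)) trace <- structure(list(rss = trace, time_s = NULL,
                                                clipped = FALSE), class = "rss_trace")
  stopifnot(inherits(trace, "rss_trace"))
  trace$rss <- pmin(pmax(trace$rss, -100), -50)
  trace$clipped <- TRUE
  trace
}

#' Per-anchor vicinity labels along a trajectory
#'
#' `label[t, u] = 1` iff the target at step `t` is within `radius_m` metres
#' of anchor `u` (boundary inclusive). The intersection of per-anchor
#' vicinities confines the target to a region of interest without
#' coordinates.
#'
#' @param scene An `anchor_scene`.
#' @param traj A `trajectory`.
#' @param radius_m Vicinity radius in metres (default 15).
#' @return T x U binary (0/1) matrix.
#' @export
vicinity_labels <- function(scene, traj, radius_m = 15) {
  stopifnot(radius_m > 0)
  (anchor_distances(scene, traj) <= radius_m) * 1
}
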