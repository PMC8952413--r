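## Fingerprint codebook construction and k-NN centroid localization.

#' Build a fingerprint codebook from reference recordings
#'
#' Each reference point (grid cell `(i, j)` in room `k`) contributes the
#' time-mean RSS from every anchor as its fingerprint, paired with its 3D
#' reference coordinates. An anchor entirely absent from a recording is
#' stored at `nu_min` with a warning. Fingerprints are clipped to the
#' receiver range \[-100, -50\] dBm for consistency with the feature
#' preprocessing used elsewhere.
#'
#' @param recordings List of per-point RSS trace matrices (samples x U, dBm;
#'   `NA` marks missing packets from an anchor).
#' @param coordinates N x 3 matrix of reference coordinates (metres; z = 0
#'   for planar layouts).
#' @param rooms Optional integer room index per point (default all 1).
#' @param grid_ij Optional N x 2 matrix of grid indices; defaults to a
#'   running index in column i.
#' @param nu_min Minimum possible RSS (dBm) substituted for silent anchors.
#' @param clip Clip stored fingerprints to \[-100, -50\] dBm (default TRUE).
#' @return An object of class `fingerprint_codebook` with fields
#'   `fingerprints` (N x U), `coordinates` (N x 3), `rooms`, `grid_ij`,
#'   `nu_min`.
#' @export
build_codebook <- function(recordings, coordinates, rooms = NULL,
                           grid_ij = NULL, nu_min = -100, clip = TRUE) {
  stopifnot(is.list(recordings), length(recordings) >= 1)
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) == 2) coordinates <- cbind(coordinates, 0)
  stopifnot(ncol(coordinates) == 3, nrow(coordinates) == length(recordings))
  u <- ncol(recordings[[1]])
  fp <- matrix(NA_real_, length(recordings), u)
  for (i in seq_along(recordings)) {
    m <- as.matrix(recordings[[i]])
    if (ncol(m) != u) stop("all recordings must cover the same ", u, " anchors")
    mu <- colMeans(m, na.rm = TRUE)
    if (any(is.nan(mu))) {
      warning("reference point ", i, " missing anchor(s) ",
              paste(which(is.nan(mu)), collapse = ", "), "; stored as nu_min")
      mu[is.nan(mu)] <- nu_min
    }
    fp[i, ] <- mu
  }
  if (clip) fp <- pmin(pmax(fp, -100), -50)
  if (is.null(rooms)) rooms <- rep(1L, length(recordings))
  if (is.null(grid_ij)) grid_ij <- cbind(seq_along(recordings), 1L)
  key <- paste(grid_ij[, 1], grid_ij[, 2], rooms)
  if (anyDuplicated(key)) stop("duplicate (i, j, room) indices in codebook")
  structure(list(fingerprints = fp, coordinates = coordinates,
                 rooms = as.integer(rooms), grid_ij = as.matrix(grid_ij),
                 nu_min = nu_min),
            class = "fingerprint_codebook")
}

#' Preprocess raw test packets into a test fingerprint
#'
#' Averages timestamped RSS packets per anchor within consecutive 0.25 s
#' bins (a 4 Hz output rate). An anchor with no packets in a bin carries
#' `nu_min` in that slot.
#'
#' @param packets Data frame with columns `time_s`, `anchor` (1..U) and
#'   `rss_dbm`.
#' @param n_anchors Number of anchors U.
#' @param bin_s Averaging bin length in seconds (default 0.25, i.e. 4 Hz).
#' @param nu_min Value substituted for silent anchors (default -100 dBm).
#' @return List with `fingerprints` (bins x U matrix) and `time_s` (bin
#'   start times); each row is one test fingerprint G.
#' @export
preprocess_test_rss <- function(packets, n_anchors, bin_s = 0.25, nu_min = -100) {
  stopifnot(is.data.frame(packets),
            all(c("time_s", "anchor", "rss_dbm") %in% names(packets)),
            nrow(packets) >= 1, bin_s > 0,
            all(packets$anchor %in% seq_len(n_anchors)))
  t0 <- min(packets$time_s)
  bin <- floor((packets$time_s - t0) / bin_s)
  nbin <- max(bin) + 1
  out <- matrix(nu_min, nbin, n_anchors)
  agg <- stats::aggregate(rss_dbm ~ bin + anchor, data = cbind(packets, bin = bin),
                          FUN = mean)
  out[cbind(agg$bin + 1, agg$anchor)] <- agg$rss_dbm
  list(fingerprints = out, time_s = t0 + (seq_len(nbin) - 1) * bin_s)
}

#' Closest codebook fingerprints to a test fingerprint
#'
#' Ranks codebook entries by the Euclidean norm of the RSS difference
#' `||F - G||` and returns the indices of the `w` smallest, ascending. Ties
#' are broken by codebook insertion order.
#'
#' @param cb A `fingerprint_codebook`.
#' @param g Test fingerprint: numeric vector of U RSS values (dBm).
#' @param w Number of neighbours (default 3).
#' @return Integer vector of `w` codebook row indices.
#' @export
closest_fingerprints <- function(cb, g, w = 3) {
  stopifnot(inherits(cb, "fingerprint_codebook"),
            length(g) == ncol(cb$fingerprints), w >= 1)
  n <- nrow(cb$fingerprints)
  if (w > n) stop("w (", w, ") exceeds the number of codebook entries (", n, ")")
  d <- sqrt(colSums((t(cb$fingerprints) - as.numeric(g))^2))
  order(d)[seq_len(w)]  # order() breaks ties by index, i.e. insertion order
}

#' Centroid position estimate from selected reference points
#'
#' @param cb A `fingerprint_codebook`.
#' @param indices Codebook row indices (e.g. from
#'   [closest_fingerprints()]).
#' @return Length-3 numeric: the centroid of the selected reference
#'   coordinates (metres).
#' @export
position_estimate <- function(cb, indices) {
  stopifnot(inherits(cb, "fingerprint_codebook"), length(indices) >= 1,
            all(indices %in% seq_len(nrow(cb$fingerprints))))
  colMeans(cb$coordinates[indices, , drop = FALSE])
}

#' Locate a series of test fingerprints
#'
#' Convenience wrapper running [closest_fingerprints()] and
#' [position_estimate()] per row.
#'
#' @param cb A `fingerprint_codebook`.
#' @param g_series Bins x U matrix of test fingerprints.
#' @param w Number of neighbours.
#' @return Bins x 3 matrix of position estimates (metres).
#' @export
locate_fingerprints <- function(cb, g_series, w = 3) {
  g_series <- as.matrix(g_series)
  t(apply(g_series, 1, function(g)
    position_estimate(cb, closest_fingerprints(cb, g, w))))
}

#' Localization error summary
#'
#' @param estimates,truths Aligned N x 3 (or N x 2) coordinate matrices
#'   (metres).
#' @return List with `mse` (mean squared Euclidean error, m^2), `rmse` (m)
#'   and `errors` (per-point Euclidean distances, m).
#' @export
evaluate_localization <- function(estimates, truths) {
  estimates <- as.matrix(estimates)
  truths <- as.matrix(truths)
  if (ncol(estimates) == 2) estimates <- cbind(estimates, 0)
  if (ncol(truths) == 2) truths <- cbind(truths, 0)
  if (nrow(estimates) != nrow(truths))
    stop("estimate and truth series lengths differ")
  err <- sqrt(rowSums((estimates - truths)^2))
  list(mse = mean(err^2), rmse = sqrt(mean(err^2)), errors = err)
}

#' Read / write a fingerprint codebook as JSON
#'
#' @param cb A `fingerprint_codebook`.
#' @param path File path.
#' @return `read_codebook_json()` returns a `fingerprint_codebook`;
#'   `write_codebook_json()` returns `path` invisibly.
#' @export
write_codebook_json <- function(cb, path) {
  stopifnot(inherits(cb, "fingerprint_codebook"))
  jsonlite::write_json(list(
    n_anchors = ncol(cb$fingerprints),
    nu_min = cb$nu_min,
    rooms = cb$rooms,
    grid_i = cb$grid_ij[, 1],
    grid_j = cb$grid_ij[, 2],
    fingerprints = apply(cb$fingerprints, 1, identity, simplify = FALSE),
    coordinates = apply(cb$coordinates, 1, identity, simplify = FALSE)
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook_json
#' @export
read_codebook_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(z) if (is.list(z)) do.call(rbind, z) else as.matrix(z)
  structure(list(fingerprints = as_mat(x$fingerprints),
                 coordinates = as_mat(x$coordinates),
                 rooms = as.integer(x$rooms),
                 grid_ij = cbind(as.integer(x$grid_i), as.integer(x$grid_j)),
                 nu_min = as.numeric(x$nu_min)),
            class = "fingerprint_codebook")
}
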