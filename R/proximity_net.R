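## Neural proximity reporting: per-anchor vicinity classifiers (plain
## feed-forward and LSTM), the single-region (RoI) classifier variant, and
## the three accuracy metrics.

#' Proximity model configuration
#'
#' Training defaults follow the reference protocol: stochastic gradient
#' descent with learning rate 0.01, 400 epochs, batch size 500, training
#' shadowing variance 7.5 dB^2, decision threshold 0.5. The LSTM consumes
#' sliding windows of `t_lstm` time steps (default 10); the plain DNN sees
#' one RSS vector at a time through two hidden ReLU layers.
#'
#' @param architecture `"dnn"` or `"lstm"`.
#' @param hidden Hidden layer widths for the DNN.
#' @param lstm_hidden Hidden state size of the LSTM layer.
#' @param t_lstm LSTM memory in time steps.
#' @param learning_rate SGD learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param threshold Decision threshold on the sigmoid output (strict `>`).
#' @param train_shadowing_var Shadowing variance (dB^2) of the training
#'   condition; the simulator receives its square root as the noise
#'   standard deviation.
#' @return A list of class `proximity_config`.
#' @export
proximity_config <- function(architecture = c("dnn", "lstm"),
                             hidden = c(12, 12), lstm_hidden = 16,
                             t_lstm = 10, learning_rate = 0.01,
                             epochs = 400, batch_size = 500,
                             threshold = 0.5, train_shadowing_var = 7.5) {
  architecture <- match.arg(architecture)
  stopifnot(all(hidden > 0), lstm_hidden > 0, t_lstm >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            threshold > 0, threshold < 1, train_shadowing_var >= 0)
  structure(list(architecture = architecture, hidden = hidden,
                 lstm_hidden = lstm_hidden, t_lstm = t_lstm,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, threshold = threshold,
                 train_shadowing_var = train_shadowing_var),
            class = "proximity_config")
}

#' Scale clipped RSS features to the unit interval
#'
#' Affine map from the receiver range: -100 dBm to 0 and -50 dBm to 1.
#' The trace must have been clipped first ([clip_rss()]).
#'
#' @param trace A clipped `rss_trace`, or a matrix already within
#'   \[-100, -50\] dBm.
#' @return T x U matrix of features in \[0, 1\].
#' @export
scale_inputs <- function(trace) {
  m <- if (inherits(trace, "rss_trace")) {
    if (!isTRUE(trace$clipped)) stop("clip the trace to [-100, -50] dBm before scaling")
    trace$rss
  } else trace
  if (any(m < -100 | m > -50)) stop("values outside [-100, -50] dBm; clip first")
  (m + 100) / 50
}

## Sliding windows of t steps ending at each sample, padded at the start by
## repeating the first row. Returns list of T matrices (N x U), oldest first.
lstm_window_slices <- function(features, t_lstm) {
  n <- nrow(features)
  lapply(seq_len(t_lstm) - t_lstm, function(off) {
    idx <- pmax(seq_len(n) + off + 0L, 1L)
    features[idx, , drop = FALSE]
  })
}

#' Train a proximity-report classifier
#'
#' Minimizes per-anchor binary cross entropy over the `U` vicinity outputs
#' by stochastic gradient descent. The DNN maps a single scaled RSS vector
#' through two hidden ReLU layers; the LSTM consumes a sliding window of
#' `t_lstm` consecutive RSS vectors and classifies from its final hidden
#' state, exploiting the temporal correlation a moving target induces.
#'
#' @param features T x U matrix of scaled RSS features in \[0, 1\].
#' @param labels T x U binary matrix of vicinity labels.
#' @param cfg A `proximity_config`.
#' @param seed Integer seed fixing initialization and batch order.
#' @return A `proximity_model` with the fitted parameters and the per-epoch
#'   mean training loss in `$loss`.
#' @export
train_proximity <- function(features, labels, cfg = proximity_config(),
                            seed = 1) {
  stopifnot(is.matrix(features), is.matrix(labels),
            nrow(features) == nrow(labels), ncol(features) == ncol(labels),
            all(labels %in% c(0, 1)), all(features >= 0 & features <= 1))
  set.seed(seed)
  u <- ncol(features)
  n <- nrow(features)
  if (cfg$architecture == "dnn") {
    dims <- c(u, cfg$hidden, u)
    layers <- lapply(seq_len(length(dims) - 1),
                     function(i) nn_dense(dims[i], dims[i + 1]))
    model <- list(arch = "dnn", layers = layers, cfg = cfg, u = u)
  } else {
    model <- list(arch = "lstm",
                  cell = nn_lstm(u, cfg$lstm_hidden),
                  out = nn_dense(cfg$lstm_hidden, u),
                  cfg = cfg, u = u)
  }
  params <- nn_params(model[setdiff(names(model), c("arch", "cfg", "u"))])
  slices <- if (model$arch == "lstm") lstm_window_slices(features, cfg$t_lstm)
  loss_hist <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (n > cfg$batch_size) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = cfg$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
      if (model$arch == "lstm") {
        lv <- lstm_bce_pass_fast(model$cell, model$out, slices, idx,
                                 labels[idx, , drop = FALSE])
      } else {
        lv <- dnn_bce_pass(model$layers, features[idx, , drop = FALSE],
                           labels[idx, , drop = FALSE])
      }
      if (!is.finite(lv)) stop("training diverged: non-finite loss at epoch ", epoch)
      opt_sgd_step(params, cfg$learning_rate)
      batch_losses[bi] <- lv
    }
    loss_hist[epoch] <- mean(batch_losses)
  }
  model$loss <- loss_hist
  class(model) <- "proximity_model"
  model
}

## Fused LSTM forward + backward (truncated BPTT over the window) for the
## proximity classifier: one pass computes the binary cross entropy (summed
## over anchors, averaged over samples) and accumulates parameter gradients.
## Equivalent to the tape path but with far less interpreter overhead.
lstm_bce_pass <- function(cell, out, slices, idx, y) {
  nh <- cell$nh
  n <- length(idx)
  t_len <- length(slices)
  Wx <- cell$Wx$value; Wh <- cell$Wh$value; b <- cell$b$value
  ii <- 1:nh; fi <- (nh + 1):(2 * nh); gi <- (2 * nh + 1):(3 * nh)
  oi <- (3 * nh + 1):(4 * nh)
  ## input contribution for every step in one product
  X_all <- do.call(rbind, lapply(slices, function(s) s[idx, , drop = FALSE]))
  Zx <- X_all %*% Wx
  bias <- rep(as.numeric(b), each = n)
  hs <- vector("list", t_len + 1)
  cs <- vector("list", t_len + 1)
  gates <- vector("list", t_len)
  hs[[1]] <- matrix(0, n, nh); cs[[1]] <- matrix(0, n, nh)
  for (t in seq_len(t_len)) {
    rows <- ((t - 1) * n + 1):(t * n)
    z <- Zx[rows, , drop = FALSE] + hs[[t]] %*% Wh + bias
    i <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, fi, drop = FALSE]))
    g <- tanh(z[, gi, drop = FALSE])
    o <- 1 / (1 + exp(-z[, oi, drop = FALSE]))
    cs[[t + 1]] <- f * cs[[t]] + i * g
    hs[[t + 1]] <- o * tanh(cs[[t + 1]])
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
  }
  zo <- hs[[t_len + 1]] %*% out$W$value + rep(as.numeric(out$b$value), each = n)
  loss <- sum(pmax(zo, 0) - zo * y + log1p(exp(-abs(zo)))) / n
  dz <- (1 / (1 + exp(-zo)) - y) / n
  out$W$grad <- out$W$grad + crossprod(hs[[t_len + 1]], dz)
  out$b$grad <- out$b$grad + colSums(dz)
  dh <- dz %*% t(out$W$value)
  dc <- matrix(0, n, nh)
  DZ <- matrix(0, t_len * n, 4 * nh)
  for (t in rev(seq_len(t_len))) {
    gt <- gates[[t]]
    tc <- tanh(cs[[t + 1]])
    dc <- dc + dh * gt$o * (1 - tc^2)
    dzg <- matrix(0, n, 4 * nh)
    dzg[, ii] <- (dc * gt$g) * gt$i * (1 - gt$i)
    dzg[, fi] <- (dc * cs[[t]]) * gt$f * (1 - gt$f)
    dzg[, gi] <- (dc * gt$i) * (1 - gt$g^2)
    dzg[, oi] <- (dh * tc) * gt$o * (1 - gt$o)
    DZ[((t - 1) * n + 1):(t * n), ] <- dzg
    cell$Wh$grad <- cell$Wh$grad + crossprod(hs[[t]], dzg)
    dh <- dzg %*% t(Wh)
    dc <- dc * gt$f
  }
  cell$Wx$grad <- cell$Wx$grad + crossprod(X_all, DZ)
  cell$b$grad <- cell$b$grad + colSums(DZ)
  loss
}

## Compiled variant of lstm_bce_pass (identical mathematics; both are held
## to the same finite-difference gradient checks).
lstm_bce_pass_fast <- function(cell, out, slices, idx, y) {
  X_all <- do.call(rbind, lapply(slices, function(s) s[idx, , drop = FALSE]))
  r <- .lstm_bce_pass_cpp(cell$Wx$value, cell$Wh$value, as.numeric(cell$b$value),
                          out$W$value, as.numeric(out$b$value), X_all, y,
                          length(slices))
  cell$Wx$grad <- cell$Wx$grad + r$dWx
  cell$Wh$grad <- cell$Wh$grad + r$dWh
  cell$b$grad <- cell$b$grad + r$db
  out$W$grad <- out$W$grad + r$dWo
  out$b$grad <- out$b$grad + r$dbo
  r$loss
}

## Fused forward + backward for the feed-forward classifier (ReLU hidden
## layers, sigmoid-cross-entropy output); same mathematics as the tape path.
dnn_bce_pass <- function(layers, x, y) {
  nl <- length(layers)
  n <- nrow(x)
  hs <- vector("list", nl + 1)
  hs[[1]] <- x
  for (l in seq_len(nl - 1)) {
    a <- hs[[l]] %*% layers[[l]]$W$value +
      rep(as.numeric(layers[[l]]$b$value), each = n)
    hs[[l + 1]] <- pmax(a, 0)
  }
  z <- hs[[nl]] %*% layers[[nl]]$W$value +
    rep(as.numeric(layers[[nl]]$b$value), each = n)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  d <- (1 / (1 + exp(-z)) - y) / n
  for (l in rev(seq_len(nl))) {
    layers[[l]]$W$grad <- layers[[l]]$W$grad + crossprod(hs[[l]], d)
    layers[[l]]$b$grad <- layers[[l]]$b$grad + colSums(d)
    if (l > 1) d <- (d %*% t(layers[[l]]$W$value)) * (hs[[l]] > 0)
  }
  loss
}

## Plain (no-gradient) forward pass returning sigmoid probabilities.
proximity_probs <- function(model, features) {
  if (model$arch == "dnn") {
    h <- features
    nl <- length(model$layers)
    for (i in seq_len(nl - 1))
      h <- pmax(h %*% model$layers[[i]]$W$value +
                  rep(model$layers[[i]]$b$value, each = nrow(h)), 0)
    z <- h %*% model$layers[[nl]]$W$value +
      rep(model$layers[[nl]]$b$value, each = nrow(h))
  } else {
    slices <- lstm_window_slices(features, model$cfg$t_lstm)
    nh <- model$cell$nh
    h <- matrix(0, nrow(features), nh)
    cc <- matrix(0, nrow(features), nh)
    for (t in seq_along(slices)) {
      zz <- slices[[t]] %*% model$cell$Wx$value + h %*% model$cell$Wh$value +
        rep(model$cell$b$value, each = nrow(h))
      i <- 1 / (1 + exp(-zz[, 1:nh, drop = FALSE]))
      f <- 1 / (1 + exp(-zz[, (nh + 1):(2 * nh), drop = FALSE]))
      g <- tanh(zz[, (2 * nh + 1):(3 * nh), drop = FALSE])
      o <- 1 / (1 + exp(-zz[, (3 * nh + 1):(4 * nh), drop = FALSE]))
      cc <- f * cc + i * g
      h <- o * tanh(cc)
    }
    z <- h %*% model$out$W$value + rep(model$out$b$value, each = nrow(h))
  }
  1 / (1 + exp(-z))
}

#' Predict proximity reports
#'
#' Thresholds the per-anchor sigmoid outputs: an anchor is reported
#' in-vicinity iff its output strictly exceeds the threshold (a tie at the
#' threshold classifies as out-of-vicinity).
#'
#' @param model A trained `proximity_model`.
#' @param features T x U matrix of scaled RSS features.
#' @return T x U binary matrix of predicted vicinity labels.
#' @export
predict_proximity <- function(model, features) {
  stopifnot(inherits(model, "proximity_model"), is.matrix(features))
  if (ncol(features) != model$u)
    stop("feature dimension ", ncol(features), " does not match the model (", model$u, ")")
  (proximity_probs(model, features) > model$cfg$threshold) * 1
}

#' Proximity, distance and overall accuracy
#'
#' Proximity accuracy: fraction of in-vicinity ground-truth entries
#' correctly reported in-vicinity. Distance accuracy: fraction of
#' out-of-vicinity entries correctly reported out. Overall accuracy:
#' fraction correct over all entries, which equals the label-weighted
#' combination of the first two. A metric with no supporting ground-truth
#' entries is reported as `NA`.
#'
#' @param pred,truth Aligned T x U binary matrices.
#' @return List with `proximity`, `distance`, `overall`, and the counts
#'   `n_pos`, `n_neg`.
#' @export
proximity_metrics <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.matrix(truth), all(dim(pred) == dim(truth)),
            all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  pos <- truth == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  prox <- if (n_pos > 0) mean(pred[pos] == 1) else NA_real_
  dist <- if (n_neg > 0) mean(pred[!pos] == 0) else NA_real_
  list(proximity = prox, distance = dist, overall = mean(pred == truth),
       n_pos = n_pos, n_neg = n_neg)
}

## ---- region-of-interest classification -----------------------------------

#' Windowed mean RSS features
#'
#' Averages an RSS trace within consecutive windows (default 0.5 s), the
#' preprocessing used by the region-of-interest classifier. Only complete
#' windows are kept.
#'
#' @param trace An `rss_trace` with `time_s`.
#' @param window_s Window length in seconds.
#' @return List with `features` (windows x U means), `window_index` (list of
#'   step indices per window) and `centers` (window centre times).
#' @export
window_mean_rss <- function(trace, window_s = 0.5) {
  stopifnot(inherits(trace, "rss_trace"), window_s > 0, !is.null(trace$time_s))
  dt <- stats::median(diff(trace$time_s))
  k <- max(1L, round(window_s / dt))
  n <- nrow(trace$rss)
  nwin <- floor(n / k)
  if (nwin == 0) stop("trace shorter than one window")
  idx <- lapply(seq_len(nwin), function(w) ((w - 1) * k + 1):(w * k))
  feats <- do.call(rbind, lapply(idx, function(i)
    colMeans(trace$rss[i, , drop = FALSE])))
  centers <- vapply(idx, function(i) mean(trace$time_s[i]), 1)
  list(features = feats, window_index = idx, centers = centers)
}

#' Label trajectory windows with their region of interest
#'
#' @param traj A `trajectory`.
#' @param regions Data frame with columns `name`, `xmin`, `xmax`, `ymin`,
#'   `ymax` defining axis-aligned regions.
#' @param window_index List of step indices per window (from
#'   [window_mean_rss()]); the label is taken at the window's middle step.
#'   A point outside every region is rejected.
#' @return Integer vector of region indices (into `regions`), one per window.
#' @export
label_regions <- function(traj, regions, window_index) {
  stopifnot(is.data.frame(regions),
            all(c("name", "xmin", "xmax", "ymin", "ymax") %in% names(regions)))
  mid <- vapply(window_index, function(i) i[ceiling(length(i) / 2)], 1L)
  pos <- traj$positions[mid, , drop = FALSE]
  vapply(seq_len(nrow(pos)), function(i) {
    hit <- which(pos[i, 1] >= regions$xmin & pos[i, 1] <= regions$xmax &
                 pos[i, 2] >= regions$ymin & pos[i, 2] <= regions$ymax)
    if (length(hit) == 0)
      stop(sprintf("position (%.2f, %.2f) lies outside every region", pos[i, 1], pos[i, 2]))
    hit[1]
  }, 1L)
}

#' Train the region-of-interest classifier
#'
#' A three-layer stacked LSTM over sliding windows of mean-RSS features with
#' a K-way softmax output; the predicted region is the argmax. Trained with
#' softmax cross entropy and SGD.
#'
#' @param features Windows x U matrix of mean RSS features (dBm or scaled).
#' @param labels Integer region index per window (1..K).
#' @param n_regions Number of regions K.
#' @param hidden Hidden sizes of the three LSTM layers.
#' @param t_lstm Memory in windows.
#' @param learning_rate,epochs,batch_size SGD parameters.
#' @param seed Integer seed.
#' @return A `roi_model` with per-epoch loss in `$loss`.
#' @export
train_roi_classifier <- function(features, labels, n_regions,
                                 hidden = c(16, 16, 16), t_lstm = 4,
                                 learning_rate = 0.1, epochs = 400,
                                 batch_size = 32, seed = 1) {
  stopifnot(is.matrix(features), length(labels) == nrow(features),
            all(labels %in% seq_len(n_regions)), length(hidden) == 3,
            batch_size >= 1)
  set.seed(seed)
  u <- ncol(features)
  cells <- list(nn_lstm(u, hidden[1]), nn_lstm(hidden[1], hidden[2]),
                nn_lstm(hidden[2], hidden[3]))
  out <- nn_dense(hidden[3], n_regions)
  params <- nn_params(list(cells, out))
  onehot <- diag(n_regions)[labels, , drop = FALSE]
  slices <- lstm_window_slices(features, t_lstm)
  n <- nrow(features)
  loss_hist <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    ord <- if (n > batch_size) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = batch_size)
    bl <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1, n)]
      tape <- ad_tape()
      states <- vector("list", 3)
      for (t in seq_along(slices)) {
        x <- ad_const(tape, slices[[t]][idx, , drop = FALSE])
        for (l in 1:3) {
          states[[l]] <- ad_lstm_step(tape, cells[[l]], x, states[[l]], length(idx))
          x <- states[[l]]$h
        }
      }
      z <- ad_dense(tape, out, states[[3]]$h)
      loss <- ad_softmax_xent(tape, z, onehot[idx, , drop = FALSE])
      if (!is.finite(loss$value)) stop("training diverged: non-finite loss at epoch ", epoch)
      ad_backward(tape, loss)
      opt_sgd_step(params, learning_rate)
      bl[bi] <- loss$value
    }
    loss_hist[epoch] <- mean(bl)
  }
  structure(list(cells = cells, out = out, t_lstm = t_lstm,
                 n_regions = n_regions, u = u, loss = loss_hist),
            class = "roi_model")
}

#' Classify windows into regions of interest
#'
#' @param model A trained `roi_model`.
#' @param features Windows x U matrix of mean RSS features.
#' @return Integer vector of predicted region indices (argmax of the
#'   softmax output).
#' @export
classify_roi <- function(model, features) {
  stopifnot(inherits(model, "roi_model"), is.matrix(features),
            ncol(features) == model$u)
  slices <- lstm_window_slices(features, model$t_lstm)
  hs <- lapply(model$cells, function(cell) matrix(0, nrow(features), cell$nh))
  cs <- hs
  for (t in seq_along(slices)) {
    x <- slices[[t]]
    for (l in 1:3) {
      cell <- model$cells[[l]]
      nh <- cell$nh
      zz <- x %*% cell$Wx$value + hs[[l]] %*% cell$Wh$value +
        rep(cell$b$value, each = nrow(x))
      i <- 1 / (1 + exp(-zz[, 1:nh, drop = FALSE]))
      f <- 1 / (1 + exp(-zz[, (nh + 1):(2 * nh), drop = FALSE]))
      g <- tanh(zz[, (2 * nh + 1):(3 * nh), drop = FALSE])
      o <- 1 / (1 + exp(-zz[, (3 * nh + 1):(4 * nh), drop = FALSE]))
      cs[[l]] <- f * cs[[l]] + i * g
      hs[[l]] <- o * tanh(cs[[l]])
      x <- hs[[l]]
    }
  }
  z <- hs[[3]] %*% model$out$W$value + rep(model$out$b$value, each = nrow(features))
  max.col(z, ties.method = "first")
}

#' Confusion matrix for region classification
#'
#' @param pred,truth Integer region indices.
#' @param n_regions Number of regions.
#' @return K x K matrix, rows = truth, columns = predicted.
#' @export
roi_confusion <- function(pred, truth, n_regions) {
  stopifnot(length(pred) == length(truth))
  m <- matrix(0L, n_regions, n_regions)
  for (i in seq_along(pred)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  dimnames(m) <- list(truth = seq_len(n_regions), predicted = seq_len(n_regions))
  m
}
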