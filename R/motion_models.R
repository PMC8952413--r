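## Windowing, feature standardization, and the four sequence architectures
## predicting 15-segment upper-body orientation from three sparse segments
## (pelvis, right forearm, left forearm).

MOTION_INPUT_SEGMENTS <- c("Pelvis", "RightForearm", "LeftForearm")

#' Motion model configuration
#'
#' Windowing is shared by all architectures: non-overlapping raw windows of
#' `seq_len_raw` frames (stride equal to the window), decimated by
#' `downsample`, so 30 raw frames at 240 Hz become 5 model frames at 40 Hz
#' (a 0.125 s motion snippet); input and output sequences have equal length
#' (in/out ratio 1). Architecture defaults: recurrent models use hidden
#' size 512; the transformer encoder uses 21 heads, 2 layers and
#' feed-forward width 200 (its width is the smallest multiple of 21 not
#' below 64, i.e. 84); the full transformer uses 4 heads, 4 layers,
#' feed-forward width 2048 and width 64. Optimization is AdamW with
#' learning rate 0.001; the transformers use momentum parameters beta1 =
#' 0.95 and beta2 = 0.99.
#'
#' @param architecture One of `"seq2seq"`, `"seq2seq_attn"`,
#'   `"transformer_enc"`, `"transformer_full"`.
#' @param batch_size Minibatch size.
#' @param seq_len_raw Raw window length in 240 Hz frames.
#' @param downsample Decimation factor applied inside each window.
#' @param stride Window stride in raw frames.
#' @param hidden Recurrent hidden size.
#' @param heads,n_layers,ff Transformer shape parameters (defaults depend
#'   on the architecture).
#' @param dropout Dropout probability during training.
#' @param epochs Training epochs.
#' @param learning_rate AdamW learning rate.
#' @param beta1,beta2 AdamW momentum parameters (architecture-dependent
#'   defaults).
#' @return A list of class `model_config`.
#' @export
model_config <- function(architecture = c("seq2seq", "seq2seq_attn",
                                          "transformer_enc", "transformer_full"),
                         batch_size = 32, seq_len_raw = 30, downsample = 6,
                         stride = 30, hidden = 512, heads = NULL,
                         n_layers = NULL, ff = NULL, dropout = 0.1,
                         epochs = 3, learning_rate = 0.001,
                         beta1 = NULL, beta2 = NULL) {
  architecture <- match.arg(architecture)
  if (architecture == "transformer_enc") {
    if (is.null(heads)) heads <- 21
    if (is.null(n_layers)) n_layers <- 2
    if (is.null(ff)) ff <- 200
  } else if (architecture == "transformer_full") {
    if (is.null(heads)) heads <- 4
    if (is.null(n_layers)) n_layers <- 4
    if (is.null(ff)) ff <- 2048
  }
  transformer <- grepl("transformer", architecture)
  if (is.null(beta1)) beta1 <- if (transformer) 0.95 else 0.9
  if (is.null(beta2)) beta2 <- if (transformer) 0.99 else 0.999
  stopifnot(batch_size >= 1, seq_len_raw >= 1, downsample >= 1,
            stride >= 1, hidden >= 1, dropout >= 0, dropout < 1,
            epochs >= 1, learning_rate > 0)
  d_model <- if (transformer) {
    m <- heads * ceiling(64 / heads)  # smallest multiple of heads >= 64
    m
  } else NA_integer_
  structure(list(architecture = architecture, batch_size = batch_size,
                 seq_len_raw = seq_len_raw, downsample = downsample,
                 stride = stride, hidden = hidden, heads = heads,
                 n_layers = n_layers, ff = ff, dropout = dropout,
                 epochs = epochs, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, d_model = d_model,
                 n_model_frames = length(seq(1, seq_len_raw, by = downsample))),
            class = "model_config")
}

#' Cut a normalized pose sequence into feature windows
#'
#' Takes non-overlapping windows of `cfg$seq_len_raw` frames, decimates each
#' by `cfg$downsample`, and extracts the input channels (pelvis and both
#' forearms: 4 quaternion + 3 acceleration values each, 21 per frame) and
#' the target channels (all 15 segment quaternions, 60 per frame).
#'
#' @param seq A pelvis-normalized `pose_sequence` at 240 Hz with
#'   accelerations for the input segments.
#' @param cfg A `model_config`.
#' @return List of windows, each `list(input = frames x 21, target =
#'   frames x 60)`; empty (with a warning) when the sequence is shorter
#'   than one window.
#' @export
build_windows <- function(seq, cfg = model_config()) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(cfg, "model_config"))
  if (seq$frame != "pelvis")
    stop("windows are built from pelvis-normalized sequences; normalize first")
  if (is.null(seq$acceleration)) stop("input windows need acceleration channels")
  miss <- setdiff(MOTION_INPUT_SEGMENTS, seq$segments)
  if (length(miss) > 0) stop("missing input segment(s): ", paste(miss, collapse = ", "))
  targets <- upper_body_segments()
  miss <- setdiff(targets, seq$segments)
  if (length(miss) > 0) stop("missing target segment(s): ", paste(miss, collapse = ", "))
  n <- n_frames(seq)
  if (n < cfg$seq_len_raw) {
    warning("sequence shorter than one window (", n, " < ", cfg$seq_len_raw, ")")
    return(list())
  }
  starts <- seq(1, n - cfg$seq_len_raw + 1, by = cfg$stride)
  pick <- seq(1, cfg$seq_len_raw, by = cfg$downsample)
  lapply(starts, function(s0) {
    idx <- s0 + pick - 1
    inp <- do.call(cbind, lapply(MOTION_INPUT_SEGMENTS, function(sg)
      cbind(matrix(seq$orientation[idx, sg, ], ncol = 4),
            matrix(seq$acceleration[idx, sg, ], ncol = 3))))
    tgt <- do.call(cbind, lapply(targets, function(sg)
      matrix(seq$orientation[idx, sg, ], ncol = 4)))
    list(input = inp, target = tgt)
  })
}

#' Fit / apply input-feature standardization
#'
#' Means and standard deviations are computed per flattened input column
#' (frame x channel) over the training windows only, then frozen for
#' validation and test data. A zero-variance column has its standard
#' deviation clamped to 1 with a warning. Targets (quaternion components)
#' are left on their natural scale.
#'
#' @param windows List of feature windows (from [build_windows()]).
#' @return `fit_standardization()`: list of class `standardization_stats`
#'   with `mean` and `sd` vectors. `apply_standardization()` /
#'   `invert_standardization()`: the windows with transformed inputs.
#' @export
fit_standardization <- function(windows) {
  stopifnot(length(windows) >= 1)
  ## rows = windows, cols = flattened (frame x channel) input features
  X <- do.call(rbind, lapply(windows, function(w) as.numeric(w$input)))
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (length(windows) == 1) sd <- rep(0, length(mu))
  zero <- sd < 1e-12 | !is.finite(sd)
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s); sd clamped to 1")
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "standardization_stats")
}

#' @rdname fit_standardization
#' @param stats A `standardization_stats`.
#' @export
apply_standardization <- function(windows, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  lapply(windows, function(w) {
    v <- (as.numeric(w$input) - stats$mean) / stats$sd
    w$input <- matrix(v, nrow(w$input), ncol(w$input))
    w
  })
}

#' @rdname fit_standardization
#' @export
invert_standardization <- function(windows, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  lapply(windows, function(w) {
    v <- as.numeric(w$input) * stats$sd + stats$mean
    w$input <- matrix(v, nrow(w$input), ncol(w$input))
    w
  })
}

## Stack windows into arrays: X [n, frames, 21], Y [n, frames, 60].
windows_to_arrays <- function(windows) {
  n <- length(windows)
  fr <- nrow(windows[[1]]$input)
  X <- array(0, c(n, fr, ncol(windows[[1]]$input)))
  Y <- array(0, c(n, fr, ncol(windows[[1]]$target)))
  for (i in seq_len(n)) {
    X[i, , ] <- windows[[i]]$input
    Y[i, , ] <- windows[[i]]$target
  }
  list(X = X, Y = Y)
}

## Sinusoidal positional encoding, frames x d.
positional_encoding <- function(frames, d) {
  pe <- matrix(0, frames, d)
  pos <- seq_len(frames) - 1
  for (k in seq_len(d)) {
    i <- (k - 1) %/% 2
    w <- pos / 10000^(2 * i / d)
    pe[, k] <- if (k %% 2 == 1) sin(w) else cos(w)
  }
  pe
}

## ---- model construction ---------------------------------------------------

new_motion_model <- function(cfg, n_in = 21, n_out = 60) {
  a <- cfg$architecture
  if (a == "seq2seq") {
    list(enc = nn_lstm(n_in, cfg$hidden),
         dec = nn_lstm(n_out, cfg$hidden),
         out = nn_dense(cfg$hidden, n_out))
  } else if (a == "seq2seq_attn") {
    h <- cfg$hidden
    list(enc_f = nn_lstm(n_in, h), enc_b = nn_lstm(n_in, h),
         dec = nn_lstm(2 * h + n_out, h),
         att_W1 = nn_init(2 * h, h), att_W2 = nn_init(h, h),
         att_b = nn_zeros(h), att_v = nn_init(h, 1),
         out = nn_dense(h, n_out))
  } else if (a == "transformer_enc") {
    d <- cfg$d_model
    list(embed = nn_dense(n_in, d),
         layers = lapply(seq_len(cfg$n_layers), function(i)
           new_transformer_layer(d, cfg$heads, cfg$ff, cross = FALSE)),
         ln_f = list(g = nn_ones(d), b = nn_zeros(d)),
         out = nn_dense(d, n_out))
  } else {
    d <- cfg$d_model
    list(embed = nn_dense(n_in, d), dec_embed = nn_dense(n_in, d),
         enc_layers = lapply(seq_len(cfg$n_layers), function(i)
           new_transformer_layer(d, cfg$heads, cfg$ff, cross = FALSE)),
         dec_layers = lapply(seq_len(cfg$n_layers), function(i)
           new_transformer_layer(d, cfg$heads, cfg$ff, cross = TRUE)),
         ln_enc = list(g = nn_ones(d), b = nn_zeros(d)),
         ln_f = list(g = nn_ones(d), b = nn_zeros(d)),
         out = nn_dense(d, n_out))
  }
}

## Residual-branch output projections start at zero (skip-style
## initialization): every block begins as the identity map, so optimization
## starts from the linear embed-to-head model and grows the blocks in.
new_attention <- function(d) {
  list(Wq = nn_init(d, d), Wk = nn_init(d, d), Wv = nn_init(d, d),
       Wo = nn_param(matrix(0, d, d)))
}

new_transformer_layer <- function(d, heads, ff, cross) {
  ff2 <- nn_dense(ff, d)
  ff2$W$value[] <- 0
  L <- list(self = new_attention(d),
            ln1 = list(g = nn_ones(d), b = nn_zeros(d)),
            ff1 = nn_dense(d, ff), ff2 = ff2,
            ln2 = list(g = nn_ones(d), b = nn_zeros(d)),
            d = d, heads = heads)
  if (cross) {
    L$cross <- new_attention(d)
    L$ln3 <- list(g = nn_ones(d), b = nn_zeros(d))
  }
  L
}

## ---- forward passes -------------------------------------------------------

ad_ln <- function(tape, ln, x) {
  ad_layernorm(tape, x, ad_leaf(tape, ln$g), ad_leaf(tape, ln$b))
}

## Multi-head attention over lists of per-position nodes (batch x d).
ad_mha <- function(tape, att, d, heads, xs, kvs = xs, causal = FALSE) {
  dk <- d %/% heads
  stopifnot(dk * heads == d)
  Q <- lapply(xs, function(x) ad_mm(tape, x, ad_leaf(tape, att$Wq)))
  K <- lapply(kvs, function(x) ad_mm(tape, x, ad_leaf(tape, att$Wk)))
  V <- lapply(kvs, function(x) ad_mm(tape, x, ad_leaf(tape, att$Wv)))
  head_cols <- lapply(seq_len(heads), function(h) ((h - 1) * dk + 1):(h * dk))
  Kh <- lapply(head_cols, function(cc) lapply(K, function(k) ad_slice_cols(tape, k, cc)))
  Vh <- lapply(head_cols, function(cc) lapply(V, function(v) ad_slice_cols(tape, v, cc)))
  lapply(seq_along(xs), function(i) {
    js <- if (causal) seq_len(min(i, length(kvs))) else seq_along(kvs)
    heads_out <- lapply(seq_len(heads), function(h) {
      qi <- ad_slice_cols(tape, Q[[i]], head_cols[[h]])
      ad_attend(tape, qi, Kh[[h]][js], Vh[[h]][js], 1 / sqrt(dk))
    })
    ad_mm(tape, ad_concat_cols(tape, heads_out), ad_leaf(tape, att$Wo))
  })
}

## One pre-norm transformer block over a list of position nodes.
ad_transformer_block <- function(tape, L, xs, enc_out = NULL, p, training) {
  a <- ad_mha(tape, L$self, L$d, L$heads,
              lapply(xs, function(x) ad_ln(tape, L$ln1, x)),
              causal = !is.null(L$cross))
  xs <- mapply(function(x, y) ad_add(tape, x, ad_dropout(tape, y, p, training)),
               xs, a, SIMPLIFY = FALSE)
  if (!is.null(L$cross)) {
    a <- ad_mha(tape, L$cross, L$d, L$heads,
                lapply(xs, function(x) ad_ln(tape, L$ln3, x)),
                kvs = enc_out)
    xs <- mapply(function(x, y) ad_add(tape, x, ad_dropout(tape, y, p, training)),
                 xs, a, SIMPLIFY = FALSE)
  }
  mapply(function(x) {
    f <- ad_dense(tape, L$ff2,
                  ad_relu(tape, ad_dense(tape, L$ff1, ad_ln(tape, L$ln2, x))))
    ad_add(tape, x, ad_dropout(tape, f, p, training))
  }, xs, SIMPLIFY = FALSE)
}

## Full forward pass: xs = list of per-frame input nodes (batch x 21).
## Returns list of per-frame output nodes (batch x 60).
forward_motion <- function(tape, model, cfg, xs, batch, training = FALSE) {
  p <- cfg$dropout
  a <- cfg$architecture
  fr <- length(xs)
  if (a == "seq2seq") {
    state <- NULL
    for (t in seq_len(fr)) state <- ad_lstm_step(tape, model$enc, xs[[t]], state, batch)
    dec_state <- state
    prev <- ad_const(tape, matrix(0, batch, 60))
    outs <- vector("list", fr)
    for (t in seq_len(fr)) {
      dec_state <- ad_lstm_step(tape, model$dec, prev, dec_state, batch)
      h <- ad_dropout(tape, dec_state$h, p, training)
      outs[[t]] <- ad_dense(tape, model$out, h)
      prev <- outs[[t]]
    }
    outs
  } else if (a == "seq2seq_attn") {
    fstate <- NULL; bstate <- NULL
    fh <- vector("list", fr); bh <- vector("list", fr)
    for (t in seq_len(fr)) {
      fstate <- ad_lstm_step(tape, model$enc_f, xs[[t]], fstate, batch)
      fh[[t]] <- fstate$h
    }
    for (t in rev(seq_len(fr))) {
      bstate <- ad_lstm_step(tape, model$enc_b, xs[[t]], bstate, batch)
      bh[[t]] <- bstate$h
    }
    enc_out <- mapply(function(f, b) ad_concat_cols(tape, list(f, b)),
                      fh, bh, SIMPLIFY = FALSE)
    keys <- lapply(enc_out, function(e)
      ad_mm(tape, e, ad_leaf(tape, model$att_W1)))
    dec_state <- fstate
    prev <- ad_const(tape, matrix(0, batch, 60))
    outs <- vector("list", fr)
    for (t in seq_len(fr)) {
      qry <- ad_add(tape, ad_mm(tape, dec_state$h, ad_leaf(tape, model$att_W2)),
                    ad_leaf(tape, model$att_b))
      scores <- lapply(keys, function(k)
        ad_mm(tape, ad_tanh(tape, ad_add(tape, k, qry)), ad_leaf(tape, model$att_v)))
      alpha <- ad_softmax_rows(tape, ad_concat_cols(tape, scores))
      ctx <- NULL
      for (j in seq_len(fr)) {
        term <- ad_colmul(tape, enc_out[[j]], ad_slice_cols(tape, alpha, j))
        ctx <- if (is.null(ctx)) term else ad_add(tape, ctx, term)
      }
      dec_in <- ad_concat_cols(tape, list(ctx, prev))
      dec_state <- ad_lstm_step(tape, model$dec, dec_in, dec_state, batch)
      h <- ad_dropout(tape, dec_state$h, p, training)
      outs[[t]] <- ad_dense(tape, model$out, h)
      prev <- outs[[t]]
    }
    outs
  } else if (a == "transformer_enc") {
    pe <- positional_encoding(fr, cfg$d_model)
    hs <- lapply(seq_len(fr), function(t) {
      e <- ad_dense(tape, model$embed, xs[[t]])
      b <- ad_const(tape, matrix(pe[t, ], 1))
      ad_dropout(tape, ad_add(tape, e, b), p, training)
    })
    for (L in model$layers) hs <- ad_transformer_block(tape, L, hs, p = p, training = training)
    lapply(hs, function(x) ad_dense(tape, model$out, ad_ln(tape, model$ln_f, x)))
  } else {
    pe <- positional_encoding(fr, cfg$d_model)
    emb <- function(layer) lapply(seq_len(fr), function(t) {
      e <- ad_dense(tape, layer, xs[[t]])
      ad_dropout(tape, ad_add(tape, e, ad_const(tape, matrix(pe[t, ], 1))),
                 p, training)
    })
    hs <- emb(model$embed)
    for (L in model$enc_layers) hs <- ad_transformer_block(tape, L, hs, p = p, training = training)
    enc_out <- lapply(hs, function(x) ad_ln(tape, model$ln_enc, x))
    ds <- emb(model$dec_embed)
    for (L in model$dec_layers)
      ds <- ad_transformer_block(tape, L, ds, enc_out = enc_out, p = p, training = training)
    lapply(ds, function(x) ad_dense(tape, model$out, ad_ln(tape, model$ln_f, x)))
  }
}

#' Train a motion-inference model
#'
#' Fits the selected architecture to feature windows by minimizing the mean
#' absolute error over raw quaternion components of all 15 target segments
#' (averaged over frames, segments and components), using AdamW. Input
#' standardization is fitted on the supplied windows and frozen inside the
#' model. Training is deterministic for a given seed.
#'
#' @param windows Training windows from [build_windows()] (unstandardized).
#' @param cfg A `model_config`.
#' @param seed Integer seed for initialization, batch order and dropout.
#' @param early_stop_loss Optional MAE value; training stops after the first
#'   epoch whose mean loss falls below it (the loss history is truncated
#'   accordingly).
#' @return A `motion_model` with `$loss` (per-epoch mean training MAE) and
#'   the frozen `$stats`.
#' @export
train_model <- function(windows, cfg = model_config(), seed = 1,
                        early_stop_loss = NULL) {
  stopifnot(inherits(cfg, "model_config"), length(windows) >= 1)
  set.seed(seed)
  stats <- fit_standardization(windows)
  std <- apply_standardization(windows, stats)
  arr <- windows_to_arrays(std)
  n <- dim(arr$X)[1]
  fr <- dim(arr$X)[2]
  model <- new_motion_model(cfg)
  ## data-dependent head initialization: the output bias starts at the mean
  ## target so initial predictions sit at the average pose rather than zero
  ybar <- colMeans(do.call(rbind, lapply(seq_len(fr), function(t)
    matrix(arr$Y[, t, ], n))))
  model$out$b$value[] <- ybar
  params <- nn_params(model)
  loss_hist <- numeric(cfg$epochs)
  step <- 0
  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (n > 1) sample.int(n) else 1L
    starts <- seq(1, n, by = cfg$batch_size)
    bl <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
      tape <- ad_tape()
      xs <- lapply(seq_len(fr), function(t)
        ad_const(tape, matrix(arr$X[idx, t, ], length(idx))))
      outs <- forward_motion(tape, model, cfg, xs, length(idx), training = TRUE)
      pred <- ad_concat_cols(tape, outs)
      target <- do.call(cbind, lapply(seq_len(fr), function(t)
        matrix(arr$Y[idx, t, ], length(idx))))
      loss <- ad_mae(tape, pred, target)
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss at epoch ", epoch)
      ad_backward(tape, loss)
      step <- step + 1
      opt_adamw_step(params, cfg$learning_rate, step,
                     beta1 = cfg$beta1, beta2 = cfg$beta2)
      bl[bi] <- loss$value
    }
    loss_hist[epoch] <- mean(bl)
    if (!is.null(early_stop_loss) && loss_hist[epoch] < early_stop_loss) {
      loss_hist <- loss_hist[seq_len(epoch)]
      break
    }
  }
  structure(list(net = model, cfg = cfg, stats = stats, loss = loss_hist),
            class = "motion_model")
}

#' Predict upper-body orientation sequences
#'
#' Standardizes the inputs with the model's frozen statistics, runs the
#' network, and renormalizes each predicted 4-vector to a unit quaternion.
#'
#' @param model A trained `motion_model`.
#' @param windows Feature windows (unstandardized, as from
#'   [build_windows()]).
#' @return Array `[window, frame, segment, 4]` of unit quaternions for the
#'   15 upper-body segments, with segment dimnames.
#' @export
predict_upper_body <- function(model, windows) {
  stopifnot(inherits(model, "motion_model"), length(windows) >= 1)
  fr0 <- model$cfg$n_model_frames
  bad <- vapply(windows, function(w)
    nrow(w$input) != fr0 || ncol(w$input) != 21, TRUE)
  if (any(bad)) stop("window shape mismatch: expected ", fr0, " x 21 inputs")
  std <- apply_standardization(windows, model$stats)
  arr <- windows_to_arrays(std)
  n <- dim(arr$X)[1]
  fr <- dim(arr$X)[2]
  tape <- ad_tape()
  xs <- lapply(seq_len(fr), function(t) ad_const(tape, matrix(arr$X[, t, ], n)))
  outs <- forward_motion(tape, model$net, model$cfg, xs, n, training = FALSE)
  segs <- upper_body_segments()
  pred <- array(0, c(n, fr, length(segs), 4),
                dimnames = list(NULL, NULL, segs, c("qw", "qx", "qy", "qz")))
  for (t in seq_len(fr)) {
    raw <- outs[[t]]$value
    for (si in seq_along(segs)) {
      q <- raw[, ((si - 1) * 4 + 1):(si * 4), drop = FALSE]
      nrm <- sqrt(rowSums(q^2))
      nrm[nrm < 1e-12] <- 1
      pred[, t, si, ] <- q / nrm
    }
  }
  pred
}

#' Ground-truth quaternions of windows as an array
#'
#' Companion to [predict_upper_body()]: reshapes window targets to
#' `[window, frame, segment, 4]` for evaluation.
#'
#' @param windows Feature windows.
#' @return Array of the same layout as [predict_upper_body()] output.
#' @export
window_targets <- function(windows) {
  arr <- windows_to_arrays(windows)
  n <- dim(arr$Y)[1]; fr <- dim(arr$Y)[2]
  segs <- upper_body_segments()
  out <- array(0, c(n, fr, length(segs), 4),
               dimnames = list(NULL, NULL, segs, c("qw", "qx", "qy", "qz")))
  for (si in seq_along(segs))
    out[, , si, ] <- arr$Y[, , ((si - 1) * 4 + 1):(si * 4)]
  out
}
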