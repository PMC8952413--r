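## Gradient correctness of the reverse-mode tape against central finite
## differences, on a composite network touching every op family used by the
## sequence models.

fd_check <- function(build_loss, params, eps = 1e-6, n_entries = 3, tol = 1e-5) {
  loss0 <- build_loss()
  grads <- lapply(params, function(p) p$grad)
  for (p in params) p$grad[] <- 0
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    k <- min(n_entries, length(p$value))
    for (j in seq_len(k)) {
      p$value[j] <- p$value[j] + eps
      lp <- as.numeric(build_loss()); for (q in params) q$grad[] <- 0
      p$value[j] <- p$value[j] - 2 * eps
      lm <- as.numeric(build_loss()); for (q in params) q$grad[] <- 0
      p$value[j] <- p$value[j] + eps
      expect_equal(grads[[pi]][j], (lp - lm) / (2 * eps), tolerance = tol)
    }
  }
  invisible(loss0)
}

test_that("dense + activations + losses backpropagate correctly", {
  set.seed(21)
  l1 <- rehabsense:::nn_dense(4, 6)
  l2 <- rehabsense:::nn_dense(6, 3)
  x <- matrix(stats::rnorm(20), 5, 4)
  y <- matrix(stats::rnorm(15), 5, 3)
  yb <- matrix(rbinom(15, 1, 0.5), 5, 3)
  params <- rehabsense:::nn_params(list(l1, l2))
  run_mae <- function() {
    tape <- rehabsense:::ad_tape()
    h <- rehabsense:::ad_relu(tape, rehabsense:::ad_dense(tape, l1, rehabsense:::ad_const(tape, x)))
    o <- rehabsense:::ad_dense(tape, l2, rehabsense:::ad_tanh(tape, h))
    loss <- rehabsense:::ad_mae(tape, o, y)
    rehabsense:::ad_backward(tape, loss)
    loss$value
  }
  fd_check(run_mae, params, tol = 1e-4)
  run_bce <- function() {
    tape <- rehabsense:::ad_tape()
    h <- rehabsense:::ad_sigmoid(tape, rehabsense:::ad_dense(tape, l1, rehabsense:::ad_const(tape, x)))
    o <- rehabsense:::ad_dense(tape, l2, h)
    loss <- rehabsense:::ad_bce_logits(tape, o, yb)
    rehabsense:::ad_backward(tape, loss)
    loss$value
  }
  fd_check(run_bce, params, tol = 1e-4)
})

test_that("layernorm, softmax attention and LSTM cell backpropagate correctly", {
  set.seed(22)
  d <- 6
  att <- rehabsense:::new_attention(d)
  att$Wo$value[] <- stats::rnorm(d * d, sd = 0.3)  # make all paths gradient-active
  ln <- list(g = rehabsense:::nn_ones(d), b = rehabsense:::nn_zeros(d))
  cell <- rehabsense:::nn_lstm(d, 5)
  out <- rehabsense:::nn_dense(5, 2)
  xs_v <- lapply(1:3, function(i) matrix(stats::rnorm(4 * d), 4, d))
  y <- matrix(stats::rnorm(8), 4, 2)
  params <- rehabsense:::nn_params(list(att, ln, cell, out))
  run <- function() {
    tape <- rehabsense:::ad_tape()
    xs <- lapply(xs_v, function(v) rehabsense:::ad_const(tape, v))
    xs <- lapply(xs, function(x) rehabsense:::ad_layernorm(
      tape, x, rehabsense:::ad_leaf(tape, ln$g), rehabsense:::ad_leaf(tape, ln$b)))
    hs <- rehabsense:::ad_mha(tape, att, d, 2, xs)
    state <- NULL
    for (t in 1:3) state <- rehabsense:::ad_lstm_step(tape, cell, hs[[t]], state, 4)
    o <- rehabsense:::ad_dense(tape, out, state$h)
    loss <- rehabsense:::ad_mae(tape, o, y)
    rehabsense:::ad_backward(tape, loss)
    loss$value
  }
  fd_check(run, params, tol = 1e-4)
})

test_that("fused proximity LSTM pass matches numerical gradients", {
  set.seed(23)
  n <- 6; u <- 3; nh <- 4
  feats <- matrix(stats::runif(15 * u), 15, u)
  y <- matrix(rbinom(n * u, 1, 0.4), n, u)
  slices <- rehabsense:::lstm_window_slices(feats, 4)
  idx <- 3:8
  cell <- rehabsense:::nn_lstm(u, nh)
  out <- rehabsense:::nn_dense(nh, u)
  params <- rehabsense:::nn_params(list(cell, out))
  run <- function() {
    v <- rehabsense:::lstm_bce_pass(cell, out, slices, idx, y)
    v
  }
  l0 <- run()
  grads <- lapply(params, function(p) p$grad)
  for (p in params) p$grad[] <- 0
  eps <- 1e-6
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    for (j in seq_len(min(3, length(p$value)))) {
      p$value[j] <- p$value[j] + eps
      lp <- run(); for (q in params) q$grad[] <- 0
      p$value[j] <- p$value[j] - 2 * eps
      lm <- run(); for (q in params) q$grad[] <- 0
      p$value[j] <- p$value[j] + eps
      expect_equal(grads[[pi]][j], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("optimizer steps move parameters and reset gradients", {
  p <- rehabsense:::nn_param(matrix(1, 2, 2))
  p$grad[] <- 0.5
  rehabsense:::opt_sgd_step(list(p), lr = 0.1)
  expect_equal(p$value, matrix(0.95, 2, 2))
  expect_equal(p$grad, matrix(0, 2, 2))
  p$grad[] <- 0.5
  rehabsense:::opt_adamw_step(list(p), lr = 0.1, step = 1, weight_decay = 0)
  expect_true(all(p$value < 0.95))
  expect_equal(p$grad, matrix(0, 2, 2))
})
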