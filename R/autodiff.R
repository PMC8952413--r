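## Minimal reverse-mode automatic differentiation on matrices.
##
## A tape records nodes in creation order; ad_backward() walks it in reverse,
## accumulating gradients. Values are plain numeric matrices. This is the
## computational core under every neural model in the package; gradients are
## verified against central finite differences in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$last <- NULL
  class(e) <- "ad_tape"
  e
}

## Nodes form a linked chain in creation order (no growing list, so node
## creation stays O(1)).
ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$prev <- tape$last
  tape$last <- nd
  nd
}

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

## Constant leaf (no gradient flows out).
ad_const <- function(tape, value) ad_node(tape, value)

## Parameter leaf: after backward, the gradient is added into param$grad.
ad_leaf <- function(tape, param) {
  nd <- ad_node(tape, param$value)
  nd$backward <- function(g) param$grad <- param$grad + g
  nd
}

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  nd <- tape$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

## ---- elementary ops ------------------------------------------------------

ad_mm <- function(tape, a, b) {
  nd <- ad_node(tape, a$value %*% b$value)
  nd$backward <- function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, crossprod(a$value, g))
  }
  nd
}

## Matrix plus matrix (same shape) or matrix plus bias row (length ncol).
ad_add <- function(tape, a, b) {
  bias <- !is.matrix(b$value) || nrow(b$value) == 1
  av <- a$value
  bv <- if (bias) rep(as.numeric(b$value), each = nrow(av)) else b$value
  nd <- ad_node(tape, av + bv)
  nd$backward <- function(g) {
    ad_accum(a, g)
    if (bias) {
      gb <- colSums(g)
      if (is.matrix(b$value)) gb <- matrix(gb, nrow = 1)
      ad_accum(b, gb)
    } else ad_accum(b, g)
  }
  nd
}

ad_sub <- function(tape, a, b) {
  nd <- ad_node(tape, a$value - b$value)
  nd$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  }
  nd
}

ad_mul <- function(tape, a, b) {
  nd <- ad_node(tape, a$value * b$value)
  nd$backward <- function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  }
  nd
}

ad_scale <- function(tape, a, k) {
  nd <- ad_node(tape, a$value * k)
  nd$backward <- function(g) ad_accum(a, g * k)
  nd
}

## Elementwise product with a fixed (non-differentiated) mask or matrix.
ad_mul_const <- function(tape, a, m) {
  nd <- ad_node(tape, a$value * m)
  nd$backward <- function(g) ad_accum(a, g * m)
  nd
}

## Scale rows of a by a column vector node c (n x 1).
ad_colmul <- function(tape, a, cn) {
  cv <- as.vector(cn$value)
  nd <- ad_node(tape, a$value * cv)
  nd$backward <- function(g) {
    ad_accum(a, g * cv)
    ad_accum(cn, matrix(rowSums(g * a$value), ncol = 1))
  }
  nd
}

## Row-wise dot product -> n x 1.
ad_rowdot <- function(tape, a, b) {
  nd <- ad_node(tape, matrix(rowSums(a$value * b$value), ncol = 1))
  nd$backward <- function(g) {
    gv <- as.vector(g)
    ad_accum(a, b$value * gv)
    ad_accum(b, a$value * gv)
  }
  nd
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  nd <- ad_node(tape, v)
  nd$backward <- function(g) ad_accum(a, g * (1 - v^2))
  nd
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  nd <- ad_node(tape, v)
  nd$backward <- function(g) ad_accum(a, g * v * (1 - v))
  nd
}

ad_relu <- function(tape, a) {
  v <- pmax(a$value, 0)
  nd <- ad_node(tape, v)
  nd$backward <- function(g) ad_accum(a, g * (a$value > 0))
  nd
}

ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  v <- e / rowSums(e)
  nd <- ad_node(tape, v)
  nd$backward <- function(g) ad_accum(a, (g - rowSums(g * v)) * v)
  nd
}

ad_concat_cols <- function(tape, nodes) {
  vals <- lapply(nodes, function(x) x$value)
  widths <- vapply(vals, ncol, 1L)
  nd <- ad_node(tape, do.call(cbind, vals))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  nd$backward <- function(g) {
    for (i in seq_along(nodes))
      ad_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  }
  nd
}

ad_slice_cols <- function(tape, a, idx) {
  nd <- ad_node(tape, a$value[, idx, drop = FALSE])
  nd$backward <- function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[, idx] <- g
    ad_accum(a, ga)
  }
  nd
}

## Row-wise layer normalization with learnable gain and bias (1 x k params).
ad_layernorm <- function(tape, a, gain, bias, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- rep(as.numeric(gain$value), each = nrow(x))
  nd <- ad_node(tape, xhat * gv + rep(as.numeric(bias$value), each = nrow(x)))
  nd$backward <- function(g) {
    ad_accum(gain, matrix(colSums(g * xhat), nrow = 1))
    ad_accum(bias, matrix(colSums(g), nrow = 1))
    gx <- g * gv
    k <- ncol(x)
    ## d xhat / d x for row-wise normalization
    ga <- inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    ad_accum(a, ga)
  }
  nd
}

## Fused scaled-dot-product attention for one query position and one head:
## alpha = softmax_j(scale * <q, K_j>), output = sum_j alpha_j V_j.
## One tape node replaces the score/softmax/weighted-sum subgraph.
ad_attend <- function(tape, q, Ks, Vs, scale) {
  qv <- q$value
  tl <- length(Ks)
  S <- matrix(0, nrow(qv), tl)
  for (j in seq_len(tl)) S[, j] <- rowSums(qv * Ks[[j]]$value) * scale
  S <- S - apply(S, 1, max)
  A <- exp(S)
  A <- A / rowSums(A)
  ctx <- A[, 1] * Vs[[1]]$value
  if (tl > 1) for (j in 2:tl) ctx <- ctx + A[, j] * Vs[[j]]$value
  nd <- ad_node(tape, ctx)
  nd$backward <- function(g) {
    dA <- matrix(0, nrow(qv), tl)
    for (j in seq_len(tl)) {
      dA[, j] <- rowSums(g * Vs[[j]]$value)
      ad_accum(Vs[[j]], A[, j] * g)
    }
    dS <- (dA - rowSums(dA * A)) * A
    dq <- dS[, 1] * Ks[[1]]$value
    ad_accum(Ks[[1]], (dS[, 1] * scale) * qv)
    if (tl > 1) for (j in 2:tl) {
      dq <- dq + dS[, j] * Ks[[j]]$value
      ad_accum(Ks[[j]], (dS[, j] * scale) * qv)
    }
    ad_accum(q, dq * scale)
  }
  nd
}

## ---- losses --------------------------------------------------------------

## Mean absolute error against a constant target matrix.
ad_mae <- function(tape, a, target) {
  d <- a$value - target
  nd <- ad_node(tape, matrix(mean(abs(d)), 1, 1))
  nd$backward <- function(g) ad_accum(a, sign(d) * (as.numeric(g) / length(d)))
  nd
}

## Numerically stable binary cross entropy on logits z with labels y,
## summed over outputs and averaged over rows (samples).
ad_bce_logits <- function(tape, z, y) {
  zv <- z$value
  v <- sum(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv)))) / nrow(zv)
  nd <- ad_node(tape, matrix(v, 1, 1))
  nd$backward <- function(g) {
    p <- 1 / (1 + exp(-zv))
    ad_accum(z, (p - y) * (as.numeric(g) / nrow(zv)))
  }
  nd
}

## Mean softmax cross entropy on logits z with one-hot labels y (n x K).
ad_softmax_xent <- function(tape, z, y) {
  zv <- z$value - apply(z$value, 1, max)
  e <- exp(zv)
  p <- e / rowSums(e)
  v <- -mean(rowSums(y * (zv - log(rowSums(e)))))
  nd <- ad_node(tape, matrix(v, 1, 1))
  nd$backward <- function(g) ad_accum(z, (p - y) * (as.numeric(g) / nrow(zv)))
  nd
}

## ---- parameters and optimizers -------------------------------------------

nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- as.matrix(value)
  p$grad <- p$value * 0
  p$m <- p$value * 0
  p$v <- p$value * 0
  p
}

## Glorot-uniform initial weights.
nn_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  nn_param(matrix(stats::runif(nin * nout, -lim, lim), nin, nout))
}

nn_zeros <- function(n) nn_param(matrix(0, 1, n))
nn_ones <- function(n) nn_param(matrix(1, 1, n))

## Collect every nn_param inside a (nested) list of layers.
nn_params <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, nn_params), recursive = FALSE))
  list()
}

opt_sgd_step <- function(params, lr) {
  for (p in params) {
    p$value <- p$value - lr * p$grad
    p$grad[] <- 0
  }
}

opt_adamw_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0.01) {
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^step)
    vhat <- p$v / (1 - beta2^step)
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
    p$grad[] <- 0
  }
}

## ---- shared layer helpers -------------------------------------------------

## Dense layer parameters.
nn_dense <- function(nin, nout) list(W = nn_init(nin, nout), b = nn_zeros(nout))

ad_dense <- function(tape, layer, x) {
  ad_add(tape, ad_mm(tape, x, ad_leaf(tape, layer$W)), ad_leaf(tape, layer$b))
}

## LSTM cell parameters; gates ordered [i, f, g, o] in one weight block.
## The forget-gate bias starts at 1 (standard initialization easing
## gradient flow through time).
nn_lstm <- function(nin, nh) {
  b <- nn_zeros(4 * nh)
  b$value[1, (nh + 1):(2 * nh)] <- 1
  list(Wx = nn_init(nin, 4 * nh), Wh = nn_init(nh, 4 * nh), b = b, nh = nh)
}

## One LSTM step. state is list(h, c) of tape nodes (batch x nh) or NULL.
ad_lstm_step <- function(tape, cell, x, state, batch) {
  nh <- cell$nh
  if (is.null(state)) {
    zero <- ad_const(tape, matrix(0, batch, nh))
    state <- list(h = zero, c = zero)
  }
  z <- ad_add(tape,
              ad_add(tape, ad_mm(tape, x, ad_leaf(tape, cell$Wx)),
                     ad_mm(tape, state$h, ad_leaf(tape, cell$Wh))),
              ad_leaf(tape, cell$b))
  i <- ad_sigmoid(tape, ad_slice_cols(tape, z, 1:nh))
  f <- ad_sigmoid(tape, ad_slice_cols(tape, z, (nh + 1):(2 * nh)))
  g <- ad_tanh(tape, ad_slice_cols(tape, z, (2 * nh + 1):(3 * nh)))
  o <- ad_sigmoid(tape, ad_slice_cols(tape, z, (3 * nh + 1):(4 * nh)))
  c_new <- ad_add(tape, ad_mul(tape, f, state$c), ad_mul(tape, i, g))
  h_new <- ad_mul(tape, o, ad_tanh(tape, c_new))
  list(h = h_new, c = c_new)
}

## Dropout mask application (training only); mask drawn by the caller's RNG.
ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= p) / (1 - p)
  ad_mul_const(tape, x, mask)
}
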