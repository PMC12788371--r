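# Minimal dense/conv/recurrent neural-network engine.
#
# The encoder-decoder CoP regressors are trained with plain
# double-precision matrix arithmetic (BLAS-backed), full analytic
# backpropagation, Adam, and a step-decay learning-rate schedule. The
# engine is deliberately small: exactly the primitives the CoP
# architectures need (strided 2D convolution via im2col, identity-shortcut
# residual blocks, LSTM / bidirectional LSTM over windows, fully connected
# layers). Gradients are verified against numerical differentiation in the
# test suite.

# ---- convolution plans -----------------------------------------------------

# Precompute im2col index maps for a fixed input geometry.
#
# Activations through the conv stack are stored TRANSPOSED and
# channel-fastest: a matrix (features x N) whose feature layout is
# column-major over (c, h, w). With that layout both the im2col gather and
# the output reshape are plain dim reinterpretations (no aperm/copies):
# gathering rows (K x P) of the padded input gives a (K, P*N) matrix whose
# product with the (K x cout) weights yields (cout, P*N) = the next layer's
# (c, h, w)-fastest feature matrix after a zero-copy dim change.
make_conv_plan <- function(in_h, in_w, cin, kh, kw, cout, stride, pad) {
  Hp <- in_h + 2L * pad; Wp <- in_w + 2L * pad
  out_h <- (Hp - kh) %/% stride + 1L
  out_w <- (Wp - kw) %/% stride + 1L
  K <- kh * kw * cin; P <- out_h * out_w
  # patch indices point straight into the unpadded input; 0 marks padding
  idx <- matrix(0L, K, P)
  for (ow in seq_len(out_w)) for (oh in seq_len(out_h)) {
    p <- oh + (ow - 1L) * out_h
    h0 <- (oh - 1L) * stride - pad; w0 <- (ow - 1L) * stride - pad
    k <- 0L
    for (kwi in seq_len(kw)) for (khi in seq_len(kh)) for (c in seq_len(cin)) {
      k <- k + 1L
      h <- h0 + khi; w <- w0 + kwi
      idx[k, p] <- if (h >= 1L && h <= in_h && w >= 1L && w <= in_w)
        c + (h - 1L) * cin + (w - 1L) * cin * in_h else 0L
    }
  }
  # weight rows follow the same (c, kh, kw) order as k
  list(in_h = in_h, in_w = in_w, cin = cin, kh = kh, kw = kw, cout = cout,
       stride = stride, pad = pad, out_h = out_h, out_w = out_w,
       K = K, P = P, idx = idx, in_len = in_h * in_w * cin,
       out_len = P * cout)
}

# X: (in_len x N) channel-fastest feature matrix
conv_fwd <- function(X, W, b, plan) {
  N <- ncol(X)
  M <- cpp_im2col(X, plan$idx)        # (K, P*N)
  Y <- crossprod(W, M) + b            # b recycles over rows (cout fastest)
  dim(Y) <- c(plan$out_len, N)
  list(Y = Y, M = M)
}

conv_bwd <- function(dY, M, W, plan, N) {
  dim(dY) <- c(plan$cout, plan$P * N)
  dW <- tcrossprod(M, dY)
  db <- rowSums(dY)
  dM <- W %*% dY                      # K x (P*N)
  dX <- cpp_col2im(dM, plan$idx, plan$in_len, N)
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}
relu_bwd <- function(dY, mask) dY * mask

fc_fwd <- function(X, W, b) sweep(X %*% W, 2L, b, `+`)
fc_bwd <- function(dY, X, W) list(dX = tcrossprod(dY, W),
                                  dW = crossprod(X, dY), db = colSums(dY))

# ---- LSTM ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Xm: (B*Tw) x Din with row order t-within-b. Returns hidden sequence in the
# same row order, plus caches for backprop.
lstm_fwd <- function(Xm, Wx, Wh, b, B, Tw, reverse = FALSE) {
  H <- ncol(Wh)
  Hn <- H %/% 4L
  stopifnot(ncol(Wx) == H)
  h <- matrix(0, B, Hn); cc <- matrix(0, B, Hn)
  out <- matrix(0, nrow(Xm), Hn)
  steps <- if (reverse) rev(seq_len(Tw)) else seq_len(Tw)
  cache <- vector("list", Tw)
  XW <- sweep(Xm %*% Wx, 2L, b, `+`)  # input contribution for all steps at once
  for (t in steps) {
    rows <- (seq_len(B) - 1L) * Tw + t
    Z <- XW[rows, , drop = FALSE] + h %*% Wh
    i <- sigmoid(Z[, 1:Hn, drop = FALSE])
    f <- sigmoid(Z[, (Hn + 1):(2 * Hn), drop = FALSE])
    g <- tanh(Z[, (2 * Hn + 1):(3 * Hn), drop = FALSE])
    o <- sigmoid(Z[, (3 * Hn + 1):(4 * Hn), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_new <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                       h_prev = h)
    h <- h_new
    out[rows, ] <- h
  }
  list(Y = out, cache = cache)
}

lstm_bwd <- function(dOut, Xm, Wx, Wh, b, B, Tw, cache, reverse = FALSE) {
  H4 <- ncol(Wx); Hn <- H4 %/% 4L
  dXm <- matrix(0, nrow(Xm), ncol(Xm))
  dWx <- matrix(0, nrow(Wx), H4); dWh <- matrix(0, Hn, H4); db <- numeric(H4)
  dh_next <- matrix(0, B, Hn); dc_next <- matrix(0, B, Hn)
  steps <- if (reverse) seq_len(Tw) else rev(seq_len(Tw))
  dZall <- matrix(0, nrow(Xm), H4)
  for (t in steps) {
    rows <- (seq_len(B) - 1L) * Tw + t
    cc_ <- cache[[t]]
    dh <- dOut[rows, , drop = FALSE] + dh_next
    dc <- dc_next + dh * cc_$o * (1 - cc_$tc^2)
    di <- dc * cc_$g * cc_$i * (1 - cc_$i)
    df <- dc * cc_$c_prev * cc_$f * (1 - cc_$f)
    dg <- dc * cc_$i * (1 - cc_$g^2)
    do_ <- dh * cc_$tc * cc_$o * (1 - cc_$o)
    dZ <- cbind(di, df, dg, do_)
    dZall[rows, ] <- dZ
    dWh <- dWh + crossprod(cc_$h_prev, dZ)
    dh_next <- tcrossprod(dZ, Wh)
    dc_next <- dc * cc_$f
  }
  dWx <- crossprod(Xm, dZall)
  db <- colSums(dZall)
  dXm <- tcrossprod(dZall, Wx)
  list(dX = dXm, dWx = dWx, dWh = dWh, db = db)
}

# ---- parameter initialisation ---------------------------------------------

he_init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

init_lstm_params <- function(prefix, din, hn, params) {
  s <- 1 / sqrt(hn)
  params[[paste0(prefix, "_Wx")]] <- matrix(stats::runif(din * 4 * hn, -s, s), din, 4 * hn)
  params[[paste0(prefix, "_Wh")]] <- matrix(stats::runif(hn * 4 * hn, -s, s), hn, 4 * hn)
  b <- numeric(4 * hn); b[(hn + 1):(2 * hn)] <- 1  # forget-gate bias
  params[[paste0(prefix, "_b")]] <- b
  params
}
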