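# Minimal dense/convolutional network primitives with explicit backward
# passes. Parameters live in a flat named list of arrays so the optimizer,
# checkpoints and parameter counting stay trivial. Convolutions are
# evaluated in compiled code (src/conv.cpp); everything else is BLAS-backed
# matrix algebra.

.relu <- function(x) pmax(x, 0)
.relu_bwd <- function(dz, z) dz * (z > 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# d/dz of softmax(z) applied to upstream grad ds (both K x N)
.softmax_bwd <- function(ds, s) {
  dot <- colSums(ds * s)
  s * sweep(ds, 2, dot, "-")
}

.init_linear <- function(n_in, n_out) {
  list(w = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

.init_conv <- function(k, c_in, c_out) {
  list(w = array(rnorm(k * k * c_in * c_out, sd = sqrt(2 / (k * k * c_in))),
                 c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

.linear_fwd <- function(x, w, b) w %*% x + b  # x: in x N, recycled bias by col
.linear_bwd <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

# conv2d as im2col + BLAS GEMM; x: (H, W, Cin, N), w: (k, k, Cin, Cout)
.conv2d_forward <- function(x, w, b, stride, pad) {
  wd <- dim(w)
  xd <- dim(x)
  k <- wd[1]
  ho <- (xd[1] + 2 * pad - k) %/% stride + 1
  wo <- (xd[2] + 2 * pad - k) %/% stride + 1
  cols <- .im2col(x, k, stride, pad)
  wm <- matrix(w, k * k * wd[3], wd[4])
  out <- crossprod(wm, cols) + b          # Cout x (Ho*Wo*N)
  aperm(array(out, c(wd[4], ho, wo, xd[4])), c(2, 3, 1, 4))
}

.conv2d_backward <- function(x, w, gout, stride, pad) {
  wd <- dim(w)
  xd <- dim(x)
  gd <- dim(gout)
  k <- wd[1]
  gm <- matrix(aperm(gout, c(3, 1, 2, 4)), wd[4])  # Cout x (Ho*Wo*N)
  cols <- .im2col(x, k, stride, pad)
  gw <- array(tcrossprod(cols, gm), wd)            # rows x Cout
  wm <- matrix(w, k * k * wd[3], wd[4])
  dcols <- wm %*% gm                               # rows x (Ho*Wo*N)
  gx <- .col2im(dcols, as.integer(xd), k, stride, pad)
  list(gx = gx, gw = gw, gb = rowSums(gm))
}

# global average pool over the two spatial dims of (H, W, C, N)
.gap_fwd <- function(a) {
  d <- dim(a)
  matrix(colMeans(matrix(a, d[1] * d[2], d[3] * d[4])), d[3], d[4])  # C x N
}
.gap_bwd <- function(dg, d) {
  scale <- 1 / (d[1] * d[2])
  array(rep(as.vector(dg), each = d[1] * d[2]) * scale, d)
}

# ---- Adam ----

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
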