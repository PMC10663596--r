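# Minimal 3D convolutional network engine. Volumes are column-major R
# arrays (X, Y, Z, C). Convolutions are evaluated as gather (im2col) +
# matrix product against BLAS; transposed convolutions are the exact
# adjoint (scatter of the same geometry), so one index table serves both.
# Backward passes are analytic and are verified against finite differences
# in the test suite.

# Precompute gather geometry for a convolution in_shape -> out_shape.
# idx[n_pos, K] indexes the zero-padded input (flat, channel-last), with
# K = k^3 * in_ch patch elements per output position.
conv_geom <- function(in_shape, in_ch, k, stride, pad) {
  in_shape <- as.integer(in_shape)
  pd <- in_shape + 2L * pad
  out <- (pd - k) %/% stride + 1L
  pos <- as.matrix(expand.grid(x = seq_len(out[1]), y = seq_len(out[2]),
                               z = seq_len(out[3])))
  base <- (pos - 1L) * stride + 1L
  off <- as.matrix(expand.grid(kx = 0:(k - 1), ky = 0:(k - 1),
                               kz = 0:(k - 1), c = seq_len(in_ch)))
  ix <- outer(base[, 1], off[, 1], `+`)
  iy <- outer(base[, 2], off[, 2], `+`)
  iz <- outer(base[, 3], off[, 3], `+`)
  ic <- matrix(off[, 4], nrow(pos), nrow(off), byrow = TRUE)
  idx <- ix + (iy - 1L) * pd[1] + (iz - 1L) * pd[1] * pd[2] +
    (ic - 1L) * pd[1] * pd[2] * pd[3]
  storage.mode(idx) <- "integer"
  list(in_shape = in_shape, pd = pd, out_shape = out, in_ch = as.integer(in_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       idx = idx, n_pos = nrow(pos), K = nrow(off))
}

pad_array <- function(x, geom) {
  if (geom$pad == 0L) return(as.vector(x))
  ch <- length(x) / prod(geom$in_shape)
  xp <- array(0, c(geom$pd, ch))
  p <- geom$pad
  xp[p + seq_len(geom$in_shape[1]), p + seq_len(geom$in_shape[2]),
     p + seq_len(geom$in_shape[3]), ] <- x
  as.vector(xp)
}

unpad_array <- function(xp_flat, geom, ch) {
  if (geom$pad == 0L) return(array(xp_flat, c(geom$in_shape, ch)))
  xp <- array(xp_flat, c(geom$pd, ch))
  p <- geom$pad
  xp[p + seq_len(geom$in_shape[1]), p + seq_len(geom$in_shape[2]),
     p + seq_len(geom$in_shape[3]), , drop = FALSE]
}

gather_cols <- function(x_pad_flat, geom) {
  matrix(x_pad_flat[geom$idx], geom$n_pos, geom$K)
}

# Adjoint of gather: accumulate patch-element values back onto the padded
# grid. For a fixed patch element the map position -> input voxel is
# injective, so a per-column vector update is exact.
scatter_add <- function(vals, geom) {
  acc <- numeric(prod(geom$pd) * geom$in_ch)
  idx <- geom$idx
  for (j in seq_len(geom$K)) {
    ij <- idx[, j]
    acc[ij] <- acc[ij] + vals[, j]
  }
  acc
}

# --- conv layer: W is (K x out_ch), b length out_ch ------------------------
conv_fwd <- function(x, W, b, geom) {
  cols <- gather_cols(pad_array(x, geom), geom)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = array(y, c(geom$out_shape, ncol(W))), cols = cols)
}

conv_bwd <- function(dy, cols, W, geom) {
  out_ch <- ncol(W)
  dY <- matrix(dy, geom$n_pos, out_ch)
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dx_pad <- scatter_add(tcrossprod(dY, W), geom)
  list(dx = array(unpad_array(dx_pad, geom, geom$in_ch),
                  c(geom$in_shape, geom$in_ch)),
       dW = dW, db = db)
}

# --- transposed conv: maps geom$out_shape -> geom$in_shape -----------------
# Weight W is (K x in_ch) where K = k^3 * out_ch of the *output* (big) side;
# geometry is the conv geometry of the corresponding downsampling conv.
convt_fwd <- function(x, W, b, geom) {
  in_ch <- ncol(W)
  X <- matrix(x, geom$n_pos, in_ch)
  y_pad <- scatter_add(tcrossprod(X, W), geom)
  y <- array(unpad_array(y_pad, geom, geom$in_ch), c(geom$in_shape, geom$in_ch))
  y <- sweep(y, 4, b, `+`)
  list(y = y, X = X)
}

convt_bwd <- function(dy, X, W, geom) {
  cols_dy <- gather_cols(pad_array(dy, geom), geom)
  list(dx = array(cols_dy %*% W, c(geom$out_shape, ncol(W))),
       dW = crossprod(cols_dy, X),
       db = colSums(matrix(dy, prod(geom$in_shape), geom$in_ch)))
}

# --- instance normalization (per channel over space, no affine) ------------
inorm_fwd <- function(x, eps = 1e-5) {
  d <- dim(x)
  nv <- prod(d[1:3])
  X <- matrix(x, nv, d[4])
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, m, `-`), 2, istd, `*`)
  list(y = array(xhat, d), xhat = xhat, istd = istd)
}

inorm_bwd <- function(dy, xhat, istd) {
  d <- dim(dy)
  nv <- prod(d[1:3])
  dY <- matrix(dy, nv, d[4])
  mg <- colMeans(dY)
  mgx <- colMeans(dY * xhat)
  dX <- sweep(sweep(dY, 2, mg, `-`) - sweep(xhat, 2, mgx, `*`),
              2, istd, `*`)
  array(dX, d)
}

# --- activations -----------------------------------------------------------
lrelu_fwd <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
lrelu_bwd <- function(dy, x, slope = 0.01) {
  neg <- x < 0
  dy[neg] <- slope * dy[neg]
  dy
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# --- dense layer -----------------------------------------------------------
dense_fwd <- function(x, W, b) as.vector(x %*% W) + b
dense_bwd <- function(dy, x, W) {
  list(dx = as.vector(W %*% dy), dW = outer(x, dy), db = dy)
}

# --- parameter initialization ---------------------------------------------
he_init <- function(nrow_, ncol_, fan_in) {
  matrix(rnorm(nrow_ * ncol_, 0, sqrt(2 / fan_in)), nrow_, ncol_)
}

# --- Adam optimizer --------------------------------------------------------
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pad a (X,Y,Z,C) array with zeros up to `target` spatial shape (corner
# placement) and crop back; padding voxels never enter the loss.
pad_to_shape <- function(x, target) {
  d <- dim(x)
  if (all(d[1:3] == target)) return(x)
  out <- array(0, c(target, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
  out
}

crop_to_shape <- function(x, orig) {
  d <- dim(x)
  if (all(d[1:3] == orig)) return(x)
  x[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), , drop = FALSE]
}

# Smallest grid >= shape divisible by 2^n_stages per axis.
stride_compatible_shape <- function(shape, n_stages) {
  f <- 2L^n_stages
  as.integer(ceiling(shape / f) * f)
}
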