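# Differentiable primitives. Each op_* returns list(v = value, bw = closure);
# bw(g) returns list(gx = grad wrt input(s), pg = named list of parameter
# grads). With grad = FALSE no closure is created, so nothing is retained.
#
# INTERNAL layout is channels-last (N, H, W, C); the public API converts at
# the boundary (see nchw_to_nhwc). Convolution weights are (C_in*k*k) x C_out
# matrices; see src/conv.cpp for the row ordering and the cross-correlation
# convention.

nchw_to_nhwc <- function(x) aperm(x, c(1L, 3L, 4L, 2L))
nhwc_to_nchw <- function(x) aperm(x, c(1L, 4L, 2L, 3L))

conv_param <- function(k, cin, cout, W = NULL, b = NULL) {
  if (is.null(W)) W <- matrix(0, cin * k * k, cout)
  if (is.null(b)) b <- numeric(cout)
  list(W = W, b = b, k = k, cin = cin, cout = cout)
}

# 1-based row index of weight for input channel `cin_ch`, kernel offset
# (dy, dx) from the tap centre, dy/dx in [-(k-1)/2, (k-1)/2].
conv_w_index <- function(k, cin_ch, dy = 0L, dx = 0L) {
  pad <- (k - 1L) %/% 2L
  (dx + pad) + k * (dy + pad) + k * k * (cin_ch - 1L) + 1L
}

op_conv <- function(x, p, grad = TRUE) {
  y <- .conv_fwd_cpp(x, p$W, p$b, p$k)
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) {
    r <- .conv_bwd_cpp(x, p$W, g, p$k)
    list(gx = r$gx, pg = list(W = r$gW, b = r$gb))
  })
}

op_prelu <- function(x, a, grad = TRUE) {
  y <- .prelu_fwd_cpp(x, a)
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) {
    r <- .prelu_bwd_cpp(x, a, g)
    list(gx = r$gx, pg = list(a = r$ga))
  })
}

op_sigmoid <- function(x, grad = TRUE) {
  y <- 1 / (1 + exp(-x))
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) list(gx = g * y * (1 - y), pg = NULL))
}

# per-(image, channel) spatial mean -> (N, 1, 1, C)
gap_nhwc <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1L], 1L, 1L, d[4L]))
  hw <- d[2L] * d[3L]
  for (cc in seq_len(d[4L]))
    out[, 1L, 1L, cc] <- rowMeans(matrix(x[, , , cc], d[1L], hw))
  out
}

op_gap <- function(x, grad = TRUE) {
  d <- dim(x)
  y <- gap_nhwc(x)
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) {
    hw <- d[2L] * d[3L]
    gx <- array(0, d)
    for (cc in seq_len(d[4L]))
      gx[, , , cc] <- g[, 1L, 1L, cc] / hw      # recycles N over (H, W)
    list(gx = gx, pg = NULL)
  })
}

expand_cmask <- function(m, H, W) m[, rep(1L, H), rep(1L, W), , drop = FALSE]

# x (N,H,W,C) * channel mask m (N,1,1,C)
op_cmask_mul <- function(x, m, grad = TRUE) {
  d <- dim(x)
  mf <- expand_cmask(m, d[2L], d[3L])
  y <- x * mf
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) {
    z <- g * x
    gm <- array(0, dim(m))
    hw <- d[2L] * d[3L]
    for (cc in seq_len(d[4L]))
      gm[, 1L, 1L, cc] <- rowSums(matrix(z[, , , cc], d[1L], hw))
    list(gx = g * mf, gm = gm, pg = NULL)
  })
}

# x (N,H,W,C) * spatial mask m (N,H,W,1), broadcast over channels (last axis)
op_smask_mul <- function(x, m, grad = TRUE) {
  d <- dim(x)
  y <- x * as.vector(m)                        # recycles N*H*W over C
  if (!grad) return(list(v = y))
  list(v = y, bw = function(g) {
    gm <- array(rowSums(matrix(g * x, d[1L] * d[2L] * d[3L], d[4L])),
                c(d[1L], d[2L], d[3L], 1L))
    list(gx = g * as.vector(m), gm = gm, pg = NULL)
  })
}

op_add <- function(x, y, grad = TRUE) {
  v <- x + y
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) list(gx = g, gy = g, pg = NULL))
}

# concatenate along channels (the slowest axis: a plain vector concat)
op_concat_ch <- function(x, y, grad = TRUE) {
  dx <- dim(x); dy <- dim(y)
  v <- c(x, y)
  dim(v) <- c(dx[1L], dx[2L], dx[3L], dx[4L] + dy[4L])
  if (!grad) return(list(v = v))
  nx <- length(x)
  list(v = v, bw = function(g) {
    gx <- g[seq_len(nx)]; dim(gx) <- dx
    gy <- g[nx + seq_len(length(g) - nx)]; dim(gy) <- dy
    list(gx = gx, gy = gy, pg = NULL)
  })
}

# PixelShuffle (channels-last): (N, H, W, C*r^2) -> (N, r*H, r*W, C);
# channel c*r^2 + i*r + j (0-based) lands at output (h*r + i, w*r + j).
pixel_shuffle <- function(x, r) {
  d <- dim(x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; Crr <- d[4L]
  C <- Crr %/% (r * r)
  stopifnot(C * r * r == Crr)
  dim(x) <- c(N, H, W, r, r, C)                # (n, h, w, j, i, c)
  x <- aperm(x, c(1L, 5L, 2L, 4L, 3L, 6L))     # (n, i, h, j, w, c)
  dim(x) <- c(N, r * H, r * W, C)
  x
}

pixel_unshuffle <- function(y, r) {
  d <- dim(y)
  N <- d[1L]; rH <- d[2L]; rW <- d[3L]; C <- d[4L]
  H <- rH %/% r; W <- rW %/% r
  dim(y) <- c(N, r, H, r, W, C)                # (n, i, h, j, w, c)
  y <- aperm(y, c(1L, 3L, 5L, 4L, 2L, 6L))     # (n, h, w, j, i, c)
  dim(y) <- c(N, H, W, C * r * r)
  y
}

op_pixel_shuffle <- function(x, r, grad = TRUE) {
  v <- pixel_shuffle(x, r)
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) list(gx = pixel_unshuffle(g, r), pg = NULL))
}
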