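# Independent oracles, deliberately implemented with naive loops / closed
# forms so they share no code path with the package engine.

# Naive direct cross-correlation on a public-layout (N, C, H, W) tensor,
# stride 1, zero padding (k-1)/2. Weights use the package's documented
# (C_in*k*k) x C_out layout via conv_w_index().
naive_conv <- function(x, W, b, k) {
  d <- dim(x)
  N <- d[1]; Cin <- d[2]; H <- d[3]; Wd <- d[4]
  Cout <- ncol(W)
  pad <- (k - 1) %/% 2
  y <- array(0, c(N, Cout, H, Wd))
  for (n in seq_len(N)) for (co in seq_len(Cout)) for (h in seq_len(H)) for (w in seq_len(Wd)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (dy in -pad:pad) for (dx in -pad:pad) {
      ih <- h + dy; iw <- w + dx
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= Wd)
        acc <- acc + W[conv_w_index(k, ci, dy, dx), co] * x[n, ci, ih, iw]
    }
    y[n, co, h, w] <- acc
  }
  y
}

naive_prelu <- function(x, a) {
  y <- x
  d <- dim(x)
  for (ci in seq_len(d[2]))
    y[, ci, , ] <- ifelse(x[, ci, , , drop = FALSE] > 0,
                          x[, ci, , , drop = FALSE],
                          a[ci] * x[, ci, , , drop = FALSE])
  y
}

naive_sigmoid <- function(x) 1 / (1 + exp(-x))

naive_gap <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 1, 1))
  for (n in seq_len(d[1])) for (ci in seq_len(d[2]))
    out[n, ci, 1, 1] <- mean(x[n, ci, , ])
  out
}

# multiply x by a channel mask (N,C,1,1) or spatial mask (N,1,H,W)
naive_mask_mul <- function(x, m) {
  d <- dim(x); y <- x
  if (all(dim(m)[3:4] == 1L)) {
    for (n in seq_len(d[1])) for (ci in seq_len(d[2]))
      y[n, ci, , ] <- x[n, ci, , ] * m[n, ci, 1, 1]
  } else {
    for (ci in seq_len(d[2])) y[, ci, , ] <- x[, ci, , , drop = FALSE] * m
  }
  y
}

# a small fully-enabled configuration used across architecture tests
tiny_config <- function(C = 4L, N = 1L, scale = 2L, seed = 5L, ...) {
  hacr_config(base_channels = C, caam_count = N, scale = scale,
              ca_reduction = 2L, sa_reduction = 2L, crab_width = C %/% 2L,
              seed = seed, ...)
}

rand_tensor <- function(dims, seed = 1L) {
  set.seed(seed)
  array(runif(prod(dims)), dims)
}

# closed-form per-layer parameter enumeration, written from the architecture
# definition (independently of param_shapes)
enum_count <- function(cfg) {
  C <- cfg$base_channels; Cr <- C / cfg$ca_reduction; Cs <- C / cfg$sa_reduction
  Cw <- cfg$crab_width
  conv <- function(k, a, b) k * k * a * b + b
  n <- conv(3, cfg$in_channels, C) + C               # shallow conv + PReLU
  if (cfg$use_ham)
    n <- n + conv(1, C, Cr) + Cr + conv(1, Cr, C) +  # channel attention
      conv(1, C, Cs) + conv(7, Cs, Cs) + Cs + conv(1, Cs, 1)  # spatial
  per <- 2 * conv(3, C, C) + 2 * C +                 # residual block
    conv(3, C, C)                                    # shared conv
  if (cfg$use_mfab)
    per <- per + 2 * conv(3, C, C) + 2 * C +         # branch 1
      conv(3, C, C) + conv(1, C, C) + 2 * C +        # branch 2
      conv(1, C, Cr) + Cr + conv(1, Cr, C) +         # aggregation attention
      conv(1, C, C)                                  # high-frequency path
  if (cfg$use_crab)
    per <- per + conv(3, C, C) + conv(1, C, Cw) + conv(1, Cw, Cw) + Cw +
      conv(1, Cw, Cw) + conv(1, Cw, C)
  nb <- max(cfg$use_mfab + cfg$use_crab, 1)
  per <- per + conv(1, nb * C, C)                    # fusion projection
  n <- n + cfg$caam_count * per
  n <- n + conv(3, C, C)                             # pre-skip conv
  stages <- if (cfg$scale == 2) 1 else if (cfg$upsample_single_stage) 0 else 2
  if (cfg$scale == 4 && cfg$upsample_single_stage) n <- n + conv(3, C, 16 * C)
  else n <- n + stages * conv(3, C, 4 * C)
  n + conv(3, C, cfg$out_channels)
}

make_phantom_pairs <- function(n, size = 64L, scale = 2L, seed0 = 1L) {
  hr <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_config(size = size, seed = seed0 + i - 1L)))
  build_pairs(hr, scale = scale,
              volume_ids = sprintf("ph%03d", seq_len(n) + seed0 - 1L))
}

# ---- line-by-line module oracles (naive primitives only) -------------------

naive_ham <- function(pa, cfg, x) {
  f <- naive_prelu(naive_conv(x, pa[["ham.conv"]]$W, pa[["ham.conv"]]$b, 3),
                   pa[["ham.act"]]$a)
  if (!cfg$use_ham) return(f)
  z <- naive_gap(f)
  z <- naive_conv(z, pa[["ham.ca.reduce"]]$W, pa[["ham.ca.reduce"]]$b, 1)
  z <- naive_prelu(z, pa[["ham.ca.act"]]$a)
  z <- naive_conv(z, pa[["ham.ca.expand"]]$W, pa[["ham.ca.expand"]]$b, 1)
  fch <- naive_mask_mul(f, naive_sigmoid(z))
  s <- naive_conv(fch, pa[["ham.sa.reduce"]]$W, pa[["ham.sa.reduce"]]$b, 1)
  s <- naive_conv(s, pa[["ham.sa.conv"]]$W, pa[["ham.sa.conv"]]$b, 7)
  s <- naive_prelu(s, pa[["ham.sa.act"]]$a)
  s <- naive_conv(s, pa[["ham.sa.out"]]$W, pa[["ham.sa.out"]]$b, 1)
  naive_mask_mul(fch, naive_sigmoid(s))
}

naive_resblock <- function(pa, pf, f) {
  g <- naive_prelu(f, pa[[paste0(pf, "rb.act1")]]$a)
  g <- naive_conv(g, pa[[paste0(pf, "rb.conv1")]]$W, pa[[paste0(pf, "rb.conv1")]]$b, 3)
  g <- naive_prelu(g, pa[[paste0(pf, "rb.act2")]]$a)
  g <- naive_conv(g, pa[[paste0(pf, "rb.conv2")]]$W, pa[[paste0(pf, "rb.conv2")]]$b, 3)
  f + g
}

naive_mfab <- function(pa, pf, cin) {
  cv <- function(z, nm, k) naive_conv(z, pa[[paste0(pf, nm)]]$W, pa[[paste0(pf, nm)]]$b, k)
  pr <- function(z, nm) naive_prelu(z, pa[[paste0(pf, nm)]]$a)
  fa1 <- cv(pr(cv(pr(cin, "a1.act1"), "a1.conv1", 3), "a1.act2"), "a1.conv2", 3)
  fa2 <- cv(pr(cv(pr(cin, "a2.act1"), "a2.conv1", 3), "a2.act2"), "a2.conv2", 1)
  s <- fa1 + fa2
  att <- naive_sigmoid(cv(pr(cv(naive_gap(s), "att.reduce", 1), "att.act"),
                          "att.expand", 1))
  naive_mask_mul(s, att) + cv(cin, "hf", 1)
}

naive_crab <- function(pa, pf, cin) {
  cv <- function(z, nm, k) naive_conv(z, pa[[paste0(pf, nm)]]$W, pa[[paste0(pf, nm)]]$b, k)
  h <- cv(cin, "crab.conv", 3)
  z <- naive_gap(h)
  u <- cv(z, "crab.a", 1)
  u <- cv(u, "crab.b", 1)
  u <- naive_prelu(u, pa[[paste0(pf, "crab.act")]]$a)
  u <- cv(u, "crab.c", 1)
  u <- cv(u, "crab.d", 1)
  naive_mask_mul(h, naive_sigmoid(u)) + h
}

naive_caam <- function(pa, cfg, f, i) {
  pf <- sprintf("caam%02d.", i)
  res <- naive_resblock(pa, pf, f)
  cin <- naive_conv(res, pa[[paste0(pf, "cin.conv")]]$W,
                    pa[[paste0(pf, "cin.conv")]]$b, 3)
  branches <- list()
  if (cfg$use_mfab) branches <- c(branches, list(naive_mfab(pa, pf, cin)))
  if (cfg$use_crab) branches <- c(branches, list(naive_crab(pa, pf, cin)))
  fin <- if (length(branches) == 0) cin
         else if (length(branches) == 1) branches[[1]]
         else {
           d <- dim(branches[[1]])
           out <- array(0, c(d[1], 2 * d[2], d[3], d[4]))
           out[, seq_len(d[2]), , ] <- branches[[1]]
           out[, d[2] + seq_len(d[2]), , ] <- branches[[2]]
           out
         }
  naive_conv(fin, pa[[paste0(pf, "fuse")]]$W, pa[[paste0(pf, "fuse")]]$b, 1) + f
}
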