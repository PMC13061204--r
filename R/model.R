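# HACR-Net computational graph.
#
# The network is: shallow hybrid attention (3x3 conv + PReLU, channel gating,
# spatial gating), N stacked context-aware aggregation modules (residual
# block -> shared 3x3 conv -> parallel multiscale-aggregation and
# channel-retention branches -> 1x1 fusion + module residual), a global skip
# from the shallow features, and sub-pixel (PixelShuffle) reconstruction.
#
# Every fwd_* function returns list(v = value[, bw = closure]); bw(g) returns
# list(gx = grad wrt module input, pg = named parameter gradients). Gradients
# are exact reverse-mode; correctness is pinned by finite-difference tests.

pg_add <- function(acc, nm, v) {
  if (is.null(v)) return(acc)
  if (is.null(acc[[nm]])) acc[[nm]] <- v
  else for (f in names(v)) acc[[nm]][[f]] <- acc[[nm]][[f]] + v[[f]]
  acc
}

pg_merge <- function(a, b) {
  for (nm in names(b)) a <- pg_add(a, nm, b[[nm]])
  a
}

caam_prefix <- function(i) sprintf("caam%02d.", i)

# ---- parameter layout ------------------------------------------------------

param_shapes <- function(cfg) {
  C <- cfg$base_channels
  Cr <- C %/% cfg$ca_reduction
  Cs <- C %/% cfg$sa_reduction
  Cw <- cfg$crab_width
  sh <- list()
  conv <- function(k, cin, cout) list(type = "conv", k = k, cin = cin, cout = cout)
  prelu <- function(n) list(type = "prelu", n = n)

  sh[["ham.conv"]] <- conv(3L, cfg$in_channels, C)
  sh[["ham.act"]] <- prelu(C)
  if (cfg$use_ham) {
    sh[["ham.ca.reduce"]] <- conv(1L, C, Cr)
    sh[["ham.ca.act"]] <- prelu(Cr)
    sh[["ham.ca.expand"]] <- conv(1L, Cr, C)
    sh[["ham.sa.reduce"]] <- conv(1L, C, Cs)
    sh[["ham.sa.conv"]] <- conv(7L, Cs, Cs)
    sh[["ham.sa.act"]] <- prelu(Cs)
    sh[["ham.sa.out"]] <- conv(1L, Cs, 1L)
  }
  for (i in seq_len(cfg$caam_count)) {
    p <- caam_prefix(i)
    sh[[paste0(p, "rb.act1")]] <- prelu(C)
    sh[[paste0(p, "rb.conv1")]] <- conv(3L, C, C)
    sh[[paste0(p, "rb.act2")]] <- prelu(C)
    sh[[paste0(p, "rb.conv2")]] <- conv(3L, C, C)
    sh[[paste0(p, "cin.conv")]] <- conv(3L, C, C)
    if (cfg$use_mfab) {
      sh[[paste0(p, "a1.act1")]] <- prelu(C)
      sh[[paste0(p, "a1.conv1")]] <- conv(3L, C, C)
      sh[[paste0(p, "a1.act2")]] <- prelu(C)
      sh[[paste0(p, "a1.conv2")]] <- conv(3L, C, C)
      sh[[paste0(p, "a2.act1")]] <- prelu(C)
      sh[[paste0(p, "a2.conv1")]] <- conv(3L, C, C)
      sh[[paste0(p, "a2.act2")]] <- prelu(C)
      sh[[paste0(p, "a2.conv2")]] <- conv(1L, C, C)
      sh[[paste0(p, "att.reduce")]] <- conv(1L, C, Cr)
      sh[[paste0(p, "att.act")]] <- prelu(Cr)
      sh[[paste0(p, "att.expand")]] <- conv(1L, Cr, C)
      sh[[paste0(p, "hf")]] <- conv(1L, C, C)
    }
    if (cfg$use_crab) {
      sh[[paste0(p, "crab.conv")]] <- conv(3L, C, C)
      sh[[paste0(p, "crab.a")]] <- conv(1L, C, Cw)
      sh[[paste0(p, "crab.b")]] <- conv(1L, Cw, Cw)
      sh[[paste0(p, "crab.act")]] <- prelu(Cw)
      sh[[paste0(p, "crab.c")]] <- conv(1L, Cw, Cw)
      sh[[paste0(p, "crab.d")]] <- conv(1L, Cw, C)
    }
    nb <- cfg$use_mfab + cfg$use_crab
    sh[[paste0(p, "fuse")]] <- conv(1L, max(nb, 1L) * C, C)
  }
  sh[["rec.conv"]] <- conv(3L, C, C)
  if (cfg$scale == 2L) {
    sh[["up1.conv"]] <- conv(3L, C, 4L * C)
  } else if (cfg$upsample_single_stage) {
    sh[["up1.conv"]] <- conv(3L, C, 16L * C)
  } else {
    sh[["up1.conv"]] <- conv(3L, C, 4L * C)
    sh[["up2.conv"]] <- conv(3L, C, 4L * C)
  }
  sh[["rec.out"]] <- conv(3L, C, cfg$out_channels)
  sh
}

shape_count <- function(s) {
  if (s$type == "conv") s$cin * s$k * s$k * s$cout + s$cout else s$n
}

#' Count trainable parameters
#'
#' Exact number of learnable scalars: convolution weights and biases plus
#' per-channel PReLU slopes. Works on a configuration (no allocation) or on
#' a built model. Invariant to input and batch size.
#'
#' @param x an `hacr_config` or `hacr_model`.
#' @return integer count.
#' @examples
#' count_parameters(hacr_config(base_channels = 8, caam_count = 1,
#'                              ca_reduction = 4, sa_reduction = 4))
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.hacr_config <- function(x) {
  sum(vapply(param_shapes(x), shape_count, numeric(1)))
}

#' @export
count_parameters.hacr_model <- function(x) {
  sum(vapply(x$params, function(p) {
    if (!is.null(p$W)) length(p$W) + length(p$b) else length(p$a)
  }, numeric(1)))
}

# Seeded Kaiming fan-in init (PReLU gain, a0 = 0.25); caller RNG preserved.
# The fusion projections and the output convolution start downscaled (x0.1)
# so every aggregation module begins near the identity and the initial
# prediction is small: the shallow path learns interpolation first and the
# deep modules wake up gradually, which speeds early convergence without
# changing the architecture (all weights stay nonzero and trainable).
init_params <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  a0 <- 0.25
  sh <- param_shapes(cfg)
  out <- lapply(sh, function(s) {
    if (s$type == "conv") {
      fan_in <- s$cin * s$k * s$k
      sdv <- sqrt(2 / ((1 + a0^2) * fan_in))
      conv_param(s$k, s$cin, s$cout,
                 W = matrix(rnorm(fan_in * s$cout, sd = sdv), fan_in, s$cout))
    } else {
      list(a = rep(a0, s$n))
    }
  })
  for (nm in grep("(fuse$)|(^rec\\.out$)", names(out), value = TRUE))
    out[[nm]]$W <- out[[nm]]$W * 0.1
  out
}

#' Build an HACR-Net model
#'
#' Allocates and seeds every learnable tensor for the configured graph.
#'
#' @param config an [hacr_config()].
#' @return an object of class `hacr_model` with elements `config` and
#'   `params` (named list of weight matrices, biases and PReLU slopes).
#' @examples
#' m <- hacr_model(hacr_config(base_channels = 4, caam_count = 1,
#'                             ca_reduction = 2, sa_reduction = 2, crab_width = 2))
#' count_parameters(m)
#' @export
hacr_model <- function(config = hacr_reference_config()) {
  validate_config(config)
  structure(list(config = config, params = init_params(config)),
            class = "hacr_model")
}

# ---- module forwards -------------------------------------------------------

fwd_ham <- function(pa, cfg, x, grad = TRUE) {
  o1 <- op_conv(x, pa[["ham.conv"]], grad)
  o2 <- op_prelu(o1$v, pa[["ham.act"]]$a, grad)
  if (!cfg$use_ham) {
    if (!grad) return(list(v = o2$v))
    return(list(v = o2$v, bw = function(g) {
      pg <- list()
      b2 <- o2$bw(g); pg <- pg_add(pg, "ham.act", b2$pg)
      b1 <- o1$bw(b2$gx); pg <- pg_add(pg, "ham.conv", b1$pg)
      list(gx = b1$gx, pg = pg)
    }))
  }
  f0 <- o2$v
  g0 <- op_gap(f0, grad)
  r1 <- op_conv(g0$v, pa[["ham.ca.reduce"]], grad)
  a1 <- op_prelu(r1$v, pa[["ham.ca.act"]]$a, grad)
  e1 <- op_conv(a1$v, pa[["ham.ca.expand"]], grad)
  m1 <- op_sigmoid(e1$v, grad)
  fc <- op_cmask_mul(f0, m1$v, grad)
  s1 <- op_conv(fc$v, pa[["ham.sa.reduce"]], grad)
  s2 <- op_conv(s1$v, pa[["ham.sa.conv"]], grad)
  s3 <- op_prelu(s2$v, pa[["ham.sa.act"]]$a, grad)
  s4 <- op_conv(s3$v, pa[["ham.sa.out"]], grad)
  m2 <- op_sigmoid(s4$v, grad)
  out <- op_smask_mul(fc$v, m2$v, grad)
  if (!grad) return(list(v = out$v))
  list(v = out$v, bw = function(g) {
    pg <- list()
    bo <- out$bw(g)
    bm2 <- m2$bw(bo$gm)
    bs4 <- s4$bw(bm2$gx); pg <- pg_add(pg, "ham.sa.out", bs4$pg)
    bs3 <- s3$bw(bs4$gx); pg <- pg_add(pg, "ham.sa.act", bs3$pg)
    bs2 <- s2$bw(bs3$gx); pg <- pg_add(pg, "ham.sa.conv", bs2$pg)
    bs1 <- s1$bw(bs2$gx); pg <- pg_add(pg, "ham.sa.reduce", bs1$pg)
    bfc <- fc$bw(bo$gx + bs1$gx)
    bm1 <- m1$bw(bfc$gm)
    be1 <- e1$bw(bm1$gx); pg <- pg_add(pg, "ham.ca.expand", be1$pg)
    ba1 <- a1$bw(be1$gx); pg <- pg_add(pg, "ham.ca.act", ba1$pg)
    br1 <- r1$bw(ba1$gx); pg <- pg_add(pg, "ham.ca.reduce", br1$pg)
    bg0 <- g0$bw(br1$gx)
    b2 <- o2$bw(bfc$gx + bg0$gx); pg <- pg_add(pg, "ham.act", b2$pg)
    b1 <- o1$bw(b2$gx); pg <- pg_add(pg, "ham.conv", b1$pg)
    list(gx = b1$gx, pg = pg)
  })
}

# res = f + Conv(phi(Conv(phi(f))))
fwd_resblock <- function(pa, pf, f, grad = TRUE) {
  q1 <- op_prelu(f, pa[[paste0(pf, "rb.act1")]]$a, grad)
  q2 <- op_conv(q1$v, pa[[paste0(pf, "rb.conv1")]], grad)
  q3 <- op_prelu(q2$v, pa[[paste0(pf, "rb.act2")]]$a, grad)
  q4 <- op_conv(q3$v, pa[[paste0(pf, "rb.conv2")]], grad)
  v <- f + q4$v
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) {
    pg <- list()
    b4 <- q4$bw(g); pg <- pg_add(pg, paste0(pf, "rb.conv2"), b4$pg)
    b3 <- q3$bw(b4$gx); pg <- pg_add(pg, paste0(pf, "rb.act2"), b3$pg)
    b2 <- q2$bw(b3$gx); pg <- pg_add(pg, paste0(pf, "rb.conv1"), b2$pg)
    b1 <- q1$bw(b2$gx); pg <- pg_add(pg, paste0(pf, "rb.act1"), b1$pg)
    list(gx = g + b1$gx, pg = pg)
  })
}

# two parallel branches, squeeze-style aggregation attention, 1x1 HF path
fwd_mfab <- function(pa, pf, cin, grad = TRUE) {
  u1 <- op_prelu(cin, pa[[paste0(pf, "a1.act1")]]$a, grad)
  u2 <- op_conv(u1$v, pa[[paste0(pf, "a1.conv1")]], grad)
  u3 <- op_prelu(u2$v, pa[[paste0(pf, "a1.act2")]]$a, grad)
  u4 <- op_conv(u3$v, pa[[paste0(pf, "a1.conv2")]], grad)
  w1 <- op_prelu(cin, pa[[paste0(pf, "a2.act1")]]$a, grad)
  w2 <- op_conv(w1$v, pa[[paste0(pf, "a2.conv1")]], grad)
  w3 <- op_prelu(w2$v, pa[[paste0(pf, "a2.act2")]]$a, grad)
  w4 <- op_conv(w3$v, pa[[paste0(pf, "a2.conv2")]], grad)
  s <- u4$v + w4$v
  gp <- op_gap(s, grad)
  t1 <- op_conv(gp$v, pa[[paste0(pf, "att.reduce")]], grad)
  t2 <- op_prelu(t1$v, pa[[paste0(pf, "att.act")]]$a, grad)
  t3 <- op_conv(t2$v, pa[[paste0(pf, "att.expand")]], grad)
  t4 <- op_sigmoid(t3$v, grad)
  facr <- op_cmask_mul(s, t4$v, grad)
  hf <- op_conv(cin, pa[[paste0(pf, "hf")]], grad)
  v <- facr$v + hf$v
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) {
    pg <- list()
    bhf <- hf$bw(g); pg <- pg_add(pg, paste0(pf, "hf"), bhf$pg)
    bf <- facr$bw(g)
    bt4 <- t4$bw(bf$gm)
    bt3 <- t3$bw(bt4$gx); pg <- pg_add(pg, paste0(pf, "att.expand"), bt3$pg)
    bt2 <- t2$bw(bt3$gx); pg <- pg_add(pg, paste0(pf, "att.act"), bt2$pg)
    bt1 <- t1$bw(bt2$gx); pg <- pg_add(pg, paste0(pf, "att.reduce"), bt1$pg)
    bgp <- gp$bw(bt1$gx)
    gs <- bf$gx + bgp$gx
    bu4 <- u4$bw(gs); pg <- pg_add(pg, paste0(pf, "a1.conv2"), bu4$pg)
    bu3 <- u3$bw(bu4$gx); pg <- pg_add(pg, paste0(pf, "a1.act2"), bu3$pg)
    bu2 <- u2$bw(bu3$gx); pg <- pg_add(pg, paste0(pf, "a1.conv1"), bu2$pg)
    bu1 <- u1$bw(bu2$gx); pg <- pg_add(pg, paste0(pf, "a1.act1"), bu1$pg)
    bw4 <- w4$bw(gs); pg <- pg_add(pg, paste0(pf, "a2.conv2"), bw4$pg)
    bw3 <- w3$bw(bw4$gx); pg <- pg_add(pg, paste0(pf, "a2.act2"), bw3$pg)
    bw2 <- w2$bw(bw3$gx); pg <- pg_add(pg, paste0(pf, "a2.conv1"), bw2$pg)
    bw1 <- w1$bw(bw2$gx); pg <- pg_add(pg, paste0(pf, "a2.act1"), bw1$pg)
    list(gx = bu1$gx + bw1$gx + bhf$gx, pg = pg)
  })
}

# spatial conv -> pooled descriptor -> retained-width bottleneck gate -> +h
fwd_crab <- function(pa, pf, cin, grad = TRUE) {
  h <- op_conv(cin, pa[[paste0(pf, "crab.conv")]], grad)
  z <- op_gap(h$v, grad)
  c1 <- op_conv(z$v, pa[[paste0(pf, "crab.a")]], grad)
  c2 <- op_conv(c1$v, pa[[paste0(pf, "crab.b")]], grad)
  c3 <- op_prelu(c2$v, pa[[paste0(pf, "crab.act")]]$a, grad)
  c4 <- op_conv(c3$v, pa[[paste0(pf, "crab.c")]], grad)
  c5 <- op_conv(c4$v, pa[[paste0(pf, "crab.d")]], grad)
  cm <- op_sigmoid(c5$v, grad)
  gtd <- op_cmask_mul(h$v, cm$v, grad)
  v <- gtd$v + h$v
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) {
    pg <- list()
    bg <- gtd$bw(g)
    bcm <- cm$bw(bg$gm)
    b5 <- c5$bw(bcm$gx); pg <- pg_add(pg, paste0(pf, "crab.d"), b5$pg)
    b4 <- c4$bw(b5$gx); pg <- pg_add(pg, paste0(pf, "crab.c"), b4$pg)
    b3 <- c3$bw(b4$gx); pg <- pg_add(pg, paste0(pf, "crab.act"), b3$pg)
    b2 <- c2$bw(b3$gx); pg <- pg_add(pg, paste0(pf, "crab.b"), b2$pg)
    b1 <- c1$bw(b2$gx); pg <- pg_add(pg, paste0(pf, "crab.a"), b1$pg)
    bz <- z$bw(b1$gx)
    gh <- bg$gx + g + bz$gx
    bh <- h$bw(gh); pg <- pg_add(pg, paste0(pf, "crab.conv"), bh$pg)
    list(gx = bh$gx, pg = pg)
  })
}

fwd_caam <- function(pa, cfg, f, i, grad = TRUE) {
  pf <- caam_prefix(i)
  rb <- fwd_resblock(pa, pf, f, grad)
  cin <- op_conv(rb$v, pa[[paste0(pf, "cin.conv")]], grad)
  mf <- if (cfg$use_mfab) fwd_mfab(pa, pf, cin$v, grad)
  cr <- if (cfg$use_crab) fwd_crab(pa, pf, cin$v, grad)
  cat_ <- NULL
  fuse_in <- if (cfg$use_mfab && cfg$use_crab) {
    cat_ <- op_concat_ch(mf$v, cr$v, grad)
    cat_$v
  } else if (cfg$use_mfab) mf$v
  else if (cfg$use_crab) cr$v
  else cin$v
  fp <- op_conv(fuse_in, pa[[paste0(pf, "fuse")]], grad)
  v <- fp$v + f
  if (!grad) return(list(v = v))
  list(v = v, bw = function(g) {
    pg <- list()
    bfp <- fp$bw(g); pg <- pg_add(pg, paste0(pf, "fuse"), bfp$pg)
    gcin <- NULL
    addg <- function(a, b) if (is.null(a)) b else a + b
    if (cfg$use_mfab && cfg$use_crab) {
      bc <- cat_$bw(bfp$gx)
      bm <- mf$bw(bc$gx); pg <- pg_merge(pg, bm$pg)
      bcr <- cr$bw(bc$gy); pg <- pg_merge(pg, bcr$pg)
      gcin <- bm$gx + bcr$gx
    } else if (cfg$use_mfab) {
      bm <- mf$bw(bfp$gx); pg <- pg_merge(pg, bm$pg)
      gcin <- bm$gx
    } else if (cfg$use_crab) {
      bcr <- cr$bw(bfp$gx); pg <- pg_merge(pg, bcr$pg)
      gcin <- bcr$gx
    } else {
      gcin <- bfp$gx
    }
    bcin <- cin$bw(gcin); pg <- pg_add(pg, paste0(pf, "cin.conv"), bcin$pg)
    brb <- rb$bw(bcin$gx); pg <- pg_merge(pg, brb$pg)
    list(gx = g + brb$gx, pg = pg)
  })
}

fwd_recon <- function(pa, cfg, f, fskip, grad = TRUE) {
  rc <- op_conv(f, pa[["rec.conv"]], grad)
  fres <- rc$v + fskip
  stages <- list()
  cur <- fres
  if (cfg$scale == 4L && cfg$upsample_single_stage) {
    cv <- op_conv(cur, pa[["up1.conv"]], grad)
    ps <- op_pixel_shuffle(cv$v, 4L, grad)
    stages[[1L]] <- list(cv = cv, ps = ps, nm = "up1.conv")
    cur <- ps$v
  } else {
    nstage <- if (cfg$scale == 2L) 1L else 2L
    for (s in seq_len(nstage)) {
      nm <- paste0("up", s, ".conv")
      cv <- op_conv(cur, pa[[nm]], grad)
      ps <- op_pixel_shuffle(cv$v, 2L, grad)
      stages[[s]] <- list(cv = cv, ps = ps, nm = nm)
      cur <- ps$v
    }
  }
  out <- op_conv(cur, pa[["rec.out"]], grad)
  if (!grad) return(list(v = out$v))
  list(v = out$v, bw = function(g) {
    pg <- list()
    bo <- out$bw(g); pg <- pg_add(pg, "rec.out", bo$pg)
    gcur <- bo$gx
    for (s in rev(seq_along(stages))) {
      st <- stages[[s]]
      bps <- st$ps$bw(gcur)
      bcv <- st$cv$bw(bps$gx); pg <- pg_add(pg, st$nm, bcv$pg)
      gcur <- bcv$gx
    }
    brc <- rc$bw(gcur); pg <- pg_add(pg, "rec.conv", brc$pg)
    list(gx = brc$gx, gskip = gcur, pg = pg)
  })
}

fwd_net <- function(pa, cfg, x, grad = TRUE) {
  ham <- fwd_ham(pa, cfg, x, grad)
  fskip <- ham$v
  caams <- vector("list", cfg$caam_count)
  cur <- fskip
  for (i in seq_len(cfg$caam_count)) {
    caams[[i]] <- fwd_caam(pa, cfg, cur, i, grad)
    cur <- caams[[i]]$v
  }
  rec <- fwd_recon(pa, cfg, cur, fskip, grad)
  if (!grad) return(list(v = rec$v))
  list(v = rec$v, bw = function(g) {
    pg <- list()
    brec <- rec$bw(g); pg <- pg_merge(pg, brec$pg)
    gcur <- brec$gx
    for (i in rev(seq_len(cfg$caam_count))) {
      bc <- caams[[i]]$bw(gcur); pg <- pg_merge(pg, bc$pg)
      gcur <- bc$gx
    }
    bham <- ham$bw(gcur + brec$gskip); pg <- pg_merge(pg, bham$pg)
    list(gx = bham$gx, pg = pg)
  })
}

# ---- exposed operations ----------------------------------------------------

#' Full network forward pass
#'
#' Maps a low-resolution input tensor to the super-resolved output,
#' deterministic given the weights. Output is the raw network response
#' (unclamped); [predict.hacr_model()] clamps to `[0, 1]`.
#'
#' @param model an `hacr_model`.
#' @param x `(N, C_in, H, W)` image tensor in `[0, 1]`.
#' @return `(N, C_out, scale*H, scale*W)` tensor.
#' @export
hacrnet_forward <- function(model, x) {
  check_image_tensor(x)
  if (dim(x)[2L] != model$config$in_channels)
    stop("input has ", dim(x)[2L], " channels; model expects ",
         model$config$in_channels)
  nhwc_to_nchw(fwd_net(model$params, model$config, nchw_to_nhwc(x),
                       grad = FALSE)$v)
}

#' Shallow hybrid-attention forward
#'
#' Extracts shallow features (3x3 conv + PReLU) and applies channel gating
#' then spatial gating. The returned tensor also serves as the global skip
#' source for reconstruction.
#'
#' @inheritParams hacrnet_forward
#' @return `(N, C, H, W)` feature tensor.
#' @export
ham_forward <- function(model, x) {
  nhwc_to_nchw(fwd_ham(model$params, model$config, nchw_to_nhwc(x),
                       grad = FALSE)$v)
}

#' Channel-attention gate of the shallow module
#'
#' Squeeze (global average pooling), 1x1 reduce, PReLU, 1x1 expand, sigmoid.
#'
#' @param model an `hacr_model` with the hybrid-attention branch enabled.
#' @param f `(N, C, H, W)` feature tensor.
#' @return `(N, C, 1, 1)` mask, entries strictly in (0, 1).
#' @export
channel_attention <- function(model, f) {
  pa <- model$params
  if (!model$config$use_ham) stop("hybrid-attention branch disabled in this config")
  if (dim(f)[2L] != model$config$base_channels)
    stop("feature tensor must have ", model$config$base_channels, " channels")
  f <- nchw_to_nhwc(f)
  g0 <- op_gap(f, grad = FALSE)
  r1 <- op_conv(g0$v, pa[["ham.ca.reduce"]], grad = FALSE)
  a1 <- op_prelu(r1$v, pa[["ham.ca.act"]]$a, grad = FALSE)
  e1 <- op_conv(a1$v, pa[["ham.ca.expand"]], grad = FALSE)
  nhwc_to_nchw(op_sigmoid(e1$v, grad = FALSE)$v)
}

#' Spatial-attention gate of the shallow module
#'
#' 1x1 reduce, 7x7 wide-receptive-field conv, PReLU, 1x1 projection to one
#' channel, sigmoid; the mask is broadcast over channels by the caller.
#'
#' @inheritParams channel_attention
#' @return `(N, 1, H, W)` mask, entries strictly in (0, 1).
#' @export
spatial_attention <- function(model, f) {
  pa <- model$params
  if (!model$config$use_ham) stop("hybrid-attention branch disabled in this config")
  s1 <- op_conv(nchw_to_nhwc(f), pa[["ham.sa.reduce"]], grad = FALSE)
  s2 <- op_conv(s1$v, pa[["ham.sa.conv"]], grad = FALSE)
  s3 <- op_prelu(s2$v, pa[["ham.sa.act"]]$a, grad = FALSE)
  s4 <- op_conv(s3$v, pa[["ham.sa.out"]], grad = FALSE)
  nhwc_to_nchw(op_sigmoid(s4$v, grad = FALSE)$v)
}

#' Residual block of one aggregation module
#' @param model an `hacr_model`.
#' @param f `(N, C, H, W)` feature tensor.
#' @param module 1-based module index.
#' @return tensor of the same shape.
#' @export
residual_block <- function(model, f, module = 1L) {
  nhwc_to_nchw(fwd_resblock(model$params, caam_prefix(module),
                            nchw_to_nhwc(f), grad = FALSE)$v)
}

#' Multiscale feature-aggregation branch forward
#' @inheritParams residual_block
#' @param cin output of the module's shared 3x3 convolution.
#' @export
mfab_forward <- function(model, cin, module = 1L) {
  if (!model$config$use_mfab) stop("multiscale branch disabled in this config")
  nhwc_to_nchw(fwd_mfab(model$params, caam_prefix(module),
                        nchw_to_nhwc(cin), grad = FALSE)$v)
}

#' Channel-retention attention branch forward
#' @inheritParams mfab_forward
#' @export
crab_forward <- function(model, cin, module = 1L) {
  if (!model$config$use_crab) stop("channel-retention branch disabled in this config")
  nhwc_to_nchw(fwd_crab(model$params, caam_prefix(module),
                        nchw_to_nhwc(cin), grad = FALSE)$v)
}

#' One full context-aware aggregation module forward
#' @inheritParams residual_block
#' @export
caam_forward <- function(model, f, module = 1L) {
  nhwc_to_nchw(fwd_caam(model$params, model$config, nchw_to_nhwc(f), module,
                        grad = FALSE)$v)
}

#' Reconstruction head: global skip fusion and sub-pixel upsampling
#' @param model an `hacr_model`.
#' @param f deep features `(N, C, H, W)`.
#' @param f_skip shallow skip features, same shape as `f`.
#' @return `(N, C_out, scale*H, scale*W)` tensor.
#' @export
upsample_reconstruct <- function(model, f, f_skip) {
  if (!identical(dim(f), dim(f_skip)))
    stop("f and f_skip shapes differ: ", paste(dim(f), collapse = "x"), " vs ",
         paste(dim(f_skip), collapse = "x"))
  nhwc_to_nchw(fwd_recon(model$params, model$config, nchw_to_nhwc(f),
                         nchw_to_nhwc(f_skip), grad = FALSE)$v)
}
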