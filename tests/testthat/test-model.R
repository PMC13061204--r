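# Architecture: shapes, gating ranges, identity collapses, and agreement
# with naive line-by-line oracles.

test_that("configuration invariants are enforced with named errors", {
  expect_error(hacr_config(scale = 3), "scale")
  expect_error(hacr_config(base_channels = 10, ca_reduction = 4), "ca_reduction")
  expect_error(hacr_config(base_channels = 16, sa_reduction = 5), "sa_reduction")
  expect_error(hacr_config(base_channels = 16, crab_width = 4), "crab_width")
  expect_error(hacr_config(caam_count = 0), "caam_count")
  expect_silent(validate_config(tiny_config()))
})

test_that("forward output dims are exactly scale times input dims", {
  for (sc in c(2L, 4L)) {
    m <- hacr_model(tiny_config(scale = sc))
    for (hw in list(c(8L, 8L), c(9L, 13L))) {
      x <- rand_tensor(c(1, 1, hw[1], hw[2]), seed = hw[1])
      y <- hacrnet_forward(m, x)
      expect_identical(dim(y), c(1L, 1L, sc * hw[1], sc * hw[2]))
    }
  }
  # single-stage x4 upsampler variant
  m4 <- hacr_model(tiny_config(scale = 4L, upsample_single_stage = TRUE))
  y <- hacrnet_forward(m4, rand_tensor(c(1, 1, 8, 8)))
  expect_identical(dim(y)[3:4], c(32L, 32L))
  # spec-style smallest instance: N=1, C=4, x2, 8x8 -> 16x16
  y2 <- hacrnet_forward(hacr_model(tiny_config(C = 4L, N = 1L)),
                        rand_tensor(c(1, 1, 8, 8)))
  expect_identical(dim(y2), c(1L, 1L, 16L, 16L))
})

test_that("attention masks are strictly inside (0, 1) and shaped per contract", {
  m <- hacr_model(tiny_config(C = 4L))
  f <- rand_tensor(c(2, 4, 6, 6), seed = 2) * 2 - 0.5
  cm <- channel_attention(m, f)
  sm <- spatial_attention(m, f)
  expect_identical(dim(cm), c(2L, 4L, 1L, 1L))
  expect_identical(dim(sm), c(2L, 1L, 6L, 6L))
  expect_true(all(cm > 0 & cm < 1))
  expect_true(all(sm > 0 & sm < 1))
})

test_that("channel attention matches scalar hand-computation on a 2x2x2 instance", {
  cfg <- hacr_config(base_channels = 2L, caam_count = 1L, ca_reduction = 2L,
                     sa_reduction = 2L, crab_width = 1L, seed = 3L)
  m <- hacr_model(cfg)
  # hand-fixed weights: reduce 2->1 with weights (0.5, -0.25), bias 0.1;
  # expand 1->2 with weights (2, -1), biases (0.05, -0.05); slope 0.3
  m$params[["ham.ca.reduce"]]$W <- matrix(c(0.5, -0.25), 2, 1)
  m$params[["ham.ca.reduce"]]$b <- 0.1
  m$params[["ham.ca.act"]]$a <- 0.3
  m$params[["ham.ca.expand"]]$W <- matrix(c(2, -1), 1, 2)
  m$params[["ham.ca.expand"]]$b <- c(0.05, -0.05)
  f <- array(c(1, 2, 3, 4, -1, 0, 1, 2), c(1, 2, 2, 2))
  g1 <- mean(f[1, 1, , ]); g2 <- mean(f[1, 2, , ])
  z <- 0.5 * g1 - 0.25 * g2 + 0.1
  z <- if (z > 0) z else 0.3 * z
  expected <- 1 / (1 + exp(-c(2 * z + 0.05, -z - 0.05)))
  got <- channel_attention(m, f)
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  # constant channels: pooled descriptor is exact, so the mask is identical
  # for any image with the same per-channel means
  f2 <- array(0, dim(f)); f2[1, 1, , ] <- g1; f2[1, 2, , ] <- g2
  expect_equal(channel_attention(m, f2), got, tolerance = 1e-12)
})

test_that("spatial attention with zeroed weights is a flat 0.5 mask", {
  m <- hacr_model(tiny_config(C = 4L))
  for (nm in c("ham.sa.reduce", "ham.sa.conv", "ham.sa.out")) {
    m$params[[nm]]$W[] <- 0
    m$params[[nm]]$b[] <- 0
  }
  sm <- spatial_attention(m, rand_tensor(c(1, 4, 5, 5), seed = 4))
  expect_equal(as.numeric(sm), rep(0.5, 25), tolerance = 1e-15)
})

test_that("module forwards match naive line-by-line oracles on tiny instances", {
  cfg <- tiny_config(C = 4L, N = 2L, seed = 9L)
  m <- hacr_model(cfg)
  pa <- m$params
  x <- rand_tensor(c(1, 1, 4, 4), seed = 11)
  expect_equal(ham_forward(m, x), naive_ham(pa, cfg, x), tolerance = 1e-10)
  f <- rand_tensor(c(1, 4, 4, 4), seed = 12) - 0.5
  expect_equal(residual_block(m, f, 1), naive_resblock(pa, "caam01.", f),
               tolerance = 1e-10)
  cin <- rand_tensor(c(1, 4, 3, 3), seed = 13) - 0.5
  expect_equal(mfab_forward(m, cin, 2), naive_mfab(pa, "caam02.", cin),
               tolerance = 1e-10)
  cin2 <- rand_tensor(c(2, 4, 2, 2), seed = 14) - 0.5
  expect_equal(crab_forward(m, cin2, 1), naive_crab(pa, "caam01.", cin2),
               tolerance = 1e-10)
  expect_equal(caam_forward(m, f, 2), naive_caam(pa, cfg, f, 2),
               tolerance = 1e-10)
})

test_that("residual block with zeroed convolutions is the identity", {
  m <- hacr_model(tiny_config(C = 4L))
  for (nm in c("caam01.rb.conv1", "caam01.rb.conv2")) {
    m$params[[nm]]$W[] <- 0; m$params[[nm]]$b[] <- 0
  }
  f <- rand_tensor(c(1, 4, 5, 5), seed = 7)
  expect_identical(residual_block(m, f, 1), f)
})

test_that("MFAB degenerate weight settings isolate its branches", {
  m <- hacr_model(tiny_config(C = 4L))
  pa <- m$params
  cin <- rand_tensor(c(1, 4, 3, 3), seed = 21) - 0.5
  # all-zero branch, attention and HF weights: output identically zero
  z <- m
  for (nm in grep("^caam01\\.(a1|a2|att|hf)", names(pa), value = TRUE)) {
    if (!is.null(z$params[[nm]]$W)) { z$params[[nm]]$W[] <- 0; z$params[[nm]]$b[] <- 0 }
  }
  expect_equal(max(abs(mfab_forward(z, cin, 1))), 0)
  # attention saturated to ~1 and branch 2 zeroed: output ~= branch1 + HF path
  s <- m
  s$params[["caam01.a2.conv2"]]$W[] <- 0; s$params[["caam01.a2.conv2"]]$b[] <- 0
  s$params[["caam01.att.reduce"]]$W[] <- 0; s$params[["caam01.att.reduce"]]$b[] <- 0
  s$params[["caam01.att.expand"]]$W[] <- 0; s$params[["caam01.att.expand"]]$b[] <- 30
  pa2 <- s$params
  a1 <- naive_conv(naive_prelu(naive_conv(naive_prelu(cin, pa2[["caam01.a1.act1"]]$a),
                                          pa2[["caam01.a1.conv1"]]$W,
                                          pa2[["caam01.a1.conv1"]]$b, 3),
                               pa2[["caam01.a1.act2"]]$a),
                   pa2[["caam01.a1.conv2"]]$W, pa2[["caam01.a1.conv2"]]$b, 3)
  hf <- naive_conv(cin, pa2[["caam01.hf"]]$W, pa2[["caam01.hf"]]$b, 1)
  expect_equal(mfab_forward(s, cin, 1), a1 + hf, tolerance = 1e-6)
})

test_that("CRAB with zeroed gate weights returns 1.5x its spatial features", {
  m <- hacr_model(tiny_config(C = 4L))
  for (nm in c("caam01.crab.a", "caam01.crab.b", "caam01.crab.c", "caam01.crab.d")) {
    m$params[[nm]]$W[] <- 0; m$params[[nm]]$b[] <- 0
  }
  cin <- rand_tensor(c(1, 4, 4, 4), seed = 30) - 0.5
  h <- naive_conv(cin, m$params[["caam01.crab.conv"]]$W,
                  m$params[["caam01.crab.conv"]]$b, 3)
  expect_equal(crab_forward(m, cin, 1), 1.5 * h, tolerance = 1e-10)
})

test_that("zeroing any module's fusion projection collapses it to the identity", {
  cfg <- tiny_config(C = 4L, N = 3L, seed = 17L)
  m <- hacr_model(cfg)
  f <- rand_tensor(c(2, 4, 6, 6), seed = 18) - 0.3
  for (i in 1:3) {
    z <- m
    nm <- sprintf("caam%02d.fuse", i)
    z$params[[nm]]$W[] <- 0; z$params[[nm]]$b[] <- 0
    expect_lt(max(abs(caam_forward(z, f, i) - f)), 1e-6)
  }
})

test_that("a fully fusion-zeroed network equals shallow module + reconstruction", {
  m <- hacr_model(tiny_config(C = 4L, N = 2L))
  for (i in 1:2) {
    nm <- sprintf("caam%02d.fuse", i)
    m$params[[nm]]$W[] <- 0; m$params[[nm]]$b[] <- 0
  }
  x <- rand_tensor(c(1, 1, 8, 8), seed = 40)
  f1 <- ham_forward(m, x)
  expect_equal(hacrnet_forward(m, x), upsample_reconstruct(m, f1, f1),
               tolerance = 1e-12)
})

test_that("sub-pixel shuffle maps channels (a,b,c,d) to a row-major 2x2 block", {
  # internal layout is channels-last: (1, 1, 1, 4) -> (1, 2, 2, 1)
  x <- array(c(1, 2, 3, 4), c(1, 1, 1, 4))
  y <- hacrnet:::pixel_shuffle(x, 2L)
  expect_identical(dim(y), c(1L, 2L, 2L, 1L))
  expect_identical(matrix(y[1, , , 1], 2, 2), matrix(c(1, 3, 2, 4), 2, 2))
  # and unshuffle inverts it
  expect_identical(hacrnet:::pixel_unshuffle(y, 2L), x)
})

test_that("reconstruction head obeys shape and degenerate-weight contracts", {
  m <- hacr_model(tiny_config(C = 4L))
  f <- rand_tensor(c(1, 4, 8, 8), seed = 50)
  expect_error(upsample_reconstruct(m, f, rand_tensor(c(1, 4, 6, 8))), "shape")
  z <- m; z$params[["rec.out"]]$W[] <- 0; z$params[["rec.out"]]$b[] <- 0
  expect_equal(max(abs(upsample_reconstruct(z, f, f))), 0)
})

test_that("seeded builds and forwards are bit-identical", {
  m1 <- hacr_model(tiny_config(seed = 123L))
  m2 <- hacr_model(tiny_config(seed = 123L))
  expect_identical(m1$params, m2$params)
  x <- rand_tensor(c(1, 1, 8, 8), seed = 60)
  expect_identical(hacrnet_forward(m1, x), hacrnet_forward(m2, x))
  m3 <- hacr_model(tiny_config(seed = 124L))
  expect_false(identical(m1$params, m3$params))
})

test_that("non-finite or channel-mismatched inputs are rejected", {
  m <- hacr_model(tiny_config())
  bad <- rand_tensor(c(1, 1, 8, 8)); bad[1] <- NA
  expect_error(hacrnet_forward(m, bad), "finite")
  expect_error(hacrnet_forward(m, rand_tensor(c(1, 2, 8, 8))), "channels")
})

test_that("parameter counts equal the independent layer enumeration on a config grid", {
  grid <- list()
  for (C in c(4L, 8L)) for (N in c(1L, 3L)) for (sc in c(2L, 4L))
    grid <- c(grid, list(hacr_config(base_channels = C, caam_count = N,
                                     scale = sc, ca_reduction = 2L,
                                     sa_reduction = 2L, crab_width = C %/% 2L)))
  grid <- c(grid, list(
    tiny_config(C = 8L, use_mfab = FALSE),
    tiny_config(C = 8L, use_crab = FALSE),
    tiny_config(C = 8L, use_ham = FALSE),
    tiny_config(C = 8L, use_ham = FALSE, use_mfab = FALSE, use_crab = FALSE),
    tiny_config(C = 4L, scale = 4L, upsample_single_stage = TRUE)))
  expect_gte(length(grid), 12)
  for (cfg in grid)
    expect_identical(count_parameters(cfg), enum_count(cfg))
  # built-model count agrees and is input-size independent by construction
  cfg <- grid[[1]]
  expect_identical(count_parameters(hacr_model(cfg)), count_parameters(cfg))
})

test_that("every parameter receives gradient from a generic L1 training signal", {
  # seed chosen so every PReLU sees both signs in this tiny batch: a slope
  # whose inputs are all positive legitimately has zero gradient, which
  # would mask a genuinely dead branch
  cfg <- tiny_config(C = 4L, N = 2L, seed = 2L)
  m <- hacr_model(cfg)
  x <- hacrnet:::nchw_to_nhwc(rand_tensor(c(3, 1, 8, 8), seed = 70))
  fw <- hacrnet:::fwd_net(m$params, cfg, x, grad = TRUE)
  target <- array(runif(length(fw$v)), dim(fw$v))
  bk <- fw$bw(sign(fw$v - target) / length(target))
  norms <- vapply(names(m$params), function(nm) {
    g <- bk$pg[[nm]]
    if (is.null(g)) return(0)
    sqrt(sum(vapply(g, function(v) sum(v^2), numeric(1))))
  }, numeric(1))
  expect_true(all(norms > 0), info = paste("zero-gradient params:",
                                           paste(names(norms)[norms == 0],
                                                 collapse = ", ")))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_config(C = 4L, N = 1L, seed = 6L)
  m <- hacr_model(cfg)
  x <- hacrnet:::nchw_to_nhwc(rand_tensor(c(1, 1, 6, 6), seed = 80))
  fw <- hacrnet:::fwd_net(m$params, cfg, x, grad = TRUE)
  set.seed(81)
  R <- array(rnorm(length(fw$v)), dim(fw$v))
  bk <- fw$bw(R)
  lossf <- function(params) sum(hacrnet:::fwd_net(params, cfg, x, grad = FALSE)$v * R)
  eps <- 1e-6
  set.seed(82)
  for (nm in sample(names(m$params), 12)) {
    p <- m$params[[nm]]
    f <- if (!is.null(p$W)) sample(c("W", "b"), 1) else "a"
    i <- sample(length(p[[f]]), 1)
    pp <- m$params; pp[[nm]][[f]][i] <- pp[[nm]][[f]][i] + eps
    pm <- m$params; pm[[nm]][[f]][i] <- pm[[nm]][[f]][i] - eps
    num <- (lossf(pp) - lossf(pm)) / (2 * eps)
    expect_equal(bk$pg[[nm]][[f]][i], num, tolerance = 1e-4,
                 info = paste(nm, f, i))
  }
})

test_that("calibration finds the published parameter budget and behaves sanely", {
  # an exactly attainable target has residual zero
  known <- hacr_config(base_channels = 8L, caam_count = 2L, ca_reduction = 4L,
                       sa_reduction = 4L, crab_width = 4L)
  hit <- calibrate_config(count_parameters(known), caam_count = 2L,
                          base_channels = 6:10, ca_reduction = c(2L, 4L),
                          sa_reduction = c(2L, 4L))
  expect_identical(attr(hit, "residual"), 0)
  # achieved count is non-decreasing in C at fixed ratios
  counts <- vapply(seq(8L, 32L, by = 4L), function(C)
    count_parameters(hacr_config(base_channels = C, caam_count = 2L,
                                 ca_reduction = 4L, sa_reduction = 4L,
                                 crab_width = C %/% 2L)), numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(calibrate_config(1000, base_channels = integer()), "empty")
  # the frozen reference configuration reproduces the published 1,674k total
  expect_identical(round(count_parameters(hacr_reference_config()) / 1000), 1674)
})
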