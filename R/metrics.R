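# Image-quality metrics. Evaluation convention: dynamic range [0, 1]
# (peak L = 1), full slice, no border crop, grayscale.

as_slice <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L && d[1L] == 1L && d[2L] == 1L)
    return(matrix(x[1L, 1L, , ], d[3L], d[4L]))
  stop("expected a matrix or a (1, 1, H, W) tensor")
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` over all pixels, in dB. Identical images give
#' `Inf`; [aggregate_metrics()] excludes such sentinels from means with a
#' logged count.
#'
#' @param x,y arrays of identical shape.
#' @param peak dynamic range (default 1 for `[0, 1]` images; the 8-bit
#'   `(2^n - 1)^2` form is equivalent after rescaling).
#' @return dB value.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(1, 4, 4))  # 0 dB
#' @export
psnr <- function(x, y, peak = 1.0) {
  if (!identical(dim(x), dim(y))) stop("psnr: shape mismatch")
  if (peak <= 0) stop("psnr: peak must be > 0")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

ssim_window <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1L) / 2
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g / sum(g)
}

# (n - w + 1) x n valid-window filtering matrix for a 1D window g
valid_filter_matrix <- function(n, g) {
  w <- length(g)
  M <- matrix(0, n - w + 1L, n)
  for (i in seq_len(n - w + 1L)) M[i, i:(i + w - 1L)] <- g
  M
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `L = 1`, population (not sample)
#' moments, windows fully inside the image (valid mode). This is the
#' canonical windowed form
#' `(2 mux muy + C1)(2 sxy + C2) / ((mux^2 + muy^2 + C1)(sxx + syy + C2))`.
#'
#' @param x,y single-channel images of identical shape, at least as large as
#'   the window.
#' @param window_size,window_sigma local window parameters.
#' @param L dynamic range.
#' @return scalar in `[-1, 1]`; 1 iff `x == y`.
#' @export
ssim <- function(x, y, window_size = 11L, window_sigma = 1.5, L = 1.0) {
  x <- as_slice(x); y <- as_slice(y)
  if (!identical(dim(x), dim(y))) stop("ssim: shape mismatch")
  if (nrow(x) < window_size || ncol(x) < window_size)
    stop("image (", nrow(x), "x", ncol(x), ") smaller than the ", window_size,
         "x", window_size, " window; resize or use a smaller window")
  g <- ssim_window(window_size, window_sigma)
  Mr <- valid_filter_matrix(nrow(x), g)
  Mc <- valid_filter_matrix(ncol(x), g)
  filt <- function(z) Mr %*% z %*% t(Mc)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mux <- filt(x); muy <- filt(y)
  sxx <- filt(x * x) - mux^2
  syy <- filt(y * y) - muy^2
  sxy <- filt(x * y) - mux * muy
  num <- (2 * mux * muy + C1) * (2 * sxy + C2)
  den <- (mux^2 + muy^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Learned perceptual similarity (plugin interface)
#'
#' Feature-weighted perceptual distance: for each backend layer `l`,
#' `1/(Hl Wl) * sum_{h,w} || w_l * (fhat_l(x) - fhat_l(y)) ||^2` where
#' `fhat` is the channel-unit-normalized feature vector at each position.
#' No pretrained feature network ships with the package; the caller supplies
#' a backend (`list(features = function(img) -> list of (C, H, W) arrays,
#' weights = list of per-channel weight vectors)`), e.g. wrapping an external
#' feature extractor. Without one the metric is reported as absent, never 0.
#'
#' @param x,y single-channel images.
#' @param feature_backend backend list as described; `NULL` raises an error.
#' @return nonnegative scalar.
#' @export
lpips <- function(x, y, feature_backend = NULL) {
  if (is.null(feature_backend))
    stop("perceptual-metric plugin not installed: supply `feature_backend` ",
         "(list(features = <function>, weights = <list>))")
  fx <- feature_backend$features(as_slice(x))
  fy <- feature_backend$features(as_slice(y))
  wts <- feature_backend$weights
  stopifnot(length(fx) == length(fy), length(fx) == length(wts))
  unitnorm <- function(f) {
    nrm <- sqrt(apply(f^2, c(2, 3), sum))
    sweep(f, c(2, 3), pmax(nrm, 1e-10), "/")
  }
  total <- 0
  for (l in seq_along(fx)) {
    dx <- unitnorm(fx[[l]]) - unitnorm(fy[[l]])
    wdx <- dx * wts[[l]]                   # recycles over (H, W): C first axis
    total <- total + mean(apply(wdx^2, c(2, 3), sum))
  }
  total
}

#' Absolute-error map
#'
#' Per-pixel `|sr - hr|`, optionally min-max scaled for export.
#'
#' @param sr,hr images of identical shape.
#' @param rescale scale the map to `[0, 1]` by its max.
#' @return array of the same shape.
#' @export
error_map <- function(sr, hr, rescale = FALSE) {
  if (!identical(dim(sr), dim(hr))) stop("error_map: shape mismatch")
  m <- abs(sr - hr)
  if (rescale && max(m) > 0) m <- m / max(m)
  m
}

#' Aggregate per-pair metrics into a report
#'
#' Mean and sample standard deviation per metric across slices. Infinite
#' PSNR sentinels (identical pairs) are excluded from the aggregates and
#' counted. A single-row input reports SD 0 with a degenerate-sample warning.
#'
#' @param per_pair data.frame with columns `pair_id`, `psnr`, `ssim` and
#'   optionally `lpips`.
#' @return object of class `metric_report`: `per_pair` plus an `aggregates`
#'   data.frame (metric, mean, sd, n, excluded_inf).
#' @export
aggregate_metrics <- function(per_pair) {
  if (!is.data.frame(per_pair) || nrow(per_pair) == 0L)
    stop("aggregate_metrics: need at least one row")
  if (nrow(per_pair) == 1L)
    warning("single pair: standard deviation reported as 0")
  metrics <- intersect(c("psnr", "ssim", "lpips"), names(per_pair))
  agg <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_pair[[m]]
    fin <- is.finite(v)
    vv <- v[fin]
    data.frame(metric = m,
               mean = if (length(vv)) mean(vv) else NA_real_,
               sd = if (length(vv) > 1L) sd(vv) else 0,
               n = length(vv),
               excluded_inf = sum(!fin & !is.na(v)))
  }))
  structure(list(per_pair = per_pair, aggregates = agg), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Image-quality report over", nrow(x$per_pair), "pairs\n")
  for (i in seq_len(nrow(x$aggregates))) {
    a <- x$aggregates[i, ]
    cat(sprintf("  %-5s %8.4f +/- %.4f  (n = %d%s)\n", a$metric, a$mean, a$sd,
                a$n,
                if (a$excluded_inf > 0)
                  paste0(", ", a$excluded_inf, " infinite excluded") else ""))
  }
  invisible(x)
}

#' Evaluate a model over paired slices
#'
#' Runs super-resolution on each pair's LR input and scores it against the
#' HR reference with PSNR/SSIM (and LPIPS if a backend is supplied).
#'
#' @param model an `hacr_model` or `hacr_fit`.
#' @param pairs list of [slice_pair()] objects matching the model scale.
#' @param lpips_backend optional perceptual-metric backend (see [lpips()]).
#' @return a `metric_report`.
#' @export
evaluate_pairs <- function(model, pairs, lpips_backend = NULL) {
  if (length(pairs) == 0L) stop("evaluate_pairs: empty pair list")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sr <- predict(model, p$lr)
    r <- data.frame(pair_id = paste0(p$volume_id, ":", p$slice_index),
                    psnr = psnr(sr, p$hr), ssim = ssim(sr, p$hr))
    if (!is.null(lpips_backend)) r$lpips <- lpips(sr, p$hr, lpips_backend)
    r
  })
  aggregate_metrics(do.call(rbind, rows))
}
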