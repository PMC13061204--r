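#' Degradation configuration
#'
#' The HR -> LR observation model: a small Gaussian blur followed by bicubic
#' decimation. The published protocol is a 3x3 Gaussian filter with standard
#' deviation 1 followed by bicubic downsampling at x2 or x4; the bicubic
#' dialect (sharpness `a`) and the blur border mode are configurable because
#' they are not part of the printed protocol.
#'
#' @param kernel_size odd blur kernel size (default 3).
#' @param sigma blur standard deviation in pixels (default 1).
#' @param scale decimation factor, 2 or 4.
#' @param bicubic_a cubic-convolution sharpness parameter (default -0.5, the
#'   Catmull-Rom dialect).
#' @param border_mode blur border handling; `"reflect"` (mirror without edge
#'   duplication) is the only supported mode.
#' @return an object of class `degradation_config`.
#' @export
degradation_config <- function(kernel_size = 3L, sigma = 1.0, scale = 2L,
                               bicubic_a = -0.5, border_mode = "reflect") {
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  if (sigma <= 0) stop("sigma must be > 0")
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4")
  border_mode <- match.arg(border_mode, "reflect")
  structure(list(kernel_size = as.integer(kernel_size), sigma = sigma,
                 scale = as.integer(scale), bicubic_a = bicubic_a,
                 border_mode = border_mode),
            class = "degradation_config")
}

#' Normalized 2D Gaussian kernel
#'
#' Entries proportional to `exp(-(dx^2 + dy^2) / (2 sigma^2))` on the integer
#' offset grid, normalized to sum exactly 1.
#'
#' @param size odd kernel side length.
#' @param sigma standard deviation in pixels.
#' @return `size x size` matrix.
#' @examples
#' sum(gaussian_kernel(3, 1))  # 1
#' @export
gaussian_kernel <- function(size, sigma) {
  if (size %% 2L == 0L) stop("kernel size must be odd")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- (size - 1L) / 2
  d <- (-h):h
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# mirror padding without duplicating the edge sample (reflect-101)
reflect_pad <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  ri <- c((p + 1L):2L, 1L:H, (H - 1L):(H - p))
  ci <- c((p + 1L):2L, 1L:W, (W - 1L):(W - p))
  x[ri, ci, drop = FALSE]
}

gaussian_blur <- function(x, kernel) {
  p <- (nrow(kernel) - 1L) %/% 2L
  if (p == 0L) return(x * kernel[1L, 1L])
  xp <- reflect_pad(x, p)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(kernel)))
    for (j in seq_len(ncol(kernel)))
      out <- out + kernel[i, j] * xp[(i):(i + H - 1L), (j):(j + W - 1L)]
  out
}

# Keys cubic-convolution kernel with sharpness a
cubic_weight <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# n_out x n_in interpolation matrix, center-aligned sampling, edge clamp
bicubic_matrix <- function(n_in, n_out, a = -0.5) {
  M <- matrix(0, n_out, n_in)
  ratio <- n_in / n_out
  for (oi in seq_len(n_out)) {
    s <- (oi - 0.5) * ratio - 0.5          # 0-based source coordinate
    base <- floor(s)
    for (t in -1:2) {
      j <- base + t
      w <- cubic_weight(s - j, a)
      jc <- min(max(j, 0), n_in - 1)       # clamp to the image
      M[oi, jc + 1L] <- M[oi, jc + 1L] + w
    }
  }
  M
}

#' Bicubic resampling
#'
#' Separable cubic-convolution resampling with configurable sharpness `a`.
#' Sampling positions are center-aligned; borders clamp to the edge sample.
#' No anti-aliasing prefilter is applied (the degradation pipeline blurs
#' explicitly before decimating).
#'
#' @param x matrix (one slice).
#' @param out_h,out_w output dims.
#' @param a cubic kernel sharpness (default -0.5).
#' @return `out_h x out_w` matrix.
#' @export
bicubic_resize <- function(x, out_h, out_w, a = -0.5) {
  Mr <- bicubic_matrix(nrow(x), out_h, a)
  Mc <- bicubic_matrix(ncol(x), out_w, a)
  Mr %*% x %*% t(Mc)
}

#' Degrade a high-resolution image to its low-resolution observation
#'
#' Gaussian blur (reflect border) followed by bicubic decimation by the
#' configured scale, then clamping to `[0, 1]`. Deterministic.
#'
#' @param hr matrix or `(N, C, H, W)` tensor with intensities in `[0, 1]`;
#'   spatial dims must be divisible by `cfg$scale`.
#' @param cfg a [degradation_config()].
#' @return same container type as `hr` at `1/scale` resolution.
#' @examples
#' lr <- degrade(matrix(0.5, 16, 16), degradation_config(scale = 2))
#' dim(lr)  # 8 8
#' @export
degrade <- function(hr, cfg = degradation_config()) {
  if (is.matrix(hr)) {
    if (nrow(hr) %% cfg$scale != 0L || ncol(hr) %% cfg$scale != 0L)
      stop("image dims ", nrow(hr), "x", ncol(hr),
           " not divisible by scale ", cfg$scale)
    k <- gaussian_kernel(cfg$kernel_size, cfg$sigma)
    b <- gaussian_blur(hr, k)
    lr <- bicubic_resize(b, nrow(hr) %/% cfg$scale, ncol(hr) %/% cfg$scale,
                         cfg$bicubic_a)
    return(pmin(pmax(lr, 0), 1))
  }
  check_image_tensor(hr, "hr")
  d <- dim(hr)
  out <- array(0, c(d[1L], d[2L], d[3L] %/% cfg$scale, d[4L] %/% cfg$scale))
  for (n in seq_len(d[1L]))
    for (cc in seq_len(d[2L]))
      out[n, cc, , ] <- degrade(matrix(hr[n, cc, , ], d[3L], d[4L]), cfg)
  out
}

#' Min-max intensity normalization
#'
#' Affine map of a volume (or any array) onto `[0, 1]`: min -> 0, max -> 1.
#' Applied per volume so inter-slice contrast relationships are preserved.
#'
#' @param volume finite numeric array with `max > min`.
#' @return array of the same shape.
#' @export
normalize_intensity <- function(volume) {
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) stop("constant volume: normalization undefined")
  (volume - lo) / (hi - lo)
}
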