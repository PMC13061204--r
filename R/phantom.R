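#' Synthetic tissue-like phantom configuration
#'
#' Desk-scale stand-in for brain MRI slices: overlapping soft-edged ellipses
#' with well-separated mean intensities (piecewise-smooth "tissue" classes),
#' band-limited texture, a smooth multiplicative bias field, and Gaussian
#' pixel noise, clipped to `[0, 1]`. Defaults are chosen to look like a
#' mildly noisy structural slice: a few tissue classes spanning most of the
#' intensity range, texture and noise around 1-3% of the dynamic range.
#'
#' @param size image side in pixels (>= 32; default 256).
#' @param n_ellipses number of tissue ellipses.
#' @param texture_amp standard deviation of the band-limited texture.
#' @param bias_amp peak relative amplitude of the multiplicative bias field.
#' @param noise_sd standard deviation of the additive pixel noise.
#' @param seed integer seed; the generator is a pure function of this config.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(size = 256L, n_ellipses = 6L, texture_amp = 0.02,
                           bias_amp = 0.08, noise_sd = 0.01, seed = 1L) {
  if (size < 32L) stop("size must be >= 32")
  if (texture_amp < 0 || bias_amp < 0 || noise_sd < 0)
    stop("amplitudes must be >= 0")
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 texture_amp = texture_amp, bias_amp = bias_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic MRI-like phantom slice
#'
#' @param cfg a [phantom_config()].
#' @return `size x size` matrix in `[0, 1]`.
#' @examples
#' ph <- generate_phantom(phantom_config(size = 64, seed = 3))
#' range(ph)
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  with_preserved_rng(cfg$seed, {
    n <- cfg$size
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), n), n, n)          # row coordinate
    img <- matrix(0.05, n, n)                       # dark background

    if (cfg$n_ellipses > 0L) {
      # well-separated class means so the histogram stays multi-modal
      levels <- seq(0.30, 0.90, length.out = cfg$n_ellipses)
      levels <- sample(levels)
      for (e in seq_len(cfg$n_ellipses)) {
        cx <- runif(1, 0.30, 0.70) * n
        cy <- runif(1, 0.30, 0.70) * n
        ax <- runif(1, 0.10, 0.28) * n
        ay <- runif(1, 0.10, 0.28) * n
        th <- runif(1, 0, pi)
        xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        q <- (xr / ax)^2 + (yr / ay)^2
        m <- 1 / (1 + exp(-(1 - q) / 0.06))         # soft edge
        img <- img * (1 - m) + levels[e] * m
      }
    }

    if (cfg$texture_amp > 0) {
      tx <- matrix(rnorm(n * n), n, n)
      tx <- gaussian_blur(tx, gaussian_kernel(7L, 1.2))
      img <- img + tx / sd(tx) * cfg$texture_amp
    }

    if (cfg$bias_amp > 0) {
      u <- (xs / n - 0.5); v <- (ys / n - 0.5)
      co <- rnorm(5)
      b <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
      b <- b / max(abs(b))
      img <- img * (1 + cfg$bias_amp * b)
    }

    if (cfg$noise_sd > 0) img <- img + matrix(rnorm(n * n, sd = cfg$noise_sd), n, n)

    pmin(pmax(img, 0), 1)
  })
}
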