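#' Image tensors
#'
#' All images moving between pipeline stages are 4-axis arrays with dims
#' `(batch, channel, height, width)` and, at pipeline boundaries, intensities
#' in `[0, 1]`. `image_tensor()` coerces a matrix (one grayscale slice), a
#' 3-axis `(channel, height, width)` array, or a 4-axis array into that layout.
#'
#' @param x matrix, 3-axis or 4-axis numeric array.
#' @return a 4-axis `(N, C, H, W)` array.
#' @examples
#' dim(image_tensor(matrix(0, 8, 8)))  # 1 1 8 8
#' @export
image_tensor <- function(x) {
  if (is.matrix(x)) {
    arr <- array(0, c(1L, 1L, nrow(x), ncol(x)))
    arr[1L, 1L, , ] <- x
    return(arr)
  }
  d <- dim(x)
  if (is.null(d)) stop("image_tensor: input must have dims")
  if (length(d) == 3L) {
    arr <- array(0, c(1L, d))
    arr[1L, , , ] <- x
    return(arr)
  }
  if (length(d) == 4L) return(x)
  stop("image_tensor: expected 2, 3 or 4 axes, got ", length(d))
}

#' @rdname image_tensor
#' @param tensor a 4-axis image tensor with a single image and channel.
#' @return `tensor_to_matrix()`: the `H x W` matrix of the first image/channel.
#' @export
tensor_to_matrix <- function(tensor) {
  d <- dim(tensor)
  stopifnot(length(d) == 4L)
  matrix(tensor[1L, 1L, , ], d[3L], d[4L])
}

check_image_tensor <- function(x, what = "input") {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop(what, " must be a 4-axis (batch, channel, height, width) array")
  if (d[3L] < 1L || d[4L] < 1L) stop(what, ": spatial dims must be >= 1")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
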