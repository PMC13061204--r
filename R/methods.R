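# S3 methods for hacr_model and hacr_fit.

#' @export
print.hacr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("HACR-Net model: C = %d, N = %d modules, x%d upscaling\n",
              cfg$base_channels, cfg$caam_count, cfg$scale))
  cat(sprintf("  trainable parameters: %s (%.0fk)\n",
              format(count_parameters(x), big.mark = ","),
              round(count_parameters(x) / 1000)))
  invisible(x)
}

module_of <- function(nm) {
  ifelse(grepl("^ham\\.", nm), "shallow attention",
         ifelse(grepl("^caam", nm), "aggregation modules", "reconstruction"))
}

#' @export
summary.hacr_model <- function(object, input_size = c(128L, 128L), ...) {
  counts <- vapply(object$params, function(p)
    if (!is.null(p$W)) length(p$W) + length(p$b) else length(p$a), numeric(1))
  by_mod <- tapply(counts, module_of(names(counts)), sum)
  out <- list(config = object$config, total = sum(counts),
              by_module = by_mod,
              macs = count_macs(object$config, input_size),
              input_size = input_size)
  class(out) <- "summary.hacr_model"
  out
}

#' @export
print.summary.hacr_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("Trainable parameters: %s total\n", format(x$total, big.mark = ",")))
  for (nm in names(x$by_module))
    cat(sprintf("  %-20s %s\n", nm, format(x$by_module[[nm]], big.mark = ",")))
  cat(sprintf("Multiply-accumulates for a %dx%d input: %.2f G\n",
              x$input_size[1], x$input_size[2], x$macs / 1e9))
  cat("  (convolution MACs = k^2 * C_in * C_out * H_out * W_out; gating,\n",
      "  pooling and activations excluded)\n", sep = "")
  invisible(x)
}

#' Multiply-accumulate count for one forward pass
#'
#' Informational complexity figure using the plain convolution convention
#' `k^2 * C_in * C_out * H_out * W_out` (pooling, activations and gating
#' multiplies excluded; 1 MAC = 2 FLOPs). Reported for transparency; the
#' published FLOPs figure uses an unstated convention and is not asserted
#' against.
#'
#' @param cfg an `hacr_config`.
#' @param input_size `(H, W)` of the LR input.
#' @return numeric MAC count.
#' @export
count_macs <- function(cfg, input_size = c(128L, 128L)) {
  H <- input_size[1]; W <- input_size[2]
  sh <- param_shapes(cfg)
  # spatial area each conv runs at: LR resolution everywhere except after
  # the shuffle stages (up2.conv sees 2x, the output conv sees the full scale)
  area <- function(nm) {
    if (nm == "rec.out") return(H * W * cfg$scale^2)
    if (nm == "up2.conv") return(H * W * 4)
    H * W
  }
  total <- 0
  for (nm in names(sh)) {
    s <- sh[[nm]]
    if (s$type != "conv") next
    total <- total + s$k^2 * s$cin * s$cout * area(nm)
  }
  total
}

#' @export
coef.hacr_model <- function(object, ...) {
  unlist(lapply(object$params, function(p)
    if (!is.null(p$W)) c(W = as.numeric(p$W), b = as.numeric(p$b))
    else c(a = as.numeric(p$a))))
}

#' Super-resolve new low-resolution inputs
#'
#' @param object an `hacr_model`.
#' @param newdata LR input: matrix, `(N, C, H, W)` tensor, a [slice_pair()]
#'   (its `lr` field is used) or a list of any of these.
#' @param clamp clamp the output to `[0, 1]` (default `TRUE`).
#' @param ... unused.
#' @return super-resolved output in the same container type as the input.
#' @export
predict.hacr_model <- function(object, newdata, clamp = TRUE, ...) {
  if (inherits(newdata, "slice_pair")) newdata <- newdata$lr
  if (is.list(newdata) && !is.array(newdata))
    return(lapply(newdata, function(z) predict(object, z, clamp = clamp)))
  was_matrix <- is.matrix(newdata)
  x <- image_tensor(newdata)
  y <- hacrnet_forward(object, x)
  if (clamp) y <- pmin(pmax(y, 0), 1)
  if (was_matrix) tensor_to_matrix(y) else y
}

fit_model <- function(object, which = c("best", "final")) {
  which <- match.arg(which)
  m <- object$model
  if (which == "best") m$params <- object$best_params
  m
}

#' @rdname predict.hacr_model
#' @param which use the `"best"` validation checkpoint (default) or the
#'   `"final"` weights.
#' @export
predict.hacr_fit <- function(object, newdata, clamp = TRUE,
                             which = c("best", "final"), ...) {
  predict(fit_model(object, which), newdata, clamp = clamp)
}

#' @export
print.hacr_fit <- function(x, ...) {
  cat("Fitted HACR-Net\n")
  print(x$model)
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs / %d steps; final train L1 %.5f\n",
                last$epoch, last$step, last$train_l1))
  }
  if (is.finite(x$best$psnr))
    cat(sprintf("  best validation PSNR %.2f dB (epoch %d)\n",
                x$best$psnr, x$best$epoch))
  invisible(x)
}

#' @export
summary.hacr_fit <- function(object, ...) {
  cat("Training history (last rows):\n")
  print(utils::tail(object$history, 5))
  print(object)
  invisible(object)
}

#' @export
coef.hacr_fit <- function(object, ...) coef(fit_model(object, "best"))

#' Training-history plot
#'
#' L1 training loss per epoch (log scale) and, when present, validation
#' PSNR on a second panel.
#'
#' @param x an `hacr_fit`.
#' @param ... passed to [plot()].
#' @export
plot.hacr_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("empty training history")
  has_val <- any(is.finite(h$val_psnr))
  if (has_val) {
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
  }
  plot(h$epoch, h$train_l1, type = "l", log = "y", xlab = "epoch",
       ylab = "train L1", main = "Training loss", ...)
  if (has_val) {
    plot(h$epoch, h$val_psnr, type = "l", xlab = "epoch",
         ylab = "validation PSNR (dB)", main = "Validation PSNR", ...)
    abline(h = x$best$psnr, lty = 3)
  }
  invisible(x)
}

#' Reconstruction residual maps
#'
#' Per-pair absolute error maps `|SR - HR|` of the fitted model.
#'
#' @param object an `hacr_fit`.
#' @param pairs list of [slice_pair()] to evaluate.
#' @param which checkpoint choice, see [predict.hacr_fit()].
#' @param ... unused.
#' @return list of matrices, one per pair.
#' @export
residuals.hacr_fit <- function(object, pairs, which = "best", ...) {
  m <- fit_model(object, which)
  lapply(pairs, function(p) error_map(predict(m, p$lr), p$hr))
}
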