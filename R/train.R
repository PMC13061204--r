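#' Training control parameters
#'
#' The published optimization recipe is Adam with beta1 0.9, beta2 0.999,
#' eps 1e-8, initial learning rate 1e-4, batch size 32, 250 epochs, constant
#' learning rate, L1 objective, and nothing else (no schedule, weight decay,
#' clipping or augmentation). That is the `"paper"` profile. The `"desk"`
#' profile is the package's CPU-feasible counterpart used on small synthetic
#' phantoms: batch 8, learning rate 1e-3, capped step budget.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param lr,beta1,beta2,eps Adam parameters.
#' @param batch_size slices per step.
#' @param epochs passes over the training set.
#' @param max_steps optional hard cap on optimizer steps.
#' @param lr_decay multiplicative learning-rate factor applied after each
#'   epoch (default 1: the published constant-rate recipe). Values < 1 give
#'   a geometric decay, useful when an optimization must be driven to a very
#'   low floor (e.g. single-sample overfitting checks), since Adam at a
#'   constant rate stalls at a rate-dependent noise floor.
#' @param stop_loss optional early-stop threshold: training ends once the
#'   epoch-mean L1 falls below it (used e.g. for overfitting sanity checks).
#' @param seed seed for data ordering.
#' @param validate_every validate every this many epochs (when a validation
#'   set is given).
#' @return object of class `train_control`.
#' @export
train_control <- function(profile = c("desk", "paper"), lr = NULL,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          batch_size = NULL, epochs = NULL, max_steps = NULL,
                          lr_decay = 1, stop_loss = NULL, seed = 1L,
                          validate_every = 1L) {
  profile <- match.arg(profile)
  if (is.null(lr)) lr <- if (profile == "paper") 1e-4 else 1e-3
  if (is.null(batch_size)) batch_size <- if (profile == "paper") 32L else 8L
  if (is.null(epochs)) epochs <- if (profile == "paper") 250L else 24L
  if (lr <= 0) stop("lr must be > 0")
  if (!(beta1 > 0 && beta1 < beta2 && beta2 < 1)) stop("need 0 < beta1 < beta2 < 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(profile = profile, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 lr_decay = lr_decay, stop_loss = stop_loss,
                 seed = as.integer(seed),
                 validate_every = as.integer(validate_every)),
            class = "train_control")
}

#' Desk-scale model configuration
#'
#' Reduced network (width 16, 4 aggregation modules) used with 64x64
#' phantoms so the full train/evaluate loop runs in minutes on one CPU.
#'
#' @param scale upscaling factor.
#' @param seed initialization seed.
#' @export
desk_config <- function(scale = 2L, seed = 1L) {
  hacr_config(base_channels = 16L, caam_count = 4L, scale = scale,
              ca_reduction = 8L, sa_reduction = 8L, crab_width = 8L,
              seed = seed)
}

#' Mean absolute (L1) reconstruction loss
#'
#' @param sr,hr arrays of identical shape.
#' @return scalar mean absolute deviation over all elements.
#' @export
l1_loss <- function(sr, hr) {
  if (!identical(dim(sr), dim(hr))) stop("l1_loss: shape mismatch")
  mean(abs(sr - hr))
}

adam_init <- function(params) {
  lapply(params, function(p) {
    fields <- if (!is.null(p$W)) c("W", "b") else "a"
    setNames(lapply(fields, function(f) list(m = p[[f]] * 0, v = p[[f]] * 0)), fields)
  })
}

adam_step <- function(params, grads, state, t, ctl) {
  c1 <- 1 - ctl$beta1^t
  c2 <- 1 - ctl$beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (f in names(g)) {
      st <- state[[nm]][[f]]
      st$m <- ctl$beta1 * st$m + (1 - ctl$beta1) * g[[f]]
      st$v <- ctl$beta2 * st$v + (1 - ctl$beta2) * g[[f]]^2
      params[[nm]][[f]] <- params[[nm]][[f]] -
        ctl$lr * (st$m / c1) / (sqrt(st$v / c2) + ctl$eps)
      state[[nm]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

# batches are stacked directly in the internal channels-last layout
stack_batch <- function(pairs, idx, field) {
  d <- dim(pairs[[idx[1L]]][[field]])
  out <- array(0, c(length(idx), d[1L], d[2L], 1L))
  for (i in seq_along(idx)) out[i, , , 1L] <- pairs[[idx[i]]][[field]]
  out
}

#' Fit an HACR-Net super-resolution model
#'
#' Minimizes the L1 reconstruction objective with Adam over (LR, HR) slice
#' pairs, exactly as published: constant learning rate, no schedule, no
#' weight decay, no augmentation. Fully seeded (weight init via the model
#' config, data order via `control$seed`); per-epoch training loss and
#' validation PSNR are logged, and the parameters achieving the best
#' validation PSNR are retained.
#'
#' @param train_pairs nonempty list of [slice_pair()] objects.
#' @param val_pairs optional validation pairs (model selection by mean PSNR).
#' @param config an [hacr_config()]; ignored when `model` is given.
#' @param model optionally a pre-built (or pre-trained) `hacr_model`.
#' @param control a [train_control()].
#' @param verbose print per-epoch progress.
#' @return object of class `hacr_fit` with elements `model` (final weights),
#'   `best_params` (weights at best validation PSNR), `history` (per-epoch
#'   data.frame), `best`, `control`, `config`.
#' @seealso [predict.hacr_fit()], [validate()]
#' @export
hacr_fit <- function(train_pairs, val_pairs = NULL, config = desk_config(),
                     model = NULL, control = train_control("desk"),
                     verbose = FALSE) {
  if (length(train_pairs) == 0L) stop("empty training set")
  if (is.null(model)) model <- hacr_model(config)
  cfg <- model$config
  pscale <- train_pairs[[1L]]$scale
  if (pscale != cfg$scale)
    stop("model scale x", cfg$scale, " does not match pair scale x", pscale)

  params <- model$params
  state <- adam_init(params)
  ntr <- length(train_pairs)
  spe <- ceiling(ntr / control$batch_size)
  history <- data.frame()
  best <- list(psnr = -Inf, epoch = NA_integer_)
  best_params <- params
  step <- 0L
  done <- FALSE

  with_preserved_rng(control$seed, {
    for (ep in seq_len(control$epochs)) {
      if (done) break
      ord <- sample(ntr)
      epoch_loss <- 0; nb <- 0L
      for (bs in seq_len(spe)) {
        if (!is.null(control$max_steps) && step >= control$max_steps) {
          done <- TRUE; break
        }
        idx <- ord[((bs - 1L) * control$batch_size + 1L):min(bs * control$batch_size, ntr)]
        lr_b <- stack_batch(train_pairs, idx, "lr")
        hr_b <- stack_batch(train_pairs, idx, "hr")
        fw <- fwd_net(params, cfg, lr_b, grad = TRUE)
        loss <- l1_loss(fw$v, hr_b)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at step %d (epoch %d, lr %g, batch [%s]): aborting",
                       step + 1L, ep, control$lr, paste(idx, collapse = ",")))
        dL <- sign(fw$v - hr_b) / length(hr_b)
        bk <- fw$bw(dL)
        upd <- adam_step(params, bk$pg, state, step + 1L, control)
        params <- upd$params; state <- upd$state
        step <- step + 1L
        epoch_loss <- epoch_loss + loss; nb <- nb + 1L
      }
      if (nb == 0L) break
      vps <- NA_real_
      if (!is.null(val_pairs) && ep %% control$validate_every == 0L) {
        tmp <- model; tmp$params <- params
        rep_ <- validate(tmp, val_pairs)
        vps <- rep_$aggregates$mean[rep_$aggregates$metric == "psnr"]
        if (vps > best$psnr) {
          best <- list(psnr = vps, epoch = ep)
          best_params <- params
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, step = step,
                                  train_l1 = epoch_loss / nb, val_psnr = vps))
      if (verbose)
        message(sprintf("epoch %3d  step %5d  L1 %.5f  val PSNR %s",
                        ep, step, epoch_loss / nb,
                        if (is.na(vps)) "-" else sprintf("%.2f dB", vps)))
      if (!is.null(control$stop_loss) && epoch_loss / nb < control$stop_loss)
        done <- TRUE
      control$lr <- control$lr * control$lr_decay
    }
  })
  if (is.null(val_pairs)) best_params <- params
  model$params <- params
  structure(list(model = model, best_params = best_params, history = history,
                 best = best, control = control, config = cfg),
            class = "hacr_fit")
}

#' Validate a model over slice pairs
#'
#' Runs inference per pair and aggregates PSNR/SSIM; no optimizer state is
#' touched.
#'
#' @param model `hacr_model` or `hacr_fit`.
#' @param pairs nonempty list of [slice_pair()] at the model's scale.
#' @return a `metric_report`.
#' @export
validate <- function(model, pairs) {
  if (length(pairs) == 0L) stop("validate: empty pair list")
  cfg <- model$config
  if (pairs[[1L]]$scale != cfg$scale)
    stop("model scale x", cfg$scale, " does not match pair scale x",
         pairs[[1L]]$scale)
  evaluate_pairs(model, pairs)
}

#' Bicubic upsampling baseline
#'
#' Scores plain bicubic upscaling of each LR slice against its HR reference —
#' the training-free baseline any learned model must beat.
#'
#' @param pairs list of [slice_pair()].
#' @param a bicubic sharpness parameter.
#' @return a `metric_report`.
#' @export
baseline_bicubic <- function(pairs, a = -0.5) {
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    up <- pmin(pmax(bicubic_resize(p$lr, nrow(p$hr), ncol(p$hr), a), 0), 1)
    data.frame(pair_id = paste0(p$volume_id, ":", p$slice_index),
               psnr = psnr(up, p$hr), ssim = ssim(up, p$hr))
  }))
  aggregate_metrics(rows)
}
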