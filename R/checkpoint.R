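# Checkpoints: opaque weight blob (RDS) + human-readable JSON sidecar config.

config_fields <- c("in_channels", "out_channels", "base_channels", "caam_count",
                   "scale", "ca_reduction", "sa_reduction", "crab_width",
                   "use_ham", "use_mfab", "use_crab", "seed")

#' Hash of a configuration
#'
#' MD5 over the canonical JSON serialization; used to stamp run manifests
#' and output files.
#'
#' @param cfg an `hacr_config`.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[config_fields], tmp, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Save / load model checkpoints
#'
#' `save_checkpoint()` writes the weights as an opaque blob plus a JSON
#' sidecar (`<path>.json`) holding the architecture config.
#' `load_checkpoint()` restores the model; if `expected_config` is supplied,
#' any architectural mismatch is an error naming the first mismatched key.
#' A save -> load round trip reproduces predictions exactly.
#'
#' @param model an `hacr_model` (or `hacr_fit`, whose best weights are saved).
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "hacr_fit")) model <- fit_model(model, "best")
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  write_config(model$config, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config optional `hacr_config` the checkpoint must match.
#' @return `load_checkpoint()`: an `hacr_model`.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  blob <- readRDS(path)
  cfg <- do.call(hacr_config, blob$config[setdiff(names(blob$config),
                                                  "upsample_single_stage")])
  cfg$upsample_single_stage <- isTRUE(blob$config$upsample_single_stage)
  if (!is.null(expected_config)) {
    for (k in config_fields) {
      if (!identical(cfg[[k]], expected_config[[k]]))
        stop("checkpoint config mismatch at key '", k, "': checkpoint has ",
             cfg[[k]], ", expected ", expected_config[[k]])
    }
  }
  structure(list(config = cfg, params = blob$params), class = "hacr_model")
}
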