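# Serialisation of configurations and trained models as plain JSON/CSV.

#' Write / read a control configuration as JSON
#' @param control a [minn_control()] list.
#' @param path file path.
#' @return `path` invisibly, or the control list.
#' @export
write_minn_config <- function(control, path) {
  jsonlite::write_json(unclass(control), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_minn_config
#' @export
read_minn_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(minn_control, j[setdiff(names(j), character(0))])
}

#' Save / load a trained network (weights + scaler + control) as JSON
#'
#' The mechanistic context is not embedded (it is model-derived data);
#' supply it again when loading.
#' @param fit a fitted `minn`.
#' @param path file path.
#' @param context the `mechanistic_context` used at training time.
#' @return `path` invisibly, or the restored `minn` object.
#' @export
save_minn <- function(fit, path) {
  obj <- list(weights = lapply(fit$weights, function(w) {
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = NULL, data = as.numeric(w))
              }),
              control = unclass(fit$control),
              scaler = fit$scaler,
              seed = fit$seed,
              feature_names = fit$feature_names,
              target_names = fit$target_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_minn
#' @export
load_minn <- function(path, context) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  weights <- lapply(j$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  ctrl <- do.call(minn_control, j$control[setdiff(names(j$control), "batch_size")])
  structure(list(weights = weights, control = ctrl,
                 scaler = list(center = j$scaler$center, scale = j$scaler$scale),
                 context = context, log = NULL, seed = j$seed,
                 feature_names = j$feature_names,
                 target_names = j$target_names,
                 train_fingerprint = NA_character_, train_data = NULL),
            class = "minn")
}

#' Write the per-epoch training log as CSV
#' @param fit a fitted `minn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
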