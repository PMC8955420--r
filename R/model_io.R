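#' Save / load a model checkpoint (HDF5)
#'
#' The native checkpoint format: configuration scalars plus one dataset per
#' weight array, under groups `config` and `params`. Two evaluations of one
#' checkpoint are identical (inference is deterministic).
#'
#' @param model an `asmap_model`.
#' @param path checkpoint file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "asmap_model"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "config")
  rhdf5::h5createGroup(path, "params")
  cfg <- list(type = model$type,
              input_shape = model$input_shape,
              n_classes = model$n_classes,
              hidden_units = model$head$hidden_units,
              trained = as.integer(model$trained),
              classes = if (is.null(model$classes)) "" else model$classes)
  if (model$type == "cnn") {
    cfg$conv1_maps <- model$cnn$conv1_maps
    cfg$conv2_maps <- model$cnn$conv2_maps
    cfg$dropout_rate <- model$cnn$dropout_rate
  }
  for (nm in names(cfg)) rhdf5::h5write(cfg[[nm]], path, paste0("config/", nm))
  for (nm in names(model$params))
    rhdf5::h5write(model$params[[nm]], path, paste0("params/", nm))
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  rd <- function(nm) rhdf5::h5read(path, paste0("config/", nm))
  type <- as.character(rd("type"))
  head <- head_config(hidden_units = as.integer(rd("hidden_units")),
                      n_classes = as.integer(rd("n_classes")))
  model <- if (type == "cnn") {
    build_model(cnn_config(conv1_maps = as.integer(rd("conv1_maps")),
                           conv2_maps = as.integer(rd("conv2_maps")),
                           dropout_rate = as.numeric(rd("dropout_rate"))),
                head, input_shape = as.integer(rd("input_shape")))
  } else {
    build_dense_model(head, input_dim = as.integer(rd("input_shape")))
  }
  params <- rhdf5::h5read(path, "params")
  model$params <- lapply(params, function(p) {
    if (is.null(dim(p)) && length(p) > 1L) as.numeric(p) else p
  })
  # scalars read back as length-1 arrays; biases must be plain vectors
  model$params <- lapply(model$params, function(p) {
    if (length(dim(p)) <= 1L) as.numeric(p) else p
  })
  cl <- as.character(rd("classes"))
  model$classes <- if (identical(cl, "")) NULL else cl
  model$trained <- as.logical(as.integer(rd("trained")))
  rhdf5::h5closeAll()
  model
}
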