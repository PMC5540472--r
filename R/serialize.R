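#' Save a fitted model to JSON
#'
#' Writes every weight matrix, offset vector, the head, the scalers, class
#' order and hyperparameters to a single JSON container at full numeric
#' precision, so a reloaded model reproduces predictions exactly.
#'
#' @param model A `caresig` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_caresig <- function(model, path) {
  ser_layer <- function(l) list(W_e = l$W_e, W_d = l$W_d,
                                b_e = l$b_e, b_d = l$b_d)
  obj <- list(
    architecture = model$architecture$kind,
    classes = model$classes,
    branches = lapply(model$branches, function(br)
      list(input = br$input, layers = lapply(br$layers, ser_layer))),
    joint = lapply(model$joint, ser_layer),
    head = model$head,
    scalers = lapply(model$scalers, function(s) list(min = s$min, max = s$max)),
    sparsity = unclass(model$sparsity),
    control = unclass(model$control))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [write_caresig()]
#'
#' @param path JSON file path.
#' @return A fitted `caresig` model.
#' @export
read_caresig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(x) do.call(rbind, lapply(x, function(r) unlist(r)))
  de_layer <- function(l) structure(
    list(W_e = as_mat(l$W_e), W_d = as_mat(l$W_d),
         b_e = unlist(l$b_e), b_d = unlist(l$b_d)),
    class = "autoencoder_layer")
  branches <- lapply(obj$branches, function(br)
    list(input = br$input, layers = lapply(br$layers, de_layer)))
  joint <- lapply(obj$joint, de_layer)
  scalers <- lapply(obj$scalers, function(s)
    structure(list(min = unlist(s$min), max = unlist(s$max)),
              class = "feature_scaler"))
  structure(list(architecture = architecture_spec(obj$architecture),
                 branches = branches, joint = joint,
                 head = as_mat(obj$head), classes = unlist(obj$classes),
                 scalers = scalers,
                 sparsity = do.call(sparsity_config, obj$sparsity),
                 control = do.call(train_control, obj$control),
                 trained = TRUE),
            class = "caresig")
}
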