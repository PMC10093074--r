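# Minimal layered-network representation.
#
# This is deliberately a self-contained toy substrate, not a deep-learning
# framework binding: the ledger protocol, not the backbone, is what the
# package contributes. Layers carry weights X, bias B, structural metadata
# (stride, filter size, output size) and a named activation, which is all
# the ledger needs to fingerprint, encrypt and restore them.
#
# Forward rule: a layer computes a(X * y) + B (activation applied to the
# linear map, bias added after), except the output layer which returns
# softmax(W y + b) so scores remain a probability vector.

.activations <- list(
  identity = function(x) x,
  relu     = function(x) pmax(x, 0),
  softmax  = function(x) { z <- exp(x - max(x)); z / sum(z) }
)

activation_fun <- function(name) {
  f <- .activations[[name]]
  if (is.null(f))
    scnn_error("scnn_config_error", sprintf(
      "unknown activation '%s' (available: %s)", name,
      paste(names(.activations), collapse = ", ")))
  f
}

new_layer <- function(name, kind, weights, bias, structural, activation,
                      class_labels = NULL) {
  structure(list(
    name = name, kind = kind,
    weights = weights, bias = bias,
    structural = structural, activation = activation,
    class_labels = class_labels
  ), class = "scnn_layer")
}

#' Dense (fully connected) layer
#'
#' @param weights numeric matrix, `units x inputs`.
#' @param bias numeric vector of length `units` (default zeros).
#' @param activation activation name: `"identity"`, `"relu"` or `"softmax"`.
#' @param name layer name (used by [extract_features()]).
#' @return an `scnn_layer`.
#' @export
dense_layer <- function(weights, bias = NULL, activation = "relu",
                        name = "dense") {
  weights <- as.matrix(weights)
  bias <- bias %||% numeric(nrow(weights))
  activation_fun(activation)
  new_layer(name, "dense", weights, as.numeric(bias),
            list(stride = 0L, filter_size = dim(weights),
                 output_size = nrow(weights)),
            activation)
}

#' Convolution layer (valid padding)
#'
#' @param weights numeric array `kh x kw x in_channels x out_channels`.
#' @param bias per-output-channel bias (default zeros).
#' @param stride positive integer stride.
#' @inheritParams dense_layer
#' @return an `scnn_layer`.
#' @export
conv_layer <- function(weights, bias = NULL, stride = 1L,
                       activation = "relu", name = "conv") {
  stopifnot(length(dim(weights)) == 4L)
  bias <- bias %||% numeric(dim(weights)[4])
  activation_fun(activation)
  new_layer(name, "conv", weights, as.numeric(bias),
            list(stride = as.integer(stride),
                 filter_size = dim(weights)[1:2],
                 output_size = dim(weights)[4]),
            activation)
}

#' Mean-pooling layer
#'
#' @param pool_size pooling window edge (square window).
#' @param stride stride, defaults to `pool_size`.
#' @inheritParams dense_layer
#' @return an `scnn_layer`.
#' @export
pooling_layer <- function(pool_size = 2L, stride = pool_size, name = "pool") {
  new_layer(name, "pooling", numeric(0), numeric(0),
            list(stride = as.integer(stride),
                 filter_size = c(pool_size, pool_size),
                 output_size = 0L),
            "identity")
}

#' Elementwise activation-only layer
#' @inheritParams dense_layer
#' @return an `scnn_layer`.
#' @export
activation_layer <- function(activation = "relu", name = "act") {
  activation_fun(activation)
  new_layer(name, "activation", numeric(0), numeric(0),
            list(stride = 0L, filter_size = 0L, output_size = 0L),
            activation)
}

#' Output (classification) layer
#'
#' A dense layer followed by softmax over `class_labels`. Scores are
#' `softmax(W y + b)`; prediction takes the arg-max with ties broken by
#' the lowest class index.
#'
#' @inheritParams dense_layer
#' @param class_labels ordered character vector of class names, one per row
#'   of `weights`.
#' @return an `scnn_layer`.
#' @export
output_layer <- function(weights, class_labels, bias = NULL, name = "output") {
  weights <- as.matrix(weights)
  stopifnot(length(class_labels) == nrow(weights))
  bias <- bias %||% numeric(nrow(weights))
  new_layer(name, "output", weights, as.numeric(bias),
            list(stride = 0L, filter_size = dim(weights),
                 output_size = nrow(weights)),
            "softmax", as.character(class_labels))
}

#' Assemble a layered model
#'
#' @param layers list of `scnn_layer` objects, in execution order.
#' @param input_shape integer vector `(height, width, channels)`.
#' @return an `scnn_model`.
#' @export
layered_model <- function(layers, input_shape) {
  stopifnot(length(layers) >= 1L, length(input_shape) == 3L)
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "scnn_layer"))
      scnn_error("scnn_config_error", sprintf("layer %d is not an scnn_layer", i))
    layers[[i]]$layer_id <- i
  }
  m <- structure(list(layers = layers, input_shape = as.integer(input_shape)),
                 class = "scnn_model")
  validate_model_shapes(m)
  m
}

# Walk the shape chain; error names the offending layer.
layer_output_shape <- function(layer, in_shape) {
  s <- layer$structural
  switch(layer$kind,
    conv = {
      if (length(in_shape) != 3L || in_shape[3] != dim(layer$weights)[3])
        scnn_error("scnn_shape_error", sprintf(
          "layer %s ('%s'): input channels %s do not match kernel depth %d",
          layer$layer_id %||% "?", layer$name,
          paste(in_shape, collapse = "x"), dim(layer$weights)[3]))
      k <- s$filter_size; st <- s$stride
      oh <- (in_shape[1] - k[1]) %/% st + 1L
      ow <- (in_shape[2] - k[2]) %/% st + 1L
      if (oh < 1L || ow < 1L)
        scnn_error("scnn_shape_error", sprintf(
          "layer %s ('%s'): kernel larger than input", layer$layer_id %||% "?",
          layer$name))
      c(oh, ow, dim(layer$weights)[4])
    },
    pooling = {
      k <- s$filter_size; st <- s$stride
      c((in_shape[1] - k[1]) %/% st + 1L, (in_shape[2] - k[2]) %/% st + 1L,
        in_shape[3])
    },
    activation = in_shape,
    {
      # dense / output act on the flattened input
      if (prod(in_shape) != ncol(layer$weights))
        scnn_error("scnn_shape_error", sprintf(
          "layer %s ('%s'): flattened input length %d does not match weight columns %d",
          layer$layer_id %||% "?", layer$name, prod(in_shape),
          ncol(layer$weights)))
      nrow(layer$weights)
    })
}

validate_model_shapes <- function(model) {
  shape <- model$input_shape
  for (layer in model$layers) shape <- layer_output_shape(layer, shape)
  invisible(shape)
}

conv_forward <- function(x, w, stride) {
  k <- dim(w)[1:2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  oh <- (dim(x)[1] - k[1]) %/% stride + 1L
  ow <- (dim(x)[2] - k[2]) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  out <- array(0, dim = c(oh, ow, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(0, oh, ow)
    for (ch in seq_len(cin)) {
      xc <- x[, , ch]
      for (di in seq_len(k[1])) for (dj in seq_len(k[2])) {
        wv <- w[di, dj, ch, co]
        if (wv != 0) acc <- acc + wv * xc[ri + di - 1L, ci + dj - 1L, drop = FALSE]
      }
    }
    out[, , co] <- acc
  }
  out
}

pool_forward <- function(x, k, stride) {
  oh <- (dim(x)[1] - k[1]) %/% stride + 1L
  ow <- (dim(x)[2] - k[2]) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  out <- array(0, dim = c(oh, ow, dim(x)[3]))
  for (ch in seq_len(dim(x)[3])) {
    acc <- matrix(0, oh, ow)
    for (di in seq_len(k[1])) for (dj in seq_len(k[2]))
      acc <- acc + x[ri + di - 1L, ci + dj - 1L, ch, drop = FALSE][, , 1]
    out[, , ch] <- acc / prod(k)
  }
  out
}

layer_forward <- function(layer, x) {
  a <- activation_fun(layer$activation)
  switch(layer$kind,
    conv = {
      z <- conv_forward(x, layer$weights, layer$structural$stride)
      z <- a(z)
      sweep(z, 3L, layer$bias, "+")
    },
    pooling = pool_forward(x, layer$structural$filter_size,
                           layer$structural$stride),
    activation = a(x),
    dense = as.numeric(a(layer$weights %*% as.numeric(x)) + layer$bias),
    output = as.numeric(a(layer$weights %*% as.numeric(x) + layer$bias)),
    scnn_error("scnn_config_error", paste("unknown layer kind", layer$kind)))
}

#' Plain (unsecured) forward pass
#'
#' Runs the model on one input tensor and returns the per-layer outputs
#' together with the final class scores. Fully deterministic.
#'
#' @param model an `scnn_model`.
#' @param input numeric array matching `model$input_shape`.
#' @return list with `scores` (numeric vector), `label` (character or `NA`
#'   when the last layer is not an output layer) and `outputs` (list of
#'   per-layer outputs `P_i`).
#' @export
forward_plain <- function(model, input) {
  input <- reshape_input(model, input)
  outputs <- vector("list", length(model$layers))
  x <- input
  shape <- model$input_shape
  for (i in seq_along(model$layers)) {
    shape <- layer_output_shape(model$layers[[i]], shape)  # errors name layer
    x <- layer_forward(model$layers[[i]], x)
    outputs[[i]] <- x
  }
  last <- model$layers[[length(model$layers)]]
  label <- if (identical(last$kind, "output"))
    last$class_labels[which.max(as.numeric(x))] else NA_character_
  list(scores = as.numeric(x), label = label, outputs = outputs)
}

reshape_input <- function(model, input) {
  if (length(input) != prod(model$input_shape))
    scnn_error("scnn_shape_error", sprintf(
      "input has %d values, model expects %s", length(input),
      paste(model$input_shape, collapse = "x")))
  array(as.numeric(input), dim = model$input_shape)
}

#' @export
print.scnn_model <- function(x, ...) {
  cat(sprintf("<scnn_model> %d layers, input %s\n", length(x$layers),
              paste(x$input_shape, collapse = "x")))
  for (l in x$layers)
    cat(sprintf("  [%d] %-10s %-12s params=%d\n", l$layer_id, l$kind, l$name,
                length(l$weights) + length(l$bias)))
  invisible(x)
}

# Parameterized layers are the tamper surface.
is_parameterized <- function(layer) length(layer$weights) > 0L
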