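# Canonical layer serialization.
#
# Every cryptographic statement the ledger makes is a statement about
# bytes, so the byte encoding must be total and canonical: a fixed-field
# JSON header (name, kind, activation, structural metadata, class labels,
# tensor shapes) followed by the weights in row-major order as 64-bit IEEE
# little-endian doubles, then the bias. Identical layers produce identical
# bytes; any single-bit parameter or metadata change produces different
# bytes, which is what makes the keyed digests tamper-evident.

layer_header <- function(layer) {
  list(
    name = layer$name,
    kind = layer$kind,
    activation = layer$activation,
    stride = as.integer(layer$structural$stride),
    filter_size = as.integer(layer$structural$filter_size),
    output_size = as.integer(layer$structural$output_size),
    class_labels = if (is.null(layer$class_labels)) character(0)
                   else layer$class_labels,
    wdim = as.integer(dim(layer$weights) %||% length(layer$weights)),
    bdim = length(layer$bias)
  )
}

header_bytes <- function(layer) {
  charToRaw(jsonlite::toJSON(layer_header(layer), auto_unbox = FALSE,
                             digits = NA))
}

row_major <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(d))))
}

#' Canonical byte serialization of a layer
#'
#' Deterministic encoding used for hashing, encryption and restoration:
#' structural metadata as a fixed-field record, then weights (row-major,
#' 64-bit IEEE little-endian), then bias. Rejects non-finite parameters.
#'
#' @param layer an `scnn_layer`.
#' @return a raw vector.
#' @seealso [canonical_deserialize()]
#' @export
canonical_serialize <- function(layer) {
  stopifnot(inherits(layer, "scnn_layer"))
  if (length(layer$weights) && !all(is.finite(layer$weights)))
    scnn_error("scnn_serialize_error",
               sprintf("layer '%s': non-finite weight value", layer$name))
  if (length(layer$bias) && !all(is.finite(layer$bias)))
    scnn_error("scnn_serialize_error",
               sprintf("layer '%s': non-finite bias value", layer$name))
  h <- header_bytes(layer)
  c(raw4(length(h)), h, doubles_raw(row_major(layer$weights)),
    doubles_raw(layer$bias))
}

#' Rebuild a layer from its canonical bytes
#'
#' Bit-exact inverse of [canonical_serialize()]; restoration from the
#' ledger goes through this path.
#'
#' @param bytes raw vector from [canonical_serialize()].
#' @return an `scnn_layer`.
#' @export
canonical_deserialize <- function(bytes) {
  hlen <- raw4_to_int(bytes[1:4])
  h <- jsonlite::fromJSON(rawToChar(bytes[4L + seq_len(hlen)]),
                          simplifyVector = TRUE)
  body <- raw_doubles(bytes[-seq_len(4L + hlen)])
  nw <- prod(h$wdim)
  if (length(body) != nw + h$bdim)
    scnn_error("scnn_serialize_error", "corrupt layer record: length mismatch")
  w <- body[seq_len(nw)]
  if (length(h$wdim) >= 2L)
    w <- aperm(array(w, dim = rev(h$wdim)), rev(seq_along(h$wdim)))
  bias <- body[nw + seq_len(h$bdim)]
  new_layer(h$name, h$kind, w, bias,
            list(stride = as.integer(h$stride),
                 filter_size = as.integer(h$filter_size),
                 output_size = as.integer(h$output_size)),
            h$activation,
            if (length(h$class_labels)) as.character(h$class_labels) else NULL)
}

# Bytes of (parameters_i - parameters_{i-1}) feeding the chained hash.
# When the numeric shapes align the delta is elementwise (prefixed by both
# layers' metadata records so structural edits still perturb the hash);
# otherwise the two full serializations are concatenated, because a shape
# change is itself a structural tamper.
param_delta_bytes <- function(current, previous) {
  if (is.null(previous)) return(canonical_serialize(current))
  same <- identical(dim(current$weights) %||% length(current$weights),
                    dim(previous$weights) %||% length(previous$weights)) &&
          length(current$bias) == length(previous$bias)
  if (same) {
    c(header_bytes(current), header_bytes(previous),
      doubles_raw(row_major(current$weights) - row_major(previous$weights)),
      doubles_raw(current$bias - previous$bias))
  } else {
    c(canonical_serialize(current), canonical_serialize(previous))
  }
}

#' Write a model snapshot container
#'
#' Single-file container: magic bytes, a JSON manifest (layer order, kinds,
#' shapes, structural metadata, class labels) and the raw little-endian
#' tensors. Round-trips bit-exactly.
#'
#' @param model an `scnn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_snapshot <- function(model, path) {
  stopifnot(inherits(model, "scnn_model"))
  blobs <- lapply(model$layers, canonical_serialize)
  manifest <- charToRaw(jsonlite::toJSON(list(
    format = "scnn-snapshot-v1",
    input_shape = model$input_shape,
    n_layers = length(model$layers),
    blob_lengths = vapply(blobs, length, integer(1))
  ), auto_unbox = FALSE, digits = NA))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("SCNNSNAP"), con)
  writeBin(raw4(length(manifest)), con)
  writeBin(manifest, con)
  for (b in blobs) writeBin(b, con)
  invisible(path)
}

#' Read a model snapshot container
#' @param path file written by [write_model_snapshot()].
#' @return an `scnn_model`.
#' @export
read_model_snapshot <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(rawToChar(bytes[1:8]), "SCNNSNAP"))
    scnn_error("scnn_serialize_error", "not a model snapshot file")
  mlen <- raw4_to_int(bytes[9:12])
  man <- jsonlite::fromJSON(rawToChar(bytes[12L + seq_len(mlen)]))
  pos <- 12L + mlen
  layers <- vector("list", man$n_layers)
  for (i in seq_len(man$n_layers)) {
    len <- man$blob_lengths[i]
    layers[[i]] <- canonical_deserialize(bytes[pos + seq_len(len)])
    pos <- pos + len
  }
  layered_model(layers, man$input_shape)
}
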