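# Deep-feature fusion: extraction from named layers, serial fusion,
# mode-value ordering.

#' Registry of backbone feature layers
#'
#' Which layer of each pretrained backbone yields the feature vector, and
#' its width: InceptionV3 "avg pool" (2048), GoogleNet "global avg pool"
#' (1000), DenseNet201 "fc" (1000). The registry drives the fused
#' dimensionality: 2048 + 1000 + 1000 = 4048.
#'
#' @return data.frame with columns `backbone`, `layer`, `dim`.
#' @export
feature_layer_registry <- function() {
  data.frame(
    backbone = c("inceptionv3", "googlenet", "densenet201"),
    layer = c("avg pool", "global avg pool", "fc"),
    dim = c(2048L, 1000L, 1000L),
    stringsAsFactors = FALSE
  )
}

#' Extract per-image features from a named layer
#'
#' Row i is the flattened output of the named layer for image i.
#'
#' @param model an `scnn_model` whose layers carry names.
#' @param layer_name name of the feature layer.
#' @param images list of input arrays.
#' @return numeric matrix, `length(images)` x layer width.
#' @export
extract_features <- function(model, layer_name, images) {
  names_avail <- vapply(model$layers, `[[`, character(1), "name")
  idx <- which(names_avail == layer_name)
  if (!length(idx))
    scnn_error("scnn_config_error", sprintf(
      "unknown layer '%s'; available: %s", layer_name,
      paste(names_avail, collapse = ", ")))
  idx <- idx[1]
  rows <- lapply(images, function(img)
    as.numeric(forward_plain(model, img)$outputs[[idx]]))
  do.call(rbind, rows)
}

#' Serially fuse feature matrices
#'
#' Row-wise concatenation in argument order; the fused width is the sum
#' of the input widths (the registry widths 2048/1000/1000 fuse to 4048).
#'
#' @param ... feature matrices with equal row counts.
#' @param labels optional class label vector (length = row count).
#' @return an `scnn_feature_table`: list with `x` (matrix), `y` (factor or
#'   `NULL`), `feature_order` (identity permutation until
#'   [mode_order()] runs).
#' @export
serial_fuse <- function(..., labels = NULL) {
  mats <- lapply(list(...), as.matrix)
  stopifnot(length(mats) >= 1L)
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1L)
    scnn_error("scnn_config_error", sprintf(
      "row-count mismatch across feature matrices: %s",
      paste(nr, collapse = ", ")))
  x <- do.call(cbind, mats)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    labels <- factor(labels)
  }
  structure(list(x = x, y = labels, feature_order = seq_len(ncol(x))),
            class = "scnn_feature_table")
}

#' @export
print.scnn_feature_table <- function(x, ...) {
  cat(sprintf("<scnn_feature_table> %d samples x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$y)) "" else sprintf(
                ", %d classes", nlevels(x$y))))
  invisible(x)
}

# Mode of a rounded numeric vector: the most frequent value; among equally
# frequent values the smallest qualifies.
mode_value <- function(v, decimals) {
  r <- round(v, decimals)
  tab <- table(r)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Order fused features by mode value
#'
#' Each feature's values are rounded to `decimals` places, the mode is
#' taken (ties between equally frequent values resolve to the smallest),
#' and features are reordered by descending mode; ties between features
#' keep the original index order. The permutation is recorded in
#' `feature_order`, so the ordering is a bijection: no feature is lost or
#' duplicated.
#'
#' @param table an `scnn_feature_table`.
#' @param decimals rounding used to quantize continuous values before the
#'   mode is taken (default 2).
#' @return the reordered `scnn_feature_table`.
#' @export
mode_order <- function(table, decimals = 2L) {
  stopifnot(inherits(table, "scnn_feature_table"), nrow(table$x) >= 1L)
  modes <- apply(table$x, 2L, mode_value, decimals = decimals)
  perm <- order(-modes, seq_along(modes))
  table$x <- table$x[, perm, drop = FALSE]
  table$feature_order <- table$feature_order[perm]
  table
}

#' Shannon entropy of a probability vector
#'
#' Natural-log entropy with the `0 log 0 = 0` convention. Rejects
#' negative entries and vectors not summing to 1 (tolerance 1e-9).
#'
#' @param p numeric probability vector.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0))
    scnn_error("scnn_config_error", "negative probability")
  if (abs(sum(p) - 1) > 1e-9)
    scnn_error("scnn_config_error", "probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

# Pooled entropy of the selected features: values of all selected columns
# pooled over samples, dropped into 10 quantile bins, normalized histogram.
pooled_feature_entropy <- function(x, mask, bins = 10L) {
  v <- as.numeric(x[, mask, drop = FALSE])
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(0)  # all values identical: degenerate, H = 0
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = length(br) - 1L)
  shannon_entropy(cnt / sum(cnt))
}

#' Write a feature table to CSV
#'
#' Header row, one feature per column, last column `label` (omitted when
#' the table is unlabeled). Values are written in full precision so the
#' round trip through [read_feature_table()] is lossless.
#'
#' @param table an `scnn_feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "scnn_feature_table"))
  df <- as.data.frame(format(table$x, digits = 17, trim = TRUE,
                             scientific = TRUE),
                      stringsAsFactors = FALSE)
  colnames(df) <- colnames(table$x)
  if (!is.null(table$y)) df$label <- as.character(table$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV written by [write_feature_table()] (or any CSV with a
#'   header and an optional final `label` column).
#' @return an `scnn_feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_label <- identical(colnames(df)[ncol(df)], "label")
  labels <- if (has_label) df[[ncol(df)]] else NULL
  if (has_label) df <- df[, -ncol(df), drop = FALSE]
  serial_fuse(as.matrix(df), labels = labels)
}
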