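# Gaussian naive Bayes, the entropy-gated fitness, and the pluggable
# classifier interface.
#
# NB is authored here rather than imported: the entropy-controlled NB
# fitness is part of the method itself, and features are continuous, so a
# Gaussian variant with lambda acting as Laplace-style smoothing on class
# priors and as a variance floor is the natural reading.

nb_fit <- function(x, y, lambda = 1) {
  y <- factor(y)
  k <- nlevels(y)
  n <- nrow(x)
  pooled_var <- mean(apply(x, 2L, stats::var)) + 1e-12
  means <- vars <- matrix(0, k, ncol(x))
  priors <- numeric(k)
  for (c in seq_len(k)) {
    xc <- x[y == levels(y)[c], , drop = FALSE]
    priors[c] <- (nrow(xc) + lambda) / (n + k * lambda)
    means[c, ] <- colMeans(xc)
    v <- apply(xc, 2L, stats::var)
    v[is.na(v)] <- 0
    # lambda-scaled variance floor (1% of pooled variance): keeps
    # near-constant columns (e.g. clipped pixels) from dominating the
    # log-likelihood through spuriously tiny variances
    vars[c, ] <- v + lambda * 0.01 * pooled_var + 1e-12
  }
  list(levels = levels(y), priors = priors, means = means, vars = vars)
}

nb_predict <- function(fit, x) {
  k <- length(fit$levels)
  ll <- matrix(0, nrow(x), k)
  for (c in seq_len(k)) {
    mu <- fit$means[c, ]; v <- fit$vars[c, ]
    ll[, c] <- log(fit$priors[c]) -
      0.5 * rowSums(sweep(sweep(x, 2L, mu)^2, 2L, v, "/") +
                    rep(log(2 * pi * v), each = nrow(x)))
  }
  fit$levels[max.col(ll, ties.method = "first")]
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Entropy-gated naive Bayes fitness of a feature mask
#'
#' The chromosome's selected features are pooled over samples, binned into
#' 10 quantile bins and their Shannon entropy `H` computed; when `H >
#' tau` the fitness is 0 (the gate rejects unstructured subsets). Below
#' the gate, the fitness is the stratified k-fold cross-validated accuracy
#' of a Gaussian naive Bayes on the masked columns, with `lambda`
#' smoothing class priors and flooring per-class variances.
#'
#' @param table an `scnn_feature_table` with labels.
#' @param mask logical or 0/1 vector over features; at least one bit set.
#' @param cfg a [ga_config()] (supplies `lambda`, `tau`, `folds`, `seed`).
#' @return fitness in `[0, 1]`.
#' @export
nb_fitness <- function(table, mask, cfg = ga_config()) {
  stopifnot(inherits(table, "scnn_feature_table"))
  mask <- as.logical(mask)
  if (!any(mask))
    scnn_error("scnn_config_error", "mask selects no feature")
  if (is.null(table$y) || nlevels(table$y) < 2L)
    scnn_error("scnn_config_error", "fitness needs labels with >= 2 classes")
  h <- pooled_feature_entropy(table$x, mask)
  if (h > cfg$tau) return(0)
  x <- table$x[, mask, drop = FALSE]
  y <- table$y
  folds <- stratified_folds(y, cfg$folds, derive_seed(cfg$seed, "cv-folds"))
  correct <- 0L
  for (f in seq_len(cfg$folds)) {
    tr <- folds != f
    fit <- nb_fit(x[tr, , drop = FALSE], y[tr], cfg$lambda)
    pred <- nb_predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == as.character(y[!tr]))
  }
  correct / length(y)
}

## ---- pluggable classifiers ----------------------------------------------

nearest_centroid_fit <- function(x, y, ...) {
  y <- factor(y)
  cent <- t(vapply(levels(y), function(lv)
    colMeans(x[y == lv, , drop = FALSE]), numeric(ncol(x))))
  list(levels = levels(y), centroids = cent)
}
nearest_centroid_predict <- function(fit, x) {
  # linear discriminant with identity covariance: w = c, b = -|c|^2/2
  scores <- x %*% t(fit$centroids) -
    rep(rowSums(fit$centroids^2) / 2, each = nrow(x))
  fit$levels[max.col(scores, ties.method = "first")]
}

.classifiers <- list(
  gaussian_nb = list(fit = nb_fit, predict = nb_predict),
  nearest_centroid = list(fit = nearest_centroid_fit,
                          predict = nearest_centroid_predict)
)

macro_metrics <- function(truth, pred, levels) {
  cm <- table(factor(truth, levels), factor(pred, levels))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(cm),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = levels, precision = prec,
                              recall = rec, f1 = f1, row.names = NULL))
}

#' Classify on selected features
#'
#' Trains a built-in classifier on a stratified split (default 70/30,
#' fixed seed) restricted to the selected feature indices and reports
#' macro-averaged accuracy, precision, recall and F1.
#'
#' @param table an `scnn_feature_table` with labels.
#' @param indices non-empty feature column indices.
#' @param classifier `"gaussian_nb"` or `"nearest_centroid"`.
#' @param split training fraction (default 0.7).
#' @param seed split seed.
#' @param lambda smoothing for the NB classifier.
#' @return list with the macro metrics, `per_class` breakdown, and the
#'   split sizes.
#' @export
classify <- function(table, indices, classifier = "gaussian_nb",
                     split = 0.7, seed = 1L, lambda = 1) {
  stopifnot(inherits(table, "scnn_feature_table"))
  if (!length(indices))
    scnn_error("scnn_config_error", "indices must be non-empty")
  clf <- .classifiers[[classifier]]
  if (is.null(clf))
    scnn_error("scnn_config_error", sprintf(
      "unknown classifier '%s'; built-ins: %s", classifier,
      paste(names(.classifiers), collapse = ", ")))
  x <- table$x[, indices, drop = FALSE]
  y <- factor(table$y)
  # Content-addressed stratified split: rows rank within their class by a
  # seeded hash of their feature bytes, so the split is deterministic AND
  # invariant to row shuffling of the table.
  seed_bytes <- derive_bytes(seed, "split", 16L)
  keys <- vapply(seq_len(nrow(x)), function(i)
    paste(as.character(openssl::sha256(c(seed_bytes, doubles_raw(x[i, ])))),
          collapse = ""), character(1))
  tr <- logical(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[order(keys[idx], idx)]
    tr[idx[seq_len(max(1L, round(split * length(idx))))]] <- TRUE
  }
  fit <- clf$fit(x[tr, , drop = FALSE], y[tr], lambda)
  pred <- clf$predict(fit, x[!tr, , drop = FALSE])
  m <- macro_metrics(as.character(y[!tr]), pred, levels(y))
  c(m, list(n_train = sum(tr), n_test = sum(!tr), classifier = classifier))
}
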