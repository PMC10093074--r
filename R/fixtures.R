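# Synthetic fixtures: class-structured toy images in the four-class
# brain-MRI folder layout, small named-feature-layer backbones, planted
# informative-feature tables, and random toy models for protocol tests.
# Everything is a pure function of config + seed, so regenerated fixtures
# are byte-identical and every downstream test is hermetic.

#' Image generator configuration
#'
#' Emulates a class-per-folder MRI-style dataset at desk scale: four
#' classes, 40 images per class, 64x64 grayscale. Class signal is a
#' per-class blob recipe (count, intensity, radius, position region) on a
#' smooth elliptical "head" background plus Gaussian pixel noise; the
#' recipes are distinct enough that a pixel-mean naive Bayes beats chance.
#' No radiological realism is attempted or implied.
#'
#' @param classes ordered class labels.
#' @param per_class_n images per class.
#' @param image_size `(height, width, channels)`; grayscale only.
#' @param noise_std pixel noise standard deviation.
#' @param seed integer seed.
#' @return an `image_gen_config`.
#' @export
image_gen_config <- function(classes = c("no_tumor", "meningioma",
                                         "pituitary", "glioma"),
                             per_class_n = 40L,
                             image_size = c(64L, 64L, 1L),
                             noise_std = 0.05, seed = 1L) {
  if (!length(classes))
    scnn_error("scnn_config_error", "at least one class is required")
  stopifnot(per_class_n >= 1L, length(image_size) == 3L, image_size[3] == 1L)
  structure(list(classes = as.character(classes),
                 per_class_n = as.integer(per_class_n),
                 image_size = as.integer(image_size),
                 noise_std = noise_std, seed = as.integer(seed)),
            class = "image_gen_config")
}

# Blob recipes per class slot (recycled if more classes than recipes):
# list(count range, intensity, radius fraction, centre region).
.blob_recipes <- list(
  list(count = 0L, intensity = 0.0, radius = 0.00, region = c(0.5, 0.5)),
  list(count = 1L, intensity = 0.9, radius = 0.10, region = c(0.25, 0.30)),
  list(count = 1L, intensity = 1.0, radius = 0.06, region = c(0.50, 0.52)),
  list(count = 3L, intensity = 0.6, radius = 0.16, region = c(0.70, 0.65))
)

gen_one_image <- function(class_idx, cfg, rseed) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  rec <- .blob_recipes[[(class_idx - 1L) %% length(.blob_recipes) + 1L]]
  with_seed(rseed, {
    yy <- matrix(seq_len(h) / h, h, w)
    xx <- matrix(rep(seq_len(w) / w, each = h), h, w)
    # elliptical head on dark background
    img <- 0.35 * (((yy - 0.5) / 0.45)^2 + ((xx - 0.5) / 0.38)^2 < 1)
    if (rec$count > 0L) {
      for (b in seq_len(rec$count)) {
        cy <- rec$region[1] + stats::rnorm(1, 0, 0.04)
        cx <- rec$region[2] + stats::rnorm(1, 0, 0.04)
        r <- rec$radius * (1 + stats::runif(1, -0.25, 0.25))
        img <- img + rec$intensity *
          exp(-(((yy - cy)^2 + (xx - cx)^2) / (2 * r^2)))
      }
    }
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_std), h, w)
    array(pmin(pmax(img, 0), 1), dim = cfg$image_size)
  })
}

#' Generate a labeled image set in memory
#'
#' @param cfg an [image_gen_config()].
#' @return list with `images` (list of arrays) and `labels` (character).
#' @export
gen_image_set <- function(cfg = image_gen_config()) {
  images <- list(); labels <- character(0)
  for (ci in seq_along(cfg$classes)) {
    for (j in seq_len(cfg$per_class_n)) {
      images[[length(images) + 1L]] <-
        gen_one_image(ci, cfg, derive_seed(cfg$seed,
                                           sprintf("img/%d/%d", ci, j)))
      labels <- c(labels, cfg$classes[ci])
    }
  }
  list(images = images, labels = labels)
}

#' Write a class-per-folder image dataset to disk
#'
#' 8-bit grayscale PNGs under one folder per class, plus a
#' `manifest.csv` (`path,label`). Deterministic under the config seed:
#' regenerating yields byte-identical files.
#'
#' @param cfg an [image_gen_config()].
#' @param dir output directory.
#' @return the manifest data.frame, invisibly.
#' @export
gen_images <- function(cfg = image_gen_config(), dir) {
  set <- gen_image_set(cfg)
  rows <- vector("list", length(set$images))
  counter <- integer(length(cfg$classes)); names(counter) <- cfg$classes
  for (i in seq_along(set$images)) {
    lab <- set$labels[i]
    counter[lab] <- counter[lab] + 1L
    d <- file.path(dir, lab)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    # quantize to 8 bit so the PNG round trip is exact
    img <- round(set$images[[i]][, , 1] * 255) / 255
    path <- file.path(d, sprintf("%s_%03d.png", lab, counter[lab]))
    png::writePNG(img, path)
    rows[[i]] <- data.frame(path = path, label = lab)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a class-per-folder dataset from its manifest
#' @param dir directory written by [gen_images()].
#' @return list with `images` and `labels`.
#' @export
read_images <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(p)
    array(img, dim = c(dim(img)[1], dim(img)[2], 1L))
  })
  list(images = images, labels = manifest$label)
}

## ---- toy backbones -------------------------------------------------------

toy_backbone <- function(name, feature_layer, width, input_shape, classes,
                         seed) {
  h <- input_shape[1]
  with_seed(seed, {
    conv_w <- array(stats::rnorm(3 * 3 * 1 * 2, 0, 0.5), c(3, 3, 1, 2))
    conv <- conv_layer(conv_w, stride = 2L, activation = "relu",
                       name = "conv1")
    pool <- pooling_layer(2L, name = "pool1")
    ph <- ((h - 3L) %/% 2L + 1L - 2L) %/% 2L + 1L
    flat <- ph * ph * 2L
    feat <- dense_layer(matrix(stats::rnorm(width * flat, 0, 1 / sqrt(flat)),
                               width, flat),
                        activation = "relu", name = feature_layer)
    out <- output_layer(matrix(stats::rnorm(length(classes) * width, 0,
                                            1 / sqrt(width)),
                               length(classes), width),
                        class_labels = classes, name = "softmax")
    layered_model(list(conv, pool, feat, out), input_shape)
  })
}

#' Build the three toy backbones
#'
#' Scaled stand-ins for the three pretrained backbones, each exposing a
#' named feature layer: `"avg pool"`, `"global avg pool"` and `"fc"`. The
#' default widths (32, 16, 16) fuse to 64 so tests run in seconds; with
#' `paper_widths = TRUE` the registry widths (2048, 1000, 1000) are used
#' and the fusion width is 4048, which exists solely to exercise the
#' dimensionality contract.
#'
#' @param seed integer seed (deterministic weights).
#' @param paper_widths emit the full registry widths.
#' @param input_shape input image shape (default 64x64x1).
#' @param classes output class labels.
#' @return named list of three `scnn_model`s
#'   (`inceptionv3`, `googlenet`, `densenet201`).
#' @export
build_toy_backbones <- function(seed = 1L, paper_widths = FALSE,
                                input_shape = c(64L, 64L, 1L),
                                classes = c("no_tumor", "meningioma",
                                            "pituitary", "glioma")) {
  reg <- feature_layer_registry()
  widths <- if (paper_widths) reg$dim else c(32L, 16L, 16L)
  models <- lapply(seq_len(3L), function(i)
    toy_backbone(reg$backbone[i], reg$layer[i], widths[i], input_shape,
                 classes, derive_seed(seed, paste0("backbone/", i))))
  names(models) <- reg$backbone
  models
}

## ---- planted feature tables ---------------------------------------------

#' Planted-informative-feature table generator
#'
#' Informative columns carry class-dependent means; the rest are pure
#' standard normal noise. `effect_size` is the total between-class
#' Mahalanobis separation of the informative block: the per-feature mean
#' shift is `effect_size / sqrt(n_informative)`, so every informative
#' feature is individually weak but jointly they separate the classes —
#' which is what makes ">= x% of planted features recovered" a meaningful
#' selection benchmark rather than a saturated one.
#'
#' @param n_samples rows (default 300).
#' @param n_features columns (default 200).
#' @param n_informative planted informative columns (default 20).
#' @param effect_size aggregate class separation (default 2.0).
#' @param n_classes classes, evenly sized (default 2).
#' @param seed integer seed.
#' @return list with `table` (an `scnn_feature_table`) and `informative`
#'   (ground-truth column indices).
#' @export
gen_planted_table <- function(n_samples = 300L, n_features = 200L,
                              n_informative = 20L, effect_size = 2.0,
                              n_classes = 2L, seed = 1L) {
  stopifnot(n_informative <= n_features, n_classes >= 2L)
  delta <- effect_size / sqrt(n_informative)
  with_seed(derive_seed(seed, "planted"), {
    y <- factor(rep_len(paste0("c", seq_len(n_classes)), n_samples))
    x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    # class positions evenly spaced in [-1/2, 1/2] along every informative axis
    pos <- (as.integer(y) - 1) / max(1L, n_classes - 1L) - 0.5
    for (j in informative) x[, j] <- x[, j] + delta * pos
    tab <- serial_fuse(x, labels = y)
    list(table = tab, informative = informative)
  })
}

## ---- random toy models for protocol tests -------------------------------

#' Random small layered model
#'
#' Dense stack (ReLU) ending in a softmax output layer; used as the
#' subject of hash-chain, wrapping and attack tests.
#'
#' @param n_layers total layers including the output layer (>= 2).
#' @param seed integer seed.
#' @param input_shape input tensor shape.
#' @param n_classes output classes.
#' @return an `scnn_model`.
#' @export
random_layered_model <- function(n_layers = 5L, seed = 1L,
                                 input_shape = c(4L, 4L, 1L),
                                 n_classes = 4L) {
  stopifnot(n_layers >= 2L)
  with_seed(derive_seed(seed, "toy-model"), {
    sizes <- c(prod(input_shape),
               pmax(n_classes, sample(4:12, n_layers - 1L, replace = TRUE)))
    layers <- vector("list", n_layers)
    for (i in seq_len(n_layers - 1L)) {
      layers[[i]] <- dense_layer(
        matrix(stats::rnorm(sizes[i + 1L] * sizes[i], 0, 1 / sqrt(sizes[i])),
               sizes[i + 1L], sizes[i]),
        bias = stats::rnorm(sizes[i + 1L], 0, 0.1),
        activation = "relu", name = paste0("dense", i))
    }
    layers[[n_layers]] <- output_layer(
      matrix(stats::rnorm(n_classes * sizes[n_layers], 0,
                          1 / sqrt(sizes[n_layers])),
             n_classes, sizes[n_layers]),
      class_labels = paste0("class", seq_len(n_classes)),
      name = "softmax")
    layered_model(layers, input_shape)
  })
}

#' Fit a template-matching benchmark model to labeled images
#'
#' conv + mean-pool front end (fixed, seeded) followed by a
#' nearest-centroid output layer over the pooled features (weights = class
#' centroids, bias = -|c|^2 / 2): a linear template matcher that beats
#' chance on the synthetic blob classes and degrades under weight noise,
#' which is exactly what the attack-severity benchmark needs.
#'
#' @param images list of input arrays.
#' @param labels class labels (character).
#' @param seed seed for the fixed convolution front end.
#' @return an `scnn_model`.
#' @export
fit_template_model <- function(images, labels, seed = 1L) {
  stopifnot(length(images) >= 2L, length(images) == length(labels))
  input_shape <- dim(images[[1]])
  with_seed(derive_seed(seed, "template-conv"), {
    conv_w <- array(0, c(3, 3, 1, 2))
    conv_w[, , 1, 1] <- 1 / 9                      # smoothing filter
    conv_w[, , 1, 2] <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3) # laplacian
    conv <- conv_layer(conv_w, stride = 2L, activation = "relu", name = "conv1")
    pool <- pooling_layer(4L, name = "pool1")
  })
  front <- layered_model(list(conv, pool), input_shape)
  feats <- t(vapply(images, function(img)
    as.numeric(forward_plain(front, img)$outputs[[2]]),
    numeric(prod(layer_output_shape(pool,
      layer_output_shape(conv, input_shape))))))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  cent <- t(vapply(classes, function(lv)
    colMeans(feats[labels == lv, , drop = FALSE]), numeric(ncol(feats))))
  out <- output_layer(cent, classes, bias = -rowSums(cent^2) / 2,
                      name = "softmax")
  layered_model(list(conv, pool, out), input_shape)
}
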