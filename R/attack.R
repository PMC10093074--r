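# Three-severity model-parameter tampering simulator.
#
# Severities mirror the attack taxonomy the ledger is designed to catch:
#   type 0 (mild)    — interchange the output class labels only;
#   type 1 (average) — seeded Gaussian noise added to the weights of every
#                      fully connected (dense/output) layer;
#   type 2 (severe)  — Gaussian noise on every parameterized layer's
#                      weights plus structural edits: stride + 1 on the
#                      first convolution and a permuted output-label order.
# Noise is N(noise_mean, noise_std); biases are untouched (the attack
# grammar names `weights` only).

#' Specify a tampering attack
#'
#' @param attack_type 0 (mild / class interchange), 1 (average /
#'   dense-layer noise) or 2 (severe / all-layer noise + structural edits).
#' @param noise_std Gaussian noise standard deviation (types 1 and 2);
#'   must be positive there. Default 0.1.
#' @param noise_mean Gaussian noise mean, default 0.
#' @param permutation `"reverse"` (default), `"random"` (seeded), or an
#'   explicit integer permutation of the class labels.
#' @param seed integer seed; same spec + seed gives a byte-identical
#'   attacked copy.
#' @return an `scnn_attack_spec`.
#' @export
attack_spec <- function(attack_type, noise_std = 0.1, noise_mean = 0,
                        permutation = "reverse", seed = 1L) {
  if (!attack_type %in% 0:2)
    scnn_error("scnn_config_error", "attack_type must be 0, 1 or 2")
  if (attack_type %in% 1:2 && !(is.numeric(noise_std) && noise_std > 0))
    scnn_error("scnn_config_error", "noise_std must be > 0 for attack types 1 and 2")
  structure(list(attack_type = as.integer(attack_type),
                 noise_std = noise_std, noise_mean = noise_mean,
                 permutation = permutation, seed = as.integer(seed)),
            class = "scnn_attack_spec")
}

label_permutation <- function(labels, permutation, seed) {
  k <- length(labels)
  if (is.numeric(permutation)) {
    stopifnot(length(permutation) == k, setequal(permutation, seq_len(k)))
    as.integer(permutation)
  } else if (identical(permutation, "reverse")) {
    rev(seq_len(k))
  } else if (identical(permutation, "random")) {
    with_seed(derive_seed(seed, "label-perm"), sample.int(k))
  } else {
    scnn_error("scnn_config_error", "permutation must be 'reverse', 'random' or an index vector")
  }
}

add_noise <- function(w, spec, layer_id) {
  noise <- with_seed(derive_seed(spec$seed, paste0("noise/", layer_id)),
                     stats::rnorm(length(w), spec$noise_mean, spec$noise_std))
  w + array(noise, dim = dim(w) %||% length(w))
}

#' Apply a tampering attack to a model copy
#'
#' The original model is never modified. Type 1 requires at least one
#' fully connected layer. Severe structural edits may leave the copy
#' unable to run a forward pass (shape break) — it remains restorable
#' from the ledger, which never needs a forward pass.
#'
#' @param model an `scnn_model`.
#' @param spec an [attack_spec()].
#' @return list with `model` (attacked copy) and `report`
#'   (`scnn_attack_report`: `layers_touched`, `parameter_count_changed`,
#'   `permutation_applied`, `seed`).
#' @export
apply_attack <- function(model, spec) {
  stopifnot(inherits(model, "scnn_model"), inherits(spec, "scnn_attack_spec"))
  layers <- model$layers
  touched <- integer(0)
  n_changed <- 0L
  perm <- NULL
  out_id <- which(vapply(layers, function(l) identical(l$kind, "output"),
                         logical(1)))

  permute_labels <- function() {
    if (!length(out_id))
      scnn_error("scnn_config_error", "model has no output layer to attack")
    i <- out_id[1]
    perm <<- label_permutation(layers[[i]]$class_labels, spec$permutation,
                               spec$seed)
    layers[[i]]$class_labels <<- layers[[i]]$class_labels[perm]
    touched <<- union(touched, i)
  }

  if (spec$attack_type == 0L) {
    permute_labels()
    if (identical(perm, seq_along(perm))) touched <- integer(0)  # no-op swap
  } else if (spec$attack_type == 1L) {
    dense_ids <- which(vapply(layers, function(l)
      l$kind %in% c("dense", "output"), logical(1)))
    if (!length(dense_ids))
      scnn_error("scnn_config_error",
                 "attack type 1 needs at least one fully connected layer")
    for (i in dense_ids) {
      layers[[i]]$weights <- add_noise(layers[[i]]$weights, spec, i)
      n_changed <- n_changed + length(layers[[i]]$weights)
      touched <- union(touched, i)
    }
  } else {
    param_ids <- which(vapply(layers, is_parameterized, logical(1)))
    for (i in param_ids) {
      layers[[i]]$weights <- add_noise(layers[[i]]$weights, spec, i)
      n_changed <- n_changed + length(layers[[i]]$weights)
      touched <- union(touched, i)
    }
    conv_ids <- which(vapply(layers, function(l) identical(l$kind, "conv"),
                             logical(1)))
    if (length(conv_ids)) {
      i <- conv_ids[1]
      layers[[i]]$structural$stride <- layers[[i]]$structural$stride + 1L
      touched <- union(touched, i)
    }
    permute_labels()
  }

  attacked <- model
  attacked$layers <- layers  # bypass shape validation: breakage is the point
  report <- structure(list(layers_touched = sort(touched),
                           parameter_count_changed = n_changed,
                           permutation_applied = perm,
                           attack_type = spec$attack_type,
                           seed = spec$seed),
                      class = "scnn_attack_report")
  list(model = attacked, report = report)
}

#' Measure an attack's impact on a probe set
#'
#' Reports probe accuracy before/after the attack and whether a ledger
#' audit of the attacked copy flags it. A structurally broken model that
#' cannot run the probe scores accuracy 0. Detection wraps the clean
#' model, swaps in the attacked layers and audits.
#'
#' @param model clean `scnn_model`.
#' @param attacked attacked copy from [apply_attack()].
#' @param probe_set list with `images` (list of arrays) and `labels`
#'   (character vector).
#' @param seed wrap seed for the detection audit.
#' @param suite [cipher_suite()] for the detection audit.
#' @return list `accuracy_before`, `accuracy_after`, `detected_by_secure`,
#'   `flagged_layers`.
#' @export
evaluate_attack_impact <- function(model, attacked, probe_set, seed = 1L,
                                   suite = cipher_suite()) {
  if (is.null(probe_set$images) || !length(probe_set$images))
    scnn_error("scnn_config_error", "empty probe set")
  stopifnot(length(probe_set$images) == length(probe_set$labels))
  acc <- function(m) {
    pred <- vapply(probe_set$images, function(img) {
      tryCatch(forward_plain(m, img)$label, error = function(e) NA_character_)
    }, character(1))
    mean(!is.na(pred) & pred == as.character(probe_set$labels))
  }
  secure <- wrap_secure(model, suite, seed)
  report <- audit_model(tamper_secure(secure, attacked))
  list(accuracy_before = acc(model),
       accuracy_after = acc(attacked),
       detected_by_secure = !report$clean,
       flagged_layers = report$tampered_layer_ids)
}
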