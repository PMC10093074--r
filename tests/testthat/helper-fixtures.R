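# Shared fixtures: tiny models and probe sets, built in code.

tiny_model <- function(seed = 1L, n_layers = 4L)
  random_layered_model(n_layers, seed = seed, input_shape = c(3L, 3L, 1L),
                       n_classes = 3L)

tiny_input <- function(seed = 1L) {
  set.seed(seed)
  array(runif(9), c(3, 3, 1))
}

# 2-class model that classifies its probe set perfectly: inputs are
# one-hot 2-vectors, weights the identity, so argmax(input) = class.
perfect_two_class <- function() {
  out <- output_layer(diag(2) * 10, class_labels = c("a", "b"),
                      name = "softmax")
  layered_model(list(out), c(1L, 2L, 1L))
}
perfect_probe <- function() {
  list(images = list(array(c(1, 0), c(1, 2, 1)), array(c(0, 1), c(1, 2, 1)),
                     array(c(0.9, 0.1), c(1, 2, 1))),
       labels = c("a", "b", "a"))
}

# small conv model so structural (stride) attacks have a target
conv_toy_model <- function(seed = 1L) {
  set.seed(seed)
  conv <- conv_layer(array(rnorm(3 * 3 * 1 * 2, 0, 0.4), c(3, 3, 1, 2)),
                     stride = 1L, name = "conv1")
  pool <- pooling_layer(2L, name = "pool1")
  dense <- dense_layer(matrix(rnorm(6 * 18, 0, 0.2), 6, 18), name = "dense1")
  out <- output_layer(matrix(rnorm(2 * 6, 0, 0.5), 2, 6),
                      class_labels = c("a", "b"), name = "softmax")
  layered_model(list(conv, pool, dense, out), c(8L, 8L, 1L))
}

small_image_cfg <- function(seed = 1L, per_class_n = 6L)
  image_gen_config(per_class_n = per_class_n, image_size = c(32L, 32L, 1L),
                   seed = seed)

expect_layers_identical <- function(a, b) {
  expect_identical(lapply(a$layers, canonical_serialize),
                   lapply(b$layers, canonical_serialize))
}
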