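# Fusion, mode ordering, entropy, NB fitness, classification.

test_that("extract_features honors shape contract and determinism", {
  bb <- build_toy_backbones(seed = 3, input_shape = c(32L, 32L, 1L))
  imgs <- replicate(4, tiny <- array(runif(32 * 32), c(32, 32, 1)),
                    simplify = FALSE)
  f <- extract_features(bb$inceptionv3, "avg pool", imgs)
  expect_identical(dim(f), c(4L, 32L))
  # identical images give identical rows
  f2 <- extract_features(bb$inceptionv3, "avg pool", list(imgs[[1]], imgs[[1]]))
  expect_identical(f2[1, ], f2[2, ])
  expect_error(extract_features(bb$inceptionv3, "nope", imgs),
               class = "scnn_config_error")
})

test_that("registry widths fuse to 4048 and fusion conserves width", {
  reg <- feature_layer_registry()
  expect_identical(reg$dim, c(2048L, 1000L, 1000L))
  tb <- serial_fuse(matrix(0, 2, 2048), matrix(0, 2, 1000), matrix(0, 2, 1000))
  expect_identical(ncol(tb$x), 4048L)

  # zero-column matrix contributes nothing
  tb2 <- serial_fuse(matrix(1, 2, 3), matrix(2, 2, 2), matrix(0, 2, 0))
  expect_identical(ncol(tb2$x), 5L)

  # row order: concatenation in argument order
  tb3 <- serial_fuse(matrix(c(1, 2), 1), matrix(3, 1), matrix(4, 1))
  expect_identical(as.numeric(tb3$x[1, ]), c(1, 2, 3, 4))

  expect_error(serial_fuse(matrix(0, 2, 3), matrix(0, 3, 3)),
               class = "scnn_config_error")
})

test_that("mode ordering follows the histogram-mode rule and is a bijection", {
  # constants: 5-feature before 3-feature
  tb <- serial_fuse(matrix(5, 4, 1), matrix(3, 4, 1))
  mo <- mode_order(tb)
  expect_identical(mo$feature_order, c(1L, 2L))
  expect_identical(as.numeric(mo$x[1, ]), c(5, 3))

  # all-identical features keep original order (tie rule)
  tb2 <- serial_fuse(matrix(1, 3, 4))
  expect_identical(mode_order(tb2)$feature_order, 1:4)

  # brute-force histogram oracle on random data
  set.seed(99)
  x <- matrix(round(rnorm(60), 1), 10, 6)
  oracle_mode <- function(v, dec) {
    r <- round(v, dec)
    freq <- vapply(unique(r), function(u) sum(r == u), numeric(1))
    min(unique(r)[freq == max(freq)])
  }
  modes <- apply(x, 2, oracle_mode, dec = 1)
  expected <- order(-modes, seq_len(6))
  mo3 <- mode_order(serial_fuse(x), decimals = 1)
  expect_identical(mo3$feature_order, as.integer(expected))

  # the example pair: {1,1,2} has mode 1; {3,.1,.2} all singletons -> 0.1
  tb4 <- serial_fuse(matrix(c(1, 1, 2), 3, 1), matrix(c(3, 0.1, 0.2), 3, 1))
  mo4 <- mode_order(tb4, decimals = 1)
  expect_identical(mo4$feature_order, c(1L, 2L))  # 1.0 > 0.1
})

test_that("entropy closed forms hold to 1e-12 and bad input errors", {
  expect_identical(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.7, 0.3, 0)), -(0.7 * log(0.7) + 0.3 * log(0.3)),
               tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "scnn_config_error")
  expect_error(shannon_entropy(c(0.5, 0.4)), class = "scnn_config_error")
})

test_that("NB fitness: entropy gate, separation, chance level", {
  pt <- gen_planted_table(n_samples = 120L, n_features = 30L,
                          n_informative = 5L, effect_size = 4, seed = 21)
  cfg <- ga_config(seed = 21)
  mask <- seq_len(30) %in% pt$informative

  # tau = near-zero gates any subset with >= 2 distinct pooled bins
  gated <- ga_config(tau = 1e-9, seed = 21)
  expect_identical(nb_fitness(pt$table, mask, gated), 0)

  # well-separated classes, informative mask, tau = Inf -> high accuracy
  open <- ga_config(tau = Inf, seed = 21)
  expect_gte(nb_fitness(pt$table, mask, open), 0.9)

  # shuffled labels -> chance level (2 classes), averaged over repeats
  accs <- vapply(1:20, function(i) {
    sh <- pt$table
    sh$y <- sample(sh$y)
    nb_fitness(sh, mask, open)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  expect_error(nb_fitness(pt$table, rep(FALSE, 30), cfg),
               class = "scnn_config_error")
  one_class <- pt$table
  one_class$y <- factor(rep("c1", nrow(one_class$x)))
  expect_error(nb_fitness(one_class, mask, cfg), class = "scnn_config_error")
})

test_that("classification: separable table, shuffle invariance, chance noise", {
  pt <- gen_planted_table(n_samples = 80L, n_features = 10L,
                          n_informative = 6L, effect_size = 8, seed = 31)
  res <- classify(pt$table, pt$informative, "nearest_centroid", seed = 2)
  expect_identical(res$accuracy, 1)
  res_nb <- classify(pt$table, pt$informative, "gaussian_nb", seed = 2)
  expect_gte(res_nb$accuracy, 0.95)

  # content-addressed split: metrics invariant to row shuffling
  sh <- pt$table
  set.seed(7)
  perm <- sample(nrow(sh$x))
  sh$x <- sh$x[perm, , drop = FALSE]
  sh$y <- sh$y[perm]
  res2 <- classify(sh, pt$informative, "nearest_centroid", seed = 2)
  expect_identical(res2[c("accuracy", "precision", "recall", "f1")],
                   res[c("accuracy", "precision", "recall", "f1")])

  # pure-noise single feature -> accuracy near chance over repeats
  accs <- vapply(1:15, function(i) {
    noise <- gen_planted_table(n_samples = 80L, n_features = 2L,
                               n_informative = 0L, effect_size = 0,
                               seed = 100 + i)
    classify(noise$table, 1L, "gaussian_nb", seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)

  expect_error(classify(pt$table, integer(0)), class = "scnn_config_error")
  expect_error(classify(pt$table, 1L, "svm"), class = "scnn_config_error")
})

test_that("Gaussian NB matches a closed-form oracle and the reference implementation", {
  # hand-computed oracle: 2 classes, 1 feature, lambda = 0-ish smoothing
  x <- matrix(c(0, 0.2, 1.0, 1.2), 4, 1)
  y <- factor(c("a", "a", "b", "b"))
  fit <- securecnn:::nb_fit(x, y, lambda = 1e-9)
  # class means 0.1 / 1.1, sample var 0.02 each, priors ~ 1/2
  expect_equal(fit$means[, 1], c(0.1, 1.1), tolerance = 1e-9)
  expect_equal(fit$vars[, 1], c(0.02, 0.02), tolerance = 1e-6)
  # posterior argmax: midpoint 0.6 tips by proximity
  expect_identical(securecnn:::nb_predict(fit, matrix(c(0.3, 0.9), 2, 1)),
                   c("a", "b"))

  # independent reference: sklearn GaussianNB on the same random table
  set.seed(77)
  n <- 60L
  xm <- matrix(rnorm(n * 4), n, 4)
  yy <- rep(c(0, 1), each = n / 2)
  xm[yy == 1, 1:2] <- xm[yy == 1, 1:2] + 1.5
  tr <- c(1:20, 31:50)
  fit2 <- securecnn:::nb_fit(xm[tr, ], factor(yy[tr]), lambda = 1e-9)
  mine <- securecnn:::nb_predict(fit2, xm[-tr, ])
  dir <- tempfile(); dir.create(dir)
  utils::write.csv(data.frame(xm, y = yy), file.path(dir, "d.csv"),
                   row.names = FALSE)
  script <- sprintf("
import pandas as pd
from sklearn.naive_bayes import GaussianNB
d = pd.read_csv('%s/d.csv')
X = d.iloc[:, :4].values; y = d['y'].values
tr = list(range(0,20)) + list(range(30,50))
te = [i for i in range(len(y)) if i not in tr]
clf = GaussianNB().fit(X[tr], y[tr])
print(','.join(str(int(v)) for v in clf.predict(X[te])))
", dir)
  out <- system2("python", "-", stdout = TRUE, input = script)
  ref <- as.integer(strsplit(out[length(out)], ",")[[1]])
  agree <- mean(as.integer(mine) == ref)
  expect_gte(agree, 0.95)
  unlink(dir, recursive = TRUE)
})

test_that("feature tables round-trip losslessly through CSV", {
  pt <- gen_planted_table(n_samples = 12L, n_features = 5L,
                          n_informative = 2L, seed = 8)
  p <- tempfile(fileext = ".csv")
  write_feature_table(pt$table, p)
  back <- read_feature_table(p)
  expect_identical(back$x, pt$table$x)
  expect_identical(back$y, pt$table$y)
  header <- strsplit(readLines(p, n = 1L), ",")[[1]]
  expect_identical(header[length(header)], "label")
  file.remove(p)
})
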