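# Three-severity tampering attacks: semantics, reproducibility, detection.

test_that("attack specs validate their arguments", {
  expect_error(attack_spec(3), class = "scnn_config_error")
  expect_error(attack_spec(1, noise_std = 0), class = "scnn_config_error")
  expect_s3_class(attack_spec(0), "scnn_attack_spec")
})

test_that("mild attack permutes labels only; identity permutation is a no-op", {
  m <- perfect_two_class()
  probe <- perfect_probe()

  idn <- apply_attack(m, attack_spec(0, permutation = c(1L, 2L)))
  expect_identical(idn$report$parameter_count_changed, 0L)
  for (img in probe$images)
    expect_identical(forward_plain(idn$model, img)$label,
                     forward_plain(m, img)$label)

  # label-permutation oracle: a perfect 2-class model scores 0 after reverse
  rv <- apply_attack(m, attack_spec(0, permutation = "reverse"))
  expect_identical(rv$report$parameter_count_changed, 0L)
  acc <- mean(vapply(seq_along(probe$images), function(i)
    forward_plain(rv$model, probe$images[[i]])$label == probe$labels[i],
    logical(1)))
  expect_identical(acc, 0)
})

test_that("average attack: dense-only noise, continuity in sigma, reproducible", {
  m <- conv_toy_model(seed = 2)
  for (sigma in c(1e-6, 1e-3)) {
    a <- apply_attack(m, attack_spec(1, noise_std = sigma, seed = 3))
    # weights-only, dense/output layers only
    expect_identical(a$report$layers_touched, c(3L, 4L))
    expect_identical(a$model$layers[[1]]$weights, m$layers[[1]]$weights)
    expect_identical(a$model$layers[[3]]$bias, m$layers[[3]]$bias)
    dmax <- max(abs(a$model$layers[[3]]$weights - m$layers[[3]]$weights))
    expect_lt(dmax, 6 * sigma)   # |dw| -> 0 with sigma
    expect_gt(dmax, 0)
  }
  a1 <- apply_attack(m, attack_spec(1, seed = 5))
  a2 <- apply_attack(m, attack_spec(1, seed = 5))
  expect_layers_identical(a1$model, a2$model)

  no_dense <- layered_model(list(pooling_layer(2L)), c(4L, 4L, 1L))
  expect_error(apply_attack(no_dense, attack_spec(1)),
               class = "scnn_config_error")
})

test_that("severe attack touches every parameterized layer plus structure", {
  m <- conv_toy_model(seed = 4)
  a <- apply_attack(m, attack_spec(2, seed = 6))
  param_ids <- which(vapply(m$layers, securecnn:::is_parameterized,
                            logical(1)))
  expect_true(all(param_ids %in% a$report$layers_touched))
  expect_identical(a$model$layers[[1]]$structural$stride,
                   m$layers[[1]]$structural$stride + 1L)
  expect_false(identical(a$model$layers[[4]]$class_labels,
                         m$layers[[4]]$class_labels))
  # original untouched
  expect_identical(m$layers[[1]]$structural$stride, 1L)
})

test_that("audit flags exactly the touched layers for every attack type", {
  m <- conv_toy_model(seed = 7)
  s <- wrap_secure(m, seed = 7)
  for (ty in 0:2) {
    a <- apply_attack(m, attack_spec(ty, seed = 20 + ty))
    r <- audit_model(tamper_secure(s, a$model))
    expect_identical(r$tampered_layer_ids, a$report$layers_touched)
  }
})

test_that("evaluate_attack_impact reports accuracies and detection", {
  m <- conv_toy_model(seed = 8)
  probe <- list(images = lapply(1:6, function(i) {
    set.seed(100 + i); array(runif(64), c(8, 8, 1))
  }), labels = rep(c("a", "b"), 3))

  clean <- evaluate_attack_impact(m, m, probe, seed = 1)
  expect_identical(clean$accuracy_before, clean$accuracy_after)
  expect_false(clean$detected_by_secure)

  for (ty in 0:2) {
    a <- apply_attack(m, attack_spec(ty, noise_std = 1e-9 + (ty == 0) * 0.1,
                                     seed = 9))
    imp <- evaluate_attack_impact(m, a$model, probe, seed = 1)
    expect_true(imp$detected_by_secure)  # any sigma >= 1e-9 is caught
  }
  expect_error(evaluate_attack_impact(m, m, list(images = list(),
                                                 labels = character(0))),
               class = "scnn_config_error")
})

test_that("attack severity orders unprotected probe accuracy (median over seeds)", {
  # scaled-down severity benchmark: template model on synthetic blobs
  accs <- sapply(1:5, function(sd) {
    set <- gen_image_set(small_image_cfg(seed = sd, per_class_n = 5L))
    m <- fit_template_model(set$images, set$labels, seed = sd)
    probe <- list(images = set$images, labels = set$labels)
    acc <- function(mm) evaluate_attack_impact(m, mm, probe,
                                               seed = sd)$accuracy_after
    avg <- apply_attack(m, attack_spec(1, noise_std = 0.1, seed = sd))$model
    sev <- apply_attack(m, attack_spec(2, noise_std = 0.1, seed = sd))$model
    c(clean = acc(m), average = acc(avg), severe = acc(sev))
  })
  med <- apply(accs, 1, median)
  expect_gte(med["clean"], med["average"])
  expect_gte(med["average"], med["severe"])
})
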