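# Plain and secured forward passes, wrapping, audit, restore.

test_that("forward_plain: identity layer, uniform softmax, determinism", {
  # identity-weight, zero-bias layer passes its input through (the ledger
  # block inserted as a layer behaves exactly like this)
  id <- llb_identity_layer(9L)
  m <- layered_model(list(id), c(3L, 3L, 1L))
  x <- tiny_input(1)
  expect_identical(forward_plain(m, x)$scores, as.numeric(x))

  # all-zero weights + softmax -> uniform scores 1/k
  mz <- layered_model(list(output_layer(matrix(0, 4, 9),
                                        paste0("c", 1:4))), c(3L, 3L, 1L))
  expect_equal(forward_plain(mz, x)$scores, rep(0.25, 4))
  expect_identical(forward_plain(mz, x)$label, "c1")  # tie -> lowest index

  m2 <- tiny_model(seed = 8)
  expect_identical(forward_plain(m2, x), forward_plain(m2, x))

  expect_error(forward_plain(m2, array(0, c(5, 5, 1))),
               class = "scnn_shape_error")
})

test_that("wrapping is transparent and deterministic in its ledger state", {
  m <- tiny_model(seed = 4)
  x <- tiny_input(2)
  s <- wrap_secure(m, seed = 10)
  expect_length(s$llbs, length(m$layers))
  plain <- forward_plain(m, x)
  fs <- forward_secure(s, x)
  expect_false(fs$halted)
  expect_identical(fs$scores, plain$scores)
  expect_identical(fs$label, plain$label)
  # n layers -> n transactions after one pass
  expect_length(fs$secure$clb$slots, length(m$layers))

  # hash chain and parameter digests are pure functions of (model, seed)
  s2 <- wrap_secure(m, seed = 10)
  expect_identical(lapply(s$llbs, `[[`, "hash_current"),
                   lapply(s2$llbs, `[[`, "hash_current"))
  expect_identical(lapply(s$llbs, `[[`, "param_digest"),
                   lapply(s2$llbs, `[[`, "param_digest"))

  # the symmetric suite is deterministic down to every ciphertext
  d1 <- wrap_secure(m, cipher_suite("symmetric"), seed = 11)
  d2 <- wrap_secure(m, cipher_suite("symmetric"), seed = 11)
  t1 <- tempfile(); t2 <- tempfile()
  write_ledger(forward_secure(d1, x)$secure, t1)
  write_ledger(forward_secure(d2, x)$secure, t2)
  expect_identical(readLines(t1), readLines(t2))
  file.remove(t1, t2)
})

test_that("tamper at a layer halts the pass before propagating", {
  m <- tiny_model(seed = 6, n_layers = 5L)
  x <- tiny_input(3)
  s <- wrap_secure(m, seed = 3)
  mt <- m
  mt$layers[[3]]$weights[] <- mt$layers[[3]]$weights + rnorm(
    length(mt$layers[[3]]$weights), 0, 0.05)
  fs <- forward_secure(tamper_secure(s, mt), x)
  expect_true(fs$halted)
  expect_identical(fs$halt_report$tampered_layer_ids, 3L)
  ids <- vapply(fs$secure$clb$slots, `[[`, integer(1), "layer_id")
  expect_true(all(ids < 3L))  # halt-before-propagate
})

test_that("auto-restore returns the pre-tamper prediction", {
  m <- tiny_model(seed = 7, n_layers = 4L)
  x <- tiny_input(4)
  s <- wrap_secure(m, seed = 5)
  before <- forward_plain(m, x)
  mt <- m
  mt$layers[[2]]$weights[1, ] <- 0
  fs <- forward_secure(tamper_secure(s, mt), x, auto_restore = TRUE)
  expect_false(fs$halted)
  expect_true(fs$restored)
  expect_identical(fs$scores, before$scores)
})

test_that("audit localizes exactly, is idempotent, honors missing records", {
  m <- tiny_model(seed = 11, n_layers = 5L)
  s <- wrap_secure(m, seed = 2)
  expect_true(audit_model(s)$clean)

  # two tampered layers -> both named, nothing else
  mt <- m
  mt$layers[[2]]$bias[1] <- mt$layers[[2]]$bias[1] + 1
  mt$layers[[4]]$weights[1, 1] <- 0
  r <- audit_model(tamper_secure(s, mt))
  expect_identical(r$tampered_layer_ids, c(2L, 4L))
  expect_identical(r, audit_model(tamper_secure(s, mt)))

  # structural tamper (stride equivalent for dense: reshape weights)
  ms <- m
  ms$layers[[3]]$structural$stride <- 7L
  expect_identical(audit_model(tamper_secure(s, ms))$tampered_layer_ids, 3L)

  # deleted ledger record -> "missing record"
  s2 <- s
  s2$llbs[3] <- list(NULL)
  r2 <- audit_model(s2)
  expect_true(3L %in% r2$tampered_layer_ids)
  expect_identical(unname(r2$reasons["3"]), "missing record")
})

test_that("restoration: no-op on clean, bit-exact on tampered, bounded", {
  m <- tiny_model(seed = 12, n_layers = 4L)
  s <- wrap_secure(m, seed = 8)
  clean <- restore_layer(m, 2L, s$llbs, s$clb, s$suite)
  expect_layers_identical(clean, m)
  expect_identical(attr(clean, "iterations_used"), 0L)

  mt <- m
  mt$layers[[2]]$weights[] <- 0
  back <- restore_layer(mt, 2L, s$llbs, s$clb, s$suite)
  expect_identical(canonical_serialize(back$layers[[2]]),
                   canonical_serialize(m$layers[[2]]))

  # ledger record deleted -> unrecoverable
  s2 <- s
  s2$llbs[[2]]$encrypted_self_params <- NULL
  expect_error(restore_layer(mt, 2L, s2$llbs, s2$clb, s2$suite),
               class = "scnn_unrecoverable_tamper")

  # corrupted ledger ciphertext -> unrecoverable
  s3 <- s
  s3$llbs[[2]]$encrypted_self_params <-
    as.raw(rev(as.integer(s3$llbs[[2]]$encrypted_self_params)))
  expect_error(restore_model(mt, s3$llbs, s3$clb, s3$suite),
               class = "scnn_unrecoverable_tamper")
})

test_that("perturbing layer i never flags an earlier layer (locality)", {
  m <- tiny_model(seed = 13, n_layers = 5L)
  s <- wrap_secure(m, seed = 13)
  for (i in 2:5) {
    mt <- m
    w <- mt$layers[[i]]$weights
    w[1] <- w[1] + 10^runif(1, -9, 0)
    mt$layers[[i]]$weights <- w
    r <- audit_model(tamper_secure(s, mt))
    expect_identical(r$tampered_layer_ids, i)
  }
})
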