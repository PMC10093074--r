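# Secured model: ledger wrapping and the verified forward pass.

#' Wrap a layered model with ledger blocks
#'
#' Builds one layer ledger block (LLB) per layer — chained keyed hash,
#' per-layer parameter fingerprint, key pair, neighbour public keys, and
#' the layer's parameters encrypted under its own public key (plus the
#' next layer's parameters, mirroring the block layout) — and an empty
#' randomized central ledger block (CLB). Wrapping never changes a clean
#' model's outputs.
#'
#' @param model an `scnn_model`.
#' @param suite a [cipher_suite()]; default the asymmetric RSA suite.
#' @param seed integer seed: drives the digest chain key, slot
#'   permutations and (for the deterministic symmetric suite) the key
#'   material. Key pairs are generated once per wrap and kept for the
#'   model lifetime.
#' @param sync_target pluggable store receiving the CLB copy.
#' @return an `scnn_secure_model` with fields `base`, `llbs`, `clb`,
#'   `suite`, `seed`, `chain_key`.
#' @export
wrap_secure <- function(model, suite = cipher_suite(), seed = 1L,
                        sync_target = new_memory_store()) {
  stopifnot(inherits(model, "scnn_model"))
  n <- length(model$layers)
  chain_key <- derive_bytes(seed, "chain-key")
  # n layer key pairs plus a terminal recipient for the last output
  kps <- lapply(seq_len(n + 1L), function(i)
    suite$keygen(i, derive_bytes(seed, paste0("layer-key/", i))))
  hashes <- vector("list", n)
  prev_hash <- genesis_hash()
  for (i in seq_len(n)) {
    prev_layer <- if (i > 1L) model$layers[[i - 1L]] else NULL
    hashes[[i]] <- compute_layer_hash(prev_hash, model$layers[[i]],
                                      prev_layer, suite, chain_key)
    prev_hash <- hashes[[i]]
  }
  llbs <- vector("list", n)
  for (i in seq_len(n)) {
    ser_i <- canonical_serialize(model$layers[[i]])
    enc_next <- if (i < n)
      suite$encrypt(kps[[i]]$public_key,
                    canonical_serialize(model$layers[[i + 1L]])) else NULL
    llbs[[i]] <- new_llb(
      layer_id = i,
      hash_current = hashes[[i]],
      hash_previous = if (i > 1L) hashes[[i - 1L]] else genesis_hash(),
      key_pair = kps[[i]],
      neighbor_public_keys = list(
        prev = if (i > 1L) kps[[i - 1L]]$public_key else NULL,
        nxt = kps[[i + 1L]]$public_key),
      encrypted_self_params = suite$encrypt(kps[[i]]$public_key, ser_i),
      encrypted_next_params = enc_next,
      param_digest = layer_param_digest(model$layers[[i]], suite, chain_key))
  }
  clb <- new_central_ledger(n, suite$name, seed, sync_target)
  clb$header$chain_key <- chain_key
  structure(list(base = model, llbs = llbs, clb = clb, suite = suite,
                 seed = as.integer(seed), chain_key = chain_key,
                 out_keypair = kps[[n + 1L]]),
            class = "scnn_secure_model")
}

#' @export
print.scnn_secure_model <- function(x, ...) {
  cat(sprintf("<scnn_secure_model> %d layers, suite '%s', seed %d, %d transaction(s)\n",
              length(x$llbs), x$suite$name, x$seed, length(x$clb$slots)))
  invisible(x)
}

# Signature payload of a transaction: chained pass hash + plaintext digest.
txn_payload <- function(hash, raw_output_digest) c(hash, raw_output_digest)

#' Secured forward pass
#'
#' At each layer: the layer's parameter fingerprint and chained hash are
#' re-verified against its ledger block and the previous layer's
#' transaction signature and encrypted handoff are checked; only then is
#' the layer executed, its output encrypted for the next layer and the
#' signed transaction recorded in the CLB. On the first failure the pass
#' halts (no later transaction is recorded) and, with `auto_restore =
#' TRUE`, the tampered layers are restored from the ledger and the pass is
#' rerun on the restored model.
#'
#' @param secure an `scnn_secure_model`.
#' @param input numeric array matching the model input shape.
#' @param auto_restore restore-and-rerun on tamper detection.
#' @return an `scnn_forward_result`: `scores`, `label`, `outputs`, `halted`,
#'   `halt_report` (a validation report when halted), `restored`, and the
#'   updated `secure` model (new CLB transactions; restored base when
#'   restoration ran).
#' @export
forward_secure <- function(secure, input, auto_restore = FALSE) {
  stopifnot(inherits(secure, "scnn_secure_model"))
  model <- secure$base
  suite <- secure$suite
  key <- secure$chain_key
  n <- length(model$layers)
  input <- reshape_input(model, input)
  pass_id <- secure$clb$pass_count + 1L
  clb <- secure$clb

  halt <- function(layer_id, reason) {
    report <- validation_report(layer_id, reason)
    if (auto_restore) {
      res <- restore_model(model, secure$llbs, clb, suite)
      secure$base <- res$model
      secure$clb <- clb
      out <- forward_secure(secure, input, auto_restore = FALSE)
      out$restored <- TRUE
      out$halt_report <- report
      return(out)
    }
    secure$clb <- clb
    structure(list(scores = NULL, label = NA_character_, outputs = NULL,
                   halted = TRUE, halt_report = report, restored = FALSE,
                   secure = secure),
              class = "scnn_forward_result")
  }

  x <- input
  outputs <- vector("list", n)
  h_prev <- genesis_hash()
  y_cur <- suite$encrypt(secure$llbs[[1L]]$key_pair$public_key,
                         tensor_bytes(input))
  y_prev_digest <- genesis_hash()
  prev_txn <- NULL
  shape <- model$input_shape
  for (i in seq_len(n)) {
    llb <- secure$llbs[[i]]
    if (is.null(llb)) return(halt(i, "missing record"))
    # parameter fingerprint of the layer about to execute
    dg <- tryCatch(layer_param_digest(model$layers[[i]], suite, key),
                   error = function(e) NULL)
    if (is.null(dg) || !identical(dg, llb$param_digest))
      return(halt(i, "hash mismatch"))
    # handoff from the previous layer: signature + encrypted I/O agreement
    if (!is.null(prev_txn)) {
      ok <- suite$verify(secure$llbs[[i - 1L]]$key_pair$public_key,
                         txn_payload(prev_txn$hash, prev_txn$raw_output_digest),
                         prev_txn$signature)
      if (!ok) return(halt(i - 1L, "signature mismatch"))
      pt <- tryCatch(suite$decrypt(llb$key_pair$private_key, y_cur),
                     error = function(e) NULL)
      if (is.null(pt) ||
          !identical(suite$keyed_digest(key, pt), prev_txn$raw_output_digest))
        return(halt(i - 1L, "I/O mismatch"))
    }
    shape <- tryCatch(layer_output_shape(model$layers[[i]], shape),
                      error = function(e) NULL)
    if (is.null(shape)) return(halt(i, "hash mismatch"))
    x <- layer_forward(model$layers[[i]], x)
    outputs[[i]] <- x
    # encrypt for the next layer, chain the pass hash, sign, record
    next_pub <- if (i < n) secure$llbs[[i + 1L]]$key_pair$public_key
                else secure$out_keypair$public_key
    p_bytes <- tensor_bytes(x)
    y_next <- suite$encrypt(next_pub, p_bytes)
    y_cur_digest <- suite$keyed_digest(key, y_cur)
    h_i <- suite$keyed_digest(key, c(h_prev, y_cur_digest, y_prev_digest))
    p_digest <- suite$keyed_digest(key, p_bytes)
    sig <- suite$sign(llb$key_pair$private_key, txn_payload(h_i, p_digest))
    txn <- new_transaction(i, sig, y_next, h_i, p_digest, pass_id)
    clb <- record_transaction(clb, txn, pass_id)
    prev_txn <- txn
    y_prev_digest <- y_cur_digest
    y_cur <- y_next
    h_prev <- h_i
  }
  secure$clb <- clb
  last <- model$layers[[n]]
  label <- if (identical(last$kind, "output"))
    last$class_labels[which.max(as.numeric(x))] else NA_character_
  structure(list(scores = as.numeric(x), label = label, outputs = outputs,
                 halted = FALSE, halt_report = NULL, restored = FALSE,
                 secure = secure),
            class = "scnn_forward_result")
}

#' Audit a secure model without running it
#'
#' Full-chain validation of the wrapped model against its ledger blocks
#' and recorded transactions; any layer can be validated at any time.
#'
#' @param secure an `scnn_secure_model`.
#' @return an `scnn_validation_report`.
#' @export
audit_model <- function(secure) {
  stopifnot(inherits(secure, "scnn_secure_model"))
  validate_chain(secure$base, secure$llbs, secure$clb, secure$suite)
}

#' Swap a (possibly tampered) model body under an existing wrap
#'
#' The attacker's move in experiments: the ledger stays honest while the
#' model parameters change underneath it. Useful with [apply_attack()] to
#' exercise [audit_model()] and restoration.
#'
#' @param secure an `scnn_secure_model`.
#' @param model the replacement (e.g. attacked) `scnn_model`.
#' @return the secure model with `base` replaced.
#' @export
tamper_secure <- function(secure, model) {
  stopifnot(inherits(secure, "scnn_secure_model"))
  secure$base <- model
  secure
}
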