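# Ledger substrate: chained layer hashes, layer ledger blocks (LLBs),
# the randomized central ledger block (CLB) and its pluggable sync store.

GENESIS_HASH <- as.raw(rep(0L, 32))  # fixed 32-byte zero genesis constant

#' Chained layer hash
#'
#' `h_i = HMAC(key, h_{i-1} || bytes(parameters_i - parameters_{i-1}))`.
#' The delta is elementwise when the two layers' tensor shapes align
#' (metadata records of both layers are always included, so structural
#' edits perturb the hash) and the concatenation of both canonical
#' serializations otherwise. For the first layer, `previous = NULL` and
#' the delta is the layer's full serialization; `prev_hash` is then the
#' 32-byte zero genesis constant.
#'
#' @param prev_hash raw, previous layer's hash (or `genesis_hash()`).
#' @param current,previous `scnn_layer` objects (`previous = NULL` only at
#'   the first layer).
#' @param suite a [cipher_suite()].
#' @param key raw digest key; missing key is a configuration error.
#' @return raw 32-byte hash.
#' @export
compute_layer_hash <- function(prev_hash, current, previous, suite, key) {
  if (is.null(key) || !length(key))
    scnn_error("scnn_config_error", "compute_layer_hash: missing digest key")
  suite$keyed_digest(key, c(prev_hash, param_delta_bytes(current, previous)))
}

#' Genesis hash constant
#' @return the fixed 32-byte zero raw vector seeding the chain.
#' @export
genesis_hash <- function() GENESIS_HASH

# Per-layer keyed fingerprint used for exact tamper localization: unlike
# the chained hash it depends only on this layer's bytes, so a tamper at
# layer i never implicates untouched layers.
layer_param_digest <- function(layer, suite, key) {
  suite$keyed_digest(key, canonical_serialize(layer))
}

## ---- pluggable CLB sync stores ------------------------------------------

#' In-memory key-value store (default CLB sync target)
#' @return an `scnn_store`.
#' @export
new_memory_store <- function() {
  env <- new.env(parent = emptyenv())
  structure(list(
    put = function(key, bytes) assign(key, bytes, envir = env),
    get = function(key) get0(key, envir = env),
    keys = function() ls(env)
  ), class = "scnn_store")
}

#' Directory-backed key-value store
#'
#' Stands in for the protocol's "cloud" copy of the central ledger: an
#' availability mechanism, not an algorithm, hence a plain directory.
#'
#' @param path directory (created if needed).
#' @return an `scnn_store`.
#' @export
new_dir_store <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  structure(list(
    put = function(key, bytes) writeBin(bytes, file.path(path, key)),
    get = function(key) {
      f <- file.path(path, key)
      if (!file.exists(f)) return(NULL)
      readBin(f, "raw", n = file.info(f)$size)
    },
    keys = function() list.files(path)
  ), class = "scnn_store")
}

## ---- transactions and the central ledger block --------------------------

new_transaction <- function(layer_id, signature, encrypted_output, hash,
                            raw_output_digest, pass_id) {
  structure(list(layer_id = as.integer(layer_id), signature = signature,
                 encrypted_output = encrypted_output, hash = hash,
                 raw_output_digest = raw_output_digest,
                 pass_id = as.integer(pass_id)), class = "scnn_transaction")
}

txn_record_bytes <- function(slot, txn) {
  charToRaw(jsonlite::toJSON(list(
    slot = slot, layer_id = txn$layer_id, pass_id = txn$pass_id,
    signature = jsonlite::base64_enc(txn$signature),
    encrypted_output = jsonlite::base64_enc(txn$encrypted_output),
    hash = jsonlite::base64_enc(txn$hash),
    raw_output_digest = jsonlite::base64_enc(txn$raw_output_digest)
  ), auto_unbox = TRUE))
}

#' Create an empty central ledger block
#'
#' The CLB stores one signed transaction per layer per forward pass under
#' slot keys drawn from a seeded random permutation, so iterating the
#' slots does not reveal the layer order; the sealed `layer_slot_map`
#' records the permutation. A pluggable sync target receives a
#' byte-identical serialized copy of every record.
#'
#' @param n_layers number of layers of the wrapped model.
#' @param suite_name cipher suite name (header metadata).
#' @param seed integer seed driving the slot permutations.
#' @param sync_target an `scnn_store`; default in-memory.
#' @return an `scnn_clb`.
#' @export
new_central_ledger <- function(n_layers, suite_name, seed,
                               sync_target = new_memory_store()) {
  structure(list(
    header = list(suite = suite_name, seed = as.integer(seed),
                  n_layers = as.integer(n_layers)),
    slots = list(),            # slot key -> transaction
    layer_slot_map = list(),   # pass id -> named int vector layer -> slot
    version = 0L,
    pass_count = 0L,
    sync_target = sync_target,
    sync_pending = character(0)
  ), class = "scnn_clb")
}

slot_key <- function(pass_id, slot) sprintf("p%04d_s%03d", pass_id, slot)

#' Record a transaction in the central ledger
#'
#' The slot is drawn from the pass's seeded permutation, the version is
#' incremented and the serialized record is pushed to the sync target.
#' An unreachable sync target defers the sync (flagged in `sync_pending`)
#' while the local write still succeeds.
#'
#' @param clb an `scnn_clb`.
#' @param txn an `scnn_transaction` (complete: signature, hash and
#'   encrypted output present).
#' @param pass_id forward-pass index (defaults to the current pass).
#' @return the updated `scnn_clb`.
#' @export
record_transaction <- function(clb, txn, pass_id = NULL) {
  stopifnot(inherits(clb, "scnn_clb"), inherits(txn, "scnn_transaction"))
  if (is.null(txn$signature) || is.null(txn$hash) ||
      is.null(txn$encrypted_output))
    scnn_error("scnn_config_error", "incomplete transaction")
  pass_id <- pass_id %||% max(1L, clb$pass_count)
  key <- as.character(pass_id)
  if (is.null(clb$layer_slot_map[[key]])) {
    perm <- with_seed(derive_seed(clb$header$seed, paste0("slots/", pass_id)),
                      sample.int(clb$header$n_layers))
    clb$layer_slot_map[[key]] <- perm
    clb$pass_count <- max(clb$pass_count, pass_id)
  }
  slot <- slot_key(pass_id, clb$layer_slot_map[[key]][txn$layer_id])
  clb$slots[[slot]] <- txn
  clb$version <- clb$version + 1L
  rec <- txn_record_bytes(slot, txn)
  ok <- tryCatch({ clb$sync_target$put(slot, rec); TRUE },
                 error = function(e) FALSE)
  if (!ok) clb$sync_pending <- union(clb$sync_pending, slot)
  clb
}

# Transactions of one pass in layer order (NULL where missing).
pass_transactions <- function(clb, pass_id) {
  key <- as.character(pass_id)
  perm <- clb$layer_slot_map[[key]]
  if (is.null(perm)) return(NULL)
  lapply(seq_along(perm), function(i) clb$slots[[slot_key(pass_id, perm[i])]])
}

## ---- layer ledger blocks -------------------------------------------------

new_llb <- function(layer_id, hash_current, hash_previous, key_pair,
                    neighbor_public_keys, encrypted_self_params,
                    encrypted_next_params, param_digest) {
  structure(list(
    layer_id = as.integer(layer_id),
    hash_current = hash_current, hash_previous = hash_previous,
    key_pair = key_pair, neighbor_public_keys = neighbor_public_keys,
    encrypted_self_params = encrypted_self_params,
    encrypted_next_params = encrypted_next_params,
    param_digest = param_digest,
    encrypted_io = NULL,
    authenticity = TRUE
  ), class = "scnn_llb")
}

#' The ledger block as a pass-through layer
#'
#' A ledger block inserted into the network computes the identity: zero
#' bias, identity activation, identity weight matrix, so its output is its
#' input and wrapping never changes a clean model's predictions.
#'
#' @param n_units width of the pass-through.
#' @param name layer name.
#' @return an identity `scnn_layer`.
#' @export
llb_identity_layer <- function(n_units, name = "llb") {
  dense_layer(diag(n_units), activation = "identity", name = name)
}

## ---- ledger file ---------------------------------------------------------

b64 <- jsonlite::base64_enc
unb64 <- function(x) if (is.null(x) || !nchar(x)) NULL else jsonlite::base64_dec(x)

#' Write a secure model's ledger to a JSON-lines file
#'
#' One record per line: a header (suite name, seed, version, chain key),
#' one record per layer ledger block, one per transaction. Base64 fields.
#'
#' @param secure an `scnn_secure_model` from [wrap_secure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(secure, path) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c(list(type = "header"), secure$clb$header,
           list(version = secure$clb$version,
                pass_count = secure$clb$pass_count,
                chain_key = b64(secure$chain_key)))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE), con)
  for (llb in secure$llbs) {
    writeLines(jsonlite::toJSON(list(
      type = "llb", layer_id = llb$layer_id,
      hash_current = b64(llb$hash_current),
      hash_previous = b64(llb$hash_previous),
      param_digest = b64(llb$param_digest),
      public_key = b64(llb$key_pair$public_key),
      private_key = b64(llb$key_pair$private_key),
      prev_public_key = b64(llb$neighbor_public_keys$prev %||% raw(0)),
      next_public_key = b64(llb$neighbor_public_keys$nxt %||% raw(0)),
      encrypted_self_params = b64(llb$encrypted_self_params),
      encrypted_next_params = b64(llb$encrypted_next_params %||% raw(0))
    ), auto_unbox = TRUE), con)
  }
  for (key in names(secure$clb$layer_slot_map)) {
    writeLines(jsonlite::toJSON(list(
      type = "slot_map", pass_id = as.integer(key),
      perm = secure$clb$layer_slot_map[[key]]), auto_unbox = TRUE), con)
  }
  for (slot in names(secure$clb$slots))
    writeLines(rawToChar(txn_record_bytes(slot, secure$clb$slots[[slot]])), con)
  invisible(path)
}

#' Read a ledger file back into (llbs, clb, chain_key)
#' @param path file written by [write_ledger()].
#' @return list with `llbs`, `clb`, `chain_key`, `suite_name`, `seed`.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  hdr <- recs[[1]]
  stopifnot(identical(hdr$type, "header"))
  clb <- new_central_ledger(hdr$n_layers, hdr$suite, hdr$seed)
  clb$header$chain_key <- unb64(hdr$chain_key)
  clb$version <- hdr$version
  clb$pass_count <- hdr$pass_count
  llbs <- vector("list", hdr$n_layers)
  for (r in recs[-1]) {
    if (identical(r$type, "llb")) {
      kp <- keypair(unb64(r$public_key), unb64(r$private_key), r$layer_id)
      llbs[[r$layer_id]] <- new_llb(
        r$layer_id, unb64(r$hash_current), unb64(r$hash_previous), kp,
        list(prev = unb64(r$prev_public_key), nxt = unb64(r$next_public_key)),
        unb64(r$encrypted_self_params), unb64(r$encrypted_next_params),
        unb64(r$param_digest))
    } else if (identical(r$type, "slot_map")) {
      clb$layer_slot_map[[as.character(r$pass_id)]] <- as.integer(r$perm)
    } else {
      txn <- new_transaction(r$layer_id, unb64(r$signature),
                             unb64(r$encrypted_output), unb64(r$hash),
                             unb64(r$raw_output_digest), r$pass_id)
      clb$slots[[r$slot]] <- txn
    }
  }
  list(llbs = llbs, clb = clb, chain_key = unb64(hdr$chain_key),
       suite_name = hdr$suite, seed = hdr$seed)
}
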