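# Chain validation and ledger-based restoration.

validation_report <- function(tampered_ids = integer(0),
                              reasons = character(0),
                              restored = logical(0),
                              iterations_used = 0L) {
  tampered_ids <- as.integer(tampered_ids)
  if (length(reasons) == length(tampered_ids) && is.null(names(reasons)))
    names(reasons) <- as.character(tampered_ids)
  if (!length(restored)) {
    restored <- rep(FALSE, length(tampered_ids))
    names(restored) <- as.character(tampered_ids)
  }
  structure(list(tampered_layer_ids = sort(unique(tampered_ids)),
                 reasons = reasons, restored = restored,
                 iterations_used = as.integer(iterations_used),
                 clean = length(tampered_ids) == 0L),
            class = "scnn_validation_report")
}

#' @export
print.scnn_validation_report <- function(x, ...) {
  if (x$clean) {
    cat("<validation report> chain verifies: no tampered layers\n")
  } else {
    cat(sprintf("<validation report> %d tampered layer(s):\n",
                length(x$tampered_layer_ids)))
    for (id in x$tampered_layer_ids)
      cat(sprintf("  layer %d: %s%s\n", id,
                  x$reasons[[as.character(id)]] %||% "unknown",
                  if (isTRUE(x$restored[[as.character(id)]])) " [restored]" else ""))
  }
  invisible(x)
}

#' Validate a model against its ledger
#'
#' Three checks, in order of attribution strength:
#' \enumerate{
#' \item per-layer keyed parameter fingerprints (exact localization: a
#'   tamper at layer i flags layer i and only layer i);
#' \item the chained hash `h_i = HMAC(key, h_{i-1} || delta_i)` recomputed
#'   from genesis — if the chain disagrees where the fingerprints do not,
#'   the earliest mismatching layer is blamed (ledger inconsistency);
#' \item the last recorded pass: every transaction's signature is verified
#'   with its layer's public key, and each layer's encrypted input is
#'   decrypted and compared against the previous layer's recorded output
#'   digest; a disagreement blames the producing (earlier) layer.
#' }
#' A layer without a ledger record is reported with reason
#' `"missing record"`.
#'
#' @param model the `scnn_model` to check (possibly tampered).
#' @param llbs list of layer ledger blocks from [wrap_secure()].
#' @param clb the central ledger block.
#' @param suite the [cipher_suite()] used at wrap time (reconstructed from
#'   the CLB header if omitted).
#' @return an `scnn_validation_report`; empty `tampered_layer_ids` iff the
#'   whole chain verifies.
#' @export
validate_chain <- function(model, llbs, clb, suite = NULL) {
  stopifnot(inherits(model, "scnn_model"), inherits(clb, "scnn_clb"))
  suite <- suite %||% cipher_suite(clb$header$suite)
  key <- clb$header$chain_key
  if (is.null(key))
    scnn_error("scnn_config_error", "CLB header carries no chain key")
  n <- length(model$layers)
  reasons <- character(0)
  flag <- function(id, why) {
    id <- as.character(id)
    if (!(id %in% names(reasons))) reasons[id] <<- why
  }

  # 1. per-layer fingerprints
  for (i in seq_len(n)) {
    llb <- if (i <= length(llbs)) llbs[[i]] else NULL
    if (is.null(llb) || is.null(llb$param_digest)) { flag(i, "missing record"); next }
    dg <- tryCatch(layer_param_digest(model$layers[[i]], suite, key),
                   error = function(e) NULL)
    if (is.null(dg) || !identical(dg, llb$param_digest))
      flag(i, "hash mismatch")
  }

  # 2. chained hashes from genesis (tie-break: earliest mismatch)
  if (!length(reasons)) {
    prev_hash <- genesis_hash()
    for (i in seq_len(n)) {
      h <- compute_layer_hash(prev_hash,
                              model$layers[[i]],
                              if (i > 1L) model$layers[[i - 1L]] else NULL,
                              suite, key)
      if (!identical(h, llbs[[i]]$hash_current)) { flag(i, "hash mismatch"); break }
      prev_hash <- h
    }
  }

  # 3. last recorded pass: signatures and encrypted I/O handoffs
  if (clb$pass_count >= 1L) {
    txns <- pass_transactions(clb, clb$pass_count)
    if (!is.null(txns)) {
      for (i in seq_len(n)) {
        txn <- if (i <= length(txns)) txns[[i]] else NULL
        if (is.null(txn)) next  # halted pass legitimately stops early
        llb <- if (i <= length(llbs)) llbs[[i]] else NULL
        if (is.null(llb)) next
        ok <- suite$verify(llb$key_pair$public_key,
                           txn_payload(txn$hash, txn$raw_output_digest),
                           txn$signature)
        if (!ok) flag(i, "signature mismatch")
        if (i >= 2L && !is.null(txns[[i - 1L]])) {
          prev <- txns[[i - 1L]]
          pt <- tryCatch(suite$decrypt(llb$key_pair$private_key,
                                       prev$encrypted_output),
                         error = function(e) NULL)
          if (is.null(pt) ||
              !identical(suite$keyed_digest(key, pt), prev$raw_output_digest))
            flag(i - 1L, "I/O mismatch")
        }
      }
    }
  }

  ids <- sort(as.integer(names(reasons)))
  validation_report(ids, reasons[as.character(ids)])
}

#' Restore one tampered layer from the ledger
#'
#' Decrypts the layer's parameters stored in its ledger block, writes them
#' back, and re-validates; the loop repeats up to `max_iterations` until
#' the layer validates again. Calling it on a clean layer is a no-op.
#'
#' @param model the (tampered) `scnn_model`.
#' @param layer_id layer to restore.
#' @inheritParams validate_chain
#' @param max_iterations restoration attempts before giving up.
#' @return the restored `scnn_model` (attribute `"iterations_used"`).
#'   Throws `scnn_unrecoverable_tamper` when the ledger itself cannot
#'   produce a valid layer (e.g. its record was deleted or corrupted).
#' @export
restore_layer <- function(model, layer_id, llbs, clb, suite = NULL,
                          max_iterations = 3L) {
  suite <- suite %||% cipher_suite(clb$header$suite)
  r0 <- validate_chain(model, llbs, clb, suite)
  if (!(layer_id %in% r0$tampered_layer_ids)) {
    attr(model, "iterations_used") <- 0L
    return(model)
  }
  llb <- if (layer_id <= length(llbs)) llbs[[layer_id]] else NULL
  if (is.null(llb) || is.null(llb$encrypted_self_params))
    scnn_error("scnn_unrecoverable_tamper", sprintf(
      "layer %d: no ledger record to restore from", layer_id))
  for (it in seq_len(max_iterations)) {
    bytes <- tryCatch(suite$decrypt(llb$key_pair$private_key,
                                    llb$encrypted_self_params),
                      error = function(e) NULL)
    if (is.null(bytes))
      scnn_error("scnn_unrecoverable_tamper", sprintf(
        "layer %d: ledger record cannot be decrypted", layer_id))
    layer <- canonical_deserialize(bytes)
    layer$layer_id <- layer_id
    model$layers[[layer_id]] <- layer
    r <- validate_chain(model, llbs, clb, suite)
    if (!(layer_id %in% r$tampered_layer_ids)) {
      attr(model, "iterations_used") <- it
      return(model)
    }
  }
  scnn_error("scnn_unrecoverable_tamper", sprintf(
    "layer %d still invalid after %d restoration attempt(s)", layer_id,
    max_iterations))
}

#' Restore every tampered layer
#'
#' Validates, restores all flagged layers from their ledger blocks,
#' re-validates, and repeats up to `max_iterations` until the chain is
#' clean.
#'
#' @inheritParams restore_layer
#' @return list with `model` (clean) and `report` (an
#'   `scnn_validation_report` of the original damage with `restored`
#'   flags set and `iterations_used` filled).
#' @export
restore_model <- function(model, llbs, clb, suite = NULL,
                          max_iterations = 3L) {
  suite <- suite %||% cipher_suite(clb$header$suite)
  first <- validate_chain(model, llbs, clb, suite)
  if (first$clean)
    return(list(model = model, report = first))
  for (it in seq_len(max_iterations)) {
    r <- validate_chain(model, llbs, clb, suite)
    if (r$clean) {
      rep <- first
      rep$restored[] <- TRUE
      rep$iterations_used <- it - 1L
      return(list(model = model, report = rep))
    }
    for (id in r$tampered_layer_ids)
      model <- restore_layer(model, id, llbs, clb, suite, max_iterations)
  }
  r <- validate_chain(model, llbs, clb, suite)
  if (!r$clean)
    scnn_error("scnn_unrecoverable_tamper", sprintf(
      "layers %s still invalid after %d restoration pass(es)",
      paste(r$tampered_layer_ids, collapse = ", "), max_iterations))
  rep <- first
  rep$restored[] <- TRUE
  rep$iterations_used <- max_iterations
  list(model = model, report = rep)
}
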