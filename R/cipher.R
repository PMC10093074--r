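# Pluggable cipher suites.
#
# The protocol overloads one symbol for three roles (cipher in the chained
# hash, activation in the forward rule, noise scale in the attack
# generator). Internally these are three distinct names:
#   cipher E      -> suite$encrypt / suite$keyed_digest (this file)
#   activation a  -> layer$activation (layers.R)
#   noise sigma   -> attack_spec$noise_std (attack.R)
#
# Two suites are provided.
#   "rsa" (default): genuine asymmetric semantics — RSA key pairs,
#     RSA+AES envelope encryption to a public key, RSA-SHA256 signatures,
#     HMAC-SHA256 keyed digest. Key generation cannot be seeded, so
#     ciphertexts differ between runs even at a fixed seed (hashes and
#     slot layouts do not).
#   "symmetric": one AES-256 key per layer carried in both halves of the
#     key-pair interface, SIV-style deterministic AES-CBC encryption and
#     HMAC "signatures". This is the suite playing the role the original
#     protocol assigned to a symmetric block cipher; it is fully
#     deterministic under the wrap seed, at the cost of genuinely
#     asymmetric trust.

#' Construct a cipher suite
#'
#' @param name `"rsa"` (default, asymmetric) or `"symmetric"`
#'   (deterministic AES-256 stand-in for the protocol's symmetric cipher).
#' @param bits RSA modulus size for the `"rsa"` suite. The default (1024)
#'   is a desk-scale choice so that wrapping hundreds of toy models stays
#'   inside seconds; raise it for anything but demonstrations.
#' @return an object of class `scnn_cipher_suite` with fields
#'   `keygen(layer_id, material)`, `encrypt(public_key, bytes)`,
#'   `decrypt(private_key, bytes)`, `keyed_digest(key, bytes)`,
#'   `sign(private_key, bytes)`, `verify(public_key, bytes, signature)` and
#'   a `deterministic` flag.
#' @export
cipher_suite <- function(name = c("rsa", "symmetric"), bits = 1024L) {
  name <- match.arg(name)
  suite <- if (name == "rsa") rsa_suite(bits) else symmetric_suite()
  suite$name <- name
  class(suite) <- "scnn_cipher_suite"
  suite
}

keypair <- function(public_key, private_key, layer_id) {
  structure(list(public_key = public_key, private_key = private_key,
                 layer_id = as.integer(layer_id)), class = "scnn_keypair")
}

rsa_suite <- function(bits) {
  list(
    deterministic = FALSE,
    keygen = function(layer_id, material = NULL) {
      k <- openssl::rsa_keygen(bits)
      keypair(openssl::write_der(k$pubkey), openssl::write_der(k), layer_id)
    },
    encrypt = function(public_key, bytes) {
      stopifnot(is.raw(bytes))
      env <- openssl::encrypt_envelope(bytes, openssl::read_pubkey(public_key))
      pack_raws(list(env$iv, env$session, env$data))
    },
    decrypt = function(private_key, bytes) {
      parts <- unpack_raws(bytes)
      tryCatch(
        openssl::decrypt_envelope(parts[[3]], parts[[1]], parts[[2]],
                                  openssl::read_key(private_key)),
        error = function(e) scnn_error(
          "scnn_decrypt_error",
          paste("decryption failed (wrong key or corrupt ciphertext):",
                conditionMessage(e))))
    },
    keyed_digest = function(key, bytes) {
      if (is.null(key) || !length(key))
        scnn_error("scnn_config_error", "keyed digest requires a key")
      as.raw(openssl::sha256(bytes, key = key))
    },
    sign = function(private_key, bytes) {
      if (!length(bytes))
        scnn_error("scnn_sign_error", "refusing to sign an empty payload")
      openssl::signature_create(bytes, openssl::sha256,
                                key = openssl::read_key(private_key))
    },
    verify = function(public_key, bytes, signature) {
      isTRUE(tryCatch(
        openssl::signature_verify(bytes, signature, openssl::sha256,
                                  pubkey = openssl::read_pubkey(public_key)),
        error = function(e) FALSE))
    }
  )
}

# One shared key per layer; prefixes keep the two halves distinct byte
# strings while naming the same secret, mirroring a single-key cipher
# pressed into a public/private interface.
sym_secret <- function(key) key[-1]

symmetric_suite <- function() {
  list(
    deterministic = TRUE,
    keygen = function(layer_id, material = NULL) {
      k <- material %||% openssl::rand_bytes(32)
      stopifnot(length(k) == 32L)
      keypair(c(as.raw(0x01), k), c(as.raw(0x02), k), layer_id)
    },
    encrypt = function(public_key, bytes) {
      stopifnot(is.raw(bytes))
      k <- sym_secret(public_key)
      # SIV-style deterministic IV: MAC of the plaintext under the key.
      iv <- as.raw(openssl::sha256(c(as.raw(0x49), bytes), key = k))[1:16]
      ct <- openssl::aes_cbc_encrypt(bytes, key = k, iv = iv)
      pack_raws(list(iv, ct))
    },
    decrypt = function(private_key, bytes) {
      parts <- unpack_raws(bytes)
      k <- sym_secret(private_key)
      pt <- tryCatch(
        openssl::aes_cbc_decrypt(parts[[2]], key = k, iv = parts[[1]]),
        error = function(e) NULL)
      if (!is.null(pt)) {
        chk <- as.raw(openssl::sha256(c(as.raw(0x49), pt), key = k))[1:16]
        if (identical(chk, parts[[1]])) return(pt)
      }
      scnn_error("scnn_decrypt_error",
                 "decryption failed (wrong key or corrupt ciphertext)")
    },
    keyed_digest = function(key, bytes) {
      if (is.null(key) || !length(key))
        scnn_error("scnn_config_error", "keyed digest requires a key")
      as.raw(openssl::sha256(bytes, key = key))
    },
    sign = function(private_key, bytes) {
      if (!length(bytes))
        scnn_error("scnn_sign_error", "refusing to sign an empty payload")
      as.raw(openssl::sha256(c(as.raw(0x53), bytes),
                             key = sym_secret(private_key)))
    },
    verify = function(public_key, bytes, signature) {
      identical(as.raw(openssl::sha256(c(as.raw(0x53), bytes),
                                       key = sym_secret(public_key))),
                as.raw(signature))
    }
  )
}

#' Encrypt a layer output for its recipient layer
#'
#' Encrypts the tensor's canonical bytes under the recipient's public key;
#' the round trip through [decrypt_output()] is bit-exact.
#'
#' @param output numeric tensor (all values finite).
#' @param recipient_public_key raw public key.
#' @param suite a [cipher_suite()].
#' @return raw ciphertext.
#' @export
encrypt_output <- function(output, recipient_public_key, suite) {
  if (!all(is.finite(output)))
    scnn_error("scnn_serialize_error", "non-finite value in layer output")
  suite$encrypt(recipient_public_key, tensor_bytes(output))
}

#' Decrypt a layer output
#' @param bytes ciphertext from [encrypt_output()].
#' @param private_key raw private key of the recipient layer.
#' @inheritParams encrypt_output
#' @return the original numeric tensor, bit-exact.
#' @export
decrypt_output <- function(bytes, private_key, suite) {
  tensor_from_bytes(suite$decrypt(private_key, bytes))
}

#' Sign a transaction payload
#' @param payload non-empty raw vector.
#' @param private_key raw private key.
#' @inheritParams encrypt_output
#' @return raw signature, verifiable with [verify_transaction()].
#' @export
sign_transaction <- function(payload, private_key, suite) {
  suite$sign(private_key, payload)
}

#' Verify a transaction signature
#' @param payload raw vector that was signed.
#' @param signature raw signature.
#' @param public_key raw public key of the signer.
#' @inheritParams encrypt_output
#' @return `TRUE` iff the signature matches payload and key.
#' @export
verify_transaction <- function(payload, signature, public_key, suite) {
  suite$verify(public_key, payload, signature)
}
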