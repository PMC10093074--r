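# Internal helpers: seeded RNG scoping, seed/byte derivation, raw packing.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so package internals never
#' disturb user-level reproducibility.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed in [1, 2^31 - 1], from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- openssl::sha256(charToRaw(paste0(format(seed), "/", label)))
  v <- as.double(as.integer(h[1:4]))
  s <- (((v[1] * 256 + v[2]) * 256 + v[3]) * 256 + v[4]) %% 2147483646
  as.integer(s) + 1L
}

# Fixed-length deterministic byte material (keys, IVs) from seed + label.
derive_bytes <- function(seed, label, n = 32L) {
  out <- raw(0)
  i <- 0L
  while (length(out) < n) {
    out <- c(out, openssl::sha256(
      charToRaw(paste0(format(seed), "/", label, "/", i))))
    i <- i + 1L
  }
  out[seq_len(n)]
}

# 4-byte little-endian unsigned int <-> raw
raw4 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
raw4_to_int <- function(r) readBin(r, "integer", n = length(r) %/% 4L,
                                   size = 4L, endian = "little")

doubles_raw <- function(x) writeBin(as.numeric(x), raw(), size = 8L,
                                    endian = "little")
raw_doubles <- function(r) readBin(r, "numeric", n = length(r) %/% 8L,
                                   size = 8L, endian = "little")

# Length-prefixed concatenation of raw vectors (and its inverse).
pack_raws <- function(parts) {
  out <- raw4(length(parts))
  for (p in parts) out <- c(out, raw4(length(p)), p)
  out
}
unpack_raws <- function(bytes) {
  n <- raw4_to_int(bytes[1:4])
  pos <- 5L
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    len <- raw4_to_int(bytes[pos:(pos + 3L)])
    parts[[i]] <- if (len > 0L) bytes[pos + 3L + seq_len(len)] else raw(0)
    pos <- pos + 4L + len
  }
  parts
}

# Canonical bytes for a numeric tensor: rank, dims, row-major doubles.
tensor_bytes <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  xr <- if (length(d) >= 2L) aperm(array(x, dim = d), rev(seq_along(d))) else x
  c(raw4(length(d)), raw4(d), doubles_raw(xr))
}
tensor_from_bytes <- function(bytes) {
  rank <- raw4_to_int(bytes[1:4])
  d <- raw4_to_int(bytes[4L + seq_len(4L * rank)])
  vals <- raw_doubles(bytes[-seq_len(4L + 4L * rank)])
  if (rank >= 2L) aperm(array(vals, dim = rev(d)), rev(seq_along(d)))
  else vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scnn_error <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "scnn_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
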