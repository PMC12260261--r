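# Internal helpers shared across modules.

# Deterministically derive a child seed from (seed, offset), staying below
# 2^31 - 1 so set.seed() always receives a valid integer.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(offset) * 104729
  as.integer(s %% m)
}

# Quantize non-negative milliseconds to the nearest multiple of `resolution`,
# ties rounding half away from zero.
quantize_ms <- function(x, resolution) {
  stopifnot(resolution > 0)
  floor(x / resolution + 0.5) * resolution
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used for run
# manifests (content fingerprints, not cryptographic).
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR only touches the low byte; keep the rest in double arithmetic
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_lotqa <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lotqa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}
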