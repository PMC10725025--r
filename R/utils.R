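# Internal helpers: classed conditions (mapped to CLI exit codes) and a small
# content hash for run manifests.

stop_beeforage <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(paste0("beeforage_", class), "beeforage_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# FNV-1a over the serialized object; enough for config fingerprints in
# manifests (not cryptographic).
content_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 3)
  h <- 2166136261
  for (b in as.integer(raw)) {
    # xor only touches the low byte (b < 256); avoids 32-bit bitwXor limits
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit FNV prime multiply, kept in double precision via modular split
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
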