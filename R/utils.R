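# Internal helpers shared across modules.

# Error constructors: condition classes drive the CLI exit-code mapping
# (gda_usage_error -> 2, gda_validation_error -> 3, gda_numerical_error -> 4).
stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gda_usage_error", "gda_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gda_validation_error", "gda_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gda_numerical_error", "gda_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of a character vector, returned as 8 hex digits.
# Used to fingerprint node indexes so that serialized embeddings can be
# checked against the graph they were trained on.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor with one byte touches only the low 8 bits; keeps h a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619; split into 16-bit
    # halves so every intermediate stays exact in doubles
    h <- (((h %% 65536) * 16777619) %% 4294967296 +
          (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
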