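# Internal helpers shared across modules.

# Canonical numeric formatting used by all writers: fixed decimals so that
# write -> read -> write is byte-stable. Returns a double that survives the
# round trip unchanged.
canon_num <- function(x, digits) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  out[ok] <- as.numeric(sprintf(paste0("%.", digits, "f"), x[ok]))
  out
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

# Deterministic per-stream seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in ids) {
    v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ..., class = "foragedm_error", data = NULL) {
  abort(sprintf(fmt, ...), class = class, data = data)
}

`%theninvisible%` <- function(x, y) invisible(y)
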