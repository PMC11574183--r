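# Internal helpers shared across modules.

# Deterministic 62-bit polynomial string hash, returned as a hex-ish key.
# Used for backend-call cache keys and for deriving per-item RNG streams.
# Both accumulators stay below 2^31 * 131 < 2^53, so double arithmetic is exact.
poly_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  m <- 2147483647 # 2^31 - 1
  h1 <- 17; h2 <- 41
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% m
    h2 <- (h2 * 131 + b) %% m
  }
  sprintf("%08x%08x", h1, h2)
}

# Integer seed in [0, 2^31 - 2] derived from a string and a base seed.
derive_seed <- function(key, seed) {
  bytes <- utf8ToInt(enc2utf8(key))
  m <- 2147483647
  h <- seed %% m
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# One deterministic uniform per (key, seed); leaves the global RNG untouched.
hashed_runif <- function(key, seed) {
  withr::with_seed(derive_seed(key, seed), runif(1L))
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s, got %s.",
                  name, format(min), paste(format(x), collapse = ", ")),
          class = "trialmatchr_config_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  invisible(df)
}

compact_chr <- function(x) {
  x <- trimws(x)
  x[nzchar(x)]
}

# Remove a surrounding markdown code fence (``` or ```json) if present.
strip_code_fence <- function(raw) {
  out <- trimws(raw)
  out <- sub("^```[a-zA-Z]*\\s*", "", out)
  out <- sub("\\s*```$", "", out)
  out
}
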