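# Internal utilities shared across modules.

# Derive a reproducible substream seed from a master seed and an integer
# offset; result always fits a 32-bit R integer.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + (as.numeric(offset) %% 65521) * 104729
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# md5 of an arbitrary R object via its version-2 serialization.
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
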