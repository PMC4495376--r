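# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage index, kept inside the
# 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k)) %% 2147483647)
}

stop_data <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_data(what, " must be a single non-empty string")
  }
  x
}

# Stable rank of ids under the C collation, used for deterministic
# tie-breaking independent of the session locale.
id_rank <- function(ids) {
  r <- integer(length(ids))
  r[order(ids, method = "radix")] <- seq_along(ids)
  r
}
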